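#!/usr/bin/env Rscript
# Thin command-line front end over the hobdcs package.
#
#   Rscript scripts/hobdcs.R simulate-cohort --preset paper-effects \
#       --n 14,28,40 --seed 1 --out cohort_dir/
#   Rscript scripts/hobdcs.R run-hob --traces cohort_dir/ \
#       --subjects cohort_dir/subjects.csv --out endpoints.csv
#   Rscript scripts/hobdcs.R stats --endpoints endpoints.csv \
#       --subjects cohort_dir/subjects.csv --seed 1 --out report.json
#   Rscript scripts/hobdcs.R full-run --seed 1 --out run_dir/ [--fast]

suppressPackageStartupMessages({
  library(hobdcs)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L)
  stop("usage: hobdcs.R <simulate-cohort|fit-bfi|run-hob|stats|full-run> [options]",
       call. = FALSE)
cmd <- argv[[1L]]
rest <- argv[-1L]

opts_spec <- list(
  make_option("--preset", default = "paper-effects"),
  make_option("--n", default = "14,28,40", help = "control,mild,modsev"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", default = "out"),
  make_option("--traces", default = NULL),
  make_option("--subjects", default = NULL),
  make_option("--endpoints", default = NULL),
  make_option("--curves", default = NULL),
  make_option("--protocol", default = NULL,
              help = "protocol YAML (default: built-in 0/30/0 protocol)"),
  make_option("--fast", action = "store_true", default = FALSE,
              help = "skip per-curve BFI fitting in full-run"),
  make_option("--verbose", action = "store_true", default = FALSE)
)
opt <- parse_args(OptionParser(option_list = opts_spec), args = rest)
sizes <- as.integer(strsplit(opt$n, ",")[[1L]])
protocol <- if (is.null(opt$protocol)) hob_protocol() else read_protocol_yaml(opt$protocol)

status <- tryCatch({
  switch(cmd,
    "simulate-cohort" = {
      coh <- synth_cohort(opt$preset, sizes[1L], sizes[2L], sizes[3L],
                          seed = opt$seed, protocol = protocol)
      write_cohort(coh, opt$out)
      message("cohort written to ", opt$out)
    },
    "fit-bfi" = {
      # fit every curve in a long-format curve CSV to a BFI trace per subject
      if (is.null(opt$curves)) stop("--curves required", call. = FALSE)
      curves <- read_curves(opt$curves)
      preset <- load_effect_preset(opt$preset)
      props <- hobdcs:::preset_optics(preset)
      geom <- hobdcs:::preset_geometry(preset)
      rows <- lapply(names(curves), function(sid) {
        ests <- lapply(curves[[sid]], fit_bfi, props = props, geom = geom)
        data.frame(subject_id = sid,
                   t_mid_s = vapply(curves[[sid]], function(cv) cv$t_mid,
                                    numeric(1)),
                   bfi = vapply(ests, function(e) e$bfi, numeric(1)),
                   converged = vapply(ests, function(e) e$converged,
                                      logical(1)))
      })
      utils::write.csv(do.call(rbind, rows), opt$out, row.names = FALSE)
      message("fitted traces written to ", opt$out)
    },
    "run-hob" = {
      if (is.null(opt$traces) || is.null(opt$subjects))
        stop("--traces and --subjects required", call. = FALSE)
      subjects <- read_subject_table(opt$subjects)$subjects
      traces <- read_traces(opt$traces)
      ep <- cohort_endpoints(subjects, traces, protocol)
      utils::write.csv(ep, opt$out, row.names = FALSE)
      message("endpoints written to ", opt$out)
    },
    "stats" = {
      if (is.null(opt$endpoints) || is.null(opt$subjects))
        stop("--endpoints and --subjects required", call. = FALSE)
      ep <- utils::read.csv(opt$endpoints,
                            colClasses = c(subject_id = "character"))
      subjects <- read_subject_table(opt$subjects)$subjects
      report <- analyze_cohort(ep, subjects, seed = opt$seed)
      jsonlite::write_json(report, opt$out, auto_unbox = TRUE, digits = 10,
                           pretty = TRUE, force = TRUE)
      message("report written to ", opt$out)
    },
    "full-run" = {
      res <- full_pipeline(run_config(
        preset = opt$preset, n_control = sizes[1L], n_mild = sizes[2L],
        n_modsev = sizes[3L], seed = opt$seed, out_dir = opt$out,
        fit_curves = !opt$fast, verbose = opt$verbose))
      print(res)
    },
    stop("unknown command: ", cmd, call. = FALSE)
  )
  0L
}, error = function(e) {
  message("[", cmd, "] error: ", conditionMessage(e))
  1L
})
quit(status = status)
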