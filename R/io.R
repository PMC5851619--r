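# Plain-text I/O: long-format CSV for g2 curves, CSV subject tables and
# traces, YAML configuration blocks.

fmt17 <- function(x) formatC(x, digits = 17, format = "g")

#' Write g2 curves to a long-format CSV
#'
#' One row per lag, columns `subject_id`, `t_mid_s`, `tau_s`, `g2`. Values
#' are written with 17 significant digits so that [read_curves()]
#' round-trips doubles bit-exactly.
#'
#' @param curves Named list (by subject id) of lists of [autocorr_curve()]
#'   objects, or a single list of curves for one subject.
#' @param path Output CSV path.
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "autocorr_curve")) curves <- list(list(curves))
  if (length(curves) && inherits(curves[[1L]], "autocorr_curve"))
    curves <- list(subject = curves)
  rows <- list()
  k <- 1L
  for (sid in names(curves)) {
    for (cv in curves[[sid]]) {
      rows[[k]] <- data.frame(subject_id = sid,
                              t_mid_s = fmt17(cv$t_mid),
                              tau_s = fmt17(cv$tau),
                              g2 = fmt17(cv$g2),
                              stringsAsFactors = FALSE)
      k <- k + 1L
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read g2 curves from a long-format CSV
#'
#' @param path CSV written by [write_curves()] (columns `subject_id`,
#'   `t_mid_s`, `tau_s`, `g2`).
#' @return Named list by subject id; each element a list of
#'   [autocorr_curve()] ordered by acquisition time.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "t_mid_s", "tau_s", "g2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("curve file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (sid in unique(df$subject_id)) {
    sub <- df[df$subject_id == sid, ]
    out[[sid]] <- lapply(split(sub, sub$t_mid_s)[
      order(as.numeric(names(split(sub, sub$t_mid_s))))], function(s)
        autocorr_curve(as.numeric(s$tau_s), as.numeric(s$g2),
                       t_mid = as.numeric(s$t_mid_s[1L])))
    names(out[[sid]]) <- NULL
  }
  out
}

subject_table_columns <- c(
  "subject_id", "group", "age", "sex", "bmi", "epworth", "aht", "smoker",
  "diabetes", "dyslipidemia", "ahi", "mean_spo2", "ct90", "odi4")

#' Read and validate a subject metadata table
#'
#' Expects the standard cohort schema (id, severity group, demographics,
#' sleep-study metrics). Categorical fields are coerced to 0/1; rows with
#' physically impossible values (e.g. SpO2 > 100) are flagged, not dropped.
#'
#' @param path CSV path with the columns listed in the schema.
#' @return A list: `subjects` (typed data.frame) and `flags` (data.frame of
#'   row-level validation messages, zero rows when clean).
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  miss <- setdiff(subject_table_columns, names(df))
  if (length(miss))
    stop("subject table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  to01 <- function(v) {
    if (is.numeric(v)) return(as.integer(v != 0))
    as.integer(tolower(as.character(v)) %in% c("1", "yes", "true", "male", "m"))
  }
  for (col in c("sex", "aht", "smoker", "diabetes", "dyslipidemia"))
    df[[col]] <- to01(df[[col]])
  for (col in c("age", "bmi", "epworth", "ahi", "mean_spo2", "ct90", "odi4"))
    df[[col]] <- as.numeric(df[[col]])

  flags <- list()
  flag <- function(i, msg) flags[[length(flags) + 1L]] <<-
    data.frame(subject_id = df$subject_id[i], message = msg,
               stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    if (is.finite(df$mean_spo2[i]) && df$mean_spo2[i] > 100)
      flag(i, "mean_spo2 > 100")
    if (is.finite(df$ahi[i]) && df$ahi[i] < 0) flag(i, "negative ahi")
    if (!df$group[i] %in% c("control", "mild", "moderate_severe"))
      flag(i, paste0("unknown group '", df$group[i], "'"))
  }
  flags <- if (length(flags)) do.call(rbind, flags)
  else data.frame(subject_id = character(0), message = character(0))
  list(subjects = df, flags = flags)
}

#' Write a cohort's subject table and traces
#'
#' Writes `subjects.csv` plus one `traces/<subject_id>.csv` (columns `t_s`,
#' `bfi`) per subject, and a provenance JSON with the resolved preset.
#'
#' @param cohort A [synth_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$effects, file.path(dir, "true_effects.csv"),
                   row.names = FALSE, quote = FALSE)
  for (sid in names(cohort$traces)) {
    tr <- cohort$traces[[sid]]
    utils::write.csv(
      data.frame(t_s = fmt17(tr$t), bfi = fmt17(tr$bfi)),
      file.path(dir, "traces", paste0(sid, ".csv")),
      row.names = FALSE, quote = FALSE)
  }
  prov <- unclass(cohort$preset)
  prov$seed <- cohort$seed
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read traces written by [write_cohort()]
#'
#' @param dir Directory containing `traces/*.csv`.
#' @return Named list of [bfi_trace()] keyed by subject id.
#' @export
read_traces <- function(dir) {
  files <- list.files(file.path(dir, "traces"), pattern = "\\.csv$",
                      full.names = TRUE)
  out <- lapply(files, function(f) {
    df <- utils::read.csv(f)
    bfi_trace(as.numeric(df$t_s), as.numeric(df$bfi))
  })
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Read an optics/geometry YAML configuration
#'
#' Expects a top-level `optics:` block with fields `mua`, `musp`,
#' `n_tissue`, `n_outside`, `wavelength_nm`, `rho_cm`.
#'
#' @param path YAML file path.
#' @return List with `props` ([optical_properties()]) and `geom`
#'   ([dcs_geometry()]).
#' @export
read_optics_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  o <- if (!is.null(y$optics)) y$optics else y
  list(props = optical_properties(mua = o$mua, musp = o$musp,
                                  n_tissue = o$n_tissue,
                                  n_outside = o$n_outside,
                                  wavelength = o$wavelength_nm),
       geom = dcs_geometry(rho = o$rho_cm))
}

#' Read a head-of-bed protocol YAML
#'
#' Mirrors the [hob_protocol()] fields: a `stages` list (each with `label`,
#' `angle`, `start`, `duration`) plus `transition_max`, `exclude_head`,
#' `exclude_tail`.
#'
#' @param path YAML file path.
#' @return A [hob_protocol()].
#' @export
read_protocol_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stages <- do.call(rbind, lapply(y$stages, function(s)
    data.frame(label = s$label, angle = s$angle, start = s$start,
               duration = s$duration)))
  hob_protocol(stages,
               transition_max = y$transition_max %||% 30,
               exclude_head = y$exclude_head %||% 60,
               exclude_tail = y$exclude_tail %||% 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
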