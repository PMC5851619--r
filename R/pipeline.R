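# End-to-end pipeline: simulate -> synthesise curves -> fit BFI -> stage
# windows -> endpoints -> cohort statistics.

#' Fit a measured BFI trace from per-timepoint g2 curves
#'
#' For each sample of a true BFI trajectory lying inside an analysis window,
#' synthesises a noisy g2 curve with the forward model and inverts it with
#' [fit_bfi()], producing the "measured" trace the windowing stage consumes.
#' Samples outside the analysis windows are skipped: the exclusion windows
#' guarantee they cannot influence any endpoint.
#'
#' @param trace True [bfi_trace()].
#' @param protocol [hob_protocol()] defining the analysis windows.
#' @param props,geom Optics and geometry.
#' @param beta_coh Coherence factor used for synthesis.
#' @param noise [noise_spec()] for the per-curve noise.
#' @param tau_grid Lag grid.
#' @param fit_opts [fit_options()] for the inversion.
#' @return A [bfi_trace()] of fitted values (quality mask marks
#'   non-converged fits).
#' @export
fit_trace_from_curves <- function(trace, protocol = hob_protocol(),
                                  props = optical_properties(),
                                  geom = dcs_geometry(), beta_coh = 0.5,
                                  noise = noise_spec(),
                                  tau_grid = default_tau_grid(),
                                  fit_opts = fit_options()) {
  win <- stage_windows(protocol)
  in_any <- rep(FALSE, length(trace$t))
  for (i in seq_len(nrow(win)))
    in_any <- in_any | (trace$t >= win$win_start[i] & trace$t < win$win_end[i])
  idx <- which(in_any)
  t_out <- trace$t[idx]
  bfi_out <- numeric(length(idx))
  ok <- logical(length(idx))
  for (j in seq_along(idx)) {
    cv <- synth_curve(trace$bfi[idx[j]], beta_coh, props, geom, noise,
                      tau_grid, t_mid = t_out[j])
    est <- fit_bfi(cv, props, geom, fit_opts)
    bfi_out[j] <- est$bfi
    ok[j] <- est$converged
  }
  bfi_trace(t_out, bfi_out, quality = ok & bfi_out >= 0)
}

#' Cohort statistics report
#'
#' Runs the statistics battery on a table of per-subject endpoints joined
#' with subject metadata: omnibus/pairwise group comparisons of both
#' endpoints, per-group recovery-to-baseline tests, cohort medians with
#' bootstrap CIs, Spearman correlations of the recovery endpoint with the
#' sleep metrics, and the forward-stepwise linear model of recovery (all
#' subjects and patients-only). `ln(AHI + 0.5)` is offered among the
#' stepwise candidates so zero-AHI controls remain admissible.
#'
#' @param endpoints Endpoint table from [cohort_endpoints()].
#' @param subjects Subject metadata table.
#' @param seed Seed for the bootstrap CIs.
#' @param alpha_in Stepwise entry threshold.
#' @return A nested list report (class `cohort_report`).
#' @export
analyze_cohort <- function(endpoints, subjects, seed = 1L, alpha_in = 0.05) {
  d <- merge(endpoints[endpoints$ok, ], subjects, by = "subject_id",
             suffixes = c("", ".meta"))
  if ("group.meta" %in% names(d)) d$group <- d$group.meta
  d$ln_ahi <- log(d$ahi + 0.5)
  patients <- d$group != "control"

  candidates <- c("ahi", "ln_ahi", "age", "sex", "smoker", "bmi", "aht",
                  "diabetes", "dyslipidemia", "ct90", "odi4", "epworth",
                  "mean_spo2")
  cand_tab <- d[, candidates]

  per_group_recovery <- lapply(split(d$rcbf_30_to_supine, d$group), function(v)
    c(baseline_recovery_test(v),
      list(median = stats::median(v),
           q1 = unname(stats::quantile(v, 0.25)),
           q3 = unname(stats::quantile(v, 0.75)))))

  quant_vars <- c("rcbf_30_to_supine", "rcbf_supine_to_30")
  correlations <- lapply(c("ahi", "mean_spo2", "ct90", "odi4", "bmi", "age"),
                         function(v) {
    r <- correlate(d$rcbf_30_to_supine, d[[v]])
    list(variable = v, rho = r$rho, p_value = r$p_value, n = r$n)
  })
  names(correlations) <- c("ahi", "mean_spo2", "ct90", "odi4", "bmi", "age")

  report <- list(
    n = list(total = nrow(d), by_group = as.list(table(d$group)),
             excluded = sum(!endpoints$ok)),
    drop = list(
      median_ci_all = median_ci(d$rcbf_supine_to_30, seed = seed),
      group_test = strip_fit(group_compare(d$rcbf_supine_to_30, d$group))),
    recovery = list(
      group_test = strip_fit(group_compare(d$rcbf_30_to_supine, d$group)),
      by_group = per_group_recovery,
      median_ci_modsev = if (any(d$group == "moderate_severe"))
        median_ci(d$rcbf_30_to_supine[d$group == "moderate_severe"],
                  seed = seed)),
    correlations = correlations,
    stepwise_all = strip_fit(stepwise_lm(d$rcbf_30_to_supine, cand_tab,
                                         alpha_in = alpha_in)),
    stepwise_patients = strip_fit(stepwise_lm(
      d$rcbf_30_to_supine[patients], cand_tab[patients, , drop = FALSE],
      alpha_in = alpha_in)),
    settings = list(seed = seed, alpha_in = alpha_in,
                    candidates = candidates)
  )
  class(report) <- c("cohort_report", "list")
  report
}

# drop the lm object so the report serialises cleanly to JSON
strip_fit <- function(x) {
  x$fit <- NULL
  x$medians <- as.list(x$medians)
  x$iqrs <- as.list(x$iqrs)
  if (!is.null(x$coefficients)) x$coefficients <- as.list(x$coefficients)
  if (!is.null(x$entry_p)) x$entry_p <- as.list(x$entry_p)
  unclass(x)
}

#' Run configuration for the full pipeline
#'
#' @param preset Preset name or path (see [load_effect_preset()]).
#' @param n_control,n_mild,n_modsev Group sizes.
#' @param seed Master seed controlling every random stage.
#' @param out_dir Optional output directory; when given, `endpoints.csv`,
#'   `subjects.csv`, `report.json` and `manifest.json` are written there.
#' @param fit_curves If `TRUE` (default) BFI is re-estimated from noisy
#'   synthetic g2 curves at every in-window timepoint; if `FALSE` the true
#'   trajectories are windowed directly (fast, skips the inverse problem).
#' @param alpha_in Stepwise entry threshold.
#' @param verbose Emit per-stage progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(preset = "paper-effects", n_control = 14,
                       n_mild = 28, n_modsev = 40, seed = 1L,
                       out_dir = NULL, fit_curves = TRUE,
                       alpha_in = 0.05, verbose = FALSE) {
  stopifnot(length(seed) == 1L, is.finite(seed), seed == round(seed))
  structure(list(preset = preset, n_control = n_control, n_mild = n_mild,
                 n_modsev = n_modsev, seed = as.integer(seed),
                 out_dir = out_dir, fit_curves = fit_curves,
                 alpha_in = alpha_in, verbose = verbose),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config)[setdiff(names(config), "out_dir")],
                       tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Run the full simulate-fit-window-statistics pipeline
#'
#' Generates a synthetic cohort from the preset, optionally re-estimates
#' every in-window BFI sample from a noisy synthetic g2 curve, computes the
#' per-subject rCBF endpoints, and runs the cohort statistics battery. The
#' whole run is deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_result`: `cohort`, `endpoints`,
#'   `report`, `config`, `config_hash`.
#' @export
#' @examples
#' \donttest{
#' res <- full_pipeline(run_config(n_control = 2, n_mild = 2, n_modsev = 2,
#'                                 seed = 7, fit_curves = FALSE))
#' res$endpoints
#' }
full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$verbose) message(...)
  preset <- load_effect_preset(config$preset)
  protocol <- hob_protocol()

  say("[simulate] cohort n = ", config$n_control, "/", config$n_mild, "/",
      config$n_modsev, ", seed ", config$seed)
  cohort <- synth_cohort(preset, config$n_control, config$n_mild,
                         config$n_modsev, seed = config$seed,
                         protocol = protocol)

  traces <- cohort$traces
  if (config$fit_curves) {
    props <- preset_optics(preset)
    geom <- preset_geometry(preset)
    nz <- preset$noise
    noise <- noise_spec(rel_scale = nz$rel_scale,
                        tau_exponent = nz$tau_exponent,
                        drift_sd = nz$drift_sd)
    say("[fit] inverting g2 curves for ", length(traces), " subjects")
    traces <- with_local_seed(config$seed + 500009L, {
      lapply(traces, fit_trace_from_curves, protocol = protocol,
             props = props, geom = geom, beta_coh = preset$beta_coh,
             noise = noise)
    })
    n_bad <- sum(vapply(traces, function(tr) sum(!tr$quality), integer(1)))
    say("[fit] non-converged samples: ", n_bad)
  }

  say("[hob] computing endpoints")
  endpoints <- suppressMessages(
    cohort_endpoints(cohort$subjects, traces, protocol))

  say("[stats] cohort statistics")
  report <- analyze_cohort(endpoints, cohort$subjects,
                           seed = config$seed, alpha_in = config$alpha_in)

  hash <- config_hash(config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(endpoints, file.path(config$out_dir, "endpoints.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$subjects,
                     file.path(config$out_dir, "subjects.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
    manifest <- list(config = unclass(config), config_hash = hash,
                     package_version = as.character(
                       utils::packageVersion("hobdcs")))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }

  structure(list(cohort = cohort, endpoints = endpoints, report = report,
                 config = config, config_hash = hash),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat("HOB-DCS pipeline result (seed ", x$config$seed, ", ",
      r$n$total, " subjects)\n", sep = "")
  cat(sprintf("  supine->30 median: %+.1f%% (95%% CI %.1f, %.1f)\n",
              r$drop$median_ci_all$median, r$drop$median_ci_all$ci_lower,
              r$drop$median_ci_all$ci_upper))
  if (!is.null(r$recovery$median_ci_modsev))
    cat(sprintf("  moderate/severe 30->supine median: %+.1f%%\n",
                r$recovery$median_ci_modsev$median))
  sel <- r$stepwise_all$selected
  cat("  stepwise (all): ",
      if (length(sel)) paste(sel, collapse = ", ") else "intercept only",
      "\n", sep = "")
  invisible(x)
}
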