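# Synthetic-data generator: noisy g2 curves, protocol-shaped BFI
# trajectories, and full cohorts with the statistical structure the
# downstream analysis assumes.

#' Noise specification for the generator
#'
#' @param rel_scale Relative noise amplitude on `g2 - 1` at the shortest lag.
#' @param tau_exponent Lag-dependence exponent: the per-lag noise SD grows as
#'   `(tau / tau_min)^tau_exponent`, capped at 10x `rel_scale` (photon
#'   correlation noise grows with lag).
#' @param drift_sd Slow physiological drift SD as a fraction of the baseline
#'   BFI (AR(1), ~2-min correlation time).
#' @param seed Optional RNG seed for reproducibility.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(rel_scale = 0.02, tau_exponent = 0.2,
                       drift_sd = 0.03, seed = NULL) {
  stopifnot(rel_scale >= 0, drift_sd >= 0)
  structure(list(rel_scale = rel_scale, tau_exponent = tau_exponent,
                 drift_sd = drift_sd, seed = seed),
            class = "noise_spec")
}

#' Per-subject generator truth for the head-of-bed response
#'
#' @param baseline_bfi Supine blood flow index (cm^2/s), positive.
#' @param drop_frac Fractional BFI change supine -> 30 degrees (signed,
#'   e.g. -0.175), in (-1, 1).
#' @param recovery_offset_frac Residual fractional offset on return to
#'   supine, in (-1, 1).
#' @param transition_tc Exponential transition time constant (s).
#' @return A list of class `subject_effects`.
#' @export
subject_effects <- function(baseline_bfi = 1e-8, drop_frac = -0.175,
                            recovery_offset_frac = 0,
                            transition_tc = 10) {
  stopifnot(baseline_bfi > 0, transition_tc > 0,
            drop_frac > -1, drop_frac < 1,
            recovery_offset_frac > -1, recovery_offset_frac < 1)
  structure(list(baseline_bfi = baseline_bfi, drop_frac = drop_frac,
                 recovery_offset_frac = recovery_offset_frac,
                 transition_tc = transition_tc),
            class = "subject_effects")
}

# run expr with a locally-seeded RNG, restoring the caller's RNG state;
# a NULL seed uses (and advances) the global stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a noisy intensity autocorrelation curve
#'
#' Forward model plus multiplicative noise on the decaying part:
#' `g2 = 1 + (g2_clean - 1) * (1 + eps(tau))` with `eps` zero-mean Gaussian,
#' SD `rel_scale * min((tau/tau_min)^tau_exponent, 10)`.
#'
#' @param bfi True blood flow index (cm^2/s).
#' @param beta_coh Coherence factor.
#' @param props,geom Optics and geometry, see [optical_properties()] and
#'   [dcs_geometry()].
#' @param noise A [noise_spec()]; with `rel_scale = 0` the output equals the
#'   forward model exactly. Deterministic given `noise$seed`.
#' @param tau_grid Lag grid (s).
#' @param t_mid,t_avg Acquisition timestamp and averaging duration (s).
#' @return An [autocorr_curve()].
#' @export
synth_curve <- function(bfi, beta_coh = 0.5, props = optical_properties(),
                        geom = dcs_geometry(), noise = noise_spec(),
                        tau_grid = default_tau_grid(),
                        t_mid = NA_real_, t_avg = 3) {
  g1 <- g1_semi_infinite(tau_grid, props, geom, bfi)
  g2c <- g2_from_g1(g1, beta_coh)
  g2 <- with_local_seed(noise$seed, {
    if (noise$rel_scale > 0) {
      sdv <- noise$rel_scale *
        pmin((tau_grid / tau_grid[1L])^noise$tau_exponent, 10)
      1 + (g2c - 1) * (1 + stats::rnorm(length(tau_grid), 0, sdv))
    } else g2c
  })
  autocorr_curve(tau_grid, g2, t_mid = t_mid, t_avg = t_avg)
}

# plateau flow level per protocol stage for a subject's effects: initial
# supine = baseline; elevated stages = drop level; later supine stages =
# recovery level
stage_plateaus <- function(protocol, eff) {
  a <- protocol$stages$angle
  lev <- numeric(length(a))
  for (i in seq_along(a)) {
    lev[i] <- if (i == 1L) eff$baseline_bfi
    else if (a[i] != 0) eff$baseline_bfi * (1 + eff$drop_frac)
    else eff$baseline_bfi * (1 + eff$recovery_offset_frac)
  }
  lev
}

#' Simulate a protocol-shaped BFI trajectory
#'
#' Piecewise-constant plateaus at the per-stage levels implied by the
#' subject's effects, sampled every `dt` seconds. Posture transitions decay
#' exponentially (time constant `eff$transition_tc`) strictly inside the
#' between-stage gaps, so stage plateaus are exact by construction. Additive
#' slow drift noise (AR(1)) is scaled by `noise$drift_sd`.
#'
#' @param protocol A [hob_protocol()].
#' @param eff A [subject_effects()].
#' @param noise A [noise_spec()]; deterministic given `noise$seed`.
#' @param dt Sampling interval (s), default 3.
#' @return A [bfi_trace()].
#' @export
synth_bfi_trajectory <- function(protocol = hob_protocol(),
                                 eff = subject_effects(),
                                 noise = noise_spec(), dt = 3) {
  stopifnot(inherits(protocol, "hob_protocol"),
            inherits(eff, "subject_effects"))
  st <- protocol$stages
  ends <- st$start + st$duration
  total <- ends[nrow(st)]
  t <- seq(dt / 2, total - dt / 2, by = dt)
  plat <- stage_plateaus(protocol, eff)

  level <- numeric(length(t))
  for (j in seq_along(t)) {
    tj <- t[j]
    i_stage <- which(tj >= st$start & tj < ends)
    if (length(i_stage) == 1L) {
      level[j] <- plat[i_stage]
    } else {
      # in a transition gap (or before/after the protocol)
      i_prev <- which(ends <= tj)
      if (length(i_prev) == 0L) level[j] <- plat[1L]
      else if (max(i_prev) == nrow(st)) level[j] <- plat[nrow(st)]
      else {
        i <- max(i_prev)
        level[j] <- plat[i + 1L] +
          (plat[i] - plat[i + 1L]) * exp(-(tj - ends[i]) / eff$transition_tc)
      }
    }
  }

  bfi <- with_local_seed(noise$seed, {
    if (noise$drift_sd > 0) {
      phi <- exp(-dt / 120)  # ~2-min drift correlation time
      sd_st <- noise$drift_sd * eff$baseline_bfi
      innov <- stats::rnorm(length(t), 0, sd_st * sqrt(1 - phi^2))
      drift <- stats::filter(innov, phi, method = "recursive",
                             init = stats::rnorm(1, 0, sd_st))
      pmax(level + as.numeric(drift), 1e-12)
    } else level
  })
  bfi_trace(t, bfi)
}

# --- preset handling -------------------------------------------------------

# location calibration: mu such that the median of the [lo, hi]-truncated
# Normal(mu, sd) equals m (on the log scale for log-normals)
calibrate_trunc_location <- function(m, sd, lo, hi) {
  if (sd <= 0) return(m)
  f <- function(mu) {
    p <- (stats::pnorm(lo, mu, sd) + stats::pnorm(hi, mu, sd)) / 2
    mu + sd * stats::qnorm(p) - m
  }
  stats::uniroot(f, interval = c(m - 6 * sd, m + 6 * sd), tol = 1e-10)$root
}

r_trunc_norm <- function(n, mu, sd, lo, hi) {
  if (sd <= 0) return(rep(mu, n))
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

# one sleep metric: truncated normal or log-normal matched to median/IQR,
# with optional zero-inflation
sample_metric <- function(n, spec) {
  p0 <- if (is.null(spec$p_zero)) 0 else spec$p_zero
  if (spec$dist == "normal") {
    sd <- (spec$q3 - spec$q1) / 1.349
    mu <- calibrate_trunc_location(spec$median, sd, spec$lower, spec$upper)
    x <- r_trunc_norm(n, mu, sd, spec$lower, spec$upper)
  } else if (spec$dist == "lognormal") {
    sd <- (log(spec$q3) - log(spec$q1)) / 1.349
    mu <- calibrate_trunc_location(log(spec$median), sd,
                                   log(spec$lower), log(spec$upper))
    x <- exp(r_trunc_norm(n, mu, sd, log(spec$lower), log(spec$upper)))
  } else stop("unknown distribution family: ", spec$dist, call. = FALSE)
  if (p0 > 0) x[stats::runif(n) < p0] <- 0
  if (!is.null(spec$round)) x <- round(x, spec$round)
  x
}

#' Load an effect preset
#'
#' Presets bundle the generator parameters: per-group sleep-metric
#' distributions, group effect sizes, the SpO2-recovery coupling, noise
#' levels, optics and the coherence factor. The shipped `"paper-effects"`
#' preset encodes the effect sizes of the OSA head-of-bed study the package
#' models.
#'
#' @param preset `"paper-effects"` or a path to a preset YAML file.
#' @return A list of class `effect_preset`.
#' @export
load_effect_preset <- function(preset = "paper-effects") {
  path <- if (file.exists(preset)) preset
  else system.file("extdata", paste0("preset-", preset, ".yaml"),
                   package = "hobdcs")
  if (!nzchar(path) || !file.exists(path))
    stop("preset not found: ", preset, call. = FALSE)
  p <- yaml::read_yaml(path)
  stopifnot(all(c("groups", "effects", "noise") %in% names(p)))
  p$source_path <- path
  structure(p, class = "effect_preset")
}

preset_optics <- function(preset) {
  o <- preset$optics
  optical_properties(mua = o$mua, musp = o$musp, n_tissue = o$n_tissue,
                     n_outside = o$n_outside, wavelength = o$wavelength_nm)
}

preset_geometry <- function(preset) dcs_geometry(rho = preset$optics$rho_cm)

#' Simulate a full cohort
#'
#' Draws per-group demographics and sleep metrics from the preset
#' distributions, assigns every subject a head-of-bed response (baseline
#' BFI, supine-to-30 drop, back-to-supine recovery offset), and synthesises
#' the corresponding BFI trajectories. The supine-to-30 drop is
#' group-independent; the recovery offset follows one linear coupling to
#' mean nocturnal SpO2 shared by all subjects
#' (`recovery% = intercept + slope * SpO2 + noise`), so OSA severity acts
#' on recovery only through its effect on nocturnal saturation.
#'
#' @param preset An [load_effect_preset()] object or preset name.
#' @param n_control,n_mild,n_modsev Group sizes (default 14 / 28 / 40).
#' @param seed RNG seed; the whole cohort is deterministic given the seed.
#' @param protocol A [hob_protocol()].
#' @param traces If `TRUE` (default) also synthesise per-subject BFI
#'   trajectories.
#' @return A list of class `synth_cohort`: `subjects` (data.frame in the
#'   subject-table schema), `effects` (per-subject generator truth), and
#'   `traces` (named list of [bfi_trace()], if requested).
#' @export
#' @examples
#' coh <- synth_cohort(n_control = 3, n_mild = 3, n_modsev = 3, seed = 1)
#' table(coh$subjects$group)
synth_cohort <- function(preset = "paper-effects", n_control = 14,
                         n_mild = 28, n_modsev = 40, seed = NULL,
                         protocol = hob_protocol(), traces = TRUE) {
  if (is.character(preset)) preset <- load_effect_preset(preset)
  stopifnot(inherits(preset, "effect_preset"))
  sizes <- c(control = n_control, mild = n_mild, moderate_severe = n_modsev)
  if (any(sizes < 0) || any(sizes != round(sizes)))
    stop("group sizes must be non-negative integers", call. = FALSE)

  with_local_seed(seed, {
    rows <- list()
    for (g in names(sizes)) {
      n <- sizes[[g]]
      if (n == 0L) next
      gs <- preset$groups[[g]]
      df <- data.frame(
        group = rep(g, n),
        sex = stats::rbinom(n, 1, gs$male_frac),
        aht = stats::rbinom(n, 1, gs$aht_frac),
        smoker = stats::rbinom(n, 1, gs$smoker_frac),
        diabetes = stats::rbinom(n, 1, gs$diabetes_frac),
        dyslipidemia = stats::rbinom(n, 1, gs$dyslipidemia_frac)
      )
      for (m in names(gs$metrics)) df[[m]] <- sample_metric(n, gs$metrics[[m]])
      rows[[g]] <- df
    }
    subjects <- do.call(rbind, rows)
    n_tot <- nrow(subjects)
    subjects <- cbind(subject_id = sprintf("S%03d", seq_len(n_tot)), subjects)
    rownames(subjects) <- NULL

    ef <- preset$effects
    baseline <- ef$baseline_bfi$median *
      exp(stats::rnorm(n_tot, 0, ef$baseline_bfi$sigma_log))
    drop <- pmin(pmax(stats::rnorm(n_tot, ef$drop_frac$mean,
                                   ef$drop_frac$sd), -0.9), 0.9)
    rec <- ef$recovery
    rec_pct <- rec$intercept + rec$slope * subjects$mean_spo2 +
      stats::rnorm(n_tot, 0, rec$residual_sd)
    recovery <- pmin(pmax(rec_pct / 100, -0.9), 0.9)

    effects <- data.frame(
      subject_id = subjects$subject_id,
      baseline_bfi = baseline,
      drop_frac = drop,
      recovery_offset_frac = recovery,
      stringsAsFactors = FALSE
    )

    trace_list <- NULL
    if (traces) {
      nz <- preset$noise
      trace_list <- vector("list", n_tot)
      names(trace_list) <- subjects$subject_id
      for (i in seq_len(n_tot)) {
        eff_i <- subject_effects(baseline[i], drop[i], recovery[i],
                                 transition_tc = ef$transition_tc)
        trace_list[[i]] <- synth_bfi_trajectory(
          protocol, eff_i,
          noise_spec(rel_scale = nz$rel_scale,
                     tau_exponent = nz$tau_exponent,
                     drift_sd = nz$drift_sd))
      }
    }

    structure(list(subjects = subjects, effects = effects,
                   traces = trace_list, preset = preset,
                   protocol = protocol, seed = seed),
              class = "synth_cohort")
  })
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects (")
  cat(paste(names(table(x$subjects$group)), table(x$subjects$group),
            sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Simulate a pre/post-CPAP follow-up arm
#'
#' Selects severe-OSA subjects (AHI > 30) from a synthetic cohort and pairs
#' their pre-treatment recovery offsets with post-treatment offsets drawn
#' from the preset's zero-centred post-CPAP distribution (long-term CPAP
#' normalises the recovery response).
#'
#' @param cohort A [synth_cohort()].
#' @param n Number of followed-up subjects (default 13).
#' @param seed RNG seed.
#' @return data.frame with `subject_id`, `pre` and `post` recovery offsets
#'   in percent.
#' @export
synth_cpap_followup <- function(cohort, n = 13, seed = NULL) {
  stopifnot(inherits(cohort, "synth_cohort"))
  severe <- cohort$subjects$subject_id[cohort$subjects$ahi > 30]
  if (length(severe) < n)
    stop("cohort has only ", length(severe), " severe subjects", call. = FALSE)
  cp <- cohort$preset$effects$cpap_post_recovery
  with_local_seed(seed, {
    ids <- sample(severe, n)
    pre <- 100 * cohort$effects$recovery_offset_frac[
      match(ids, cohort$effects$subject_id)]
    post <- stats::rnorm(n, cp$mean, cp$sd)
    data.frame(subject_id = ids, pre = pre, post = post,
               stringsAsFactors = FALSE)
  })
}
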