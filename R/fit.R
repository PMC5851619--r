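#' Select the early-decay portion of a g2 curve
#'
#' Fitting only the early lags of the intensity autocorrelation raises the
#' relative sensitivity of the blood flow index to the brain versus the
#' scalp. The rule implemented here keeps the contiguous prefix of the lag
#' grid up to (and excluding) the first lag at which the normalised decay
#' `(g2 - 1) / beta_coh` has fallen below `decay_fraction`.
#'
#' @param curve An [autocorr_curve()].
#' @param beta_coh Coherence factor used to normalise the decay.
#' @param decay_fraction Threshold in `[0, 1)`; `0` disables the cut and
#'   selects the whole grid.
#' @return Logical mask over the lag grid; never empty (if the whole curve
#'   sits below the threshold the first lag alone is kept, with a warning).
#' @export
select_early_lags <- function(curve, beta_coh, decay_fraction = 0.3) {
  stopifnot(inherits(curve, "autocorr_curve"))
  if (!is.numeric(decay_fraction) || length(decay_fraction) != 1L ||
      decay_fraction < 0 || decay_fraction >= 1)
    stop("'decay_fraction' must be in [0, 1)", call. = FALSE)
  n <- length(curve$tau)
  if (decay_fraction == 0) return(rep(TRUE, n))
  decay <- (curve$g2 - 1) / beta_coh
  below <- which(decay < decay_fraction)
  mask <- rep(FALSE, n)
  if (length(below) == 0L) {
    mask[] <- TRUE
  } else if (below[1L] == 1L) {
    warning("entire curve below the decay threshold; keeping first lag only",
            call. = FALSE)
    mask[1L] <- TRUE
  } else {
    mask[seq_len(below[1L] - 1L)] <- TRUE
  }
  mask
}

#' Fit a blood flow index to an intensity autocorrelation curve
#'
#' Least-squares inversion of the semi-infinite correlation diffusion model
#' through the Siegert relation: minimises
#' `sum((1 + beta_coh * g1(tau; bfi)^2 - g2_obs(tau))^2)` over the selected
#' lags. By default the coherence factor is fitted jointly with the flow
#' index; it can be fixed via `fix_beta`. Optimisation uses bounded
#' Levenberg-Marquardt with an analytic Jacobian, with log-spaced
#' multi-starts on the flow index if the first start fails to converge.
#'
#' @param curve An [autocorr_curve()]. NA lags are dropped.
#' @param props [optical_properties()].
#' @param geom [dcs_geometry()].
#' @param fit_opts A list of options, see [fit_options()].
#'
#' @return An object of class `bfi_estimate`: a list with `bfi` (cm^2/s),
#'   `beta_coh`, `residual` (sum of squared residuals over fitted lags),
#'   `n_lags_used`, and a logical `converged`.
#' @export
#' @examples
#' props <- optical_properties(); geom <- dcs_geometry()
#' tau <- default_tau_grid()
#' g2 <- g2_from_g1(g1_semi_infinite(tau, props, geom, 1e-8), 0.5)
#' fit_bfi(autocorr_curve(tau, g2), props, geom)
fit_bfi <- function(curve, props, geom, fit_opts = fit_options()) {
  stopifnot(inherits(curve, "autocorr_curve"))
  keep <- is.finite(curve$g2) & is.finite(curve$tau)
  if (!any(keep)) stop("no finite samples in curve", call. = FALSE)
  tau <- curve$tau[keep]
  g2o <- curve$g2[keep]

  # initial coherence factor from the zero-lag intercept of the data
  beta0 <- if (is.null(fit_opts$beta_fixed)) {
    min(max(max(g2o) - 1, 1e-3), 1)
  } else fit_opts$beta_fixed

  mask <- if (fit_opts$decay_fraction > 0) {
    m <- suppressWarnings(
      select_early_lags(autocorr_curve(tau, g2o), beta0,
                        fit_opts$decay_fraction))
    m
  } else rep(TRUE, length(tau))
  tau_f <- tau[mask]
  g2_f <- g2o[mask]

  sg <- semi_infinite_geometry(props, geom)
  k0 <- wavenumber(props)
  a_tau <- 6 * props$musp^2 * k0^2 * tau_f   # K^2 = k00sq + a_tau * bfi
  k00sq <- 3 * props$mua * props$musp
  den <- exp(-sqrt(k00sq) * sg$r1) / sg$r1 - exp(-sqrt(k00sq) * sg$r2) / sg$r2
  r1 <- sg$r1; r2 <- sg$r2

  g1_of <- function(bfi) {
    kk <- sqrt(k00sq + a_tau * bfi)
    (exp(-kk * r1) / r1 - exp(-kk * r2) / r2) / den
  }
  free_beta <- is.null(fit_opts$beta_fixed)

  resid_fn <- function(par) {
    bfi <- par[[1L]]
    beta <- if (free_beta) par[[2L]] else fit_opts$beta_fixed
    1 + beta * g1_of(bfi)^2 - g2_f
  }
  jac_fn <- function(par) {
    bfi <- par[[1L]]
    beta <- if (free_beta) par[[2L]] else fit_opts$beta_fixed
    kk <- sqrt(k00sq + a_tau * bfi)
    g1 <- (exp(-kk * r1) / r1 - exp(-kk * r2) / r2) / den
    dk <- a_tau / (2 * kk)
    dg1 <- (-exp(-kk * r1) + exp(-kk * r2)) * dk / den
    if (free_beta) cbind(2 * beta * g1 * dg1, g1^2)
    else cbind(2 * beta * g1 * dg1)
  }

  starts <- fit_opts$bfi_init
  if (length(starts) == 1L) {
    starts <- c(starts, starts * c(0.1, 10))  # multi-start fallbacks
  }
  lower <- if (free_beta) c(0, 1e-6) else 0
  upper <- if (free_beta) c(Inf, 1) else Inf

  best <- NULL
  for (s in starts) {
    par0 <- if (free_beta) c(s, beta0) else s
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                         fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = fit_opts$maxiter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid_fn(fit$par)^2)
    conv <- fit$info %in% 1:4
    if (is.null(best) || ssr < best$ssr) {
      best <- list(par = fit$par, ssr = ssr, converged = conv)
    }
    if (conv) break
  }
  if (is.null(best)) {
    best <- list(par = if (free_beta) c(starts[1L], beta0) else starts[1L],
                 ssr = sum(resid_fn(if (free_beta) c(starts[1L], beta0)
                                    else starts[1L])^2),
                 converged = FALSE)
  }

  structure(list(
    bfi = max(best$par[[1L]], 0),
    beta_coh = if (free_beta) best$par[[2L]] else fit_opts$beta_fixed,
    residual = best$ssr,
    n_lags_used = length(tau_f),
    converged = best$converged
  ), class = "bfi_estimate")
}

#' Options for [fit_bfi()]
#'
#' @param decay_fraction Early-lag threshold passed to [select_early_lags()];
#'   0 fits the whole grid. Default 0.3.
#' @param beta_fixed If non-NULL, the coherence factor is held at this value
#'   instead of being fitted.
#' @param bfi_init Initial flow index (cm^2/s); additional log-spaced starts
#'   are tried automatically on non-convergence.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(decay_fraction = 0.3, beta_fixed = NULL,
                        bfi_init = 1e-8, maxiter = 100L) {
  if (!is.null(beta_fixed) &&
      (beta_fixed <= 0 || beta_fixed > 1))
    stop("'beta_fixed' must be in (0, 1]", call. = FALSE)
  stopifnot(bfi_init > 0)
  structure(list(decay_fraction = decay_fraction, beta_fixed = beta_fixed,
                 bfi_init = bfi_init, maxiter = as.integer(maxiter)),
            class = "fit_options")
}

#' @export
print.bfi_estimate <- function(x, ...) {
  cat(sprintf("BFI estimate: %.4g cm^2/s (beta = %.3f, SSR = %.3g, %d lags%s)\n",
              x$bfi, x$beta_coh, x$residual, x$n_lags_used,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
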