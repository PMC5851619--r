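#' Optical properties of the probed tissue
#'
#' Bundles the homogeneous-medium optical properties assumed by the
#' correlation diffusion model. Defaults are conventional adult-head values
#' at 785 nm; the absorption and reduced scattering coefficients are assumed
#' constants of the analysis, not fitted.
#'
#' @param mua Absorption coefficient (1/cm).
#' @param musp Reduced scattering coefficient (1/cm). The diffusion
#'   approximation requires `musp >> mua`; a warning is emitted when
#'   `musp / mua < 10`.
#' @param n_tissue Refractive index of the tissue.
#' @param n_outside Refractive index of the exterior medium (air).
#' @param wavelength Source wavelength in nm.
#'
#' @return An object of class `optical_properties`.
#' @export
#' @examples
#' optical_properties()
optical_properties <- function(mua = 0.1, musp = 10, n_tissue = 1.4,
                               n_outside = 1.0, wavelength = 785) {
  stopifnot(is.numeric(mua), length(mua) == 1L,
            is.numeric(musp), length(musp) == 1L,
            is.numeric(n_tissue), length(n_tissue) == 1L,
            is.numeric(n_outside), length(n_outside) == 1L,
            is.numeric(wavelength), length(wavelength) == 1L)
  if (!is.finite(mua) || mua <= 0) stop("'mua' must be positive", call. = FALSE)
  if (!is.finite(musp) || musp <= 0) stop("'musp' must be positive", call. = FALSE)
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("'wavelength' must be positive", call. = FALSE)
  if (n_tissue <= 0 || n_outside <= 0)
    stop("refractive indices must be positive", call. = FALSE)
  if (musp / mua < 10)
    warning("musp/mua < 10: diffusion approximation is questionable",
            call. = FALSE)
  structure(list(mua = mua, musp = musp, n_tissue = n_tissue,
                 n_outside = n_outside, wavelength = wavelength),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "Optical properties: mua = %g 1/cm, musp = %g 1/cm, n = %g/%g, lambda = %g nm\n",
    x$mua, x$musp, x$n_tissue, x$n_outside, x$wavelength))
  invisible(x)
}

#' Reflection-mode DCS measurement geometry
#'
#' @param rho Source-detector separation on the tissue surface (cm).
#'   Default 2.4 cm, a separation probing the adult cerebral cortex.
#' @return An object of class `dcs_geometry`.
#' @export
dcs_geometry <- function(rho = 2.4) {
  stopifnot(is.numeric(rho), length(rho) == 1L)
  if (!is.finite(rho) || rho <= 0) stop("'rho' must be positive", call. = FALSE)
  structure(list(rho = rho), class = "dcs_geometry")
}

#' In-medium optical wavenumber
#'
#' `k0 = 2 * pi * n_tissue / lambda` with the wavelength converted from nm
#' to cm, so the result is in 1/cm.
#'
#' @param props An [optical_properties()] object.
#' @return Wavenumber in 1/cm.
#' @export
#' @examples
#' wavenumber(optical_properties()) # ~1.12e5 1/cm at 785 nm in tissue
wavenumber <- function(props) {
  stopifnot(inherits(props, "optical_properties"))
  2 * pi * props$n_tissue / (props$wavelength * 1e-7)
}

# Effective reflection coefficient of the tissue-air boundary from the
# standard polynomial in the relative refractive index.
effective_reflection <- function(n_rel) {
  -1.440 / n_rel^2 + 0.710 / n_rel + 0.668 + 0.0636 * n_rel
}

# Geometry constants of the extrapolated-boundary semi-infinite solution:
# source depth z0, extrapolation length zb, and the two source-image
# distances r1, r2 for a surface detector at separation rho.
semi_infinite_geometry <- function(props, geom) {
  z0 <- 1 / props$musp
  reff <- effective_reflection(props$n_tissue / props$n_outside)
  zb <- 2 * (1 + reff) / (3 * props$musp * (1 - reff))
  r1 <- sqrt(geom$rho^2 + z0^2)
  r2 <- sqrt(geom$rho^2 + (z0 + 2 * zb)^2)
  list(z0 = z0, zb = zb, r1 = r1, r2 = r2)
}

#' Normalised field autocorrelation for a semi-infinite medium
#'
#' Evaluates the extrapolated-boundary solution of the correlation diffusion
#' equation for a point source on a homogeneous semi-infinite medium with
#' Brownian scatterer dynamics (mean-square displacement `6 * Db * tau`):
#'
#' \deqn{G_1(\rho,\tau) \propto \frac{e^{-K(\tau) r_1}}{r_1} -
#'       \frac{e^{-K(\tau) r_2}}{r_2}, \quad
#'       K(\tau) = \sqrt{3\mu_a\mu_s' + 6\mu_s'^2 k_0^2\, \alpha D_b\, \tau}}
#'
#' and returns `G1(tau) / G1(0)`, which decays from 1 and is monotonically
#' non-increasing in both `tau` and `bfi`.
#'
#' @param tau Lag times in seconds (non-negative, typically a log-spaced grid).
#' @param props [optical_properties()].
#' @param geom [dcs_geometry()].
#' @param bfi Blood flow index `alpha * Db` in cm^2/s (non-negative).
#'
#' @return Numeric vector of g1 values in (0, 1].
#' @export
#' @examples
#' g1_semi_infinite(c(1e-6, 1e-5, 1e-4), optical_properties(), dcs_geometry(),
#'                  bfi = 1e-8)
g1_semi_infinite <- function(tau, props, geom, bfi) {
  stopifnot(inherits(props, "optical_properties"), inherits(geom, "dcs_geometry"))
  if (!is.numeric(bfi) || length(bfi) != 1L || !is.finite(bfi) || bfi < 0)
    stop("'bfi' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(tau) || any(!is.finite(tau)) || any(tau < 0))
    stop("'tau' must be finite and non-negative", call. = FALSE)
  sg <- semi_infinite_geometry(props, geom)
  k0 <- wavenumber(props)
  kk <- sqrt(3 * props$mua * props$musp +
               6 * props$musp^2 * k0^2 * bfi * tau)
  k00 <- sqrt(3 * props$mua * props$musp)
  num <- exp(-kk * sg$r1) / sg$r1 - exp(-kk * sg$r2) / sg$r2
  den <- exp(-k00 * sg$r1) / sg$r1 - exp(-k00 * sg$r2) / sg$r2
  num / den
}

#' Siegert relation
#'
#' Maps a field autocorrelation to the measured intensity autocorrelation,
#' `g2 = 1 + beta_coh * g1^2`, where `beta_coh` is the coherence factor set
#' by the detection optics (the intercept of `g2 - 1` at zero lag).
#'
#' @param g1 Field autocorrelation values.
#' @param beta_coh Coherence factor in (0, 1].
#' @return Intensity autocorrelation values.
#' @export
g2_from_g1 <- function(g1, beta_coh) {
  if (!is.numeric(beta_coh) || length(beta_coh) != 1L ||
      !is.finite(beta_coh) || beta_coh <= 0 || beta_coh > 1)
    stop("'beta_coh' must be in (0, 1]", call. = FALSE)
  1 + beta_coh * g1^2
}

#' Default logarithmic lag grid
#'
#' Multi-tau-like log-spaced lag grid, 1e-7 s to 1e-2 s, 128 points.
#'
#' @param tau_min,tau_max Grid limits in seconds.
#' @param n Number of lags.
#' @return Strictly increasing numeric vector of lags.
#' @export
default_tau_grid <- function(tau_min = 1e-7, tau_max = 1e-2, n = 128L) {
  stopifnot(tau_min > 0, tau_max > tau_min, n >= 2)
  exp(seq(log(tau_min), log(tau_max), length.out = n))
}

#' Intensity autocorrelation curve
#'
#' Container for one measured or simulated g2 curve on a lag grid.
#'
#' @param tau Strictly increasing lag grid (s), all positive.
#' @param g2 Intensity autocorrelation values (same length as `tau`).
#' @param t_mid Acquisition timestamp within the protocol (s).
#' @param t_avg Averaging duration of the acquisition (s).
#' @return An object of class `autocorr_curve`.
#' @export
autocorr_curve <- function(tau, g2, t_mid = NA_real_, t_avg = 3) {
  stopifnot(is.numeric(tau), is.numeric(g2), length(tau) == length(g2))
  if (length(tau) < 2L || any(diff(tau) <= 0) || tau[1L] <= 0)
    stop("'tau' must be strictly increasing and positive", call. = FALSE)
  if (all(is.na(g2))) stop("all-NA g2 curve", call. = FALSE)
  structure(list(tau = as.numeric(tau), g2 = as.numeric(g2),
                 t_mid = t_mid, t_avg = t_avg),
            class = "autocorr_curve")
}

#' @export
print.autocorr_curve <- function(x, ...) {
  cat(sprintf("g2 curve: %d lags in [%.3g, %.3g] s, g2 range [%.4f, %.4f]\n",
              length(x$tau), min(x$tau), max(x$tau),
              min(x$g2, na.rm = TRUE), max(x$g2, na.rm = TRUE)))
  invisible(x)
}
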