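# Forward model and inverse fit of the DCS core.

props0 <- optical_properties()
geom0 <- dcs_geometry()

test_that("wavenumber follows 2*pi*n/lambda with nm -> cm conversion", {
  # unit-cancellation identity: lambda = 2*pi*1e7 nm, n = 1 gives k0 = 1/cm
  expect_equal(wavenumber(optical_properties(n_tissue = 1,
                                             wavelength = 2 * pi * 1e7)), 1)
  # direct evaluation at the instrument wavelength (frozen from
  # high-precision arithmetic)
  expect_equal(wavenumber(props0), 112056.80802613275, tolerance = 1e-12)
  # linear in the refractive index
  expect_equal(wavenumber(optical_properties(n_tissue = 2.8)),
               2 * wavenumber(props0))
  expect_error(optical_properties(wavelength = -5), "wavelength")
})

test_that("semi-infinite g1 matches the high-precision closed-form oracle", {
  # frozen from a 40-digit independent evaluation of the extrapolated
  # boundary solution at mua=0.1, musp=10, n=1.4/1.0, rho=2.4, 785 nm
  expect_equal(g1_semi_infinite(1e-5, props0, geom0, bfi = 1e-8),
               0.6653786777435266, tolerance = 1e-12)
})

test_that("g1 limits and monotonicity hold across random parameter draws", {
  tau <- default_tau_grid()
  # static medium and zero-lag normalisation
  expect_equal(g1_semi_infinite(tau, props0, geom0, bfi = 0), rep(1, 128))
  expect_equal(g1_semi_infinite(0, props0, geom0, bfi = 3e-8), 1)
  expect_error(g1_semi_infinite(tau, props0, geom0, bfi = -1e-9), "bfi")

  set.seed(101)
  for (i in 1:25) {
    pr <- suppressWarnings(optical_properties(
      mua = runif(1, 0.02, 0.3), musp = runif(1, 5, 15),
      n_tissue = runif(1, 1.3, 1.5)))
    gm <- dcs_geometry(runif(1, 1, 3))
    bfi <- 10^runif(1, -9, -7)
    g1 <- g1_semi_infinite(tau, pr, gm, bfi)
    expect_true(all(g1 > 0 & g1 <= 1))
    expect_true(all(diff(g1) <= 1e-14))              # non-increasing in tau
    g1_fast <- g1_semi_infinite(tau, pr, gm, bfi * 2.5)
    expect_true(all(g1_fast <= g1 + 1e-14))          # non-increasing in bfi
  }
})

test_that("Siegert relation maps g1 to g2 with the coherence intercept", {
  expect_equal(g2_from_g1(1, 0.5), 1.5)
  expect_equal(g2_from_g1(0, 0.9), 1)
  expect_equal(g2_from_g1(0.5, 0.5), 1.125)
  expect_error(g2_from_g1(0.5, 0), "beta_coh")
  expect_error(g2_from_g1(0.5, 1.2), "beta_coh")
})

test_that("early-lag selection cuts at the analytic decay threshold", {
  tau <- default_tau_grid()
  g2 <- g2_from_g1(g1_semi_infinite(tau, props0, geom0, 1e-8), 0.5)
  curve <- autocorr_curve(tau, g2)

  # degenerate threshold keeps everything
  expect_true(all(select_early_lags(curve, 0.5, decay_fraction = 0)))

  # cut boundary brackets the lag at which g1^2 = 0.5, frozen from an
  # independent root-find on the closed form
  tau_half <- 8.449070649049604e-6
  mask <- select_early_lags(curve, 0.5, decay_fraction = 0.5)
  expect_true(all(diff(mask) <= 0))                  # contiguous prefix
  expect_lt(max(tau[mask]), tau_half)
  expect_gte(min(tau[!mask]), max(tau[mask]))
  expect_true(tau[which(!mask)[1L]] >= tau_half)

  # fully decayed curve keeps one lag and warns
  flat <- autocorr_curve(tau, rep(1, length(tau)))
  expect_warning(m1 <- select_early_lags(flat, 0.5, 0.3), "first lag")
  expect_identical(sum(m1), 1L)
})

test_that("noiseless curves round-trip through fit_bfi to 0.1%", {
  tau <- default_tau_grid()
  for (bfi in c(1e-9, 1e-8, 1e-7)) {
    for (beta in c(0.3, 0.5)) {
      g2 <- g2_from_g1(g1_semi_infinite(tau, props0, geom0, bfi), beta)
      est <- fit_bfi(autocorr_curve(tau, g2), props0, geom0)
      expect_true(est$converged)
      expect_lt(abs(est$bfi - bfi) / bfi, 1e-3)
      expect_lt(abs(est$beta_coh - beta) / beta, 1e-3)
    }
  }
})

test_that("fitting with a vanishing early-lag cut matches the full-grid fit", {
  tau <- default_tau_grid()
  cv <- synth_curve(2e-8, 0.5, props0, geom0, noise_spec(seed = 77), tau)
  full <- fit_bfi(cv, props0, geom0, fit_options(decay_fraction = 0))
  tiny <- fit_bfi(cv, props0, geom0, fit_options(decay_fraction = 1e-6))
  expect_equal(tiny$bfi, full$bfi, tolerance = 1e-6)
})

test_that("degenerate curves are flagged rather than mis-fitted", {
  tau <- default_tau_grid()
  # flat curve: no flow signal; must not return a spurious converged flow
  flat <- autocorr_curve(tau, rep(1, length(tau)))
  est <- suppressWarnings(fit_bfi(flat, props0, geom0))
  expect_true(est$beta_coh <= 1e-3 || !est$converged)
  expect_error(autocorr_curve(tau, rep(NA_real_, length(tau))), "NA")
  expect_error(autocorr_curve(rev(tau), rep(1, length(tau))), "increasing")
})

test_that("fixing the coherence factor constrains the fit accordingly", {
  tau <- default_tau_grid()
  g2 <- g2_from_g1(g1_semi_infinite(tau, props0, geom0, 1e-8), 0.5)
  est <- fit_bfi(autocorr_curve(tau, g2), props0, geom0,
                 fit_options(beta_fixed = 0.5))
  expect_identical(est$beta_coh, 0.5)
  expect_lt(abs(est$bfi - 1e-8) / 1e-8, 1e-3)
})
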