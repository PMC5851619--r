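# Synthetic-data generator: curves, trajectories, cohorts.

props0 <- optical_properties()
geom0 <- dcs_geometry()

test_that("synth_curve is exact at zero noise and deterministic under seed", {
  tau <- default_tau_grid()
  clean <- synth_curve(1e-8, 0.5, props0, geom0,
                       noise_spec(rel_scale = 0, drift_sd = 0), tau)
  expect_identical(clean$g2,
                   g2_from_g1(g1_semi_infinite(tau, props0, geom0, 1e-8), 0.5))
  a <- synth_curve(1e-8, 0.5, props0, geom0, noise_spec(seed = 9), tau)
  b <- synth_curve(1e-8, 0.5, props0, geom0, noise_spec(seed = 9), tau)
  d <- synth_curve(1e-8, 0.5, props0, geom0, noise_spec(seed = 10), tau)
  expect_identical(a$g2, b$g2)
  expect_false(identical(a$g2, d$g2))
})

test_that("trajectory plateaus implement the subject's effects exactly", {
  prot <- hob_protocol()
  nz0 <- noise_spec(rel_scale = 0, drift_sd = 0)
  flat <- synth_bfi_trajectory(prot, subject_effects(1e-8, 0, 0), nz0)
  expect_true(all(flat$bfi == 1e-8))

  eff <- subject_effects(1e-8, drop_frac = -0.2, recovery_offset_frac = 0.1)
  tr <- synth_bfi_trajectory(prot, eff, nz0)
  r <- compute_rcbf(tr, prot)
  expect_equal(r$rcbf_supine_to_30, -20, tolerance = 1e-12)
  expect_equal(r$rcbf_30_to_supine, 10, tolerance = 1e-12)

  # transitions stay inside the gaps: every in-stage sample is on-plateau
  st <- prot$stages
  in_stage2 <- tr$t >= st$start[2] & tr$t < st$start[2] + st$duration[2]
  expect_true(all(tr$bfi[in_stage2] == 1e-8 * 0.8))
})

test_that("cohort bookkeeping, labels and determinism under seed", {
  coh <- synth_cohort(n_control = 4, n_mild = 5, n_modsev = 6, seed = 21)
  expect_identical(as.integer(table(coh$subjects$group)[c("control", "mild",
                                                          "moderate_severe")]),
                   c(4L, 5L, 6L))
  expect_identical(nrow(coh$subjects), 15L)
  expect_identical(names(coh$traces), coh$subjects$subject_id)
  coh2 <- synth_cohort(n_control = 4, n_mild = 5, n_modsev = 6, seed = 21)
  expect_identical(coh$subjects, coh2$subjects)
  expect_identical(coh$traces[[7]]$bfi, coh2$traces[[7]]$bfi)
  expect_error(synth_cohort(n_control = -1, n_mild = 2, n_modsev = 2),
               "group sizes")
})

test_that("generated sleep metrics converge to the preset medians", {
  coh <- synth_cohort(n_control = 2000, n_mild = 2000, n_modsev = 2000,
                      seed = 5, traces = FALSE)
  s <- coh$subjects
  ms <- s[s$group == "moderate_severe", ]
  # tolerance: 3x the asymptotic SE of the sample median (IQR-scaled) plus
  # half of the reporting lattice (values are rounded to 0.1 or 1)
  med_tol <- function(q1, q3, n, lattice = 0.1)
    3 * 1.2533 * ((q3 - q1) / 1.349) / sqrt(n) + lattice / 2
  expect_equal(median(ms$ahi), 48.5, tolerance = med_tol(21, 78, 2000) / 48.5)
  expect_equal(median(ms$mean_spo2), 93,
               tolerance = med_tol(92, 95, 2000) / 93)
  expect_equal(median(s$bmi[s$group == "control"]), 24,
               tolerance = med_tol(23, 26, 2000) / 24)
  # severity classes respected by construction
  expect_true(all(ms$ahi >= 15))
  expect_true(all(s$ahi[s$group == "control"] < 5))
  expect_true(all(s$mean_spo2 <= 100))
})

test_that("recovery offsets follow the SpO2 coupling; drop is group-free", {
  coh <- synth_cohort(n_control = 2000, n_mild = 2000, n_modsev = 2000,
                      seed = 8, traces = FALSE)
  s <- coh$subjects
  ef <- merge(coh$effects, s[, c("subject_id", "group", "mean_spo2")],
              by = "subject_id")
  preset <- load_effect_preset("paper-effects")
  fit <- lm(100 * recovery_offset_frac ~ mean_spo2, data = ef)
  expect_equal(unname(coef(fit)["mean_spo2"]),
               preset$effects$recovery$slope, tolerance = 0.05)
  # the moderate/severe recovery offset is anchored by construction
  expect_equal(median(100 * ef$recovery_offset_frac[
    ef$group == "moderate_severe"]), 9.8, tolerance = 0.05)

  # the supine->30 drop carries no group effect (null at alpha ~ 5e-4)
  kw <- group_compare(ef$drop_frac, ef$group)
  expect_lt(kw$statistic, 15)
  # cohort-level median drop sits at the preset mean
  expect_equal(median(ef$drop_frac), -0.175, tolerance = 0.02)
})

test_that("CPAP follow-up pairs severe subjects with zero-centred recovery", {
  coh <- synth_cohort(seed = 31, traces = FALSE)
  fu <- synth_cpap_followup(coh, n = 13, seed = 32)
  expect_identical(nrow(fu), 13L)
  ahi <- coh$subjects$ahi[match(fu$subject_id, coh$subjects$subject_id)]
  expect_true(all(ahi > 30))
  fu2 <- synth_cpap_followup(coh, n = 13, seed = 32)
  expect_identical(fu, fu2)
  # post-treatment offsets centred on full recovery at large n
  big <- synth_cohort(n_control = 0, n_mild = 0, n_modsev = 500, seed = 33,
                      traces = FALSE)
  fub <- synth_cpap_followup(big, n = 200, seed = 34)
  expect_lt(abs(mean(fub$post)), 1.5)
})
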