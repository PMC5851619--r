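# Stage windows, normalisation and endpoints of the head-of-bed analysis.

test_that("stage windows apply the first/last-minute exclusions", {
  win <- stage_windows(hob_protocol())
  expect_equal(win$win_start, c(60, 390, 720))
  expect_equal(win$win_end, c(240, 570, 900))
  expect_true(all(win$win_end - win$win_start == 180))

  no_excl <- hob_protocol(exclude_head = 0, exclude_tail = 0)
  win0 <- stage_windows(no_excl)
  expect_equal(win0$win_start, no_excl$stages$start)
  expect_equal(win0$win_end, no_excl$stages$start + no_excl$stages$duration)

  short <- data.frame(label = "s", angle = 0, start = 0, duration = 100)
  expect_error(hob_protocol(short), "exclude")
})

test_that("rCBF endpoints are identity on constant traces and scale-free", {
  prot <- hob_protocol()
  t <- seq(1.5, 958.5, by = 3)
  const <- bfi_trace(t, rep(2e-8, length(t)))
  r <- compute_rcbf(const, prot)
  expect_equal(r$rcbf_supine_to_30, 0)
  expect_equal(r$rcbf_30_to_supine, 0)
  expect_equal(r$baseline_mean, 2e-8)

  set.seed(11)
  noisy <- bfi_trace(t, 1e-8 * exp(rnorm(length(t), 0, 0.2)))
  r1 <- compute_rcbf(noisy, prot)
  for (c_scale in c(0.5, 3, 1e4)) {
    r2 <- compute_rcbf(bfi_trace(t, c_scale * noisy$bfi), prot)
    # invariant up to one ulp of the rescaling arithmetic
    expect_equal(r2$rcbf_supine_to_30, r1$rcbf_supine_to_30,
                 tolerance = 1e-12)
    expect_equal(r2$rcbf_30_to_supine, r1$rcbf_30_to_supine,
                 tolerance = 1e-12)
  }
})

test_that("samples outside the analysis windows never influence endpoints", {
  prot <- hob_protocol()
  t <- seq(1.5, 958.5, by = 3)
  set.seed(12)
  base <- bfi_trace(t, 1e-8 * exp(rnorm(length(t), 0, 0.1)))
  win <- stage_windows(prot)
  in_any <- rep(FALSE, length(t))
  for (i in seq_len(nrow(win)))
    in_any <- in_any | (t >= win$win_start[i] & t < win$win_end[i])
  perturbed <- base$bfi
  perturbed[!in_any] <- perturbed[!in_any] * runif(sum(!in_any), 0, 50)
  r1 <- compute_rcbf(base, prot)
  r2 <- compute_rcbf(bfi_trace(t, perturbed), prot)
  expect_identical(r1$rcbf_supine_to_30, r2$rcbf_supine_to_30)
  expect_identical(r1$rcbf_30_to_supine, r2$rcbf_30_to_supine)
  expect_identical(r1$baseline_mean, r2$baseline_mean)
})

test_that("quality masking drops samples and empty windows fail gracefully", {
  prot <- hob_protocol()
  t <- seq(1.5, 958.5, by = 3)
  bfi <- rep(1e-8, length(t))
  # mask out the whole 30-degree window
  q <- rep(TRUE, length(t))
  q[t >= 390 & t < 570] <- FALSE
  r <- compute_rcbf(bfi_trace(t, bfi, quality = q), prot)
  expect_false(r$ok)
  expect_match(r$reason, "empty analysis window")
})

test_that("cohort endpoint table flags missing traces without crashing", {
  prot <- hob_protocol()
  coh <- synth_cohort(n_control = 1, n_mild = 1, n_modsev = 1, seed = 3)
  traces <- coh$traces
  traces[[2L]] <- NULL  # drop one subject's trace
  ep <- suppressMessages(cohort_endpoints(coh$subjects, traces, prot))
  expect_identical(nrow(ep), 3L)
  expect_identical(sum(ep$ok), 2L)
  expect_identical(ep$reason[!ep$ok], "missing trace")
  expect_identical(unname(table(ep$group)), unname(table(coh$subjects$group)))
})

test_that("trace-level pipeline estimates are unbiased for the true effects", {
  # 200 seeded subjects at the default drift noise: mean estimated endpoints
  # within 0.5 percentage points of the generator truth
  prot <- hob_protocol()
  set.seed(202)
  err_drop <- err_rec <- numeric(200)
  for (i in 1:200) {
    drop <- runif(1, -0.3, -0.05)
    rec <- runif(1, -0.05, 0.15)
    eff <- subject_effects(1e-8, drop, rec)
    tr <- synth_bfi_trajectory(prot, eff, noise_spec())
    r <- compute_rcbf(tr, prot)
    err_drop[i] <- r$rcbf_supine_to_30 - 100 * drop
    err_rec[i] <- r$rcbf_30_to_supine - 100 * rec
  }
  expect_lt(abs(mean(err_drop)), 0.5)
  expect_lt(abs(mean(err_rec)), 0.5)
})
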