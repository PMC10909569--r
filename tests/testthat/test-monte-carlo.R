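test_that("noise bookkeeping: control SNR and difference SNR", {
  expect_equal(control_snr(noise_model(sigma = 0.0017)), 0.05 / 0.0017)
  snrs <- vapply(c(0.0033, 0.0017, 0.0011),
                 function(s) control_snr(noise_model(sigma = s)), numeric(1))
  expect_equal(snrs, 0.05 / c(0.0033, 0.0017, 0.0011))
  expect_lt(max(abs(snrs - c(15, 30, 45))), 0.6)
  # at the grey-matter operating point the pre-contrast PLD 1.5 s difference
  # signal sits near SNR 3.6 for sigma = 0.0017
  dm <- asl_signal(3.5, gm_truth(), std_acq())
  expect_lt(abs(difference_snr(noise_model(sigma = 0.0017), dm) - 3.6), 0.4)
})

test_that("vanishing noise reproduces the noise-free curve exactly", {
  sim <- simulate_noisy_difference(gm_truth(), std_design(), std_acq(),
                                   noise_model(sigma = 1e-300, n_reps = 3,
                                               seed = 1))
  base <- make_signal_table(gm_truth(), std_design(), std_acq())
  for (r in 1:3) {
    expect_equal(sim$dm[sim$rep == r], base$dm, tolerance = 1e-12)
  }
  # noise variance of the difference is 2 sigma^2 / roi_size
  sim2 <- simulate_noisy_difference(
    gm_truth(), std_design(), std_acq(),
    noise_model(sigma = 0.01, n_reps = 4000, roi_size = 4, seed = 2)
  )
  res <- sim2$dm - rep(base$dm, times = 4000)
  expect_equal(stats::sd(res), 0.01 * sqrt(2) / 2, tolerance = 0.03)
})

test_that("summaries implement median relative error and IQR-based CoV", {
  fits <- tibble::tibble(f = 60, t_a = 1.2, k_b = c(1, 2, 3, 4, 5))
  s <- summarize_fits(fits, gm_truth(k_b = 3), min_survivors = 5)
  expect_equal(s$rel_error_kb, 0)
  expect_equal(s$cov_kb, 100 * 2 / 3)
  expect_false(s$flagged)

  exact <- tibble::tibble(f = 60, t_a = 1.2, k_b = rep(2.65, 30))
  s2 <- summarize_fits(exact, gm_truth())
  expect_equal(s2$rel_error_kb, 0)
  expect_equal(s2$cov_kb, 0)

  # exchange fits within 5% of a screening constraint's value are excluded
  # before both metrics; the zero lower constraint has no screening width
  fits2 <- tibble::tibble(f = 60, t_a = 1.2, k_b = c(0, 2, 3, 4, 9.6))
  s3 <- summarize_fits(fits2, gm_truth(k_b = 3), min_survivors = 3,
                       screen_kb = c(0, 10))
  expect_equal(s3$extreme_fraction, 0.2)    # only the 9.6 fit is screened
  expect_equal(s3$rel_error_kb, 100 * (2.5 - 3) / 3)
  expect_equal(s3$cov_kb, 100 * (3.25 - 1.5) / 3)
  # too few survivors flags the row
  s4 <- summarize_fits(fits2, gm_truth(k_b = 3), min_survivors = 10)
  expect_true(s4$flagged)
})

test_that("the study is bit-reproducible given its seeds", {
  nm <- noise_model(sigma = 0.0017, n_reps = 30, roi_size = 500, seed = 13)
  cfg <- quick_config(n_starts = 20, seed = 14, kb_hi = 10)
  r1 <- run_mc_study(kb_values = c(1, 3), noise = nm, config = cfg)
  r2 <- run_mc_study(kb_values = c(1, 3), noise = nm, config = cfg)
  expect_identical(r1, r2)
  expect_equal(r1$kb_truth, c(1, 3))
  expect_true(all(r1$extreme_fraction >= 0 & r1$extreme_fraction <= 1))
})

test_that("ROI averaging shrinks the CoV of f and t_a as 1/sqrt(N)", {
  # in the near-linear regime (away from parameter bounds) precision of f
  # and t_a scales with the effective SNR, i.e. with sqrt(roi_size)
  cfg <- quick_config(n_starts = 25, seed = 21, kb_hi = 10)
  r <- purrr::map(c(100, 10000), function(n) {
    run_mc_study(kb_values = 2.65,
                 noise = noise_model(sigma = 0.0017, n_reps = 250,
                                     roi_size = n, seed = 22),
                 config = cfg)
  })
  expect_equal(r[[2]]$cov_f, r[[1]]$cov_f / 10, tolerance = 0.25)
  expect_equal(r[[2]]$cov_ta, r[[1]]$cov_ta / 10, tolerance = 0.25)
  # k_b precision also improves with ROI size (direction only)
  expect_gt(r[[1]]$cov_kb, r[[2]]$cov_kb)
})

test_that("k_b precision degrades with the underlying exchange rate", {
  cfg <- quick_config(n_starts = 25, seed = 31, kb_hi = 10)
  rep <- run_mc_study(kb_values = c(0.5, 2.0, 4.0),
                      noise = noise_model(sigma = 0.0017, n_reps = 250,
                                          roi_size = 500, seed = 32),
                      config = cfg)
  # the IQR of fitted k_b widens with the underlying exchange rate
  iqr <- rep$cov_kb * rep$kb_truth / 100
  expect_true(all(diff(iqr) > 0))
  # medians stay essentially unbiased across the grid
  expect_lt(max(abs(rep$rel_error_kb)), 5)
  expect_true(all(rep$extreme_fraction < 0.06))
})
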