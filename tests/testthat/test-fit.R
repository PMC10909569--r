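test_that("noise-free signals identify all three parameters", {
  dat <- make_signal_table(gm_truth(), std_design(), std_acq())
  fit <- fit_asl(dat, t1_e = 1.5, acq = std_acq(), config = quick_config())
  expect_lt(max(abs(fit$estimates - c(60, 1.2, 2.65)) / c(60, 1.2, 2.65)),
            0.001)
  expect_equal(fit$sse, 0, tolerance = 1e-16)
  expect_false(fit$extreme)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_obs, 6L)
})

test_that("fits are deterministic given the seed and invariant to row order", {
  dat <- make_signal_table(
    gm_truth(), std_design(), std_acq(),
    noise = noise_model(sigma = 0.0017, n_reps = 1, seed = 9)
  )
  cfg <- quick_config(n_starts = 50, seed = 123)
  f1 <- fit_asl(dat, 1.5, std_acq(), cfg)
  f2 <- fit_asl(dat, 1.5, std_acq(), cfg)
  expect_identical(f1$estimates, f2$estimates)
  shuffled <- withr::with_seed(4, dat[sample(nrow(dat)), ])
  f3 <- fit_asl(shuffled, 1.5, std_acq(), cfg)
  expect_identical(f1$estimates, f3$estimates)
})

test_that("random noise-free ground truths are recovered to < 0.5%", {
  acq <- std_acq()
  design <- std_design()
  cfg <- quick_config(n_starts = 50, seed = 77)
  pars <- withr::with_seed(5, data.frame(
    f = runif(200, 10, 150),
    t_a = runif(200, 0.2, 2.3),   # below min(PLD) + t_l
    k_b = runif(200, 0.2, 4.8)
  ))
  worst <- 0
  for (i in seq_len(nrow(pars))) {
    truth <- gm_truth(f = pars$f[i], t_a = pars$t_a[i], k_b = pars$k_b[i])
    dat <- make_signal_table(truth, design, acq)
    fit <- fit_asl(dat, 1.5, acq, cfg)
    rel <- abs(fit$estimates - c(pars$f[i], pars$t_a[i], pars$k_b[i])) /
      c(pars$f[i], pars$t_a[i], pars$k_b[i])
    worst <- max(worst, max(rel))
  }
  expect_lt(worst, 0.005)
})

test_that("estimates honour bounds and k_b = 0 is flagged extreme", {
  acq <- std_acq()
  dat <- make_signal_table(
    gm_truth(), std_design(), acq,
    noise = noise_model(sigma = 0.005, n_reps = 1, seed = 2)
  )
  cfg <- quick_config(n_starts = 50, seed = 8)
  fit <- fit_asl(dat, 1.5, acq, cfg)
  lo <- c(0, 0, 0); hi <- c(200, 2.5, 5)
  expect_true(all(fit$estimates >= lo & fit$estimates <= hi))

  dat0 <- make_signal_table(gm_truth(k_b = 0), std_design(), acq)
  fit0 <- fit_asl(dat0, 1.5, acq, cfg)
  expect_lt(fit0$estimates[["k_b"]], 0.25)
  expect_true(fit0$extreme)
})

test_that("the compiled LM engine agrees with minpack.lm", {
  acq <- std_acq()
  base <- make_signal_table(gm_truth(), std_design(), acq)
  sets <- withr::with_seed(31, purrr::map(1:5, function(i) {
    d <- base
    d$dm <- d$dm + rnorm(6, 0, 0.0017 * sqrt(2))
    d
  }))
  sets <- c(list(base), sets)
  for (d in sets) {
    f_cpp <- fit_asl(d, 1.5, acq, quick_config(n_starts = 60, seed = 5,
                                               kb_hi = 10))
    f_mp <- fit_asl(d, 1.5, acq, quick_config(n_starts = 60, seed = 5,
                                              kb_hi = 10,
                                              engine = "minpack"))
    # both engines must land in the same optimum basin
    expect_lt(f_cpp$sse, f_mp$sse * (1 + 1e-3) + 1e-12)
    expect_equal(f_cpp$estimates[["f"]], f_mp$estimates[["f"]],
                 tolerance = 0.02)
  }
})

test_that("the unconstrained simplex configuration recovers noise-free truth", {
  dat <- make_signal_table(gm_truth(), std_design(), std_acq())
  fit <- fit_asl(dat, 1.5, std_acq(),
                 fit_config(method = "simplex", maxfev = 5000))
  expect_lt(max(abs(fit$estimates - c(60, 1.2, 2.65)) / c(60, 1.2, 2.65)),
            0.01)
  expect_equal(fit$method, "simplex")
})

test_that("degenerate inputs raise informative errors", {
  dat <- make_signal_table(gm_truth(), std_design(), std_acq())
  expect_error(fit_asl(dat[1:3, ], 1.5, std_acq(), quick_config()),
               "at least 4")
  bad <- dat; bad$dm <- NULL
  expect_error(fit_asl(bad, 1.5, std_acq(), quick_config()), "dm")
  expect_error(fit_config(bounds = list(f = c(1, 0), t_a = c(0, 1),
                                        k_b = c(0, 1))))
})
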