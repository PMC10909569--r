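test_that("noise-free VFA signals recover T1 exactly and scale-invariantly", {
  d <- spgr_signal(t1 = 1.65, m0 = 100)
  fit <- fit_vfa_t1(d)
  expect_lt(abs(fit$t1 - 1.65) / 1.65, 1e-4)
  expect_lt(abs(fit$m0 - 100) / 100, 1e-4)
  # global intensity scaling leaves T1 unchanged, scales M0
  d2 <- d; d2$signal <- d2$signal * 7
  fit2 <- fit_vfa_t1(d2)
  expect_equal(fit2$t1, fit$t1, tolerance = 1e-6)
  expect_equal(fit2$m0, 7 * fit$m0, tolerance = 1e-6)
})

test_that("degenerate voxels are masked, multi-voxel input fans out", {
  d <- dplyr::bind_rows(
    dplyr::mutate(spgr_signal(1.3, 50), voxel = 1L),
    tibble::tibble(flip = c(2, 5, 15, 20), signal = 0, voxel = 2L)
  )
  fit <- fit_vfa_t1(d)
  expect_equal(nrow(fit), 2L)
  expect_false(fit$masked[fit$voxel == 1])
  expect_true(fit$masked[fit$voxel == 2])
  expect_lt(abs(fit$t1[fit$voxel == 1] - 1.3), 1e-3)
  expect_error(fit_vfa_t1(tibble::tibble(flip = c(5, 5), signal = c(1, 1))),
               "distinct flip angles")
})

test_that("DESPOT1 linearization agrees with the nonlinear fit at high SNR", {
  # the two estimators see the same noisy samples, so their disagreement is
  # O(noise): ~0.5% at SNR 100 and shrinking with 1/SNR
  withr::with_seed(12, {
    for (t1_true in c(0.8, 1.65)) {
      diffs_by_snr <- purrr::map_dbl(c(100, 500), function(snr) {
        median(purrr::map_dbl(1:40, function(i) {
          d <- spgr_signal(t1_true, 100)
          d$signal <- d$signal + rnorm(4, 0, max(d$signal) / snr)
          abs(fit_vfa_t1(d)$t1 - despot1_t1(d)$t1) / t1_true
        }))
      })
      expect_lt(diffs_by_snr[1], 0.01)   # SNR 100
      expect_lt(diffs_by_snr[2], 0.005)  # SNR 500
      expect_lt(diffs_by_snr[2], diffs_by_snr[1])
    }
  })
})

test_that("blood T1 extraction follows the reduction-mask percentile rule", {
  # uniform field: trivially recovered
  u <- estimate_blood_t1(rep(1.8, 6), rep(1.0, 6))
  expect_equal(u$t1b_pre, 1.8)
  expect_equal(u$t1b_post, 1.0)

  # voxels with < 20% reduction are excluded from both percentiles
  pre <- c(1.8, 1.8, 1.8, 1.8, 2.0, 2.0)
  post <- c(1.0, 1.1, 1.2, 1.3, 1.9, 1.9)  # last two reduce only 5%
  got <- estimate_blood_t1(pre, post)
  expect_equal(got$n_voxels, 4L)
  expect_equal(got$t1b_pre, 1.8)
  diff_q <- unname(quantile(pre[1:4] - post[1:4], 0.75, type = 7))
  expect_equal(got$t1b_post, 1.8 - diff_q)

  # percentile arithmetic against a direct sort-based oracle
  withr::with_seed(3, {
    pre_r <- runif(101, 1.5, 2.2)
    post_r <- pre_r * runif(101, 0.4, 0.7)  # all > 20% reduction
    got_r <- estimate_blood_t1(pre_r, post_r)
    sorted <- sort(pre_r)
    h <- (101 - 1) * 0.75 + 1  # type-7 position
    oracle <- sorted[floor(h)] + (h - floor(h)) *
      (sorted[ceiling(h)] - sorted[floor(h)])
    expect_equal(got_r$t1b_pre, oracle)
    expect_lt(got_r$t1b_post, got_r$t1b_pre)
  })

  expect_error(estimate_blood_t1(rep(1.8, 4), rep(1.75, 4)), "threshold")
})

test_that("ROI SNR is the mean/SD ratio, scale-invariant, zero-SD flagged", {
  expect_true(roi_snr(c(4, 4, 4, 4))$flagged)
  expect_identical(roi_snr(c(4, 4, 4, 4))$snr, Inf)
  withr::with_seed(8, {
    x <- rnorm(5000, mean = 3.6, sd = 1)
    got <- roi_snr(x)
    expect_lt(abs(got$snr - 3.6), 0.15)
    expect_equal(roi_snr(x * 13)$snr, got$snr, tolerance = 1e-12)
  })
})
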