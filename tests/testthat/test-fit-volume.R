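test_that("single-voxel volume fit reduces to the curve fit", {
  ph <- make_phantom(phantom_spec(
    shape = c(2, 2, 1), seed = 4,
    regions = tibble::tibble(label = 1L, f = 60, t_a = 1.2, k_b = 2.65,
                             t1_e = 1.5)
  ))
  mask <- array(FALSE, dim = c(2, 2, 1)); mask[1, 1, 1] <- TRUE
  cfg <- quick_config(n_starts = 30, seed = 9, kb_hi = 10)
  fv <- fit_asl_volume(ph$difference, ph$design, ph$m0, ph$t1e_map,
                       mask = mask, config = cfg)
  expect_equal(nrow(fv$fits), 1L)

  dat <- ph$design
  dat$dm <- ph$difference[1, 1, 1, ]
  direct <- fit_asl(dat, ph$t1e_map[1, 1, 1], ph$acq, cfg)
  expect_identical(
    unname(c(fv$fits$f, fv$fits$t_a, fv$fits$k_b)),
    unname(direct$estimates)
  )
})

test_that("noise-free phantom recovery is exact per region", {
  ph <- make_phantom(phantom_spec(
    shape = c(4, 4, 1), seed = 1,
    regions = tibble::tibble(label = 1:2, f = c(60, 40), t_a = c(1.2, 0.9),
                             k_b = c(2.65, 1.2), t1_e = c(1.5, 1.35)),
    noise = noise_model(sigma = 1e-300)
  ))
  fv <- fit_asl_volume(ph$difference, ph$design, ph$m0, ph$t1e_map,
                       config = quick_config(n_starts = 30, seed = 10,
                                             kb_hi = 10))
  med <- roi_medians(fv, ph$label_map)
  for (i in 1:2) {
    tr <- ph$truth[ph$truth$label == med$roi[i], ]
    expect_lt(abs(med$f[i] - tr$f) / tr$f, 0.005)
    expect_lt(abs(med$t_a[i] - tr$t_a) / tr$t_a, 0.005)
    expect_lt(abs(med$k_b[i] - tr$k_b) / tr$k_b, 0.005)
  }
})

test_that("regional medians order exchange rates correctly under noise", {
  ph <- make_phantom(phantom_spec(
    shape = c(8, 8, 1), seed = 6,
    regions = tibble::tibble(label = 1:2, f = 60, t_a = 1.2,
                             k_b = c(1.0, 3.5), t1_e = 1.5),
    noise = noise_model(sigma = 0.0017)  # control SNR 30
  ))
  fv <- fit_asl_volume(ph$difference, ph$design, ph$m0, ph$t1e_map,
                       config = quick_config(n_starts = 40, seed = 11,
                                             kb_hi = 10))
  med <- roi_medians(fv, ph$label_map)
  expect_lt(med$k_b[med$roi == 1], med$k_b[med$roi == 2])
})

test_that("shape mismatches and empty masks are rejected", {
  ph <- make_phantom(phantom_spec(shape = c(3, 3, 1), seed = 2))
  expect_error(
    fit_asl_volume(ph$difference, ph$design, ph$m0[1:2, , , drop = FALSE],
                   ph$t1e_map),
    "m0"
  )
  expect_error(
    fit_asl_volume(ph$difference[, , , 1:3], ph$design, ph$m0, ph$t1e_map),
    "one volume per design row"
  )
  empty <- array(FALSE, dim = c(3, 3, 1))
  expect_error(
    fit_asl_volume(ph$difference, ph$design, ph$m0, ph$t1e_map, mask = empty),
    "no voxels"
  )
})

test_that("parameter maps mask invalid exchange fits and write to NIfTI", {
  ph <- make_phantom(phantom_spec(shape = c(3, 3, 1), seed = 3))
  fv <- fit_asl_volume(ph$difference, ph$design, ph$m0, ph$t1e_map,
                       config = quick_config(n_starts = 20, seed = 12,
                                             kb_hi = 10))
  expect_true(all(is.na(fv$maps$k_b[!ph$label_map > 0])))
  ok <- fv$fits$valid
  expect_true(all(fv$maps$k_b[fv$fits$voxel[ok]] >= 0 &
                    fv$maps$k_b[fv$fits$voxel[ok]] <= 10))
  dir <- withr::local_tempdir()
  paths <- write_parameter_maps(fv, dir)
  expect_true(all(file.exists(paths)))
})
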