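test_that("signal is zero before bolus arrival and without labelling", {
  phys <- gm_truth()
  acq <- std_acq()
  expect_equal(asl_signal(c(0, 0.5, 1.19), phys, acq), c(0, 0, 0))
  acq0 <- acq_params(t_l = 2, alpha = 0, m0 = 1)
  expect_equal(asl_signal(c(0.5, 2, 3.5, 6), phys, acq0), rep(0, 4))
})

test_that("signal is continuous across both branch boundaries", {
  pars <- lhs_params(200, seed = 11)
  acq <- std_acq()
  eps <- 1e-9
  for (i in seq_len(nrow(pars))) {
    phys <- physio_params(f = pars$f[i], t_a = pars$t_a[i], k_b = pars$k_b[i],
                          t1_b = pars$t1_b[i], t1_e = pars$t1_e[i])
    b1 <- phys$t_a
    b2 <- phys$t_a + acq$t_l
    scale <- max(abs(asl_signal(seq(0.1, 6, by = 0.5), phys, acq)), 1e-12)
    expect_lt(abs(diff(asl_signal(c(b1 - eps, b1 + eps), phys, acq))),
              1e-6 * scale)
    expect_lt(abs(diff(asl_signal(c(b2 - eps, b2 + eps), phys, acq))),
              1e-6 * scale)
  }
})

test_that("signal is exactly linear in f, alpha and M0", {
  phys <- gm_truth()
  acq <- std_acq()
  t <- c(1.5, 2.8, 3.5, 5.0)
  base <- asl_signal(t, phys, acq)
  expect_identical(asl_signal(t, set_param_test(phys, f = 120), acq), 2 * base)
  expect_equal(asl_signal(t, phys, acq_params(t_l = 2, alpha = 0.425, m0 = 1)),
               base / 2, tolerance = 1e-14)
  expect_equal(asl_signal(t, phys, acq_params(t_l = 2, alpha = 0.85, m0 = 3)),
               3 * base, tolerance = 1e-14)
})

test_that("closed form agrees with the ODE oracle", {
  acq <- std_acq()
  tg <- seq(0, 6, by = 0.25)

  # the reference operating point, including a spot value at t = 3.5 s
  phys <- gm_truth()
  cf <- asl_signal(tg, phys, acq)
  od <- asl_signal_ode(tg, phys, acq)$dm
  expect_lt(max(abs(cf - od)) / max(abs(cf)), 1e-6)
  expect_equal(asl_signal(3.5, phys, acq), 0.00842329, tolerance = 1e-5)

  # random parameter sets
  pars <- lhs_params(50, seed = 3)
  for (i in seq_len(nrow(pars))) {
    phys <- physio_params(f = pars$f[i], t_a = pars$t_a[i], k_b = pars$k_b[i],
                          t1_b = pars$t1_b[i], t1_e = pars$t1_e[i])
    cf <- asl_signal(tg, phys, acq)
    od <- asl_signal_ode(tg, phys, acq)$dm
    expect_lt(max(abs(cf - od)) / max(max(abs(cf)), 1e-12), 1e-6)
  }

  # degenerate J == R1e is analytically continued, never NaN
  kbd <- 1 / 0.4 - 1 / 1.65
  pd <- physio_params(k_b = kbd, t1_b = 1.65, t1_e = 0.4)
  v <- asl_signal(c(2, 3.5, 5), pd, acq)
  expect_true(all(is.finite(v)))
  expect_equal(v, asl_signal_ode(c(2, 3.5, 5), pd, acq)$dm, tolerance = 1e-6)
})

test_that("ODE oracle decouples the tissue compartment when k_b = 0", {
  phys <- gm_truth(k_b = 0)
  acq <- std_acq()
  # with no exchange the signal cannot depend on the extravascular T1
  a <- asl_signal(seq(1.5, 6, by = 0.5), phys, acq)
  b <- asl_signal(seq(1.5, 6, by = 0.5), gm_truth(k_b = 0, t1_e = 0.9), acq)
  expect_identical(a, b)
  expect_equal(asl_signal_ode(c(0.2, 0.8, 1.1), phys, acq)$dm, rep(0, 3))
})

test_that("fast exchange drives post-bolus decay towards the tissue rate", {
  phys <- gm_truth(k_b = 150)
  acq <- std_acq()
  v <- asl_signal(c(5, 6), phys, acq)
  rate <- (log(v[1]) - log(v[2])) / 1
  expect_equal(rate, 1 / phys$t1_e, tolerance = 0.02)
})

test_that("analytic k_b sensitivity matches central finite differences", {
  acq <- std_acq()
  h <- 1e-5
  pars <- lhs_params(100, seed = 7)
  pars$k_b <- pmax(pars$k_b, 2 * h)
  for (i in seq_len(nrow(pars))) {
    phys <- physio_params(f = pars$f[i], t_a = pars$t_a[i], k_b = pars$k_b[i],
                          t1_b = pars$t1_b[i], t1_e = pars$t1_e[i])
    t <- phys$t_a + c(0.5, 1.5, 2.5)
    an <- asl_sensitivity_kb(t, phys, acq)
    up <- asl_signal(t, set_param_test(phys, k_b = phys$k_b + h), acq)
    dn <- asl_signal(t, set_param_test(phys, k_b = phys$k_b - h), acq)
    fd <- (up - dn) / (2 * h)
    scale <- pmax(abs(fd), 1e-10)
    expect_lt(max(abs(an - fd) / scale), 1e-4)
  }
  # the reference post-contrast evaluation point
  pp <- gm_truth(t1_b = 0.8)
  an <- asl_sensitivity_kb(3.5, pp, acq)
  fd <- (asl_signal(3.5, set_param_test(pp, k_b = 2.65 + h), acq) -
           asl_signal(3.5, set_param_test(pp, k_b = 2.65 - h), acq)) / (2 * h)
  expect_equal(an, fd, tolerance = 1e-6)
})

test_that("sensitivity vanishes for equal compartment T1s and before arrival", {
  acq <- std_acq()
  same <- physio_params(t1_b = 1.5, t1_e = 1.5)
  expect_equal(asl_sensitivity_kb(seq(0.5, 6, by = 0.5), same, acq),
               rep(0, 12))
  expect_equal(asl_sensitivity_kb(c(0, 0.5, 1.1), gm_truth(), acq), rep(0, 3))
  # with a slower-relaxing tissue compartment, label is retained longer:
  # sensitivity is non-negative well past the transit time
  post <- gm_truth(t1_b = 0.8)
  expect_true(all(asl_sensitivity_kb(seq(2.5, 8, by = 0.5), post, acq) >= 0))
})
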