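# Closed-form two-compartment CASL difference-signal model.
#
# With R1b = 1/T1_b, R1e = 1/T1_e, J = k_b + R1b, t' = t - t_a, s = t' - t_l
# and A = 2 f alpha (M0/lambda) exp(-R1b t_a) (f in s^-1), the difference
# signal in both non-trivial phases collapses to the single expression
#
#   dM(t) = A * [ F(J) - k_b * (F(J) - F(R1e)) / (J - R1e) ]
#
# where F(x) = (1 - exp(-x t'))/x while the bolus occupies the voxel
# (t_a <= t <= t_a + t_l) and F(x) = (exp(-x s) - exp(-x t'))/x after it.
# The divided difference (F(J) - F(R1e))/(J - R1e) has a removable
# singularity at J = R1e that is evaluated as F'(J).

# threshold below which |J - R1e| is treated as degenerate for the signal
.DEGEN_EPS <- 1e-9
# wider threshold for the k_b derivative, whose divided differences lose
# one more order to cancellation
.DEGEN_EPS_GRAD <- 1e-6

# F, F' and F'' for the bolus phase (arguments vectorized over tp)
.f_bol <- function(x, tp) (1 - exp(-x * tp)) / x
.f1_bol <- function(x, tp) (tp * exp(-x * tp) - .f_bol(x, tp)) / x
.f2_bol <- function(x, tp) (-tp^2 * exp(-x * tp) - 2 * .f1_bol(x, tp)) / x

# F, F' and F'' for the post-bolus phase (s = tp - t_l)
.f_post <- function(x, tp, s) (exp(-x * s) - exp(-x * tp)) / x
.f1_post <- function(x, tp, s) {
  (-s * exp(-x * s) + tp * exp(-x * tp) - .f_post(x, tp, s)) / x
}
.f2_post <- function(x, tp, s) {
  (s^2 * exp(-x * s) - tp^2 * exp(-x * tp) - 2 * .f1_post(x, tp, s)) / x
}

# Fast internal evaluator used by both the user-facing asl_signal() and the
# fitting residuals (no object validation). `am` is 2*alpha*m0/(lambda*6000).
.dm_eval <- function(t, f, t_a, k_b, r1b, r1e, t_l, am) {
  j <- k_b + r1b
  a <- am * f * exp(-r1b * t_a)
  tp <- t - t_a
  out <- numeric(length(t))
  bol <- tp >= 0 & tp <= t_l
  post <- tp > t_l
  degen <- abs(j - r1e) < .DEGEN_EPS
  if (any(bol)) {
    tpb <- tp[bol]
    fj <- .f_bol(j, tpb)
    dd <- if (degen) .f1_bol(j, tpb) else (fj - .f_bol(r1e, tpb)) / (j - r1e)
    out[bol] <- a * (fj - k_b * dd)
  }
  if (any(post)) {
    tpp <- tp[post]
    s <- tpp - t_l
    fj <- .f_post(j, tpp, s)
    dd <- if (degen) .f1_post(j, tpp, s)
          else (fj - .f_post(r1e, tpp, s)) / (j - r1e)
    out[post] <- a * (fj - k_b * dd)
  }
  out
}

.check_model_inputs <- function(t, phys, acq) {
  if (!inherits(phys, "physio_params")) {
    abort("`phys` must be created with physio_params().")
  }
  if (!inherits(acq, "acq_params")) {
    abort("`acq` must be created with acq_params().")
  }
  if (!is.numeric(t) || any(!is.finite(t))) {
    abort("`t` must be finite numeric times (s).")
  }
}

#' ASL difference signal of the two-compartment exchange model
#'
#' Evaluates the closed-form continuous-labelling difference signal
#' (control minus label) of the two-compartment blood/extravascular water
#' exchange model. The signal is zero before the labelled bolus arrives
#' (`t < t_a`), follows the inflow solution while the bolus occupies the
#' voxel (`t_a <= t <= t_a + t_l`) and decays bi-exponentially afterwards,
#' with rates `J = k_b + 1/t1_b` (intravascular) and `1/t1_e`
#' (extravascular). Flow is converted internally from
#' mL/min/100 mL to s^-1; the arterial equilibrium magnetization is
#' `m0 / lambda`.
#'
#' The removable singularity at `J = 1/t1_e` is evaluated through its
#' analytic limit, so the function never returns `NaN` for valid inputs.
#'
#' @param t Times from the start of labelling, s (vectorized).
#' @param phys A [physio_params()] object; `t1_b` should be the blood T1
#'   applicable to the contrast phase being modelled.
#' @param acq An [acq_params()] object (only `t_l`, `alpha`, `m0` are used).
#'
#' @return Numeric vector of difference-signal values in the units of `m0`.
#' @examples
#' phys <- physio_params(f = 60, t_a = 1.2, k_b = 2.65, t1_b = 1.65, t1_e = 1.5)
#' acq <- acq_params(t_l = 2, alpha = 0.85, m0 = 1)
#' asl_signal(c(0.5, 2, 3.5), phys, acq)
#' @seealso [asl_signal_ode()] for the ODE-integration oracle,
#'   [asl_sensitivity_kb()] for the analytic sensitivity to `k_b`.
#' @export
asl_signal <- function(t, phys, acq) {
  .check_model_inputs(t, phys, acq)
  .dm_eval(
    t,
    f = phys$f, t_a = phys$t_a, k_b = phys$k_b,
    r1b = 1 / phys$t1_b, r1e = 1 / phys$t1_e, t_l = acq$t_l,
    am = 2 * acq$alpha * acq$m0 / (phys$lambda * 6000)
  )
}

#' Analytic sensitivity of the ASL difference signal to the exchange rate
#'
#' Evaluates the partial derivative of [asl_signal()] with respect to the
#' blood-to-tissue water exchange rate `k_b`, from the differentiated closed
#' form (not finite differences). Because only `J = k_b + 1/t1_b` and the
#' explicit `k_b` prefactor depend on the exchange rate,
#' `d(dM)/d(k_b) = A * (F'(J) - ddF - k_b * (F'(J) - ddF)/(J - R1e))` with
#' `ddF` the divided difference of `F` between `J` and `R1e`. Near the
#' removable singularity `J = R1e` a second-order Taylor branch is used.
#'
#' The sensitivity is identically zero when `t1_e == t1_b` (the two
#' compartments relax identically, so the signal carries no information
#' about exchange) and zero for `t < t_a`.
#'
#' @inheritParams asl_signal
#' @return Numeric vector of sensitivities, signal units per s^-1.
#' @examples
#' phys <- physio_params(t1_b = 0.8)
#' acq <- acq_params()
#' asl_sensitivity_kb(3.5, phys, acq)
#' @export
asl_sensitivity_kb <- function(t, phys, acq) {
  .check_model_inputs(t, phys, acq)
  if (any(t < 0)) abort("`t` must be >= 0.")
  r1b <- 1 / phys$t1_b
  r1e <- 1 / phys$t1_e
  kb <- phys$k_b
  j <- kb + r1b
  a <- 2 * (phys$f / 6000) * acq$alpha * (acq$m0 / phys$lambda) *
    exp(-r1b * phys$t_a)

  tp <- t - phys$t_a
  out <- numeric(length(t))
  bol <- tp >= 0 & tp <= acq$t_l
  post <- tp > acq$t_l
  d <- j - r1e
  degen <- abs(d) < .DEGEN_EPS_GRAD
  m <- (j + r1e) / 2

  if (any(bol)) {
    tpb <- tp[bol]
    f1j <- .f1_bol(j, tpb)
    if (degen) {
      dd <- .f1_bol(m, tpb)
      grad_dd <- .f2_bol(m, tpb) / 2
    } else {
      dd <- (.f_bol(j, tpb) - .f_bol(r1e, tpb)) / d
      grad_dd <- (f1j - dd) / d
    }
    out[bol] <- a * (f1j - dd - kb * grad_dd)
  }
  if (any(post)) {
    tpp <- tp[post]
    s <- tpp - acq$t_l
    f1j <- .f1_post(j, tpp, s)
    if (degen) {
      dd <- .f1_post(m, tpp, s)
      grad_dd <- .f2_post(m, tpp, s) / 2
    } else {
      dd <- (.f_post(j, tpp, s) - .f_post(r1e, tpp, s)) / d
      grad_dd <- (f1j - dd) / d
    }
    out[post] <- a * (f1j - dd - kb * grad_dd)
  }
  out
}

#' Noise-free difference signals over an acquisition design
#'
#' Evaluates the closed-form signal at every row of a pre/post-contrast
#' design table, substituting each row's blood T1 into the model.
#'
#' @param design A design tibble from [asl_design()] (columns `phase`, `pld`,
#'   `t1b`).
#' @param phys A [physio_params()] object; its `t1_b` is overridden row-wise
#'   by `design$t1b`.
#' @param acq An [acq_params()] object (its `plds` field is ignored in favour
#'   of the design).
#'
#' @return The design tibble with added columns `time` (`t_l + pld`) and
#'   `dm` (noise-free difference signal).
#' @examples
#' asl_signal_design(asl_design(), physio_params(), acq_params())
#' @export
asl_signal_design <- function(design, phys, acq) {
  stopifnot(all(c("phase", "pld", "t1b") %in% names(design)))
  design |>
    dplyr::mutate(
      time = acq$t_l + .data$pld,
      dm = purrr::map2_dbl(
        .data$time, .data$t1b,
        function(tt, t1b) asl_signal(tt, set_param(phys, "t1_b", t1b), acq)
      )
    )
}
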