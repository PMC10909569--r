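# GBCA dose/timing planner: blood concentration -> post-contrast blood T1
# via the relaxivity relation, and time-to-target-T1 per injected dose.

#' Relaxivity parameters
#'
#' @param r1 Longitudinal relaxivity of the contrast agent, s^-1 mM^-1
#'   (default 3.4, gadoterate at 3 T).
#' @param r1b_pre Pre-contrast blood relaxation rate, s^-1 (default 0.61,
#'   i.e. T1 about 1.64 s).
#' @return A list of class `relaxivity_params`.
#' @export
relaxivity_params <- function(r1 = 3.4, r1b_pre = 0.61) {
  stopifnot(r1 > 0, r1b_pre > 0)
  structure(list(r1 = r1, r1b_pre = r1b_pre), class = "relaxivity_params")
}

#' Post-contrast blood T1 from GBCA concentration
#'
#' The fast-exchange relaxivity relation `R1_post(t) = R1_pre + r1 * cb(t)`
#' converts a blood concentration to the shortened blood T1:
#' `t1b_post = 1 / (r1b_pre + r1 * cb)`. Strictly decreasing in `cb`; at
#' `cb = 0` it returns the pre-contrast T1.
#'
#' @param cb Blood GBCA concentration, mM (vectorized, >= 0).
#' @param relax A [relaxivity_params()].
#' @return Blood T1 values, s.
#' @examples
#' gbca_t1b_post(0)            # pre-contrast T1, 1/0.61
#' gbca_cb_for_t1(0.8)         # concentration giving the optimal 0.8 s
#' @export
gbca_t1b_post <- function(cb, relax = relaxivity_params()) {
  if (any(!is.finite(cb)) || any(cb < 0)) abort("`cb` must be >= 0.")
  1 / (relax$r1b_pre + relax$r1 * cb)
}

#' @describeIn gbca_t1b_post Inverse relation: the concentration required to
#'   reach a target blood T1 (`t1 <= 1/r1b_pre`).
#' @param t1 Target blood T1, s.
#' @export
gbca_cb_for_t1 <- function(t1, relax = relaxivity_params()) {
  stopifnot(all(t1 > 0), all(t1 <= 1 / relax$r1b_pre + 1e-12))
  (1 / t1 - relax$r1b_pre) / relax$r1
}

#' Population vascular input function
#'
#' Parametric population arterial blood concentration curve: two Gaussian
#' first- and second-pass boluses plus a sigmoid-modulated exponential
#' washout. Used to extrapolate or synthesize blood concentration curves
#' when measured samples are unavailable or end early. Coefficients default
#' to the published population values for a standard full dose
#' (0.1 mmol/kg) and are fully exposed.
#'
#' @param t Time post-injection, minutes (vectorized).
#' @param params Named list of coefficients: Gaussian scales `a1`, `a2`
#'   (mM min), centres `t1`, `t2` (min), widths `s1`, `s2` (min), washout
#'   amplitude `alpha` (mM), rate `beta` (1/min), sigmoid steepness `s`
#'   (1/min) and centre `tau` (min).
#' @return Blood concentration, mM.
#' @examples
#' parametric_vif(c(1, 5, 20))
#' @export
parametric_vif <- function(t, params = list(
                             a1 = 0.809, a2 = 0.330,
                             t1 = 0.17046, t2 = 0.365,
                             s1 = 0.0563, s2 = 0.132,
                             alpha = 1.050, beta = 0.1685,
                             s = 38.078, tau = 0.483
                           )) {
  p <- params
  g <- function(a, mu, sd) a / (sd * sqrt(2 * pi)) * exp(-(t - mu)^2 / (2 * sd^2))
  g(p$a1, p$t1, p$s1) + g(p$a2, p$t2, p$s2) +
    p$alpha * exp(-p$beta * t) / (1 + exp(-p$s * (t - p$tau)))
}

#' Build a VIF curve table
#'
#' @param t Time post-injection, minutes (non-decreasing).
#' @param cb Blood concentration, mM (>= 0). If missing, synthesized from
#'   [parametric_vif()].
#' @param dose_fraction Scale relative to a full dose.
#' @param source `"measured_table"` or `"parametric"`.
#' @return A tibble of class `vif_curve` with columns `t`, `cb` and
#'   attributes `dose_fraction`, `source`.
#' @examples
#' vif_curve(t = seq(0, 30, by = 0.5))
#' @export
vif_curve <- function(t, cb = NULL, dose_fraction = 1,
                      source = if (is.null(cb)) "parametric" else "measured_table") {
  if (is.null(cb)) cb <- parametric_vif(t)
  stopifnot(length(t) == length(cb), all(diff(t) >= 0), all(cb >= 0),
            dose_fraction > 0, dose_fraction <= 1)
  structure(tibble(t = t, cb = cb),
            class = c("vif_curve", class(tibble())),
            dose_fraction = dose_fraction, source = source)
}

#' Scale a VIF to a fractional GBCA dose
#'
#' Linear-kinetics assumption: concentrations scale pointwise with the
#' injected dose.
#'
#' @param vif A [vif_curve()].
#' @param fraction Dose fraction in (0, 1].
#' @return The scaled `vif_curve`.
#' @examples
#' scale_dose(vif_curve(seq(0, 30, 0.5)), 0.25)
#' @export
scale_dose <- function(vif, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  out <- vif
  out$cb <- vif$cb * fraction
  attr(out, "dose_fraction") <- attr(vif, "dose_fraction") * fraction
  out
}

#' Time after injection at which blood T1 recovers through a target
#'
#' Converts the concentration curve to a blood-T1 recovery curve via
#' [gbca_t1b_post()] and reports the latest time at which the curve crosses
#' the target from below during washout - i.e. after this time the blood T1
#' exceeds the target, so the post-contrast acquisition should happen before
#' it. The washout limb is interpolated with a monotone cubic spline; if the
#' measured samples end before the crossing, the curve is extrapolated with
#' the parametric VIF washout tail rescaled to match the last sample.
#'
#' @param vif A [vif_curve()].
#' @param target_t1 Target blood T1, s (between the curve minimum and the
#'   pre-contrast T1).
#' @param relax A [relaxivity_params()].
#' @param t_max Extrapolation horizon, minutes.
#' @param vif_params Parametric washout coefficients used for extrapolation
#'   (see [parametric_vif()]).
#'
#' @return A one-row tibble with `t_cross` (minutes; `NA` with `open = TRUE`
#'   when the target is never reached below) and the target concentration
#'   `cb_target`.
#' @examples
#' time_to_target(vif_curve(seq(0, 60, by = 0.25)), target_t1 = 0.8)
#' @export
time_to_target <- function(vif, target_t1, relax = relaxivity_params(),
                           t_max = 250,
                           vif_params = formals(parametric_vif)$params) {
  if (target_t1 >= 1 / relax$r1b_pre) {
    return(tibble(t_cross = NA_real_, cb_target = NA_real_, open = TRUE))
  }
  cb_target <- gbca_cb_for_t1(target_t1, relax)

  t <- vif$t
  cb <- vif$cb
  # extrapolate washout with the parametric tail, rescaled for continuity
  if (max(t) < t_max && cb[length(cb)] > 0) {
    p <- if (is.call(vif_params) || is.language(vif_params)) {
      eval(vif_params)
    } else {
      vif_params
    }
    tail_t <- seq(max(t) + 0.5, t_max, by = 0.5)
    tail_ref <- p$alpha * exp(-p$beta * tail_t) /
      (1 + exp(-p$s * (tail_t - p$tau)))
    anchor <- p$alpha * exp(-p$beta * max(t)) /
      (1 + exp(-p$s * (max(t) - p$tau)))
    if (anchor > 0) {
      t <- c(t, tail_t)
      cb <- c(cb, tail_ref * (cb[length(cb)] / anchor))
    }
  }

  # washout limb: from the global concentration peak onwards
  ipk <- which.max(cb)
  tw <- t[ipk:length(t)]
  cw <- cb[ipk:length(cb)]
  if (all(cw > cb_target)) {
    return(tibble(t_cross = NA_real_, cb_target = cb_target, open = TRUE))
  }
  if (cw[1] < cb_target) {  # never shortened enough
    return(tibble(t_cross = NA_real_, cb_target = cb_target, open = TRUE))
  }
  # last index still above target
  ilast <- max(which(cw >= cb_target))
  if (ilast == length(cw)) {
    return(tibble(t_cross = tw[ilast], cb_target = cb_target, open = FALSE))
  }
  # monotone interpolation on the bracketing segment of the washout limb
  seg <- max(1, ilast - 3):min(length(cw), ilast + 3)
  dedup <- !duplicated(tw[seg])
  sf <- stats::splinefun(tw[seg][dedup], cw[seg][dedup], method = "monoH.FC")
  root <- stats::uniroot(function(x) sf(x) - cb_target,
                         lower = tw[ilast], upper = tw[ilast + 1],
                         tol = 1e-8)$root
  tibble(t_cross = root, cb_target = cb_target, open = FALSE)
}
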