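# Supporting T1 estimation: variable-flip-angle SPGR fitting, blood-ROI T1
# extraction, and the ROI SNR estimator.

#' Fit T1 and M0 from variable-flip-angle SPGR signals
#'
#' Fits the spoiled gradient-echo steady-state signal model
#' `S(theta) = m0 * sin(theta) * (1 - E) / (1 - E * cos(theta))` with
#' `E = exp(-TR / T1)` to multi-flip-angle data by Levenberg-Marquardt
#' nonlinear least squares, initialized from the linearized DESPOT1
#' regression of `S/sin(theta)` on `S/tan(theta)`. B1 is assumed nominal.
#'
#' @param data A tibble of SPGR measurements: columns `flip` (degrees) and
#'   `signal`, plus an optional `voxel` column for multi-voxel input (one fit
#'   per voxel).
#' @param tr Repetition time, s (default 4.75 ms).
#'
#' @return A tibble with one row per voxel: `voxel`, `t1` (s), `m0`,
#'   `converged`, `masked` (TRUE for degenerate inputs - all-equal or
#'   non-positive signals - which are not fit).
#' @examples
#' acqn <- spgr_signal(t1 = 1.65, m0 = 100, flip = c(2, 5, 15, 20))
#' fit_vfa_t1(acqn)
#' @export
fit_vfa_t1 <- function(data, tr = 0.00475) {
  stopifnot(all(c("flip", "signal") %in% names(data)), tr > 0)
  if (!"voxel" %in% names(data)) data$voxel <- 1L
  split(data, data$voxel) |>
    purrr::map(function(d) .fit_vfa_one(d, tr)) |>
    dplyr::bind_rows()
}

.fit_vfa_one <- function(d, tr) {
  masked_row <- function() {
    tibble(voxel = d$voxel[1], t1 = NA_real_, m0 = NA_real_,
           converged = FALSE, masked = TRUE)
  }
  if (length(unique(d$flip)) < 2L) {
    abort("at least 2 distinct flip angles are required.")
  }
  if (any(d$signal < 0) || all(d$signal == d$signal[1]) ||
      max(d$signal) <= 0) {
    return(masked_row())
  }
  th <- d$flip * pi / 180
  s <- d$signal

  # DESPOT1 linearization for starting values: S/sin = E * S/tan + m0*(1-E)
  x <- s / tan(th)
  y <- s / sin(th)
  slope <- stats::cov(x, y) / stats::var(x)
  if (!is.finite(slope) || slope <= 0 || slope >= 1) {
    slope <- exp(-tr / 1.5)
  }
  t1_0 <- -tr / log(slope)
  m0_0 <- max(mean(y - slope * x) / (1 - slope), max(s))

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(log_t1 = log(t1_0), log_m0 = log(m0_0)),
      fn = function(p) {
        e <- exp(-tr / exp(p[1]))
        s - exp(p[2]) * sin(th) * (1 - e) / (1 - e * cos(th))
      },
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(masked_row())
  tibble(voxel = d$voxel[1],
         t1 = exp(fit$par[[1]]), m0 = exp(fit$par[[2]]),
         converged = fit$info %in% 1:4, masked = FALSE)
}

#' @describeIn fit_vfa_t1 Forward SPGR signal model; returns a tibble with
#'   columns `flip` and `signal` ready for fitting.
#' @param t1 Longitudinal relaxation time, s.
#' @param m0 Equilibrium signal, arbitrary units.
#' @param flip Flip angles, degrees.
#' @export
spgr_signal <- function(t1, m0, flip = c(2, 5, 15, 20), tr = 0.00475) {
  th <- flip * pi / 180
  e <- exp(-tr / t1)
  tibble(flip = flip, signal = m0 * sin(th) * (1 - e) / (1 - e * cos(th)))
}

#' DESPOT1 linearized T1 estimate
#'
#' Ordinary least-squares regression of `S/sin(theta)` on `S/tan(theta)`;
#' the slope is `exp(-TR/T1)`. Used as an independent check of the
#' nonlinear fit (they agree closely at moderate-to-high SNR).
#'
#' @inheritParams fit_vfa_t1
#' @return A one-row tibble with `t1` and `m0`.
#' @export
despot1_t1 <- function(data, tr = 0.00475) {
  th <- data$flip * pi / 180
  s <- data$signal
  x <- s / tan(th)
  y <- s / sin(th)
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  tibble(t1 = -tr / log(slope), m0 = intercept / (1 - slope))
}

#' Extract blood T1 before and after contrast from a sinus ROI
#'
#' Within a seed ROI (sagittal/straight sinus), keeps only voxels whose T1
#' dropped by at least `reduction_threshold` after contrast - the
#' high-blood-volume voxels - then takes the 75th percentile (by default) of
#' the pre-contrast T1 as `t1b_pre`, and subtracts the same percentile of
#' the pre-post difference image to obtain `t1b_post`. Percentiles use
#' linear interpolation between order statistics.
#'
#' @param t1_pre,t1_post Pre-/post-contrast T1 values of the seed-ROI voxels
#'   (numeric vectors, co-registered, same length), s.
#' @param reduction_threshold Minimum fractional T1 reduction for a voxel to
#'   enter the blood ROI (default 0.20).
#' @param percentile Summary percentile in (0, 100), default 75.
#'
#' @return A one-row tibble with `t1b_pre`, `t1b_post`, `n_voxels` (mask
#'   size).
#' @examples
#' estimate_blood_t1(t1_pre = rep(1.8, 5), t1_post = rep(1.0, 5))
#' @export
estimate_blood_t1 <- function(t1_pre, t1_post, reduction_threshold = 0.20,
                              percentile = 75) {
  stopifnot(length(t1_pre) == length(t1_post), length(t1_pre) >= 1,
            reduction_threshold > 0, reduction_threshold < 1,
            percentile > 0, percentile < 100)
  reduction <- (t1_pre - t1_post) / t1_pre
  mask <- is.finite(reduction) & reduction >= reduction_threshold
  if (!any(mask)) {
    abort(paste0(
      "no seed voxels show a >= ", 100 * reduction_threshold,
      "% T1 reduction; consider relaxing `reduction_threshold`."
    ))
  }
  pre <- t1_pre[mask]
  dif <- (t1_pre - t1_post)[mask]
  t1b_pre <- unname(quantile(pre, percentile / 100, type = 7))
  t1b_post <- t1b_pre - unname(quantile(dif, percentile / 100, type = 7))
  tibble(t1b_pre = t1b_pre, t1b_post = t1b_post, n_voxels = sum(mask))
}

#' ROI SNR of an ASL difference image
#'
#' Approximates the voxel-level SNR within an ROI (after averaging signal
#' repetitions) as the mean divided by the standard deviation of the
#' difference values. Scale-invariant; a zero-SD ROI is flagged infinite.
#'
#' @param values Difference-image values within the ROI (>= 2 voxels).
#' @return A one-row tibble with `snr`, `mean`, `sd` and `flagged`
#'   (TRUE when the SD is zero and `snr` is `Inf`).
#' @examples
#' roi_snr(rnorm(100, mean = 3.6, sd = 1))
#' @export
roi_snr <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  m <- mean(values)
  s <- stats::sd(values)
  tibble(snr = if (s == 0) Inf else m / s, mean = m, sd = s,
         flagged = s == 0)
}
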