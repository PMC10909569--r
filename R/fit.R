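# Parameter estimation: fitting the closed-form signal to pre+post-contrast
# difference data for (f, t_a, k_b).

#' Fitting configuration
#'
#' Two configurations are provided. `"bounded_multistart"` (the default, used
#' by all simulation studies) performs box-bounded Levenberg-Marquardt
#' least squares from `n_starts` starting points drawn uniformly between the
#' bounds, keeping the lowest-SSE solution. `"simplex"` mirrors the in-vivo
#' analysis: a single unconstrained Nelder-Mead search from fixed initial
#' values (f = 60 mL/min/100 mL, t_a = 1 s, k_b = 1 s^-1).
#'
#' @param method `"bounded_multistart"` or `"simplex"`.
#' @param bounds Named list of `c(lo, hi)` per parameter. Defaults:
#'   `f` in \[0, 200\] mL/min/100 mL, `t_a` in \[0, 2.5\] s, `k_b` in
#'   \[0, 5\] s^-1.
#' @param n_starts Number of multistart draws (>= 1).
#' @param init Starting values for the simplex mode.
#' @param seed RNG seed for start-point sampling (`NULL` leaves the RNG
#'   state untouched).
#' @param screen_kb Range used for the fit-level "extreme" diagnostic flag: a
#'   fit is flagged when `k_b` falls within `screen_margin` of the range
#'   width of either end. Defaults to the `k_b` fitting bounds. (Study-level
#'   discarding in [summarize_fits()] uses its own, value-relative rule.)
#' @param screen_margin Fractional margin of the range used for the flag.
#' @param ftol,ptol Relative function / parameter convergence tolerances.
#' @param maxfev Maximum residual evaluations per start.
#' @param engine `"lm"` (compiled Levenberg-Marquardt with the analytic
#'   Jacobian; the default) or `"minpack"` ([minpack.lm::nls.lm()] with
#'   numeric differentiation). The two agree to optimizer tolerance; the
#'   minpack engine is retained as an independent cross-check.
#'
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(method = c("bounded_multistart", "simplex"),
                       bounds = list(f = c(0, 200), t_a = c(0, 2.5),
                                     k_b = c(0, 5)),
                       n_starts = 100,
                       init = c(f = 60, t_a = 1.0, k_b = 1.0),
                       seed = NULL,
                       screen_kb = NULL,
                       screen_margin = 0.05,
                       ftol = 1e-10, ptol = 1e-8, maxfev = 2000,
                       engine = c("lm", "minpack")) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  stopifnot(
    all(c("f", "t_a", "k_b") %in% names(bounds)),
    all(vapply(bounds, function(b) b[1] < b[2], logical(1))),
    n_starts >= 1
  )
  structure(
    list(method = method, bounds = bounds, n_starts = n_starts, init = init,
         seed = seed, screen_kb = screen_kb %||% bounds$k_b,
         screen_margin = screen_margin,
         ftol = ftol, ptol = ptol, maxfev = maxfev, engine = engine),
    class = "fit_config"
  )
}

# Precompute everything the residual function needs from a data table with
# columns time, dm, t1b plus fixed t1_e / acquisition settings.
.make_resid_fn <- function(data, t1_e, acq, lambda) {
  r1b <- 1 / data$t1b
  r1e <- 1 / t1_e
  am <- 2 * acq$alpha * acq$m0 / (lambda * 6000)
  t <- data$time
  dm <- data$dm
  t_l <- acq$t_l
  # r1b varies row-wise (pre/post phases); .dm_eval takes scalar r1b, so
  # evaluate per unique value
  groups <- split(seq_along(t), r1b)
  r1b_vals <- as.numeric(names(groups))
  function(par) {
    pred <- numeric(length(t))
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      pred[idx] <- .dm_eval(t[idx], f = par[1], t_a = par[2], k_b = par[3],
                            r1b = r1b_vals[gi], r1e = r1e, t_l = t_l, am = am)
    }
    dm - pred
  }
}

#' Fit the two-compartment model to multi-PLD difference data
#'
#' Estimates cerebral blood flow `f`, arterial transit time `t_a` and the
#' water exchange rate `k_b` by least squares over all supplied data points
#' (pre- and post-contrast phases jointly, unweighted), with the relaxation
#' times fixed at their supplied values.
#'
#' @param data A tibble with one row per measurement and columns `time`
#'   (seconds from labelling onset; if absent it is computed as
#'   `acq$t_l + pld`), `dm` (difference-signal value) and `t1b` (the blood T1
#'   applicable to that measurement's contrast phase, s).
#' @param t1_e Extravascular T1 fixed during fitting, s.
#' @param acq An [acq_params()] object supplying `t_l`, `alpha`, `m0`.
#' @param config A [fit_config()].
#' @param lambda Brain:blood partition coefficient.
#'
#' @return An object of class `ceasl_fit`: a list with elements `estimates`
#'   (named vector `f`, `t_a`, `k_b`), `sse`, `n_converged`, `at_bound`
#'   (named logical), `extreme` (k_b within the screening margin), `method`,
#'   and `data` (the input with a `fitted` column appended). Supports
#'   [generics::tidy()] and [generics::glance()].
#' @examples
#' design <- asl_design()
#' truth <- physio_params(f = 60, t_a = 1.2, k_b = 2.65)
#' acq <- acq_params()
#' dat <- asl_signal_design(design, truth, acq)
#' fit <- fit_asl(dat, t1_e = 1.5, acq = acq,
#'                config = fit_config(n_starts = 10, seed = 1))
#' tidy(fit)
#' @export
fit_asl <- function(data, t1_e, acq, config = fit_config(), lambda = 0.9) {
  stopifnot(inherits(config, "fit_config"))
  if (!"time" %in% names(data)) {
    if (!"pld" %in% names(data)) abort("`data` needs a `time` or `pld` column.")
    data$time <- acq$t_l + data$pld
  }
  if (!all(c("dm", "t1b") %in% names(data))) {
    abort("`data` must have columns `dm` and `t1b`.")
  }
  if (nrow(data) < 4L) {
    abort("at least 4 data points are required to fit (f, t_a, k_b).")
  }
  resid_fn <- .make_resid_fn(data, t1_e, acq, lambda)

  if (config$method == "simplex") {
    res <- optim(config$init, function(p) sum(resid_fn(p)^2),
                 method = "Nelder-Mead",
                 control = list(reltol = config$ftol, maxit = config$maxfev))
    est <- res$par
    sse <- res$value
    n_conv <- as.integer(res$convergence == 0)
  } else {
    lo <- vapply(config$bounds, `[`, numeric(1), 1L)
    hi <- vapply(config$bounds, `[`, numeric(1), 2L)
    draw <- function() {
      matrix(runif(3L * config$n_starts, rep(lo, each = config$n_starts),
                   rep(hi, each = config$n_starts)),
             ncol = 3L, dimnames = list(NULL, c("f", "t_a", "k_b")))
    }
    starts <- if (is.null(config$seed)) draw() else {
      withr::with_seed(config$seed, draw())
    }
    if (config$engine == "lm") {
      ord <- order(data$time)
      res <- .fit_multistart_lm_cpp(
        data$time[ord], data$dm[ord], 1 / data$t1b[ord], 1 / t1_e,
        acq$t_l, 2 * acq$alpha * acq$m0 / (lambda * 6000),
        starts, lo, hi, config$ftol, config$ptol, as.integer(config$maxfev)
      )
      if (!all(is.finite(res$par))) {
        abort(sprintf(
          "all %d starts failed for the %d-point fit (t1_e = %g)",
          config$n_starts, nrow(data), t1_e
        ))
      }
      est <- setNames(res$par, c("f", "t_a", "k_b"))
      sse <- res$sse
      n_conv <- res$n_converged
    } else {
      best <- NULL
      n_conv <- 0L
      for (i in seq_len(config$n_starts)) {
        res <- tryCatch(
          minpack.lm::nls.lm(
            par = starts[i, ], lower = lo, upper = hi, fn = resid_fn,
            control = minpack.lm::nls.lm.control(
              ftol = config$ftol, ptol = config$ptol, maxfev = config$maxfev
            )
          ),
          error = function(e) NULL
        )
        if (is.null(res)) next
        n_conv <- n_conv + 1L
        if (is.null(best) || res$deviance < best$deviance) best <- res
      }
      if (is.null(best)) {
        abort(sprintf(
          "all %d starts failed for the %d-point fit (t1_e = %g)",
          config$n_starts, nrow(data), t1_e
        ))
      }
      est <- setNames(as.numeric(best$par), c("f", "t_a", "k_b"))
      sse <- best$deviance
    }
  }

  lo <- vapply(config$bounds, `[`, numeric(1), 1L)
  hi <- vapply(config$bounds, `[`, numeric(1), 2L)
  tol <- 1e-6 * (hi - lo)
  at_bound <- setNames(est <= lo + tol | est >= hi - tol, c("f", "t_a", "k_b"))
  margin <- config$screen_margin * diff(config$screen_kb)
  extreme <- est[["k_b"]] <= config$screen_kb[1] + margin ||
    est[["k_b"]] >= config$screen_kb[2] - margin

  data$fitted <- data$dm - resid_fn(est)
  structure(
    list(estimates = setNames(as.numeric(est), c("f", "t_a", "k_b")),
         sse = sse, n_converged = n_conv, at_bound = at_bound,
         extreme = extreme, method = config$method, data = data),
    class = "ceasl_fit"
  )
}

#' @export
tidy.ceasl_fit <- function(x, ...) {
  tibble(
    term = names(x$estimates),
    estimate = as.numeric(x$estimates),
    at_bound = as.logical(x$at_bound)
  )
}

#' @export
glance.ceasl_fit <- function(x, ...) {
  tibble(
    sse = x$sse, n_converged = x$n_converged,
    extreme = x$extreme, method = x$method,
    n_obs = nrow(x$data)
  )
}

#' @export
print.ceasl_fit <- function(x, ...) {
  cat("<ceasl_fit>", x$method, "on", nrow(x$data), "points\n")
  cat(sprintf("  f    = %8.3f mL/min/100 mL\n", x$estimates[["f"]]))
  cat(sprintf("  t_a  = %8.4f s\n", x$estimates[["t_a"]]))
  cat(sprintf("  k_b  = %8.4f 1/s%s\n", x$estimates[["k_b"]],
              if (x$extreme) "  [extreme]" else ""))
  cat(sprintf("  SSE  = %.3e, %d converged starts\n", x$sse, x$n_converged))
  invisible(x)
}
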