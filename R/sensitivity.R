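# Protocol-optimization sweeps of the k_b sensitivity function.

.default_phys_sens <- function() {
  physio_params(f = 60, t_a = 1.2, k_b = 2.65, t1_b = 1.65, t1_e = 1.5,
                lambda = 0.9)
}

.sens_at <- function(t1b, pld, phys, acq) {
  asl_sensitivity_kb(acq$t_l + pld, set_param(phys, "t1_b", t1b), acq)
}

#' Sensitivity surface over post-contrast blood T1 and PLD
#'
#' Evaluates the analytic sensitivity of the ASL difference signal to the
#' exchange rate, `d(dM)/d(k_b)`, on a grid of blood T1 and post-labelling
#' delay values, at the single measurement time `t = t_l + pld`. The surface
#' is normalized by its maximum signed value, so the optimum is exactly 1 and
#' regions where longer blood T1 flips the sign of the sensitivity appear as
#' negative values.
#'
#' With the default grey-matter operating point (`k_b = 2.65` s^-1,
#' `t1_e = 1.5` s, `f = 60`, `t_a = 1.2` s, `t_l = 2` s) the optimum falls at
#' `t1b = 0.8` s, `pld = 1.5` s.
#'
#' @param t1b_range,pld_range Ranges (length-2) swept for blood T1 and PLD, s.
#' @param n_t1b,n_pld Number of grid points per axis (>= 50 each).
#' @param phys Fixed physiological parameters ([physio_params()]); `t1_b` is
#'   overridden by the grid.
#' @param acq Fixed acquisition parameters ([acq_params()]).
#'
#' @return A tibble of class `ceasl_sensitivity_surface` with columns `t1b`,
#'   `pld`, `sensitivity` (raw, signal units per s^-1) and `normalized`,
#'   plus attributes `argmax` (named vector `t1b`, `pld`),
#'   `normalization_constant` and `ties` (TRUE if the maximum is attained at
#'   more than one grid point).
#' @examples
#' surf <- sensitivity_surface(n_t1b = 51, n_pld = 51)
#' attr(surf, "argmax")
#' @export
sensitivity_surface <- function(t1b_range = c(0.15, 1.65),
                                pld_range = c(0.5, 3.0),
                                n_t1b = 151, n_pld = 151,
                                phys = .default_phys_sens(),
                                acq = acq_params()) {
  stopifnot(length(t1b_range) == 2L, length(pld_range) == 2L,
            diff(t1b_range) > 0, diff(pld_range) > 0)
  if (n_t1b < 2 || n_pld < 2) abort("sensitivity grid must have >= 2 points per axis")
  t1b_grid <- seq(t1b_range[1], t1b_range[2], length.out = n_t1b)
  pld_grid <- seq(pld_range[1], pld_range[2], length.out = n_pld)

  grid <- tidyr::expand_grid(t1b = t1b_grid, pld = pld_grid)
  vals <- unlist(purrr::map(t1b_grid, function(tb) {
    asl_sensitivity_kb(acq$t_l + pld_grid, set_param(phys, "t1_b", tb), acq)
  }))
  grid$sensitivity <- vals

  norm_const <- max(grid$sensitivity)
  grid$normalized <- grid$sensitivity / norm_const
  imax <- which(grid$sensitivity == norm_const)
  argmax <- c(t1b = grid$t1b[imax[1]], pld = grid$pld[imax[1]])

  structure(
    grid,
    class = c("ceasl_sensitivity_surface", class(grid)),
    argmax = argmax,
    normalization_constant = norm_const,
    ties = length(imax) > 1L
  )
}

#' Sensitivity dependence on extravascular T1 (contrast-agent leakage)
#'
#' Sweeps the extravascular relaxation time from its equilibrium value down
#' towards the post-contrast blood T1, mimicking progressive leakage of
#' gadolinium into tissue, with blood T1 and PLD held at their optimized
#' values. Sensitivity decreases approximately linearly and vanishes at
#' `t1_e = t1_b`, where the compartments become indistinguishable. Values are
#' normalized to the sweep's equilibrium anchor (`t1e_anchor`).
#'
#' @param t1e Extravascular T1 values to evaluate, s; all must be >= `t1b`.
#' @param t1b Fixed blood T1, s (default the optimized 0.8 s).
#' @param pld Fixed post-labelling delay, s (default the optimized 1.5 s).
#' @param t1e_anchor The T1_e whose sensitivity defines normalized value 1.
#' @inheritParams sensitivity_surface
#'
#' @return A tibble with columns `t1e`, `sensitivity`, `normalized`.
#' @examples
#' sensitivity_t1e_sweep(t1e = seq(0.8, 1.5, by = 0.1))
#' @export
sensitivity_t1e_sweep <- function(t1e = seq(0.8, 1.5, by = 0.01),
                                  t1b = 0.8, pld = 1.5, t1e_anchor = 1.5,
                                  phys = .default_phys_sens(),
                                  acq = acq_params()) {
  if (any(t1e < t1b)) {
    abort("`t1e` below `t1b` is outside the leakage sweep's physical range.")
  }
  phys <- set_param(phys, "t1_b", t1b)
  sens <- purrr::map_dbl(t1e, function(te) {
    asl_sensitivity_kb(acq$t_l + pld, set_param(phys, "t1_e", te), acq)
  })
  anchor <- asl_sensitivity_kb(acq$t_l + pld,
                               set_param(phys, "t1_e", t1e_anchor), acq)
  tibble(t1e = t1e, sensitivity = sens, normalized = sens / anchor)
}

#' Sensitivity dependence on the underlying exchange rate
#'
#' Evaluates, for each underlying `k_b`, the sensitivity magnitude at a fixed
#' evaluation blood T1 (default the optimized 0.8 s) and the blood T1 that
#' maximizes sensitivity at that exchange rate. Values are normalized to the
#' `kb_anchor` operating point (default `k_b = 2.65` s^-1), so the output
#' reads directly as relative measurement precision versus the nominal
#' grey-matter exchange rate.
#'
#' @param kb Exchange rates to evaluate, s^-1.
#' @param eval_t1b Blood T1 at which the normalized sensitivity is reported, s.
#' @param pld Fixed post-labelling delay, s.
#' @param t1b_range Range of blood T1 searched for the per-`k_b` optimum, s.
#' @param t1b_step Grid step of the optimum search, s.
#' @param kb_anchor Exchange rate whose sensitivity defines normalized 1.
#' @inheritParams sensitivity_surface
#'
#' @return A tibble with columns `kb`, `sensitivity` (at `eval_t1b`),
#'   `normalized` and `optimal_t1b`.
#' @examples
#' sensitivity_kb_sweep(kb = c(0.5, 2.65, 4.0))
#' @export
sensitivity_kb_sweep <- function(kb = seq(0.5, 4.0, by = 0.05),
                                 eval_t1b = 0.8, pld = 1.5,
                                 t1b_range = c(0.15, 1.65),
                                 t1b_step = 0.005,
                                 kb_anchor = 2.65,
                                 phys = .default_phys_sens(),
                                 acq = acq_params()) {
  t1b_grid <- seq(t1b_range[1], t1b_range[2], by = t1b_step)
  t <- acq$t_l + pld

  per_kb <- purrr::map(kb, function(k) {
    pk <- set_param(phys, "k_b", k)
    prof <- purrr::map_dbl(t1b_grid, function(tb) {
      asl_sensitivity_kb(t, set_param(pk, "t1_b", tb), acq)
    })
    list(
      sensitivity = asl_sensitivity_kb(t, set_param(pk, "t1_b", eval_t1b), acq),
      optimal_t1b = t1b_grid[which.max(prof)]
    )
  })

  anchor <- asl_sensitivity_kb(
    t, set_param(set_param(phys, "k_b", kb_anchor), "t1_b", eval_t1b), acq
  )
  tibble(
    kb = kb,
    sensitivity = purrr::map_dbl(per_kb, "sensitivity"),
    normalized = purrr::map_dbl(per_kb, "sensitivity") / anchor,
    optimal_t1b = purrr::map_dbl(per_kb, "optimal_t1b")
  )
}

#' @describeIn sensitivity_surface Heatmap of the normalized sensitivity
#'   surface with the optimum marked.
#' @param object A `ceasl_sensitivity_surface`.
#' @param ... Ignored.
#' @export
autoplot.ceasl_sensitivity_surface <- function(object, ...) {
  am <- attr(object, "argmax")
  ggplot2::ggplot(object, ggplot2::aes(.data$pld, .data$t1b,
                                       fill = .data$normalized)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::annotate("point", x = am[["pld"]], y = am[["t1b"]],
                      shape = 4, size = 3) +
    ggplot2::labs(x = "PLD (s)", y = expression(T[1][",b"] ~ "(s)"),
                  fill = "normalized\nsensitivity")
}
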