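#' Physiological parameters of a voxel or ROI
#'
#' Bundles the biophysical state that determines the ASL difference signal of
#' the two-compartment water-exchange model: perfusion, arterial transit time,
#' the blood-to-tissue water exchange rate and the longitudinal relaxation
#' times of the two compartments.
#'
#' @param f Cerebral blood flow, mL blood/min/100 mL tissue. Converted to
#'   s^-1 (division by 6000) inside all model equations.
#' @param t_a Arterial transit time, s.
#' @param k_b Blood-to-tissue water exchange rate, s^-1 (`k_b = PS / v_bw`).
#' @param t1_b Longitudinal relaxation time of blood, s. Use the pre-contrast
#'   value for pre-contrast signals and the GBCA-shortened value after
#'   injection.
#' @param t1_e Longitudinal relaxation time of the extravascular space, s.
#' @param lambda Brain:blood partition coefficient, mL/g.
#' @param v_bw Blood water volume fraction (optional; only needed to report
#'   the permeability-surface-area product `PS = k_b * v_bw`).
#'
#' @return An object of class `physio_params` (a named list).
#' @examples
#' physio_params(f = 60, t_a = 1.2, k_b = 2.65, t1_b = 1.65, t1_e = 1.5)
#' @export
physio_params <- function(f = 60, t_a = 1.2, k_b = 2.65, t1_b = 1.65,
                          t1_e = 1.5, lambda = 0.9, v_bw = NULL) {
  stopifnot(
    is.numeric(f), length(f) == 1L, is.finite(f), f >= 0,
    is.numeric(t_a), length(t_a) == 1L, is.finite(t_a), t_a >= 0,
    is.numeric(k_b), length(k_b) == 1L, is.finite(k_b), k_b >= 0,
    is.numeric(t1_b), length(t1_b) == 1L, is.finite(t1_b), t1_b > 0,
    is.numeric(t1_e), length(t1_e) == 1L, is.finite(t1_e), t1_e > 0,
    is.numeric(lambda), length(lambda) == 1L, lambda > 0, lambda <= 1.2
  )
  if (!is.null(v_bw)) stopifnot(is.numeric(v_bw), v_bw > 0, v_bw < 1)
  structure(
    list(f = f, t_a = t_a, k_b = k_b, t1_b = t1_b, t1_e = t1_e,
         lambda = lambda, v_bw = v_bw),
    class = "physio_params"
  )
}

#' Acquisition parameters for continuous labelling
#'
#' @param t_l Label duration, s.
#' @param alpha Inversion efficiency of the labelling, dimensionless in (0, 1].
#' @param m0 Equilibrium magnetization per mL tissue, arbitrary units.
#' @param plds Ordered post-labelling delays, s. Measurement times are
#'   `t = t_l + pld` from the start of labelling.
#'
#' @return An object of class `acq_params` (a named list).
#' @examples
#' acq_params(t_l = 2, alpha = 0.85, m0 = 1, plds = c(0.9, 1.2, 1.5, 1.8, 2.1))
#' @export
acq_params <- function(t_l = 2, alpha = 0.85, m0 = 1,
                       plds = c(0.9, 1.2, 1.5, 1.8, 2.1)) {
  stopifnot(
    is.numeric(t_l), length(t_l) == 1L, is.finite(t_l), t_l > 0,
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
    is.numeric(m0), length(m0) == 1L, is.finite(m0), m0 > 0,
    is.numeric(plds), length(plds) >= 1L, all(is.finite(plds)), all(plds >= 0),
    all(diff(plds) > 0)
  )
  structure(
    list(t_l = t_l, alpha = alpha, m0 = m0, plds = plds),
    class = "acq_params"
  )
}

#' Multi-PLD acquisition design with pre- and post-contrast phases
#'
#' Builds the tabular acquisition design used throughout the simulation
#' studies: a set of pre-contrast PLDs acquired at the equilibrium blood T1
#' and one (or more) post-contrast PLDs acquired at the GBCA-shortened blood
#' T1. The default reproduces the simulation design: five pre-contrast PLDs
#' between 0.9 and 2.1 s at T1_b = 1.65 s plus a single post-contrast PLD of
#' 1.5 s at T1_b = 0.8 s.
#'
#' @param plds_pre Pre-contrast post-labelling delays, s.
#' @param plds_post Post-contrast post-labelling delays, s.
#' @param t1b_pre Pre-contrast blood T1, s.
#' @param t1b_post Post-contrast blood T1, s.
#'
#' @return A tibble with columns `phase` ("pre"/"post"), `pld` and `t1b`.
#' @examples
#' asl_design()
#' @export
asl_design <- function(plds_pre = c(0.9, 1.2, 1.5, 1.8, 2.1),
                       plds_post = 1.5,
                       t1b_pre = 1.65, t1b_post = 0.8) {
  stopifnot(t1b_pre > 0, t1b_post > 0)
  dplyr::bind_rows(
    tibble(phase = "pre", pld = as.numeric(plds_pre), t1b = t1b_pre),
    tibble(phase = "post", pld = as.numeric(plds_post), t1b = t1b_post)
  )
}

# Replace a single field of a physio_params object, revalidating.
set_param <- function(phys, name, value) {
  args <- unclass(phys)
  args[[name]] <- value
  do.call(physio_params, args)
}
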