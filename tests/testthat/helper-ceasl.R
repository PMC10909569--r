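# Shared fixtures: the grey-matter operating point and simulation design
# used across the analyses.

gm_truth <- function(...) {
  args <- utils::modifyList(
    list(f = 60, t_a = 1.2, k_b = 2.65, t1_b = 1.65, t1_e = 1.5,
         lambda = 0.9),
    list(...)
  )
  do.call(physio_params, args)
}

std_acq <- function() acq_params(t_l = 2, alpha = 0.85, m0 = 1)

std_design <- function() asl_design()  # 5 pre-PLDs at 1.65 s + 1 post at 0.8 s

quick_config <- function(n_starts = 25, seed = 42L, kb_hi = 5, ...) {
  fit_config(bounds = list(f = c(0, 200), t_a = c(0, 2.5), k_b = c(0, kb_hi)),
             n_starts = n_starts, seed = seed, ...)
}

# Rebuild a physio_params object with some fields replaced.
set_param_test <- function(phys, ...) {
  args <- utils::modifyList(
    unclass(phys)[c("f", "t_a", "k_b", "t1_b", "t1_e", "lambda")],
    list(...)
  )
  do.call(physio_params, args)
}

# Latin-hypercube draws over the simulation parameter ranges; returns a
# data frame of physiological/acquisition parameter sets.
lhs_params <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    u <- if (requireNamespace("lhs", quietly = TRUE)) {
      lhs::randomLHS(n, 5)
    } else {
      matrix(runif(n * 5), n, 5)
    }
    data.frame(
      f = 20 + u[, 1] * 80,          # 20-100 mL/min/100 mL
      t_a = 0.5 + u[, 2] * 1.5,      # 0.5-2.0 s
      k_b = u[, 3] * 5,              # 0-5 1/s
      t1_b = 0.15 + u[, 4] * 1.5,    # 0.15-1.65 s
      t1_e = 0.8 + u[, 5] * 0.7      # 0.8-1.5 s
    )
  })
}
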