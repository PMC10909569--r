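# Synthetic-data generator: phantom parameter maps and multi-PLD ASL
# control/label/difference volumes with known ground truth.

#' Phantom specification
#'
#' Describes a rectangular 3D phantom partitioned into labelled regions,
#' each carrying its own ground-truth physiology. Regions are assigned in
#' contiguous blocks of foreground voxels (in array order) proportionally to
#' `weight`, unless an explicit `label_map` is supplied.
#'
#' @param shape 3D grid dimensions, e.g. `c(8, 8, 4)`.
#' @param regions A tibble with one row per region: columns `label`
#'   (positive integer), `f`, `t_a`, `k_b`, `t1_e`, and optionally `weight`
#'   (relative region size, default equal).
#' @param design Acquisition design from [asl_design()].
#' @param acq An [acq_params()] object (`m0` is the phantom's uniform
#'   equilibrium magnetization).
#' @param noise A [noise_model()] giving the voxel-level `sigma` and
#'   background-suppression level (its `n_reps`/`roi_size` are ignored:
#'   the phantom is one realization of every voxel).
#' @param label_map Optional integer array of `shape` with 0 = background
#'   and values matching `regions$label`.
#' @param seed RNG seed for the noise realization.
#'
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(8, 8, 4),
                         regions = tibble(
                           label = 1:2, f = c(60, 45), t_a = c(1.2, 1.0),
                           k_b = c(2.65, 1.0), t1_e = c(1.5, 1.4)
                         ),
                         design = asl_design(),
                         acq = acq_params(),
                         noise = noise_model(sigma = 0.0017),
                         label_map = NULL,
                         seed = NULL) {
  stopifnot(length(shape) == 3L, all(shape >= 1),
            all(c("label", "f", "t_a", "k_b", "t1_e") %in% names(regions)),
            all(regions$label > 0), !anyDuplicated(regions$label))
  if (!is.null(label_map)) {
    stopifnot(all(dim(label_map) == shape),
              all(label_map %in% c(0, regions$label)))
  }
  if (!"weight" %in% names(regions)) regions$weight <- 1
  structure(
    list(shape = shape, regions = regions, design = design, acq = acq,
         noise = noise, label_map = label_map, seed = seed),
    class = "phantom_spec"
  )
}

#' Generate a synthetic ASL phantom
#'
#' Builds 4D control/label/difference volumes (x, y, z, measurement - one
#' measurement per design row), a uniform M0 volume, a T1_e map, the region
#' label map and a ground-truth table. Voxel values follow
#' `control = bs * m0 + dm/2 + noise`, `label = bs * m0 - dm/2 + noise`
#' with independent zero-mean Gaussian noise on each image, so
#' `control - label` has mean `dm` and noise SD `sigma * sqrt(2)`.
#' Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `ceasl_phantom` with elements `control`, `label`,
#'   `difference` (4D arrays), `m0` (3D), `t1e_map` (3D), `label_map` (3D
#'   integer), `truth` (tibble), and the `design`, `acq`, `noise` used.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(4, 4, 1), seed = 1))
#' dim(ph$difference)
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  n_vox <- prod(shape)
  n_meas <- nrow(spec$design)
  regions <- spec$regions

  label_map <- spec$label_map
  if (is.null(label_map)) {
    w <- regions$weight / sum(regions$weight)
    sizes <- diff(round(c(0, cumsum(w)) * n_vox))
    if (any(sizes < 1)) abort("phantom too small for the requested regions")
    label_map <- array(rep(regions$label, times = sizes), dim = shape)
  }

  t1e_map <- array(0, dim = shape)
  dm_true <- matrix(0, nrow = n_vox, ncol = n_meas)
  for (i in seq_len(nrow(regions))) {
    idx <- which(label_map == regions$label[i])
    phys <- physio_params(f = regions$f[i], t_a = regions$t_a[i],
                          k_b = regions$k_b[i], t1_e = regions$t1_e[i])
    dm_row <- asl_signal_design(spec$design, phys, spec$acq)$dm
    dm_true[idx, ] <- matrix(dm_row, nrow = length(idx), ncol = n_meas,
                             byrow = TRUE)
    t1e_map[idx] <- regions$t1_e[i]
  }

  level <- spec$noise$background_suppression * spec$acq$m0
  gen <- function() {
    array(rnorm(2 * n_vox * n_meas, sd = spec$noise$sigma),
          dim = c(n_vox, n_meas, 2))
  }
  eps <- if (is.null(spec$seed)) gen() else withr::with_seed(spec$seed, gen())
  fg <- as.vector(label_map > 0)

  control <- (level + dm_true / 2 + eps[, , 1]) * fg
  label_im <- (level - dm_true / 2 + eps[, , 2]) * fg

  to4d <- function(m) array(m, dim = c(shape, n_meas))
  structure(
    list(
      control = to4d(control),
      label = to4d(label_im),
      difference = to4d(control - label_im),
      m0 = array(spec$acq$m0 * fg, dim = shape),
      t1e_map = t1e_map,
      label_map = label_map,
      truth = regions[c("label", "f", "t_a", "k_b", "t1_e")],
      design = spec$design, acq = spec$acq, noise = spec$noise,
      seed = spec$seed
    ),
    class = "ceasl_phantom"
  )
}

#' Tabular synthetic signal set
#'
#' The tabular twin of the phantom generator: noise-free or noisy replicate
#' difference-signal tables at a single ground truth, for fitting tests and
#' fixtures. With `noise = NULL` returns the noise-free design table
#' (columns `phase`, `pld`, `t1b`, `time`, `dm`); with a [noise_model()]
#' returns `n_reps` noisy replicates via [simulate_noisy_difference()].
#'
#' @param truth Ground-truth [physio_params()].
#' @param design Acquisition design from [asl_design()].
#' @param acq An [acq_params()] object.
#' @param noise Optional [noise_model()].
#' @param file Optional path; if given, the table is also written as CSV.
#'
#' @return A tibble.
#' @examples
#' make_signal_table(physio_params(), asl_design(), acq_params())
#' @export
make_signal_table <- function(truth = physio_params(),
                              design = asl_design(),
                              acq = acq_params(),
                              noise = NULL, file = NULL) {
  tab <- if (is.null(noise)) {
    asl_signal_design(design, truth, acq)
  } else {
    simulate_noisy_difference(truth, design, acq, noise)
  }
  if (!is.null(file)) utils::write.csv(tab, file, row.names = FALSE)
  tab
}

#' Write phantom volumes as NIfTI-1 files
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_phantom_nifti <- function(phantom, dir) {
  stopifnot(inherits(phantom, "ceasl_phantom"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vols <- list(control = phantom$control, label = phantom$label,
               difference = phantom$difference, m0 = phantom$m0,
               t1e = phantom$t1e_map,
               labels = array(as.numeric(phantom$label_map),
                              dim = dim(phantom$label_map)))
  paths <- vapply(names(vols), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(vols[[nm]], p)
    p
  }, character(1))
  sidecar <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(truth = phantom$truth, design = phantom$design,
         sigma = phantom$noise$sigma, seed = phantom$seed),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, truth = sidecar))
}
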