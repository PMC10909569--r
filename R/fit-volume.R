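# Voxel-wise model fitting over image volumes and ROI summaries.

#' Voxel-wise model fitting of 4D ASL difference volumes
#'
#' Fits the two-compartment model independently in every masked voxel of a
#' 4D difference volume (x, y, z, measurement), with the voxel's M0 and
#' extravascular T1 and the global per-phase blood T1 values fixed. Voxels
#' whose fitted exchange rate falls outside `kb_valid` (0-10 s^-1 by
#' default) are masked in the output maps, mirroring how extreme exchange
#' fits are displayed.
#'
#' @param difference 4D array of difference signals; the 4th dimension must
#'   match `nrow(design)`.
#' @param design Acquisition design from [asl_design()] (carries each
#'   measurement's PLD and blood T1).
#' @param m0 3D array of equilibrium magnetization.
#' @param t1e_map 3D array of extravascular T1, s.
#' @param mask Logical/0-1 3D array of voxels to fit (default: `m0 > 0`).
#' @param acq An [acq_params()] object (`t_l`, `alpha`; its `m0` is
#'   overridden voxel-wise).
#' @param config A [fit_config()].
#' @param kb_valid Range of acceptable fitted exchange rates for the output
#'   maps.
#' @param lambda Brain:blood partition coefficient.
#'
#' @return A list of class `ceasl_fit_volume`: `fits` (tibble with voxel
#'   coordinates, estimates, `sse`, `extreme`, `valid`), and `maps` (list of
#'   3D arrays `f`, `t_a`, `k_b` with invalid/extreme-`k_b` voxels set to
#'   `NA`).
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(3, 3, 1), seed = 1,
#'                                 noise = noise_model(sigma = 1e-6)))
#' fv <- fit_asl_volume(ph$difference, ph$design, ph$m0, ph$t1e_map,
#'                      config = fit_config(n_starts = 8, seed = 1))
#' @export
fit_asl_volume <- function(difference, design, m0, t1e_map, mask = NULL,
                           acq = acq_params(), config = fit_config(),
                           kb_valid = c(0, 10), lambda = 0.9) {
  dims <- dim(difference)
  if (length(dims) != 4L || dims[4] != nrow(design)) {
    abort("`difference` must be x*y*z*measurement with one volume per design row.")
  }
  shape <- dims[1:3]
  # coerce to the volume shape, tolerating dropped trailing singleton
  # dimensions (as NIfTI readers produce)
  check3d <- function(a, nm) {
    d <- dim(a) %||% length(a)
    d <- c(d, rep(1L, max(0L, 3L - length(d))))
    if (length(d) != 3L || !all(d == shape)) {
      abort(paste0("`", nm, "` does not match the volume shape."))
    }
    array(as.numeric(a), dim = shape)
  }
  m0 <- check3d(m0, "m0")
  t1e_map <- check3d(t1e_map, "t1e_map")
  mask <- if (is.null(mask)) m0 > 0 else check3d(mask, "mask")
  idx <- which(mask > 0)
  if (length(idx) == 0L) abort("`mask` selects no voxels.")

  n_vox <- prod(shape)
  dm_mat <- matrix(difference, nrow = n_vox)
  coords <- arrayInd(idx, shape)

  fits <- purrr::map(seq_along(idx), function(k) {
    v <- idx[k]
    acq_v <- acq
    acq_v$m0 <- m0[v]
    dat <- design
    dat$dm <- dm_mat[v, ]
    fit <- fit_asl(dat, t1_e = t1e_map[v], acq = acq_v, config = config,
                   lambda = lambda)
    tibble(voxel = v, x = coords[k, 1], y = coords[k, 2], z = coords[k, 3],
           f = fit$estimates[["f"]], t_a = fit$estimates[["t_a"]],
           k_b = fit$estimates[["k_b"]], sse = fit$sse,
           extreme = fit$extreme)
  }) |>
    dplyr::bind_rows()
  fits$valid <- fits$k_b >= kb_valid[1] & fits$k_b <= kb_valid[2] &
    !fits$extreme

  maps <- purrr::map(c(f = "f", t_a = "t_a", k_b = "k_b"), function(par) {
    m <- array(NA_real_, dim = shape)
    ok <- fits$valid
    m[fits$voxel[ok]] <- fits[[par]][ok]
    m
  })

  structure(list(fits = fits, maps = maps, design = design,
                 kb_valid = kb_valid),
            class = "ceasl_fit_volume")
}

#' Regional medians of voxel-wise parameter maps
#'
#' @param volume_fit A [fit_asl_volume()] result.
#' @param label_map 3D integer array of ROI labels (0 = background).
#' @return A tibble with one row per ROI label: medians of `f`, `t_a`,
#'   `k_b` over valid voxels, and voxel counts.
#' @export
roi_medians <- function(volume_fit, label_map) {
  stopifnot(inherits(volume_fit, "ceasl_fit_volume"))
  fits <- volume_fit$fits
  fits$roi <- label_map[fits$voxel]
  fits |>
    dplyr::filter(.data$roi > 0, .data$valid) |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarize(
      f = median(.data$f), t_a = median(.data$t_a), k_b = median(.data$k_b),
      n_voxels = dplyr::n(), .groups = "drop"
    )
}

#' Write fitted parameter maps as NIfTI-1 plus a JSON sidecar
#'
#' @param volume_fit A [fit_asl_volume()] result.
#' @param dir Output directory.
#' @param config The [fit_config()] used (stored in the sidecar).
#' @return Invisibly, the paths written.
#' @export
write_parameter_maps <- function(volume_fit, dir, config = NULL) {
  stopifnot(inherits(volume_fit, "ceasl_fit_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(volume_fit$maps), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    RNifti::writeNifti(volume_fit$maps[[nm]], p)
    p
  }, character(1))
  sidecar <- file.path(dir, "fit.json")
  jsonlite::write_json(
    list(design = volume_fit$design, kb_valid = volume_fit$kb_valid,
         config = config[!vapply(config, is.null, logical(1))]),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, sidecar = sidecar))
}
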