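#' Map-simulation parameters
#'
#' Controls conversion of an atomic model into a simulated density map: each
#' atom contributes an isotropic Gaussian of width
#' \code{sigma = sigma_factor * resolution}, amplitude proportional to the
#' atom weight, summed on a regular grid covering the model bounding box plus
#' padding.
#'
#' @param resolution target resolution in angstrom (> 0).
#' @param voxel_size grid spacing in angstrom (> 0); choose the experimental
#'   map's voxel size so grids are commensurable.
#' @param sigma_factor dimensionless resolution-to-sigma factor in (0, 1);
#'   the default 0.225 is the convention of the Gaussian-convolution fitting
#'   tool family this package follows (the kernel itself is a modelling
#'   choice, not a physical constant).
#' @param padding angstrom added around the bounding box; default 3 sigma.
#' @return An object of class \code{simulation_params}.
#' @export
simulation_params <- function(resolution, voxel_size,
                              sigma_factor = 0.225,
                              padding = 3 * sigma_factor * resolution) {
  stopifnot(resolution > 0, voxel_size > 0,
            sigma_factor > 0, sigma_factor < 1, padding >= 0)
  structure(list(resolution = resolution, voxel_size = voxel_size,
                 sigma_factor = sigma_factor, padding = padding),
            class = "simulation_params")
}

sim_sigma <- function(params) params$sigma_factor * params$resolution

#' Simulate a density map from an atomic model
#'
#' Sums one isotropic Gaussian per atom (amplitude = atom weight, sigma =
#' \code{sigma_factor * resolution}) on a grid covering the model bounding
#' box plus \code{padding}. Gaussians are truncated at 4 sigma.
#'
#' @param model an \code{atomic_model} with at least one atom.
#' @param params a \code{simulation_params}.
#' @param grid optionally, a \code{density_map} or \code{density_envelope}
#'   whose grid geometry (dims, origin, voxel size) should be reused instead
#'   of the bounding-box grid, e.g. to simulate onto an experimental grid.
#' @return A \code{density_map}.
#' @export
simulate_map <- function(model, params, grid = NULL) {
  a <- model$atoms
  if (nrow(a) == 0) stop("model has no atoms")
  sigma <- sim_sigma(params)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (is.null(grid)) {
    lo <- apply(xyz, 2, min) - params$padding
    hi <- apply(xyz, 2, max) + params$padding
    vox <- rep_len(params$voxel_size, 3)
    dims <- pmax(1L, as.integer(ceiling((hi - lo) / vox)) + 1L)
    origin <- lo
  } else {
    dims <- dim(if (inherits(grid, "density_envelope")) grid$mask
                else grid$values)
    origin <- grid$origin
    vox <- grid$voxel_size
  }
  vals <- cpp_splat_gaussian(xyz, a$weight, dims, origin, vox, sigma,
                             cutoff = 4)
  density_map(array(vals, dims), vox, origin, label = "simulated")
}
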