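#' Density map on a regular 3D grid
#'
#' Scalar values on a regular grid with a physical origin and voxel spacing.
#' Values are stored as a numeric array with \code{dim = c(nx, ny, nz)},
#' x fastest in memory (column-major); the centre of voxel \code{[1, 1, 1]}
#' sits at \code{origin} (angstrom) and voxel \code{[i, j, k]} at
#' \code{origin + (c(i, j, k) - 1) * voxel_size}.
#'
#' @param values numeric 3D array.
#' @param voxel_size angstrom per voxel along each axis (length 1 or 3, > 0).
#' @param origin physical position (angstrom) of the centre of the first
#'   voxel (length 3).
#' @param label free-text provenance label.
#' @return An object of class \code{density_map}.
#' @export
density_map <- function(values, voxel_size = 1, origin = c(0, 0, 0),
                        label = "") {
  values <- as.array(values)
  if (length(dim(values)) != 3L || any(dim(values) < 1L))
    stop("values must be a 3D array with dimensions >= 1")
  if (!all(is.finite(values))) stop("all map values must be finite")
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  if (any(voxel_size <= 0)) stop("voxel_size components must be > 0")
  origin <- rep_len(as.numeric(origin), 3)
  structure(list(values = values, voxel_size = voxel_size, origin = origin,
                 label = as.character(label)[1]),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_map: %d x %d x %d voxels, voxel %.3g x %.3g x %.3g A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) A, range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  if (nzchar(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' Binarized density envelope
#'
#' Boolean mask congruent with its parent map, recording the threshold that
#' was actually applied.
#' @param mask logical 3D array.
#' @param threshold intensity cutoff used (recorded for provenance).
#' @param voxel_size,origin grid geometry of the parent map.
#' @return An object of class \code{density_envelope}.
#' @export
density_envelope <- function(mask, threshold, voxel_size, origin) {
  mask <- as.array(mask)
  stopifnot(length(dim(mask)) == 3L, is.logical(mask))
  structure(list(mask = mask, threshold = threshold,
                 voxel_size = rep_len(as.numeric(voxel_size), 3),
                 origin = rep_len(as.numeric(origin), 3)),
            class = "density_envelope")
}

#' @export
print.density_envelope <- function(x, ...) {
  cat(sprintf("density_envelope: %d of %d voxels above threshold %.4g\n",
              sum(x$mask), length(x$mask), x$threshold))
  invisible(x)
}

#' Normalize a map to unit maximum
#'
#' Divides by the grid maximum so that intensity thresholds (e.g. the 0.06
#' envelope threshold) are defined on a common \[0, 1\] scale, and clamps
#' negative values to zero, treating the map as a non-negative (stain-like)
#' density.
#' @param map a \code{density_map}.
#' @return A normalized \code{density_map}.
#' @export
map_normalize <- function(map) {
  v <- map$values
  v[v < 0] <- 0
  mx <- max(v)
  if (mx <= 0) stop("map has no positive density; cannot normalize")
  density_map(v / mx, map$voxel_size, map$origin, map$label)
}

#' Mirror a map along one axis
#'
#' Reverses the values along the chosen axis. Because the reflection plane
#' passes through the map centre, physical voxel-centre positions are mapped
#' onto the original grid and the origin is unchanged. Total density is
#' conserved exactly and mirroring twice restores the original map.
#' @param map a \code{density_map}.
#' @param axis one of "x", "y", "z" (default "x"; any single-axis flip
#'   differs from another only by a proper rotation).
#' @return The mirrored \code{density_map}.
#' @export
mirror_map <- function(map, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  d <- dim(map$values)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  ax <- match(axis, c("x", "y", "z"))
  idx[[ax]] <- rev(idx[[ax]])
  density_map(map$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
              map$voxel_size, map$origin,
              paste0(map$label, " [mirrored ", axis, "]"))
}

#' Binarize a map into an envelope
#'
#' Mask is true where the value is strictly greater than the threshold.
#' @param map a \code{density_map}.
#' @param threshold finite intensity cutoff.
#' @return A \code{density_envelope}.
#' @export
binarize <- function(map, threshold) {
  stopifnot(is.finite(threshold))
  density_envelope(map$values > threshold, threshold, map$voxel_size,
                   map$origin)
}

#' Surface voxel centres of an envelope
#'
#' Centres of mask voxels having at least one face-adjacent voxel outside the
#' mask; the grid boundary counts as outside.
#' @param envelope a \code{density_envelope} with a non-empty mask.
#' @return n x 3 matrix of positions (angstrom).
#' @export
surface_points <- function(envelope) {
  m <- envelope$mask
  if (!any(m)) stop("envelope mask is empty")
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- inner & !nb_all
  ijk <- which(surf, arr.ind = TRUE)
  sweep(sweep(ijk - 1, 2, envelope$voxel_size, "*"), 2, envelope$origin, "+")
}

#' Remove dust from an envelope
#'
#' Keeps only the largest 6-connected component of the mask. Noise in a map
#' scatters isolated speckle voxels above the intensity threshold; treating
#' those as part of the molecular envelope corrupts surface-based scores
#' (Chamfer, Dice), so scoring pipelines clean the experimental envelope
#' first. Recorded threshold and grid geometry are unchanged.
#' @param envelope a \code{density_envelope}.
#' @return The cleaned \code{density_envelope}.
#' @export
clean_envelope <- function(envelope) {
  if (!any(envelope$mask)) return(envelope)
  keep <- cpp_largest_component(as.logical(envelope$mask),
                                dim(envelope$mask))
  density_envelope(array(keep, dim(envelope$mask)), envelope$threshold,
                   envelope$voxel_size, envelope$origin)
}

# physical centres of all voxels where `mask` is TRUE (or all voxels)
voxel_centers <- function(map, mask = NULL) {
  d <- dim(if (inherits(map, "density_envelope")) map$mask else map$values)
  if (is.null(mask)) {
    ijk <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  } else {
    ijk <- which(mask, arr.ind = TRUE)
  }
  sweep(sweep(ijk - 1, 2, map$voxel_size, "*"), 2, map$origin, "+")
}

# Gaussian blur of a map by discrete convolution (FFT, zero padded so there
# is no wraparound within `cutoff` sigma).  Used to evaluate the overlap
# objective at atom positions: sum_v exp(v) * G(|x - v|).
blur_map <- function(map, sigma, cutoff = 4) {
  v <- map$values
  d <- dim(v)
  k <- pmax(1L, ceiling(cutoff * sigma / map$voxel_size))
  dp <- d + 2L * k
  pad <- array(0, dp)
  pad[k[1] + seq_len(d[1]), k[2] + seq_len(d[2]), k[3] + seq_len(d[3])] <- v
  # separable kernel centred at index 1 with wraparound layout
  gx <- exp(-(c(0:k[1], rep(Inf, dp[1] - 2 * k[1] - 1), k[1]:1) *
                map$voxel_size[1])^2 / (2 * sigma^2))
  gy <- exp(-(c(0:k[2], rep(Inf, dp[2] - 2 * k[2] - 1), k[2]:1) *
                map$voxel_size[2])^2 / (2 * sigma^2))
  gz <- exp(-(c(0:k[3], rep(Inf, dp[3] - 2 * k[3] - 1), k[3]:1) *
                map$voxel_size[3])^2 / (2 * sigma^2))
  kern <- outer(outer(gx, gy), gz)
  dim(kern) <- dp
  conv <- Re(stats::fft(stats::fft(pad) * stats::fft(kern), inverse = TRUE)) /
    prod(dp)
  out <- conv[k[1] + seq_len(d[1]), k[2] + seq_len(d[2]), k[3] + seq_len(d[3])]
  density_map(out, map$voxel_size, map$origin, paste0(map$label, " [blurred]"))
}

# trilinear interpolation of map values at physical points (0 outside grid)
interpolate_map <- function(map, points) {
  cpp_trilinear(as.numeric(map$values), dim(map$values), map$origin,
                map$voxel_size, matrix(as.numeric(points), ncol = 3))
}
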