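# The four fit-quality metrics: overlap (sum of aligned density products),
# cross-correlation about zero inside the experimental envelope, Chamfer
# distance between envelope surfaces, and the envelope (Dice) score; plus the
# significance of a top fit against the remaining representatives.

# resample model map onto the experimental grid by trilinear interpolation;
# returns a plain array congruent with exp_map$values
resample_onto <- function(exp_map, model_map) {
  same <- identical(dim(exp_map$values), dim(model_map$values)) &&
    max(abs(exp_map$origin - model_map$origin)) < 1e-9 &&
    max(abs(exp_map$voxel_size - model_map$voxel_size)) < 1e-9
  if (same) return(model_map$values)
  pts <- voxel_centers(exp_map)
  array(interpolate_map(model_map, pts), dim(exp_map$values))
}

#' Overlap score (sum of aligned density products)
#'
#' The model map is resampled onto the experimental grid by trilinear
#' interpolation and the voxelwise product is summed. Negative experimental
#' values are clamped to zero (stain maps are treated as non-negative).
#'
#' @param exp_map experimental \code{density_map}.
#' @param model_map simulated model \code{density_map} (any commensurable
#'   grid).
#' @return Scalar overlap score (arbitrary units).
#' @export
overlap_score <- function(exp_map, model_map) {
  e <- exp_map$values
  e[e < 0] <- 0
  m <- resample_onto(exp_map, model_map)
  if (all(m == 0)) {
    warning("model map does not intersect the experimental grid")
    return(0)
  }
  sum(e * m)
}

#' Cross-correlation about zero
#'
#' \code{sum(e * m) / sqrt(sum(e^2) * sum(m^2))} over voxels inside the
#' experimental envelope (all voxels when no envelope is given). Computed
#' about zero, not about the mean: after clamping, stain-like maps are
#' non-negative and mean-centring misbehaves on mostly-empty grids.
#'
#' @param exp_map experimental \code{density_map}.
#' @param model_map model \code{density_map}.
#' @param envelope optional \code{density_envelope} on the experimental grid
#'   restricting the summation.
#' @return Correlation in \[-1, 1\].
#' @export
cross_correlation <- function(exp_map, model_map, envelope = NULL) {
  e <- as.numeric(exp_map$values)
  m <- as.numeric(resample_onto(exp_map, model_map))
  if (!is.null(envelope)) {
    keep <- as.logical(envelope$mask)
    e <- e[keep]; m <- m[keep]
  }
  ne <- sum(e^2); nm <- sum(m^2)
  if (ne == 0 || nm == 0) stop("zero-norm input to cross_correlation")
  sum(e * m) / sqrt(ne * nm)
}

#' Chamfer distance between two envelopes
#'
#' Symmetrized mean nearest-neighbour distance between the surface-voxel
#' centres of the two envelopes:
#' \code{0.5 * (mean_a min_b |a - b| + mean_b min_a |a - b|)}.
#' Computed on surface voxels only, matching the interpretation of a stain
#' map as an approximation of the molecular surface.
#'
#' @param envA,envB non-empty \code{density_envelope}s (or n x 3 point
#'   matrices of precomputed surface points).
#' @return Distance in angstrom (0 for identical surfaces).
#' @export
chamfer_distance <- function(envA, envB) {
  pa <- if (is.matrix(envA)) envA else surface_points(envA)
  pb <- if (is.matrix(envB)) envB else surface_points(envB)
  if (nrow(pa) == 0 || nrow(pb) == 0) stop("empty envelope")
  cpp_chamfer(pa, pb)
}

#' Envelope score (Dice coefficient)
#'
#' \code{2 |A intersect B| / (|A| + |B|)} of two binary masks on a common
#' grid; 1 for identical non-empty masks, 0 for disjoint ones.
#'
#' @param envA,envB \code{density_envelope}s on the same grid.
#' @return Score in \[0, 1\].
#' @export
envelope_score <- function(envA, envB) {
  if (!identical(dim(envA$mask), dim(envB$mask)))
    stop("envelopes are not on a common grid")
  na <- sum(envA$mask); nb <- sum(envB$mask)
  if (na + nb == 0) stop("both masks are empty")
  2 * sum(envA$mask & envB$mask) / (na + nb)
}

#' Score one placement with all four metrics
#'
#' Simulates the model map at transform \code{T} on the experimental grid,
#' normalizes both maps to unit maximum, and computes overlap,
#' cross-correlation (inside the experimental envelope), Chamfer distance
#' between envelope surfaces, and the envelope (Dice) score. The Chamfer
#' distance is also exposed negated (\code{chamfer_sim}) so that "higher is
#' better" holds for rank aggregation across all four metrics.
#'
#' @param exp_map experimental \code{density_map} (normalized internally).
#' @param model an \code{atomic_model} in its reference frame.
#' @param tr \code{rigid_transform} placing the model in map space.
#' @param params \code{simulation_params} used for the model map.
#' @param threshold normalized envelope threshold (default 0.06).
#' @param exp_norm,exp_env optionally, the precomputed normalized
#'   experimental map and its envelope (to avoid recomputation in loops).
#' @return A list of class \code{fit_scores} with fields \code{overlap},
#'   \code{ccc}, \code{chamfer}, \code{envelope}, \code{chamfer_sim}.
#' @export
score_fit <- function(exp_map, model, tr, params, threshold = 0.06,
                      exp_norm = NULL, exp_env = NULL) {
  if (is.null(exp_norm)) exp_norm <- map_normalize(exp_map)
  if (is.null(exp_env)) exp_env <- binarize(exp_norm, threshold)
  placed <- apply_transform(model, tr)
  mm <- simulate_map(placed, params, grid = exp_norm)
  mx <- max(mm$values)
  if (mx <= 0) stop("placed model lies entirely outside the map grid")
  # envelopes are defined on the unit-maximum scale of each map; the overlap
  # itself uses the raw model density (normalizing by the per-placement
  # maximum would bias it toward off-grid placements with lower peaks)
  mm_norm <- density_map(mm$values / mx, mm$voxel_size, mm$origin)
  menv <- binarize(mm_norm, threshold)
  # a placement whose density misses the experimental envelope entirely has
  # zero correlation there, not an undefined one
  ccc <- if (sum(mm$values[exp_env$mask]^2) == 0) 0
         else cross_correlation(exp_norm, mm, exp_env)
  sc <- list(
    overlap = sum(exp_norm$values * mm$values),
    ccc = ccc,
    chamfer = chamfer_distance(exp_env, menv),
    envelope = envelope_score(exp_env, menv))
  sc$chamfer_sim <- -sc$chamfer
  structure(sc, class = "fit_scores")
}

#' @export
print.fit_scores <- function(x, ...) {
  cat(sprintf("fit_scores: overlap %.4g, ccc %.4f, chamfer %.3f A, envelope %.4f\n",
              x$overlap, x$ccc, x$chamfer, x$envelope))
  invisible(x)
}

#' Significance of the top fit in an ensemble
#'
#' Standard score of the best representative against the remaining
#' representatives, \code{z = (s_top - mean(rest)) / sd(rest)}, with an
#' upper-tail normal probability. Significance is conventionally claimed at
#' p < 0.05. The reference distribution is the clustered representatives, a
#' documented approximation of published fit-significance assessments.
#'
#' @param ensemble a \code{fit_ensemble} with at least 3 representatives, or
#'   a numeric vector of scores (descending quality).
#' @param score_key which metric to use (default \code{"overlap"};
#'   \code{"chamfer"} is negated internally so larger is better).
#' @return List of class \code{fit_significance} with \code{z}, \code{p},
#'   \code{n_fits}, \code{significant}.
#' @export
fit_significance <- function(ensemble, score_key = "overlap") {
  s <- if (is.numeric(ensemble)) ensemble
       else ensemble_scores(ensemble, score_key)
  if (length(s) < 3) stop("need at least 3 representative fits")
  top <- max(s)
  rest <- s[-which.max(s)]
  sdr <- stats::sd(rest)
  if (sdr == 0) {
    if (top == rest[1]) {
      z <- 0; p <- 0.5; flagged <- FALSE
    } else {
      z <- Inf; p <- .Machine$double.xmin; flagged <- TRUE
    }
  } else {
    z <- (top - mean(rest)) / sdr
    p <- stats::pnorm(z, lower.tail = FALSE)
    flagged <- FALSE
  }
  structure(list(z = z, p = p, n_fits = length(s), significant = p < 0.05,
                 degenerate = flagged, score_key = score_key),
            class = "fit_significance")
}

#' @export
print.fit_significance <- function(x, ...) {
  cat(sprintf("fit significance (%s): z = %.3f, p = %.3g over %d fits -> %s\n",
              x$score_key, x$z, x$p, x$n_fits,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

# scores of ensemble representatives under a metric, sign-adjusted so that
# larger is always better
ensemble_scores <- function(ensemble, score_key) {
  v <- vapply(ensemble$fits, function(f) f$scores[[score_key]], numeric(1))
  if (score_key == "chamfer") v <- -v
  v
}
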