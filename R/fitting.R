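#' Multi-start fitting configuration
#'
#' @param n_placements number of random initial placements. Published
#'   protocols for real stain maps use 100,000; desk-scale synthetic cases
#'   are well served by 2,000-10,000.
#' @param opt_steps cap on local-optimization sweeps per placement (the
#'   analysed protocol reduced its optimizer's default 2000 steps to 100).
#' @param coverage_min minimum fraction of the placed model's envelope that
#'   must fall inside the experimental envelope (default 0.30).
#' @param envelope_threshold normalized intensity threshold defining
#'   envelopes (default 0.06 on the unit-maximum scale).
#' @param cluster_rot_deg,cluster_trans clustering thresholds: rotation
#'   geodesic angle (degrees) and centroid displacement (angstrom). The
#'   defaults 3 deg / 2 A are "high" (many representatives); 30 deg / 15 A is
#'   a "low" setting giving few tens of representatives. Published
#'   descriptions give only "high"/"low", so the numbers are package choices.
#' @param resolution,voxel_size,sigma_factor map-simulation settings for the
#'   model maps (voxel_size defaults to the experimental map's when fitting).
#' @param rng_seed integer seed making the whole run deterministic.
#' @return An object of class \code{fit_config}.
#' @export
fit_config <- function(n_placements = 2000, opt_steps = 100,
                       coverage_min = 0.30, envelope_threshold = 0.06,
                       cluster_rot_deg = 3, cluster_trans = 2,
                       resolution = 30, voxel_size = NULL,
                       sigma_factor = 0.225, rng_seed = 1L) {
  stopifnot(n_placements >= 1, opt_steps >= 0,
            coverage_min >= 0, coverage_min <= 1.01,
            envelope_threshold > 0, cluster_rot_deg > 0, cluster_trans > 0)
  structure(list(n_placements = as.integer(n_placements),
                 opt_steps = as.integer(opt_steps),
                 coverage_min = coverage_min,
                 envelope_threshold = envelope_threshold,
                 cluster_rot_deg = cluster_rot_deg,
                 cluster_trans = cluster_trans,
                 resolution = resolution, voxel_size = voxel_size,
                 sigma_factor = sigma_factor,
                 rng_seed = as.integer(rng_seed)),
            class = "fit_config")
}

#' Random initial placements
#'
#' Rotations uniform over the rotation group (Gaussian quaternions);
#' translations place the model centroid uniformly inside the bounding box of
#' the experimental envelope.
#'
#' @param map experimental \code{density_map}.
#' @param model \code{atomic_model}.
#' @param n number of placements.
#' @param threshold normalized envelope threshold defining the bounding box.
#' @return List of \code{rigid_transform}s.
#' @export
random_placements <- function(map, model, n, threshold = 0.06) {
  stopifnot(n >= 1)
  env <- clean_envelope(binarize(map_normalize(map), threshold))
  if (!any(env$mask)) stop("envelope is empty at this threshold")
  pts <- voxel_centers(env, env$mask)
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  c0 <- model_centroid(model)
  lapply(seq_len(n), function(i) {
    R <- quat_to_matrix(stats::rnorm(4))
    target <- lo + stats::runif(3) * (hi - lo)
    rigid_transform(R, target - as.numeric(R %*% c0))
  })
}

# precompute the blurred experimental map used as the overlap objective:
# objective(T) = sum_a w_a * blurred(T p_a) = sum_v exp(v) * modelmap_T(v)
# up to trilinear interpolation of the blurred grid.
overlap_objective_map <- function(exp_norm, sigma) {
  blur_map(exp_norm, sigma)
}

#' Local optimization of one placement
#'
#' Greedy coordinate ascent on the overlap objective over the six rigid
#' parameters (three rotations about the placed centroid, three
#' translations), with backtracking step sizes. The objective is the sum of
#' aligned density products, evaluated as the blurred experimental density
#' interpolated at the transformed atom positions. The returned score is
#' never below the initial score; \code{steps = 0} returns the scored initial
#' placement unchanged.
#'
#' @param map experimental \code{density_map} (or a precomputed objective map
#'   from internal use).
#' @param model \code{atomic_model}.
#' @param t0 initial \code{rigid_transform}.
#' @param steps maximum number of ascent sweeps.
#' @param params \code{simulation_params} (controls the Gaussian width).
#' @param objective_map optional precomputed blurred map (internal reuse).
#' @return List with \code{transform}, \code{score}, \code{trace} (per-sweep
#'   scores, non-decreasing), \code{zero_density} flag (placement entirely
#'   outside nonzero density).
#' @export
local_optimize <- function(map, model, t0, steps, params,
                           objective_map = NULL) {
  stopifnot(steps >= 0)
  if (is.null(objective_map))
    objective_map <- overlap_objective_map(map_normalize(map),
                                           sim_sigma(params))
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dims <- dim(objective_map$values)
  if (steps == 0) {
    s <- cpp_objective(as.numeric(objective_map$values), dims,
                       objective_map$origin, objective_map$voxel_size,
                       xyz, a$weight, t0$rotation, t0$translation)
    return(list(transform = t0, score = s, trace = s, zero_density = s <= 0))
  }
  # multi-scale ascent: start coarse (to cross shallow local maxima of the
  # blurred objective), shrink toward sub-voxel refinement
  res <- cpp_local_optimize(as.numeric(objective_map$values), dims,
                            objective_map$origin, objective_map$voxel_size,
                            xyz, a$weight, t0$rotation, t0$translation,
                            as.integer(steps),
                            step_rot = 0.4,
                            step_trans = 2 * min(objective_map$voxel_size),
                            min_trans = 0.02)
  list(transform = rigid_transform(res$rotation, res$translation),
       score = res$score, trace = res$trace,
       zero_density = res$score <= 0)
}

#' Coverage of a placed model by the experimental envelope
#'
#' Fraction of the placed model's own envelope voxels (model map simulated on
#' a grid commensurable with the experimental one, binarized at the same
#' normalized threshold) whose centres fall inside the experimental envelope.
#'
#' @param map_envelope experimental \code{density_envelope}.
#' @param model \code{atomic_model}.
#' @param tr \code{rigid_transform} placing the model.
#' @param params \code{simulation_params}.
#' @return Fraction in \[0, 1\].
#' @export
coverage_fraction <- function(map_envelope, model, tr, params) {
  placed <- apply_transform(model, tr)
  mm <- simulate_map(placed, params)
  mx <- max(mm$values)
  if (mx <= 0) return(0)
  mask <- mm$values / mx > map_envelope$threshold
  if (!any(mask)) return(0)
  pts <- voxel_centers(mm, mask)
  ijk <- round(sweep(sweep(pts, 2, map_envelope$origin, "-"), 2,
                     map_envelope$voxel_size, "/")) + 1
  d <- dim(map_envelope$mask)
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  covered <- logical(nrow(ijk))
  if (any(inside))
    covered[inside] <- map_envelope$mask[ijk[inside, , drop = FALSE]]
  mean(covered)
}

#' Greedy clustering of fits into representatives
#'
#' Fits are visited in descending score order; a fit joins an existing
#' representative when its rotation geodesic angle is at most
#' \code{rot_deg} degrees AND its centroid displacement at most \code{trans}
#' angstrom, and otherwise becomes a new representative. Representatives
#' carry \code{cluster_size}, the number of raw fits merged into them.
#'
#' @param fits list of fit records (each with \code{transform} and
#'   \code{score}).
#' @param rot_deg rotation threshold in degrees.
#' @param trans translation threshold in angstrom.
#' @param centroid model centroid in the reference frame (used to convert
#'   transforms into centroid displacements).
#' @return List of representative fits, sorted by descending score, each with
#'   \code{cluster_size}.
#' @export
cluster_fits <- function(fits, rot_deg, trans, centroid = c(0, 0, 0)) {
  if (length(fits) == 0) return(list())
  ord <- order(vapply(fits, function(f) f$score, numeric(1)),
               decreasing = TRUE)
  rot_rad <- rot_deg * pi / 180
  reps <- list()
  rep_R <- list()
  rep_c <- list()
  for (i in ord) {
    f <- fits[[i]]
    cen <- as.numeric(f$transform$rotation %*% centroid) +
      f$transform$translation
    joined <- FALSE
    for (k in seq_along(reps)) {
      if (sqrt(sum((cen - rep_c[[k]])^2)) <= trans &&
          rotation_between(rep_R[[k]], f$transform$rotation) <= rot_rad) {
        reps[[k]]$cluster_size <- reps[[k]]$cluster_size + 1L
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      f$cluster_size <- 1L
      reps[[length(reps) + 1]] <- f
      rep_R[[length(reps)]] <- f$transform$rotation
      rep_c[[length(reps)]] <- cen
    }
  }
  reps
}

#' Multi-start rigid-body fitting of one body into a map
#'
#' The full pipeline: random placements, local optimization of the overlap
#' objective, removal of fits whose model envelope is covered less than
#' \code{coverage_min} by the experimental envelope, scoring of the surviving
#' fits with all four metrics, greedy clustering into representatives, and
#' sorting by the chosen score. Deterministic for a fixed
#' \code{config$rng_seed}.
#'
#' @param map experimental \code{density_map}.
#' @param model \code{atomic_model} of the body in its reference frame.
#' @param config a \code{fit_config}.
#' @param map_id,body_id free-text identifiers recorded in the ensemble.
#' @param score_key metric used for sorting and clustering order (default
#'   \code{"overlap"}; the overlap objective is also what is optimized).
#' @return A \code{fit_ensemble}: list of representative fits (each with
#'   \code{transform}, \code{scores}, \code{coverage}, \code{cluster_size}),
#'   plus the configuration used.
#' @export
global_fit <- function(map, model, config = fit_config(),
                       map_id = "map", body_id = "body",
                       score_key = "overlap") {
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  vox <- if (is.null(config$voxel_size)) min(map$voxel_size)
         else config$voxel_size
  params <- simulation_params(config$resolution, vox,
                              sigma_factor = config$sigma_factor)
  exp_norm <- map_normalize(map)
  exp_env <- clean_envelope(binarize(exp_norm, config$envelope_threshold))
  obj_map <- overlap_objective_map(exp_norm, sim_sigma(params))
  # coarse-to-fine: a first ascent against a 3x-wider Gaussian objective
  # widens the attraction basins (the narrow-kernel landscape is rugged and
  # traps random starts), then the target-width objective refines
  obj_coarse <- overlap_objective_map(exp_norm, 3 * sim_sigma(params))

  starts <- random_placements(map, model, config$n_placements,
                              config$envelope_threshold)
  raw <- lapply(starts, function(t0) {
    c1 <- local_optimize(map, model, t0, config$opt_steps, params,
                         objective_map = obj_coarse)
    local_optimize(map, model, c1$transform, config$opt_steps, params,
                   objective_map = obj_map)
  })

  # coverage filter (applied after optimization so recoverable starts are
  # not discarded)
  cov <- vapply(raw, function(f)
    coverage_fraction(exp_env, model, f$transform, params), numeric(1))
  keep <- which(cov >= config$coverage_min & !vapply(raw, `[[`,
                                                     logical(1),
                                                     "zero_density"))
  if (length(keep) == 0) {
    warning("all placements were filtered out; empty ensemble")
    return(fit_ensemble(list(), map_id, body_id, config, score_key))
  }

  # cluster on the optimization (overlap) score, then compute all four
  # metrics on the representatives only; the representative of a cluster is
  # its best fit under the score that was optimized
  surviving <- lapply(keep, function(i)
    list(transform = raw[[i]]$transform, score = raw[[i]]$score,
         coverage = cov[i]))
  reps <- cluster_fits(surviving, config$cluster_rot_deg,
                       config$cluster_trans,
                       centroid = model_centroid(model))
  reps <- lapply(reps, function(f) {
    f$scores <- score_fit(map, model, f$transform, params,
                          threshold = config$envelope_threshold,
                          exp_norm = exp_norm, exp_env = exp_env)
    f$score <- if (score_key == "chamfer") -f$scores$chamfer
               else f$scores[[score_key]]
    f
  })
  reps <- reps[order(vapply(reps, `[[`, numeric(1), "score"),
                     decreasing = TRUE)]
  fit_ensemble(reps, map_id, body_id, config, score_key)
}

#' Fit ensemble container
#'
#' Clustered representative fits of one body in one map, sorted by the
#' recorded score key.
#' @param fits list of representative fits.
#' @param map_id,body_id identifiers.
#' @param config the \code{fit_config} used.
#' @param score_key the metric the sort order follows.
#' @return An object of class \code{fit_ensemble}.
#' @export
fit_ensemble <- function(fits, map_id = "map", body_id = "body",
                         config = NULL, score_key = "overlap") {
  structure(list(fits = fits, map_id = map_id, body_id = body_id,
                 config = config, score_key = score_key),
            class = "fit_ensemble")
}

#' @export
length.fit_ensemble <- function(x) length(x$fits)

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf("fit_ensemble: %d representative fit(s) of '%s' in '%s' (sorted by %s)\n",
              length(x$fits), x$body_id, x$map_id, x$score_key))
  if (length(x$fits)) {
    top <- x$fits[[1]]
    cat(sprintf("  top: overlap %.4g, ccc %.4f, chamfer %.3f A, envelope %.4f, coverage %.2f, cluster %d\n",
                top$scores$overlap, top$scores$ccc, top$scores$chamfer,
                top$scores$envelope, top$coverage, top$cluster_size))
  }
  invisible(x)
}

#' @export
summary.fit_ensemble <- function(object, ...) {
  df <- as.data.frame(object)
  cat(sprintf("fit_ensemble of '%s' in '%s': %d representatives\n",
              object$body_id, object$map_id, nrow(df)))
  if (nrow(df) >= 3) {
    sig <- fit_significance(object, object$score_key)
    cat(sprintf("  top-fit significance (%s): z = %.2f, p = %.3g\n",
                object$score_key, sig$z, sig$p))
  }
  print(utils::head(df, 5))
  invisible(df)
}

#' @export
as.data.frame.fit_ensemble <- function(x, ...) {
  if (length(x$fits) == 0)
    return(data.frame(fit_id = integer(), overlap = numeric(),
                      ccc = numeric(), chamfer = numeric(),
                      envelope = numeric(), coverage = numeric(),
                      cluster_size = integer()))
  data.frame(
    fit_id = seq_along(x$fits),
    overlap = vapply(x$fits, function(f) f$scores$overlap, numeric(1)),
    ccc = vapply(x$fits, function(f) f$scores$ccc, numeric(1)),
    chamfer = vapply(x$fits, function(f) f$scores$chamfer, numeric(1)),
    envelope = vapply(x$fits, function(f) f$scores$envelope, numeric(1)),
    coverage = vapply(x$fits, function(f) f$coverage, numeric(1)),
    cluster_size = vapply(x$fits, function(f) f$cluster_size, integer(1)))
}

#' @export
plot.fit_ensemble <- function(x, ...) {
  df <- as.data.frame(x)
  if (nrow(df) == 0) stop("empty ensemble")
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in c("overlap", "ccc", "chamfer", "envelope")) {
    graphics::plot(df$fit_id, df[[m]], xlab = "representative (rank)",
                   ylab = m, pch = 19, cex = 0.6, ...)
  }
  invisible(df)
}

# serialize an ensemble to the documented JSON schema
ensemble_to_json <- function(ensemble, path) {
  fits <- lapply(seq_along(ensemble$fits), function(i) {
    f <- ensemble$fits[[i]]
    list(fit_id = i,
         quaternion = matrix_to_quat(f$transform$rotation),
         translation = f$transform$translation,
         scores = f$scores[c("overlap", "ccc", "chamfer", "envelope")],
         coverage = f$coverage,
         cluster_size = f$cluster_size)
  })
  out <- list(map_id = ensemble$map_id, body_id = ensemble$body_id,
              score_key = ensemble$score_key, fits = fits)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# read an ensemble back from JSON
ensemble_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  fits <- lapply(x$fits, function(f) {
    list(transform = rigid_transform(
           quat_to_matrix(as.numeric(unlist(f$quaternion))),
           as.numeric(unlist(f$translation))),
         scores = structure(c(lapply(f$scores, as.numeric),
                              list(chamfer_sim = -as.numeric(f$scores$chamfer))),
                            class = "fit_scores"),
         score = as.numeric(f$scores$overlap),
         coverage = as.numeric(f$coverage),
         cluster_size = as.integer(f$cluster_size))
  })
  fit_ensemble(fits, x$map_id, x$body_id, NULL, x$score_key)
}
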