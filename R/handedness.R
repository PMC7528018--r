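# Mirror-image (handedness) determination by comparative fitting, and
# combinatorial two-body assembly.

#' Handedness decision rule on best-score tables
#'
#' A mirror is chosen only when its best fit is superior to the other
#' mirror's under all four metrics by more than \code{margin} (relative), AND
#' the same representative within that mirror is top under every metric
#' (agreement). Anything weaker is reported as "ambiguous".
#'
#' @param bestA,bestB named numeric vectors with entries \code{overlap},
#'   \code{ccc}, \code{chamfer}, \code{envelope}: best value per metric for
#'   mirror1 and mirror2 (chamfer: lower is better; others: higher).
#' @param agreeA,agreeB logical: does the same fit top all four metrics
#'   within that mirror?
#' @param margin relative superiority margin (default 0.01); differences
#'   below it are treated as ties.
#' @return \code{"mirror1"}, \code{"mirror2"} or \code{"ambiguous"}.
#' @export
decide_handedness <- function(bestA, bestB, agreeA = TRUE, agreeB = TRUE,
                              margin = 0.01) {
  better <- function(a, b, lower_is_better = FALSE) {
    if (lower_is_better) { tmp <- a; a <- -a; b <- -b }
    scale <- max(abs(a), abs(b), .Machine$double.eps)
    (a - b) / scale > margin
  }
  metrics <- c("overlap", "ccc", "chamfer", "envelope")
  winsA <- vapply(metrics, function(m)
    better(bestA[[m]], bestB[[m]], lower_is_better = (m == "chamfer")),
    logical(1))
  winsB <- vapply(metrics, function(m)
    better(bestB[[m]], bestA[[m]], lower_is_better = (m == "chamfer")),
    logical(1))
  if (all(winsA) && agreeA) return("mirror1")
  if (all(winsB) && agreeB) return("mirror2")
  "ambiguous"
}

# best value per metric over all bodies' representatives, plus whether one
# fit tops all four metrics (checked per body; all bodies must agree)
mirror_summary <- function(ensembles) {
  metrics <- c("overlap", "ccc", "chamfer", "envelope")
  best <- sapply(metrics, function(m) {
    v <- unlist(lapply(ensembles, function(e)
      vapply(e$fits, function(f) f$scores[[m]], numeric(1))))
    if (m == "chamfer") min(v) else max(v)
  })
  agree <- all(vapply(ensembles, function(e) {
    if (length(e$fits) == 0) return(FALSE)
    tops <- vapply(metrics, function(m) {
      v <- vapply(e$fits, function(f) f$scores[[m]], numeric(1))
      if (m == "chamfer") which.min(v) else which.max(v)
    }, integer(1))
    length(unique(tops)) == 1
  }, logical(1)))
  list(best = best, agree = agree)
}

#' Determine map handedness by comparative fitting
#'
#' Fits each body into the map ("mirror1") and into its x-mirrored copy
#' ("mirror2") with \code{\link{global_fit}}, compares the best fit per
#' metric, and applies the unanimity rule of \code{\link{decide_handedness}}:
#' a mirror is chosen only if it is superior under all four metrics and the
#' same top fit wins under every metric; otherwise "ambiguous".
#'
#' @param map experimental \code{density_map}.
#' @param bodies an \code{atomic_model} or list of them.
#' @param config a \code{fit_config}.
#' @param margin relative superiority margin for \code{decide_handedness}.
#' @return List of class \code{handedness_decision}: \code{chosen},
#'   per-mirror best scores, agreement flags, and the two sets of ensembles.
#' @export
assess_handedness <- function(map, bodies, config = fit_config(),
                              margin = 0.01) {
  if (inherits(bodies, "atomic_model")) bodies <- list(bodies)
  stopifnot(length(bodies) >= 1)
  mir <- mirror_map(map, "x")
  fit_all <- function(m, tag) lapply(seq_along(bodies), function(i)
    global_fit(m, bodies[[i]], config, map_id = tag,
               body_id = paste0("body", i)))
  ens1 <- fit_all(map, "mirror1")
  ens2 <- fit_all(mir, "mirror2")
  empty1 <- any(vapply(ens1, function(e) length(e$fits) == 0, logical(1)))
  empty2 <- any(vapply(ens2, function(e) length(e$fits) == 0, logical(1)))
  if (empty1 || empty2) {
    out <- list(chosen = "ambiguous", best1 = NULL, best2 = NULL,
                agree1 = FALSE, agree2 = FALSE,
                diagnostic = "empty ensemble on at least one mirror",
                ensembles1 = ens1, ensembles2 = ens2, margin = margin)
    return(structure(out, class = "handedness_decision"))
  }
  s1 <- mirror_summary(ens1)
  s2 <- mirror_summary(ens2)
  chosen <- decide_handedness(s1$best, s2$best, s1$agree, s2$agree, margin)
  structure(list(chosen = chosen, best1 = s1$best, best2 = s2$best,
                 agree1 = s1$agree, agree2 = s2$agree, diagnostic = NULL,
                 ensembles1 = ens1, ensembles2 = ens2, margin = margin),
            class = "handedness_decision")
}

#' @export
print.handedness_decision <- function(x, ...) {
  cat("handedness decision:", x$chosen, "\n")
  if (!is.null(x$best1)) {
    tab <- rbind(mirror1 = x$best1, mirror2 = x$best2)
    print(round(tab, 4))
    cat(sprintf("  same-top-fit agreement: mirror1 %s, mirror2 %s (margin %.1f%%)\n",
                x$agree1, x$agree2, 100 * x$margin))
  }
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Pairwise combination of two bodies' fits
#'
#' Cartesian product of the representatives of two ensembles. Each pair is
#' checked for steric clashes (fraction of body-A C-alpha atoms within
#' \code{clash_radius} of any body-B C-alpha); pairs exceeding
#' \code{clash_max} are removed. Each surviving combination is scored with
#' all four metrics on the union model (one map simulated jointly from both
#' placed bodies).
#'
#' @param ensA,ensB \code{fit_ensemble}s of bodies A and B in the same map.
#' @param modelA,modelB the corresponding \code{atomic_model}s.
#' @param map the experimental \code{density_map}.
#' @param clash_radius C-alpha clash distance in angstrom (default 4.0).
#' @param clash_max maximum tolerated clash fraction (default 0.2). At the
#'   placement precision a ~30 A map admits (representative fits deviate from
#'   the optimum by several angstrom), a tighter cap rejects near-optimal
#'   pairs along with the truly interpenetrating ones (whose clash fraction
#'   is several times higher).
#' @param threshold normalized envelope threshold.
#' @param params \code{simulation_params} for union-map simulation (defaults
#'   to the configuration recorded in \code{ensA}).
#' @return List of class \code{combined_fits}; each element has \code{idA},
#'   \code{idB}, \code{fitA}, \code{fitB}, \code{clash_fraction},
#'   \code{scores}.
#' @export
combine_fits <- function(ensA, ensB, modelA, modelB, map,
                         clash_radius = 4.0, clash_max = 0.2,
                         threshold = 0.06, params = NULL) {
  if (length(ensA$fits) == 0 || length(ensB$fits) == 0) {
    warning("empty input ensemble; no combined fits")
    return(structure(list(), class = "combined_fits"))
  }
  if (is.null(params)) {
    cfg <- ensA$config
    vox <- if (!is.null(cfg) && !is.null(cfg$voxel_size)) cfg$voxel_size
           else min(map$voxel_size)
    res <- if (!is.null(cfg)) cfg$resolution else 30
    sf <- if (!is.null(cfg)) cfg$sigma_factor else 0.225
    params <- simulation_params(res, vox, sigma_factor = sf)
  }
  exp_norm <- map_normalize(map)
  exp_env <- clean_envelope(binarize(exp_norm, threshold))
  caA <- coords(modelA, calpha_only = TRUE)
  caB <- coords(modelB, calpha_only = TRUE)
  if (nrow(caA) == 0) caA <- coords(modelA)
  if (nrow(caB) == 0) caB <- coords(modelB)
  out <- list()
  for (i in seq_along(ensA$fits)) {
    fa <- ensA$fits[[i]]
    pa <- transform_points(fa$transform, caA)
    for (j in seq_along(ensB$fits)) {
      fb <- ensB$fits[[j]]
      pb <- transform_points(fb$transform, caB)
      cf <- cpp_clash_fraction(pa, pb, clash_radius)
      if (cf > clash_max) next
      union_model <- atomic_model(rbind(
        apply_transform(modelA, fa$transform)$atoms,
        apply_transform(modelB, fb$transform)$atoms))
      sc <- score_fit(map, union_model, rigid_transform(), params,
                      threshold = threshold,
                      exp_norm = exp_norm, exp_env = exp_env)
      out[[length(out) + 1]] <- list(idA = i, idB = j, fitA = fa, fitB = fb,
                                     clash_fraction = cf, scores = sc)
    }
  }
  structure(out, class = "combined_fits")
}

#' @export
print.combined_fits <- function(x, ...) {
  cat(sprintf("combined_fits: %d surviving A x B combinations\n", length(x)))
  invisible(x)
}

#' Rank combined fits
#'
#' Primary order is the mean rank across the four metrics (Chamfer negated so
#' higher is better everywhere). When a crosslink table is supplied, fits
#' within the top \code{window} fraction of the ranking are reordered by
#' their crosslink satisfaction fraction (ties broken by the metric rank,
#' then by fit id, so the order is stable under input permutation).
#'
#' @param combined a \code{combined_fits} list.
#' @param modelA,modelB the body models (needed to rebuild assemblies when
#'   crosslinks are supplied).
#' @param xlinks optional crosslink table (see
#'   \code{\link{read_xlink_table}}).
#' @param xlink_config an \code{xlink_config} (chain map etc.); required with
#'   \code{xlinks}.
#' @param window fraction of the ranking within which crosslink satisfaction
#'   may reorder fits (default 0.1, i.e. the top decile).
#' @return The \code{combined_fits} list, reordered, with attributes
#'   \code{mean_rank} and (if crosslinks were used) \code{satisfaction}.
#' @export
rank_combined <- function(combined, modelA = NULL, modelB = NULL,
                          xlinks = NULL, xlink_config = NULL, window = 0.1) {
  n <- length(combined)
  if (n == 0) return(combined)
  metrics <- c("overlap", "ccc", "chamfer_sim", "envelope")
  ranks <- sapply(metrics, function(m)
    rank(-vapply(combined, function(f) f$scores[[m]], numeric(1)),
         ties.method = "average"))
  mean_rank <- rowMeans(matrix(ranks, nrow = n))
  ord <- order(mean_rank, seq_len(n))
  satisfaction <- NULL
  if (!is.null(xlinks)) {
    stopifnot(!is.null(modelA), !is.null(modelB), !is.null(xlink_config))
    satisfaction <- vapply(combined, function(f) {
      assembly <- atomic_model(rbind(
        apply_transform(modelA, f$fitA$transform)$atoms,
        apply_transform(modelB, f$fitB$transform)$atoms))
      res <- map_crosslinks(assembly, xlinks, xlink_config)
      if (res$totals$n_mapped == 0) return(0)
      satisfaction_fraction(res)
    }, numeric(1))
    k <- max(1L, ceiling(window * n))
    head_ids <- ord[seq_len(k)]
    head_ord <- head_ids[order(-satisfaction[head_ids],
                               mean_rank[head_ids], head_ids)]
    ord <- c(head_ord, ord[-seq_len(k)])
  }
  out <- combined[ord]
  attr(out, "mean_rank") <- mean_rank[ord]
  if (!is.null(satisfaction)) attr(out, "satisfaction") <- satisfaction[ord]
  class(out) <- "combined_fits"
  out
}
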