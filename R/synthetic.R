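# Synthetic ground-truth benchmarks: toy chiral chains, two-body complexes
# with simulated stain-like maps (true + mirrored, optional noise), and
# crosslink tables with planted satisfied/violated links and discriminating
# ld scores.

#' Toy C-alpha chain
#'
#' Builds a C-alpha-only chain with consecutive C-alpha distances of exactly
#' 3.8 A. The first \code{round(helical_fraction * n)} residues lie on a
#' right-handed helix (rise 1.5 A, 100 degrees per residue), guaranteeing
#' coordinate-level chirality; the remainder is a self-avoiding random walk.
#' With \code{planar = TRUE} the whole chain is a self-avoiding walk confined
#' to the z = 0 plane, giving an achiral (mirror-superposable) body.
#'
#' @param n number of residues (>= 10).
#' @param helical_fraction fraction of residues on the helix, in \[0, 1\].
#' @param seed integer RNG seed; the chain is reproducible from it.
#' @param planar build a planar achiral chain instead.
#' @return An \code{atomic_model} with one chain "A" of CA atoms (weight 1).
#' @export
make_toy_chain <- function(n, helical_fraction = 0.5, seed = 1,
                           planar = FALSE) {
  if (n < 10) stop("n must be >= 10")
  stopifnot(helical_fraction >= 0, helical_fraction <= 1)
  set.seed(seed)
  bond <- 3.8
  min_sep <- 3.5   # self-avoidance distance for non-consecutive residues
  pos <- matrix(NA_real_, n, 3)
  if (planar) {
    # gentle turns keep the 2D self-avoiding walk from trapping itself;
    # restart from scratch in the rare case it still does
    for (restart in 1:100) {
      pos[] <- NA_real_
      pos[1, ] <- c(0, 0, 0)
      ang <- stats::runif(1, 0, 2 * pi)
      ok <- TRUE
      for (i in 2:n) {
        grown <- FALSE
        for (try in 1:100) {
          cand_ang <- ang + stats::runif(1, -pi / 3, pi / 3)
          cand <- pos[i - 1, ] + bond * c(cos(cand_ang), sin(cand_ang), 0)
          prev <- pos[seq_len(max(0, i - 2)), , drop = FALSE]
          if (nrow(prev) == 0 ||
              min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
            pos[i, ] <- cand; ang <- cand_ang; grown <- TRUE; break
          }
        }
        if (!grown) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (anyNA(pos)) stop("could not grow planar self-avoiding walk")
  } else {
    n_hel <- round(helical_fraction * n)
    if (n_hel > 0) {
      rise <- 1.5
      turn <- 100 * pi / 180
      radius <- sqrt(bond^2 - rise^2) / (2 * sin(turn / 2))
      i <- seq_len(n_hel) - 1
      pos[seq_len(n_hel), ] <- cbind(radius * cos(i * turn),
                                     radius * sin(i * turn),
                                     i * rise)
    }
    start <- if (n_hel == 0) 2L else n_hel + 1L
    if (n_hel == 0) pos[1, ] <- c(0, 0, 0)
    for (i in start:n) {
      if (i > n) break
      placed <- FALSE
      for (try in 1:400) {
        u <- stats::rnorm(3)
        cand <- pos[i - 1, ] + bond * u / sqrt(sum(u^2))
        prev <- pos[seq_len(max(0, i - 2)), , drop = FALSE]
        if (nrow(prev) == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
          pos[i, ] <- cand; placed <- TRUE; break
        }
      }
      if (!placed) stop("could not grow self-avoiding walk")
    }
  }
  atomic_model(data.frame(
    chain = "A", resno = seq_len(n), insert = "", resid = "ALA",
    elety = "CA", elesy = "C", x = pos[, 1], y = pos[, 2], z = pos[, 3],
    weight = 1, stringsAsFactors = FALSE))
}

#' Parameters of a synthetic two-body benchmark case
#'
#' @param n_residues residues per body (default 60; the default case is 2 x
#'   60 residues on a roughly 40^3 grid of 4 A voxels).
#' @param helical_fraction chirality control per body (default 0.5).
#' @param resolution map resolution in angstrom (default 30, the scale of a
#'   negative-stain reconstruction).
#' @param voxel_size grid spacing (default 4 A).
#' @param noise_sd i.i.d. Gaussian voxel noise, relative to the map maximum
#'   (default 0: the reference case is noiseless).
#' @param n_satisfied,n_violated planted distance links: satisfied links have
#'   truth C-alpha distance <= max_distance - 5 A, violated ones
#'   > max_distance + 5 A (defaults 21 and 4, i.e. 25 mappable links of which
#'   4 violated).
#' @param n_decoys sub-threshold decoy links (default 10).
#' @param n_monolinks monolink rows (default 3).
#' @param ld_threshold ld score separating planted links (drawn above) from
#'   decoys (drawn below); default 40.
#' @param max_distance violation cutoff in angstrom (default 35).
#' @param seed integer seed; the whole case is reproducible from it.
#' @return An object of class \code{synthetic_params}.
#' @export
synthetic_params <- function(n_residues = 60, helical_fraction = 0.5,
                             resolution = 30, voxel_size = 4,
                             noise_sd = 0, n_satisfied = 21, n_violated = 4,
                             n_decoys = 10, n_monolinks = 3,
                             ld_threshold = 40, max_distance = 35,
                             seed = 7) {
  stopifnot(n_residues >= 10, helical_fraction >= 0, helical_fraction <= 1,
            noise_sd >= 0, resolution > 0, voxel_size > 0)
  structure(list(n_residues = n_residues,
                 helical_fraction = helical_fraction,
                 resolution = resolution, voxel_size = voxel_size,
                 noise_sd = noise_sd, n_satisfied = n_satisfied,
                 n_violated = n_violated, n_decoys = n_decoys,
                 n_monolinks = n_monolinks, ld_threshold = ld_threshold,
                 max_distance = max_distance, seed = as.integer(seed)),
            class = "synthetic_params")
}

# dock body B against body A: translate B along a random direction until the
# minimum inter-body CA distance lies in [5, 8] A
dock_bodies <- function(xyzA, xyzB) {
  dir <- stats::rnorm(3)
  dir <- dir / sqrt(sum(dir^2))
  cA <- colMeans(xyzA)
  cB <- colMeans(xyzB)
  min_d <- function(shift) {
    pb <- sweep(xyzB, 2, cB - cA - shift * dir, "-")
    d2 <- outer(rowSums(xyzA^2), rowSums(pb^2), "+") - 2 * xyzA %*% t(pb)
    sqrt(max(0, min(d2)))
  }
  lo <- 0; hi <- 300
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (min_d(mid) < 6.5) lo <- mid else hi <- mid
  }
  shift <- (lo + hi) / 2
  d <- min_d(shift)
  if (d < 5 || d > 8) {
    shift <- shift + (6.5 - d)
  }
  cA - cB + shift * dir
}

#' Generate a two-body ground-truth benchmark case
#'
#' Builds two toy chains, docks them with an interface (minimum inter-body
#' C-alpha distance 5-8 A), simulates the joint density map at the requested
#' resolution, adds seeded voxel noise, mirrors the map along x, and
#' generates a crosslink table with planted satisfied and violated links
#' (ld scores above the threshold) plus sub-threshold decoys and monolinks.
#' The bodies are returned in local (centred) frames together with the truth
#' transforms placing them into the assembly; byte-identical regeneration
#' from the same parameters is guaranteed.
#'
#' @param params a \code{synthetic_params}.
#' @return List of class \code{synthetic_case}: \code{bodyA}, \code{bodyB}
#'   (local frames), \code{truthA}, \code{truthB} (\code{rigid_transform}s),
#'   \code{map} (shared map of the whole complex), \code{mirrored_map},
#'   \code{map_bodyA}, \code{map_bodyB} (per-body maps for self-fit
#'   benchmarks), \code{xlinks} (an \code{xlink_table}), \code{params}.
#' @export
make_two_body_case <- function(params = synthetic_params()) {
  p <- params
  chainA <- make_toy_chain(p$n_residues, p$helical_fraction, seed = p$seed)
  chainB <- make_toy_chain(p$n_residues, p$helical_fraction,
                           seed = p$seed + 1000L)
  set.seed(p$seed + 2000L)
  # random assembled orientations
  RA <- quat_to_matrix(stats::rnorm(4))
  RB <- quat_to_matrix(stats::rnorm(4))
  xyzA <- coords(chainA) %*% t(RA)
  xyzB <- coords(chainB) %*% t(RB)
  tB <- dock_bodies(xyzA, xyzB)
  xyzB <- sweep(xyzB, 2, tB, "+")

  # local frames: centred bodies; truth transform places local -> assembly
  cA <- colMeans(xyzA); cB <- colMeans(xyzB)
  localA <- chainA
  localA$atoms[, c("x", "y", "z")] <- sweep(xyzA, 2, cA)
  localB <- chainB
  localB$atoms[, c("x", "y", "z")] <- sweep(xyzB, 2, cB)
  localB$atoms$chain <- "B"
  truthA <- rigid_transform(diag(3), cA)
  truthB <- rigid_transform(diag(3), cB)

  assembly <- atomic_model(rbind(apply_transform(localA, truthA)$atoms,
                                 apply_transform(localB, truthB)$atoms))
  sp <- simulation_params(p$resolution, p$voxel_size)
  clean <- simulate_map(assembly, sp)
  vals <- clean$values
  if (p$noise_sd > 0)
    vals <- vals + stats::rnorm(length(vals), 0,
                                p$noise_sd * max(vals))
  map <- density_map(vals, clean$voxel_size, clean$origin,
                     label = sprintf("synthetic two-body case seed %d",
                                     p$seed))
  xlinks <- plant_crosslinks(assembly, p)
  # per-body maps (each body alone at its truth pose), for self-fit
  # benchmarks; the shared `map` of the whole complex is what the assembly
  # and handedness stages consume
  noisy <- function(m) {
    if (p$noise_sd == 0) return(m)
    density_map(m$values + stats::rnorm(length(m$values), 0,
                                        p$noise_sd * max(m$values)),
                m$voxel_size, m$origin, m$label)
  }
  map_bodyA <- noisy(simulate_map(apply_transform(localA, truthA), sp))
  map_bodyB <- noisy(simulate_map(apply_transform(localB, truthB), sp))
  structure(list(bodyA = localA, bodyB = localB,
                 truthA = truthA, truthB = truthB,
                 map = map, mirrored_map = mirror_map(map, "x"),
                 map_bodyA = map_bodyA, map_bodyB = map_bodyB,
                 xlinks = xlinks, params = p),
            class = "synthetic_case")
}

#' @export
print.synthetic_case <- function(x, ...) {
  cat(sprintf("synthetic_case (seed %d): 2 x %d residues, %.0f A map, noise %.2g\n",
              x$params$seed, x$params$n_residues, x$params$resolution,
              x$params$noise_sd))
  print(x$map)
  if (!is.null(x$xlinks))
    cat(sprintf("  crosslink table: %d rows (%d planted satisfied, %d violated)\n",
                nrow(x$xlinks), x$params$n_satisfied, x$params$n_violated))
  invisible(x)
}

# choose planted residue pairs from the assembled pose and draw ld scores
plant_crosslinks <- function(assembly, p) {
  a <- assembly$atoms[trimws(assembly$atoms$elety) == "CA", ]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  n <- nrow(a)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  dist_p <- d[pairs]
  ok_sat <- dist_p <= p$max_distance - 5
  ok_vio <- dist_p > p$max_distance + 5
  if (sum(ok_sat) < p$n_satisfied + p$n_decoys || sum(ok_vio) < p$n_violated)
    stop("chains too small to plant the requested links")
  pick <- function(ok, k) pairs[sample(which(ok), k), , drop = FALSE]
  sat <- pick(ok_sat, p$n_satisfied)
  vio <- pick(ok_vio, p$n_violated)
  # decoys drawn from the satisfied-distance pool; their ld scores fall below
  # the threshold so the filter removes them
  dec <- pick(ok_sat, p$n_decoys)
  mono_idx <- sample(n, p$n_monolinks)
  row_of <- function(idx, ld) data.frame(
    protein1 = paste0("body", a$chain[idx[, 1]]),
    residue1 = a$resno[idx[, 1]],
    protein2 = paste0("body", a$chain[idx[, 2]]),
    residue2 = a$resno[idx[, 2]],
    ld_score = ld,
    link_type = ifelse(a$chain[idx[, 1]] == a$chain[idx[, 2]], "intra",
                       "inter"),
    stringsAsFactors = FALSE)
  ld_hi <- function(k) round(p$ld_threshold + stats::runif(k, 0, 20), 2)
  ld_lo <- function(k) round(stats::runif(k, 10, p$ld_threshold - 1), 2)
  tab <- rbind(
    row_of(sat, ld_hi(p$n_satisfied)),
    row_of(vio, ld_hi(p$n_violated)),
    row_of(dec, ld_lo(p$n_decoys)),
    data.frame(protein1 = paste0("body", a$chain[mono_idx]),
               residue1 = a$resno[mono_idx],
               protein2 = "", residue2 = NA_integer_,
               ld_score = ld_hi(p$n_monolinks), link_type = "monolink",
               stringsAsFactors = FALSE))
  rownames(tab) <- NULL
  class(tab) <- c("xlink_table", "data.frame")
  tab
}

#' Write a crosslink score table for a synthetic case
#'
#' Emits the case's planted crosslink table in the tab-separated xQuest-style
#' dialect read by \code{\link{read_xlink_table}}.
#' @param params a \code{synthetic_params} (the case is regenerated from it),
#'   or a \code{synthetic_case}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
make_score_table <- function(params, path) {
  case <- if (inherits(params, "synthetic_case")) params
          else make_two_body_case(params)
  write_xlink_table(case$xlinks, path)
  invisible(path)
}

#' Chain map of a synthetic case
#'
#' The protein-name to chain-id table matching the generator's naming
#' ("bodyA" -> chain A, "bodyB" -> chain B).
#' @return Named character vector usable as \code{chain_map} in
#'   \code{\link{xlink_config}}.
#' @export
synthetic_chain_map <- function() c(bodyA = "A", bodyB = "B")

#' Write a synthetic case to a directory
#'
#' Emits \code{bodyA.pdb}, \code{bodyB.pdb}, \code{truth.json},
#' \code{map.mrc}, \code{map_mirror.mrc}, \code{links.tsv} and
#' \code{params.yaml}. Regeneration from the same parameters is
#' byte-identical.
#' @param case a \code{synthetic_case}.
#' @param outdir output directory (created if needed).
#' @return Invisibly, \code{outdir}.
#' @export
write_case <- function(case, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_structure(case$bodyA, file.path(outdir, "bodyA.pdb"))
  write_structure(case$bodyB, file.path(outdir, "bodyB.pdb"))
  write_map(case$map, file.path(outdir, "map.mrc"))
  write_map(case$mirrored_map, file.path(outdir, "map_mirror.mrc"))
  write_xlink_table(case$xlinks, file.path(outdir, "links.tsv"))
  truth <- list(
    bodyA = list(quaternion = matrix_to_quat(case$truthA$rotation),
                 translation = case$truthA$translation),
    bodyB = list(quaternion = matrix_to_quat(case$truthB$rotation),
                 translation = case$truthB$translation))
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(case$params), file.path(outdir, "params.yaml"))
  invisible(outdir)
}

#' Single-body handedness benchmark case
#'
#' A chiral (or planar achiral) toy chain with a simulated map and its x
#' mirror. The default 8 A resolution on 2 A voxels is the scale at which the
#' toy chains' helical hand is actually resolved in the density: an
#' alpha-helical path (radius ~2.3 A) blurred to tens of angstrom is
#' effectively a featureless rod, so handedness benchmarks use a map
#' resolution commensurate with the size of the chiral features, mirroring
#' how real handedness determination relies on chiral shape at the map's own
#' scale.
#'
#' @param seed integer seed.
#' @param helical_fraction chirality control (0.8 for the chiral benchmark).
#' @param planar build an achiral planar body instead.
#' @param n_residues chain length (default 60).
#' @param resolution,voxel_size map scale (defaults 8 A / 2 A).
#' @param noise_sd relative Gaussian voxel noise (default 0.05).
#' @return List of class \code{synthetic_case} (single body in \code{bodyA};
#'   \code{bodyB}, \code{xlinks} absent).
#' @export
make_handedness_case <- function(seed, helical_fraction = 0.8,
                                 planar = FALSE, n_residues = 60,
                                 resolution = 8, voxel_size = 2,
                                 noise_sd = 0.05) {
  body <- make_toy_chain(n_residues, helical_fraction, seed = seed,
                         planar = planar)
  set.seed(seed + 5000L)
  R <- quat_to_matrix(stats::rnorm(4))
  xyz <- coords(body) %*% t(R)
  local <- body
  local$atoms[, c("x", "y", "z")] <- sweep(xyz, 2, colMeans(xyz))
  truth <- rigid_transform(diag(3), colMeans(xyz))
  sp <- simulation_params(resolution, voxel_size)
  clean <- simulate_map(apply_transform(local, truth), sp)
  vals <- clean$values
  if (noise_sd > 0)
    vals <- vals + stats::rnorm(length(vals), 0, noise_sd * max(vals))
  map <- density_map(vals, clean$voxel_size, clean$origin,
                     label = sprintf("handedness case seed %d", seed))
  structure(list(bodyA = local, bodyB = NULL, truthA = truth, truthB = NULL,
                 map = map, mirrored_map = mirror_map(map, "x"),
                 xlinks = NULL,
                 params = list(seed = seed, resolution = resolution,
                               voxel_size = voxel_size, noise_sd = noise_sd,
                               helical_fraction = helical_fraction,
                               planar = planar, n_residues = n_residues)),
            class = "synthetic_case")
}
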