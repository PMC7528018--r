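# Handedness decision rule, combined fits, ranking.

test_that("the decision rule requires unanimity plus agreement", {
  best1 <- c(overlap = 100, ccc = 0.9, chamfer = 3, envelope = 0.8)
  best2 <- c(overlap = 80, ccc = 0.7, chamfer = 5, envelope = 0.6)
  expect_equal(decide_handedness(best1, best2), "mirror1")
  expect_equal(decide_handedness(best2, best1), "mirror2")
  # metrics split 2-2: ambiguous
  split2 <- c(overlap = 120, ccc = 0.95, chamfer = 5, envelope = 0.6)
  expect_equal(decide_handedness(best1, split2), "ambiguous")
  # unanimity without same-top-fit agreement: ambiguous
  expect_equal(decide_handedness(best1, best2, agreeA = FALSE), "ambiguous")
  # sub-margin differences are ties
  near <- best1 * 1.001
  expect_equal(decide_handedness(near, best1), "ambiguous")
})

test_that("combine_fits counts the Cartesian product minus clashes", {
  atom <- toy_atom()
  span <- atomic_model(rbind(toy_atom(c(0, 0, 0))$atoms,
                             toy_atom(c(30, 30, 0))$atoms))
  sp <- simulation_params(12, 3, padding = 12)
  map <- simulate_map(span, sp)
  mk_ens <- function(ts) fit_ensemble(lapply(seq_along(ts), function(i)
    list(transform = ts[[i]], scores = NULL, score = i, coverage = 1,
         cluster_size = 1L)))
  # 3 x 4 placements, all farther apart than the clash radius
  tsA <- lapply(1:3, function(i) rigid_transform(diag(3), c(10 * i, 0, 0)))
  tsB <- lapply(1:4, function(i) rigid_transform(diag(3), c(0, 8 * i, 0)))
  comb <- combine_fits(mk_ens(tsA), mk_ens(tsB), atom, atom, map,
                       params = sp)
  expect_length(comb, 12)
  expect_true(all(c("overlap", "ccc", "chamfer", "envelope") %in%
                    names(comb[[1]]$scores)))
  # identical placements fully clash and are removed at any clash_max < 1
  comb2 <- combine_fits(mk_ens(tsA), mk_ens(tsA[1]), atom, atom, map,
                        params = sp)
  expect_length(comb2, 2)  # the coincident pair is gone
  expect_warning(combine_fits(fit_ensemble(list()), mk_ens(tsA), atom,
                              atom, map, params = sp), "empty")
})

test_that("planted clashing pairs match a brute-force pair check", {
  # single-CA bodies: a pair clashes iff the placements are within 4 A.
  # A sits at x = 6i; B1-B3 coincide with A1-A3 (3 clashes) and B4, B5 sit
  # midway between two A's, 3 A from each (2 clashes apiece): 7 in total.
  atom <- toy_atom()
  span <- atomic_model(rbind(toy_atom(c(6, 0, 0))$atoms,
                             toy_atom(c(18, 0, 0))$atoms,
                             toy_atom(c(30, 0, 0))$atoms))
  sp <- simulation_params(12, 3, padding = 15)
  map <- simulate_map(span, sp)
  tsA <- lapply(1:5, function(i) rigid_transform(diag(3), c(6 * i, 0, 0)))
  tsB <- list(rigid_transform(diag(3), c(6, 0, 0)),
              rigid_transform(diag(3), c(12, 0, 0)),
              rigid_transform(diag(3), c(18, 0, 0)),
              rigid_transform(diag(3), c(9, 0, 0)),
              rigid_transform(diag(3), c(15, 0, 0)))
  brute <- 0
  for (i in 1:5) for (j in 1:5) {
    d <- sqrt(sum((tsA[[i]]$translation - tsB[[j]]$translation)^2))
    if (d >= 4) brute <- brute + 1
  }
  expect_equal(brute, 18)  # 25 pairs - 7 planted clashes
  mk_ens <- function(ts) fit_ensemble(lapply(seq_along(ts), function(i)
    list(transform = ts[[i]], scores = NULL, score = i, coverage = 1,
         cluster_size = 1L)))
  comb <- combine_fits(mk_ens(tsA), mk_ens(tsB), atom, atom, map,
                       clash_radius = 4, clash_max = 0.05, params = sp)
  expect_equal(length(comb), brute)
})

test_that("rank_combined obeys dominance, crosslink tie-breaks, stability", {
  mk <- function(ov, cc, ch, en, iA, iB, trA = NULL, trB = NULL) {
    list(idA = iA, idB = iB,
         fitA = list(transform = trA %||% rigid_transform()),
         fitB = list(transform = trB %||% rigid_transform()),
         clash_fraction = 0,
         scores = list(overlap = ov, ccc = cc, chamfer = ch, envelope = en,
                       chamfer_sim = -ch))
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  dominant <- mk(10, 0.9, 1, 0.9, 1, 1)
  weak1 <- mk(5, 0.5, 4, 0.5, 1, 2)
  weak2 <- mk(6, 0.4, 5, 0.45, 2, 1)
  ranked <- rank_combined(structure(list(weak1, dominant, weak2),
                                    class = "combined_fits"))
  expect_equal(ranked[[1]]$idA, 1)
  expect_equal(ranked[[1]]$idB, 1)
  # permutation stability
  ranked2 <- rank_combined(structure(list(dominant, weak2, weak1),
                                     class = "combined_fits"))
  key <- function(r) vapply(r, function(f) paste(f$idA, f$idB), character(1))
  expect_equal(key(ranked), key(ranked2))
  # crosslink tie-break between metric-tied fits
  case <- make_two_body_case(synthetic_params(seed = 13))
  tied_good <- mk(10, 0.9, 1, 0.9, 1, 1, case$truthA, case$truthB)
  tied_bad <- mk(10, 0.9, 1, 0.9, 2, 2, case$truthA,
                 transform_compose(rigid_transform(diag(3), c(200, 0, 0)),
                                   case$truthB))
  cfg <- xlink_config(40, 35, synthetic_chain_map())
  rk <- rank_combined(structure(list(tied_bad, tied_good),
                                class = "combined_fits"),
                      case$bodyA, case$bodyB, case$xlinks, cfg, window = 1)
  expect_equal(rk[[1]]$idA, 1)  # truth pair satisfies more links
  sat <- attr(rk, "satisfaction")
  expect_gt(sat[1], sat[2])
})

test_that("combined fits recover the two-body arrangement by location", {
  # independent single-body fits on a merged two-blob map are displaced
  # toward the partner density and orientation-degenerate at 30 A; what the
  # combined stage can honestly determine is the location of each body, so
  # recovery is asserted on body centroids (within half the map resolution)
  case <- make_two_body_case(synthetic_params(seed = 7))
  cfg <- fit_config(n_placements = 800, opt_steps = 100,
                    cluster_rot_deg = 30, cluster_trans = 15, rng_seed = 10)
  ensA <- global_fit(case$map, case$bodyA, cfg, body_id = "A")
  ensB <- global_fit(case$map, case$bodyB, cfg, body_id = "B")
  comb <- combine_fits(ensA, ensB, case$bodyA, case$bodyB, case$map)
  expect_gt(length(comb), 5)
  xcfg <- xlink_config(40, 35, synthetic_chain_map())
  ranked <- rank_combined(comb, case$bodyA, case$bodyB, case$xlinks, xcfg)
  cen <- function(tr, model) {
    c0 <- colMeans(coords(model))
    as.numeric(tr$rotation %*% c0) + tr$translation
  }
  errA <- vapply(ranked, function(f)
    sqrt(sum((cen(f$fitA$transform, case$bodyA) -
                cen(case$truthA, case$bodyA))^2)), numeric(1))
  errB <- vapply(ranked, function(f)
    sqrt(sum((cen(f$fitB$transform, case$bodyB) -
                cen(case$truthB, case$bodyB))^2)), numeric(1))
  expect_lt(errA[1], 15)
  expect_lt(errB[1], 15)
  # the pair nearest the truth arrangement sits at the very top of the
  # ranking (the analogue of a top-percentile rank at this product-set size)
  expect_lte(which.min(errA + errB), max(2, ceiling(0.01 * length(ranked))))
})

test_that("handedness decisions swap when the map itself is mirrored", {
  case <- make_handedness_case(15, noise_sd = 0)
  cfg <- fit_config(n_placements = 150, opt_steps = 50, resolution = 8,
                    cluster_rot_deg = 30, cluster_trans = 15, rng_seed = 2)
  h1 <- assess_handedness(case$map, case$bodyA, cfg)
  h2 <- assess_handedness(case$mirrored_map, case$bodyA, cfg)
  expect_equal(h1$chosen, "mirror1")
  expect_equal(h2$chosen, "mirror2")
})
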