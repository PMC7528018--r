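# The four metrics and fit significance.

test_that("overlap equals the squared norm for identical maps, 0 when disjoint", {
  m <- toy_map(c(6, 6, 6), seed = 1)
  expect_equal(overlap_score(m, m), sum(m$values^2))
  far <- density_map(m$values, m$voxel_size, m$origin + 1000)
  expect_warning(z <- overlap_score(m, far), "intersect")
  expect_equal(z, 0)
})

test_that("direct overlap equals FFT correlation on an integer-shift scan", {
  set.seed(3)
  d <- c(8, 8, 8)
  a <- array(runif(prod(d)), d)
  b <- array(runif(prod(d)), d)
  # FFT cross-correlation of zero-padded grids
  dp <- 2 * d
  pa <- array(0, dp); pa[1:d[1], 1:d[2], 1:d[3]] <- a
  pb <- array(0, dp); pb[1:d[1], 1:d[2], 1:d[3]] <- b
  cc <- Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pb)),
                      inverse = TRUE)) / prod(dp)
  ma <- density_map(a, 1)
  for (shift in list(c(0, 0, 0), c(1, 0, 0), c(2, 3, 1), c(-1, -2, 0))) {
    mb <- density_map(b, 1, origin = -shift)  # b shifted so b[v+shift] aligns
    direct <- overlap_score(ma, mb)
    # cc[k] = sum_v pa[v] * pb[v - k]; direct = sum_v a[v] b[v + shift]
    idx <- ((-shift) %% dp) + 1
    expect_equal(direct, cc[idx[1], idx[2], idx[3]], tolerance = 1e-6)
  }
})

test_that("cross-correlation is 1 for m vs m and -1 for m vs -m", {
  m <- toy_map(c(10, 9, 8), seed = 4)
  neg <- density_map(-m$values, m$voxel_size, m$origin)
  expect_equal(cross_correlation(m, m), 1.0)
  expect_equal(cross_correlation(m, neg), -1.0)
  zero <- density_map(array(0, dim(m$values)), m$voxel_size, m$origin)
  expect_error(cross_correlation(m, zero), "zero-norm")
})

test_that("cross-correlation against independent noise is near zero", {
  set.seed(10)
  ccs <- vapply(1:20, function(i) {
    a <- density_map(array(rnorm(32^3), c(32, 32, 32)), 1)
    b <- density_map(array(rnorm(32^3), c(32, 32, 32)), 1)
    cross_correlation(a, b)
  }, numeric(1))
  expect_true(all(abs(ccs) < 0.1))
})

test_that("chamfer distance matches simple geometry and the n^2 oracle", {
  one <- array(FALSE, c(5, 5, 5)); one[2, 2, 2] <- TRUE
  two <- array(FALSE, c(5, 5, 5)); two[4, 2, 2] <- TRUE
  e1 <- density_envelope(one, 0.1, c(2, 2, 2), c(0, 0, 0))
  e2 <- density_envelope(two, 0.1, c(2, 2, 2), c(0, 0, 0))
  expect_equal(chamfer_distance(e1, e1), 0)
  expect_equal(chamfer_distance(e1, e2), 4)  # two voxels apart at 2 A
  set.seed(6)
  pa <- matrix(runif(3 * 400, 0, 50), ncol = 3)
  pb <- matrix(runif(3 * 350, 0, 50), ncol = 3)
  expect_equal(chamfer_distance(pa, pb), chamfer_brute(pa, pb),
               tolerance = 1e-9)
  expect_equal(chamfer_distance(pa, pb), chamfer_distance(pb, pa))
})

test_that("envelope (Dice) score handles identity, disjoint and half overlap", {
  d <- c(10, 10, 10)
  a <- array(FALSE, d); a[1:100] <- TRUE
  b <- array(FALSE, d); b[51:150] <- TRUE
  dis <- array(FALSE, d); dis[201:300] <- TRUE
  ea <- density_envelope(a, 0.1, 1, c(0, 0, 0))
  eb <- density_envelope(b, 0.1, 1, c(0, 0, 0))
  ed <- density_envelope(dis, 0.1, 1, c(0, 0, 0))
  expect_equal(envelope_score(ea, ea), 1.0)
  expect_equal(envelope_score(ea, ed), 0.0)
  expect_equal(envelope_score(ea, eb), 0.5)  # |A|=|B|=100, |A int B|=50
  expect_identical(envelope_score(ea, eb), envelope_score(eb, ea))
  empty <- density_envelope(array(FALSE, d), 0.1, 1, c(0, 0, 0))
  expect_error(envelope_score(empty, empty), "empty")
})

test_that("the truth placement outranks random placements on all metrics", {
  case <- make_handedness_case(9, noise_sd = 0, resolution = 12,
                               voxel_size = 3)
  sp <- simulation_params(12, 3)
  st <- score_fit(case$map, case$bodyA, case$truthA, sp)
  set.seed(12)
  rand <- random_placements(case$map, case$bodyA, 50)
  others <- lapply(rand, function(tr)
    score_fit(case$map, case$bodyA, tr, sp))
  for (m in c("overlap", "ccc", "envelope")) {
    expect_true(all(vapply(others, `[[`, numeric(1), m) < st[[m]]))
  }
  expect_true(all(vapply(others, `[[`, numeric(1), "chamfer") > st$chamfer))
  # chamfer similarity reverses the chamfer ordering
  ch <- vapply(others, `[[`, numeric(1), "chamfer")
  cs <- vapply(others, `[[`, numeric(1), "chamfer_sim")
  expect_equal(order(ch), rev(order(cs)))
})

test_that("scores are invariant under joint grid-aligned motion", {
  case <- make_handedness_case(10, noise_sd = 0, resolution = 12,
                               voxel_size = 3)
  sp <- simulation_params(12, 3)
  s0 <- score_fit(case$map, case$bodyA, case$truthA, sp)
  shift <- c(6, -9, 3)  # voxel multiples
  map2 <- density_map(case$map$values, case$map$voxel_size,
                      case$map$origin + shift)
  tr2 <- transform_compose(rigid_transform(diag(3), shift), case$truthA)
  s1 <- score_fit(map2, case$bodyA, tr2, sp)
  for (m in c("overlap", "ccc", "chamfer", "envelope"))
    expect_equal(s1[[m]], s0[[m]], tolerance = 1e-9)
})

test_that("fit significance follows the normal reference", {
  expect_error(fit_significance(c(1, 2)), "at least 3")
  flat <- fit_significance(rep(2.5, 10))
  expect_equal(flat$z, 0)
  expect_equal(flat$p, 0.5)
  set.seed(15)
  s <- c(5, rnorm(1000))
  sig <- fit_significance(s)
  expect_lt(sig$p, 1e-5)
  expect_true(sig$significant)
  # degenerate: sd 0 with a strictly greater top
  deg <- fit_significance(c(3, 1, 1, 1))
  expect_true(deg$degenerate)
  expect_lt(deg$p, 1e-300)
})

test_that("overlap and ccc rank fixed-norm model maps identically", {
  case <- make_handedness_case(11, noise_sd = 0, resolution = 12,
                               voxel_size = 3)
  sp <- simulation_params(12, 3)
  set.seed(16)
  trs <- random_placements(case$map, case$bodyA, 25)
  # keep placements whose model-map norm is constant within 1 percent
  exp_norm <- map_normalize(case$map)
  norms <- vapply(trs, function(tr) {
    mm <- simulate_map(apply_transform(case$bodyA, tr), sp, grid = exp_norm)
    sqrt(sum(mm$values^2))
  }, numeric(1))
  keep <- abs(norms / stats::median(norms) - 1) < 0.01
  if (sum(keep) >= 5) {
    sc <- lapply(trs[keep], function(tr)
      score_fit(case$map, case$bodyA, tr, sp))
    ov <- vapply(sc, `[[`, numeric(1), "overlap")
    cc <- vapply(sc, `[[`, numeric(1), "ccc")
    expect_gt(stats::cor(ov, cc, method = "spearman"), 0.99)
  } else {
    succeed("too few fixed-norm placements sampled; ranking check vacuous")
  }
})
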