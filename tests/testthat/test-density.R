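# Density-map model, MRC round trips, simulation, mirroring, envelopes.

test_that("MRC round trip preserves values, voxel size and origin", {
  m <- toy_map(c(4, 4, 4), voxel = c(1.0, 1.5, 2.0), origin = c(-10, 5, 0))
  p <- tempfile(fileext = ".mrc")
  # float32 storage: write values already representable at single precision
  m$values[] <- round(m$values, 3)
  write_map(m, p)
  m2 <- read_map(p)
  expect_equal(m2$values, m$values, tolerance = 1e-6)
  expect_equal(m2$voxel_size, m$voxel_size)
  expect_equal(m2$origin, m$origin)

  # bitwise equality of float32 payloads on a second round trip
  p2 <- tempfile(fileext = ".mrc")
  write_map(m2, p2)
  expect_identical(readBin(p, "raw", 1e6)[-(1:1024)],
                   readBin(p2, "raw", 1e6)[-(1:1024)])
})

test_that("origin recorded only in start-voxel fields is reconstructed", {
  m <- toy_map(c(5, 4, 3), voxel = 2, origin = c(-4, 6, 2))
  p <- tempfile(fileext = ".mrc")
  write_map(m, p, origin_mode = "start")
  m2 <- read_map(p)
  # header arithmetic: origin = start * voxel = (-2, 3, 1) * 2
  expect_equal(m2$origin, c(-4, 6, 2))
  expect_equal(m2$values, m$values, tolerance = 1e-6)
})

test_that("truncated or non-standard MRC files raise format errors", {
  m <- toy_map(c(6, 6, 6))
  p <- tempfile(fileext = ".mrc")
  write_map(m, p)
  full <- readBin(p, "raw", file.info(p)$size)
  pt <- tempfile(fileext = ".mrc")
  writeBin(full[1:(1024 + 100)], pt)
  expect_error(read_map(pt), "truncated")
  writeBin(full[1:500], pt)
  expect_error(read_map(pt), "header|MRC")
  # permuted axis order is refused with the order named
  perm <- full
  perm[65:68] <- writeBin(2L, raw(), size = 4)  # mapc = 2
  writeBin(perm, pt)
  expect_error(read_map(pt), "axis order")
})

test_that("simulated single atom is a Gaussian with the stated sigma", {
  sp <- simulation_params(resolution = 10, voxel_size = 1)
  sigma <- 0.225 * 10
  m <- simulate_map(toy_atom(c(0.5, 0.5, 0.5)), sp)
  peak_idx <- which(m$values == max(m$values), arr.ind = TRUE)[1, ]
  peak_pos <- m$origin + (peak_idx - 1) * m$voxel_size
  expect_lt(sqrt(sum((peak_pos - c(0.5, 0.5, 0.5))^2)),
            sqrt(3) / 2 * max(m$voxel_size))
  # value at distance sigma: exp(-1/2) of the peak
  v <- interpolate_map(m, matrix(c(0.5 + sigma, 0.5, 0.5), 1))
  expect_equal(v / max(m$values), exp(-0.5), tolerance = 0.02)
})

test_that("well-separated atoms contribute additively", {
  sp <- simulation_params(resolution = 4, voxel_size = 1, padding = 5)
  sigma <- 0.9
  one <- simulate_map(toy_atom(c(0, 0, 0)), sp)
  # separation 11 A > 10 sigma, an integer voxel multiple so both atoms sit
  # at the same grid phase and truncation geometry
  two <- simulate_map(atomic_model(rbind(toy_atom(c(0, 0, 0))$atoms,
                                         toy_atom(c(11, 0, 0))$atoms)),
                      sp)
  expect_equal(sum(two$values), 2 * sum(one$values), tolerance = 1e-6)
})

test_that("toy-chain map integrates to the Gaussian closed form", {
  chain <- make_toy_chain(50, helical_fraction = 0.5, seed = 3)
  sp <- simulation_params(resolution = 30, voxel_size = 4)
  m <- simulate_map(chain, sp)
  sigma <- 0.225 * 30
  expected <- sum(chain$atoms$weight) * (2 * pi * sigma^2)^1.5 /
    prod(m$voxel_size)
  expect_equal(sum(m$values), expected, tolerance = 0.01)
})

test_that("mirroring is an involution and conserves total density", {
  m <- toy_map(c(7, 5, 6), voxel = 1.3, origin = c(1, -2, 3), seed = 8)
  for (ax in c("x", "y", "z")) {
    mm <- mirror_map(m, ax)
    expect_equal(sum(mm$values), sum(m$values))
    back <- mirror_map(mm, ax)
    expect_identical(back$values, m$values)
    expect_equal(back$origin, m$origin)
  }
})

test_that("mirror of a map from a planar point set is a proper rotation of it", {
  # points in the z = 0 plane: reflecting along x equals a 180-degree
  # rotation about the y axis through the map centre
  set.seed(5)
  pts <- cbind(matrix(runif(20, -8, 8), 10, 2), 0)
  model <- atomic_model(data.frame(
    chain = "A", resno = 1:10, insert = "", resid = "ALA", elety = "CA",
    elesy = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3], weight = 1))
  sp <- simulation_params(resolution = 8, voxel_size = 2)
  m <- simulate_map(model, sp)
  mir <- mirror_map(m, "x")
  # rotate the model by pi about the y line through the map x centre in the
  # object's own plane z = 0
  d <- dim(m$values)
  cx <- m$origin[1] + (d[1] - 1) / 2 * m$voxel_size[1]
  R <- axis_rotation("y", pi)
  tr <- rigid_transform(R, c(2 * cx, 0, 0))
  rot_model <- apply_transform(model, tr)
  resim <- simulate_map(rot_model, sp, grid = m)
  expect_equal(max(abs(resim$values - mir$values)) / max(m$values), 0,
               tolerance = 1e-6)
})

test_that("binarize counts voxels strictly above threshold, monotonically", {
  vals <- array(0, c(3, 3, 3))
  vals[1:5] <- c(0.07, 0.08, 0.061, 0.3, 1)
  m <- density_map(vals, 1)
  expect_equal(sum(binarize(m, 0.06)$mask), 5)
  expect_equal(sum(binarize(m, 2)$mask), 0)       # above max: empty
  expect_equal(sum(binarize(m, -1)$mask), 27)     # below min: full
  thr <- sort(runif(10))
  counts <- vapply(thr, function(t) sum(binarize(m, t)$mask), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("surface_points matches the brute-force neighbour scan", {
  # single voxel
  one <- array(FALSE, c(3, 3, 3)); one[2, 2, 2] <- TRUE
  env <- density_envelope(one, 0.5, c(1, 1, 1), c(0, 0, 0))
  expect_equal(surface_points(env), matrix(c(1, 1, 1), 1),
               ignore_attr = TRUE)
  # solid 5^3 cube has 5^3 - 3^3 = 98 surface voxels
  cube <- array(FALSE, c(7, 7, 7)); cube[2:6, 2:6, 2:6] <- TRUE
  envc <- density_envelope(cube, 0.5, c(1, 1, 1), c(0, 0, 0))
  expect_equal(nrow(surface_points(envc)), 98)
  # random blob equals the independent triple-loop scan
  set.seed(11)
  blob <- array(runif(5 * 6 * 4) > 0.55, c(5, 6, 4))
  envb <- density_envelope(blob, 0.5, c(2, 2, 2), c(1, 1, 1))
  got <- surface_points(envb)
  want <- sweep(sweep(surface_brute(blob) - 1, 2, c(2, 2, 2), "*"), 2,
                c(1, 1, 1), "+")
  expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
               want[order(want[, 1], want[, 2], want[, 3]), ],
               ignore_attr = TRUE)
  expect_error(surface_points(density_envelope(array(FALSE, c(2, 2, 2)),
                                               0.5, 1, c(0, 0, 0))),
               "empty")
})

test_that("simulation is equivariant under grid-aligned rigid motion", {
  model <- toy_triatom()
  sp <- simulation_params(resolution = 8, voxel_size = 2)
  m1 <- simulate_map(model, sp)
  shift <- c(4, -6, 2)  # integer multiples of the voxel size
  m2 <- simulate_map(apply_transform(model, rigid_transform(diag(3), shift)),
                     sp)
  expect_equal(m2$values, m1$values, tolerance = 1e-9)
  expect_equal(m2$origin, m1$origin + shift, tolerance = 1e-9)
})
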