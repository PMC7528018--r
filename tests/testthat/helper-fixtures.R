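# Fixtures built in code: tiny maps, toy models and small ensembles.

# deterministic random map
toy_map <- function(dim = c(8, 8, 8), voxel = 1, origin = c(0, 0, 0),
                    seed = 42) {
  set.seed(seed)
  density_map(array(stats::runif(prod(dim)), dim), voxel, origin)
}

# a compact 3-atom carbon model
toy_triatom <- function() {
  atomic_model(data.frame(
    chain = "A", resno = 1:3, insert = "", resid = "ALA",
    elety = c("N", "CA", "C"), elesy = c("N", "C", "C"),
    x = c(0, 1.5, 2.2), y = c(0, 0.4, 1.8), z = c(0, 0.2, 0.5),
    weight = 1))
}

# single-atom model at a position
toy_atom <- function(pos = c(0, 0, 0), elesy = "C") {
  atomic_model(data.frame(
    chain = "A", resno = 1, insert = "", resid = "ALA", elety = "CA",
    elesy = elesy, x = pos[1], y = pos[2], z = pos[3], weight = 1))
}

# random proper rotation from a seed
toy_rotation <- function(seed = 1) {
  set.seed(seed)
  quat_to_matrix(stats::rnorm(4))
}

# small fit records with given scores/transforms for clustering tests
toy_fit <- function(R = diag(3), t = c(0, 0, 0), score = 1) {
  list(transform = rigid_transform(R, t), score = score)
}

# independent R-level brute-force oracles -----------------------------------

# O(n^2) chamfer
chamfer_brute <- function(pa, pb) {
  d <- sqrt(outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb))
  d[d < 0 | is.nan(d)] <- 0
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

# explicit triple-loop surface scan (boundary counts as outside)
surface_brute <- function(mask) {
  d <- dim(mask)
  out <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    nb <- list(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
               c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    expose <- any(vapply(nb, function(q) {
      any(q < 1) || q[1] > d[1] || q[2] > d[2] || q[3] > d[3] ||
        !mask[q[1], q[2], q[3]]
    }, logical(1)))
    if (expose) out <- rbind(out, c(i, j, k))
  }
  out
}

# independent greedy clustering oracle
cluster_brute <- function(fits, rot_deg, trans, centroid = c(0, 0, 0)) {
  ord <- order(vapply(fits, function(f) f$score, numeric(1)),
               decreasing = TRUE)
  reps <- list()
  for (i in ord) {
    f <- fits[[i]]
    ci <- as.numeric(f$transform$rotation %*% centroid) +
      f$transform$translation
    placed <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[[k]]
      ck <- as.numeric(r$transform$rotation %*% centroid) +
        r$transform$translation
      ang <- rotation_between(r$transform$rotation, f$transform$rotation)
      if (ang <= rot_deg * pi / 180 && sqrt(sum((ci - ck)^2)) <= trans) {
        reps[[k]]$cluster_size <- r$cluster_size + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      f$cluster_size <- 1L
      reps[[length(reps) + 1]] <- f
    }
  }
  reps
}

# a small synthetic crosslink table written to a temp file
toy_xlink_file <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "protein1\tresidue1\tprotein2\tresidue2\tld score\tlink type",
    "bodyA\t1\tbodyA\t5\t50\tintra",
    "bodyA\t2\tbodyB\t3\t45\tinter",
    "bodyA\t4\t\t\t41\tmonolink",
    "bodyB\t2\tbodyB\t6\t39\tintra",
    "bodyA\tK-\tbodyB\t2\t55\tinter"), path)
  path
}
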