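# Crosslink table ingestion, filtering, mapping and satisfaction.

test_that("tables parse with row-level rejection of bad residues", {
  p <- toy_xlink_file()
  expect_warning(links <- read_xlink_table(p), "rejected")
  expect_equal(nrow(links), 4)   # 5 parseable rows, 1 rejected ("K-")
  expect_equal(attr(links, "rejected")$row, 5)
  expect_equal(links$link_type, c("intra", "inter", "monolink", "intra"))
  # round trip preserves all fields
  p2 <- tempfile(fileext = ".tsv")
  write_xlink_table(links, p2)
  back <- read_xlink_table(p2)
  expect_equal(as.data.frame(back)[, 1:6], as.data.frame(links)[, 1:6],
               ignore_attr = TRUE)
  # a missing mandatory column is named
  p3 <- tempfile(fileext = ".tsv")
  writeLines(c("protein1\tresidue1\tprotein2\tresidue2",
               "a\t1\tb\t2"), p3)
  expect_error(read_xlink_table(p3), "ldscore")
})

test_that("ld filtering is inclusive at the threshold", {
  links <- data.frame(protein1 = "a", residue1 = 1:5, protein2 = "a",
                      residue2 = 11:15, ld_score = c(35, 39, 40, 45, 50),
                      link_type = "intra")
  class(links) <- c("xlink_table", "data.frame")
  expect_equal(nrow(filter_crosslinks(links, 40)), 3)
  expect_equal(nrow(filter_crosslinks(links, -Inf)), 5)
})

test_that("mapping computes Euclidean CA distances and violation flags", {
  model <- atomic_model(data.frame(
    chain = "A", resno = 1:2, insert = "", resid = "LYS", elety = "CA",
    elesy = "C", x = c(0, 3), y = c(0, 4), z = c(0, 0), weight = 1))
  links <- data.frame(protein1 = "p", residue1 = 1, protein2 = "p",
                      residue2 = 2, ld_score = 50, link_type = "intra")
  class(links) <- c("xlink_table", "data.frame")
  cfg <- xlink_config(40, 35, c(p = "A"))
  res <- map_crosslinks(model, links, cfg)
  expect_equal(res$per_link$distance, 5)        # 3-4-5 triangle
  expect_false(res$per_link$violated)
  # a link to an absent residue is unmappable, not dropped
  links2 <- rbind(links, data.frame(protein1 = "p", residue1 = 1,
                                    protein2 = "p", residue2 = 99,
                                    ld_score = 44, link_type = "intra"))
  class(links2) <- c("xlink_table", "data.frame")
  res2 <- map_crosslinks(model, links2, cfg)
  expect_equal(res2$totals$n_mapped, 1)
  expect_equal(nrow(res2$per_link), 2)
  # unmapped protein name likewise
  links3 <- links
  links3$protein2 <- "unknown"
  res3 <- map_crosslinks(model, links3, cfg)
  expect_equal(res3$totals$n_mapped, 0)
})

test_that("planted links are recovered exactly on the generated case", {
  case <- make_two_body_case(synthetic_params(seed = 11))
  assembly <- atomic_model(rbind(
    apply_transform(case$bodyA, case$truthA)$atoms,
    apply_transform(case$bodyB, case$truthB)$atoms))
  cfg <- xlink_config(40, 35, synthetic_chain_map())
  res <- map_crosslinks(assembly, case$xlinks, cfg)
  expect_equal(res$totals$n_mapped,
               case$params$n_satisfied + case$params$n_violated)
  expect_equal(res$totals$n_violated, case$params$n_violated)
  # brute-force recomputation of each distance
  ca <- assembly$atoms[trimws(assembly$atoms$elety) == "CA", ]
  for (i in which(res$per_link$mappable)) {
    l <- res$per_link[i, ]
    p1 <- ca[ca$chain == substr(l$protein1, 5, 5) & ca$resno == l$residue1,
             c("x", "y", "z")]
    p2 <- ca[ca$chain == substr(l$protein2, 5, 5) & ca$resno == l$residue2,
             c("x", "y", "z")]
    expect_equal(l$distance, sqrt(sum((p1 - p2)^2)), tolerance = 1e-9)
  }
  expect_equal(satisfaction_fraction(res),
               case$params$n_satisfied /
                 (case$params$n_satisfied + case$params$n_violated))
})

test_that("satisfaction spans 0 to 1 and errors with nothing mappable", {
  model <- atomic_model(data.frame(
    chain = "A", resno = 1:2, insert = "", resid = "LYS", elety = "CA",
    elesy = "C", x = c(0, 100), y = 0, z = 0, weight = 1))
  links <- data.frame(protein1 = "p", residue1 = 1, protein2 = "p",
                      residue2 = 2, ld_score = 50, link_type = "intra")
  class(links) <- c("xlink_table", "data.frame")
  cfg <- xlink_config(40, 35, c(p = "A"))
  expect_equal(satisfaction_fraction(model, links, cfg), 0)  # 100 A: violated
  model$atoms$x[2] <- 10
  expect_equal(satisfaction_fraction(model, links, cfg), 1)
  cfg_none <- xlink_config(40, 35, c())
  expect_error(satisfaction_fraction(model, links, cfg_none), "mappable")
})

test_that("totals inequalities and filter/map commutativity hold on random tables", {
  model <- make_toy_chain(40, seed = 30)
  cfg <- xlink_config(40, 20, c(toy = "A"))
  set.seed(31)
  for (rep in 1:8) {
    k <- sample(5:25, 1)
    links <- data.frame(
      protein1 = "toy", residue1 = sample(60, k, replace = TRUE),
      protein2 = sample(c("toy", "other"), k, replace = TRUE),
      residue2 = sample(60, k, replace = TRUE),
      ld_score = round(runif(k, 20, 60), 1),
      link_type = "intra")
    links$link_type <- ifelse(links$protein1 == links$protein2, "intra",
                              "inter")
    class(links) <- c("xlink_table", "data.frame")
    res <- map_crosslinks(model, links, cfg)
    t <- res$totals
    expect_lte(t$n_violated, t$n_mapped)
    expect_lte(t$n_mapped, t$n_pass_filter)
    expect_lte(t$n_pass_filter, t$n_input)
    # filter then map == map the pre-filtered table
    pre <- map_crosslinks(model, filter_crosslinks(links, 40), cfg)
    expect_equal(pre$totals$n_mapped, t$n_mapped)
    expect_equal(pre$totals$n_violated, t$n_violated)
  }
})

test_that("mapping is rigid-invariant; moving one body changes only inter links", {
  case <- make_two_body_case(synthetic_params(seed = 12))
  cfg <- xlink_config(40, 35, synthetic_chain_map())
  asm <- function(trA, trB) atomic_model(rbind(
    apply_transform(case$bodyA, trA)$atoms,
    apply_transform(case$bodyB, trB)$atoms))
  base <- map_crosslinks(asm(case$truthA, case$truthB), case$xlinks, cfg)
  glob <- rigid_transform(toy_rotation(5), c(10, -4, 2))
  moved <- map_crosslinks(asm(transform_compose(glob, case$truthA),
                              transform_compose(glob, case$truthB)),
                          case$xlinks, cfg)
  expect_equal(moved$per_link$distance, base$per_link$distance,
               tolerance = 1e-9)
  # shift only body B: intra distances unchanged, inter distances not all
  shifted <- map_crosslinks(asm(case$truthA,
                                transform_compose(
                                  rigid_transform(diag(3), c(25, 0, 0)),
                                  case$truthB)),
                            case$xlinks, cfg)
  intra <- base$per_link$link_type == "intra" & base$per_link$mappable
  inter <- base$per_link$link_type == "inter" & base$per_link$mappable
  expect_equal(shifted$per_link$distance[intra],
               base$per_link$distance[intra], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(shifted$per_link$distance[inter],
                                base$per_link$distance[inter])))
})
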