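test_that("coordination counting uses polar protein atoms and a closed ball", {
  w <- c(0, 0, 0)
  frags <- dplyr::bind_rows(
    aquabridge:::acceptor_fragment(c(2.73, 0, 0), c(-1, 0, 0), "A", 1L),
    aquabridge:::acceptor_fragment(c(0, 2.73, 0), c(0, -1, 0), "A", 5L),
    aquabridge:::acceptor_fragment(c(0, 0, 2.99), c(0, 0, -1), "A", 9L),  # boundary
    aquabridge:::acceptor_fragment(c(0, 0, -3.2), c(0, 0, 1), "A", 13L))  # outside
  s <- as_structure(frags)
  expect_equal(coordination_count(w, s), 3L)       # 2.99 included, 3.2 not
  expect_equal(coordination_count(c(50, 50, 50), s), 0L)
  # ligand atoms do not count as coordinating protein atoms
  lig <- frags
  lig$is_ligand <- TRUE
  expect_equal(coordination_count(w, as_structure(lig)), 0L)
})

test_that("central-water deviation is the brute-force minimum", {
  expect_equal(central_water_deviation(rbind(c(0, 0, 1), c(0, 0, 3)),
                                       c(0, 0, 0)), 1)
  expect_equal(central_water_deviation(rbind(c(0, 0, 0)), c(0, 0, 0)), 0)
  expect_true(is.na(central_water_deviation(matrix(numeric(0), 0, 3),
                                            c(0, 0, 0))))
  set.seed(77)
  for (k in 1:20) {
    pred <- matrix(runif(30, -5, 5), ncol = 3)
    ctr <- runif(3, -5, 5)
    oracle <- min(apply(pred, 1, function(p) sqrt(sum((p - ctr)^2))))
    expect_equal(central_water_deviation(pred, ctr), oracle)
  }
})

test_that("recovery rates count no-predictions as failures and are monotone", {
  expect_equal(recovery_rate(c(0, 0, 0))$recovery_percent, 100)
  expect_equal(recovery_rate(c(0.5, 1.5), cutoff = 1.4)$recovery_percent, 50)
  expect_equal(recovery_rate(c(0.5, NA), cutoff = 1.4)$recovery_percent, 50)
  set.seed(5)
  devs <- c(abs(rnorm(40, 0.8, 0.6)), rep(NA, 5))
  curve <- recovery_rate(devs, cutoff = seq(0.1, 2.5, by = 0.1))
  expect_true(all(diff(curve$recovery_percent) >= 0))
})

test_that("water-mesh matching is unique, bordered and correctly scored", {
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  m0 <- match_waters(ref, ref, cutoff = 1.4)
  expect_equal(m0$tp_percent, 100)
  expect_equal(m0$fp_percent, 0)
  expect_equal(m0$fn_percent, 0)
  # two predictions near one reference: single match at the shorter distance
  pred <- rbind(c(0.3, 0, 0), c(-0.5, 0, 0))
  m1 <- match_waters(pred, rbind(c(0, 0, 0)), cutoff = 1.4)
  expect_equal(nrow(m1$pairs), 1)
  expect_equal(m1$pairs$deviation, 0.3)
  expect_equal(m1$tp_percent, 50)
  expect_equal(m1$fp_percent, 50)
  expect_equal(m1$fn_percent, 0)
  expect_equal(m1$tp_percent + m1$fp_percent, 100)
  # border filtering removes distant waters from both sets
  m2 <- match_waters(rbind(c(0, 0, 0), c(10, 0, 0)),
                     rbind(c(0, 0, 0), c(11, 0, 0)),
                     cutoff = 1.4, border_center = c(0, 0, 0), border_radius = 6)
  expect_equal(m2$n_predicted, 1)
  expect_equal(m2$n_reference, 1)
  # swapping the two sets swaps the FN role and keeps pair deviations
  a <- matrix(runif(15, 0, 5), ncol = 3)
  b <- matrix(runif(12, 0, 5), ncol = 3)
  mab <- match_waters(a, b, cutoff = 2)
  mba <- match_waters(b, a, cutoff = 2)
  expect_equal(sort(mab$pairs$deviation), sort(mba$pairs$deviation))
  expect_equal(nrow(mab$pairs), nrow(mba$pairs))
})

test_that("greedy matching never beats the maximum matching and usually ties", {
  skip_if_not_installed("igraph")
  # waters in a mesh cannot overlap: sample sets with 2.4 A min separation
  sample_mesh <- function(n, box = 8) {
    pts <- matrix(numeric(0), 0, 3)
    while (nrow(pts) < n) {
      p <- runif(3, 0, box)
      if (!nrow(pts) || min(aquabridge:::dist_to_point(pts, p)) > 2.4)
        pts <- rbind(pts, p)
    }
    pts
  }
  set.seed(99)
  ties <- 0; n_inst <- 60
  for (k in seq_len(n_inst)) {
    pred <- sample_mesh(10)
    ref <- sample_mesh(10)
    g <- match_waters(pred, ref, cutoff = 1.5, method = "greedy")
    o <- match_waters(pred, ref, cutoff = 1.5, method = "optimal")
    expect_lte(nrow(g$pairs), nrow(o$pairs))
    if (nrow(g$pairs) == nrow(o$pairs)) ties <- ties + 1
  }
  expect_gte(ties / n_inst, 0.95)
})

test_that("chi-1 recovery uses circular arithmetic and a strict tolerance", {
  set.seed(13)
  a <- dplyr::bind_rows(
    aquabridge:::ideal_residue("SER", c(0, 0, 0), "A", 1L, chi = c(64)),
    aquabridge:::ideal_residue("LEU", c(20, 0, 0), "A", 2L, chi = c(-65, 175)))
  s <- as_structure(a)
  expect_equal(chi1_recovery(s, s)$percent, 100)
  # wrap-around: -179 vs +179 is a 2-degree deviation
  set.seed(14)
  r1 <- aquabridge:::ideal_residue("SER", c(0, 0, 0), "A", 1L, chi = c(-179))
  set.seed(14)
  r2 <- aquabridge:::ideal_residue("SER", c(0, 0, 0), "A", 1L, chi = c(179))
  expect_equal(chi1_recovery(as_structure(r1), as_structure(r2))$percent, 100)
  # a deviation of exactly the tolerance does not count (strict less-than)
  set.seed(15)
  m1 <- aquabridge:::ideal_residue("SER", c(0, 0, 0), "A", 1L, chi = c(60))
  set.seed(15)
  m2 <- aquabridge:::ideal_residue("SER", c(0, 0, 0), "A", 1L, chi = c(80))
  expect_equal(chi1_recovery(as_structure(m1), as_structure(m2))$percent, 0)
  # alanine/glycine and unpaired residues stay out of the denominator
  ala <- aquabridge:::ideal_residue("ALA", c(40, 0, 0), "A", 3L)
  both <- as_structure(dplyr::bind_rows(a, ala))
  expect_equal(chi1_recovery(both, s)$n_evaluated, 2)
})

test_that("side-chain RMSD excludes backbone/CB and honours ring symmetry", {
  set.seed(21)
  phe <- aquabridge:::ideal_residue("PHE", c(0, 0, 0), "A", 1L, chi = c(-65, 90))
  s <- as_structure(phe)
  expect_equal(sidechain_rmsd(s, s)$rmsd, 0)
  # flipping the ring by 180 degrees in chi2 is chemically identical
  set.seed(21)
  phe_flip <- aquabridge:::ideal_residue("PHE", c(0, 0, 0), "A", 1L,
                                         chi = c(-65, 90 + 180))
  r <- sidechain_rmsd(as_structure(phe_flip), s)
  expect_lt(r$rmsd, 0.02)   # template ring is idealised, not exactly 2-fold
  # a single displaced OG gives exactly its displacement
  set.seed(22)
  ser <- aquabridge:::ideal_residue("SER", c(10, 0, 0), "A", 2L, chi = c(64))
  ser_shift <- ser
  ser_shift[ser_shift$name == "OG", c("x")] <-
    ser_shift[ser_shift$name == "OG", ]$x + 1
  r2 <- sidechain_rmsd(as_structure(ser_shift), as_structure(ser))
  expect_equal(r2$rmsd, 1, tolerance = 1e-12)
  expect_equal(r2$n_atoms, 1)
  # main chain and CB displacements are invisible to the metric
  ser_bb <- ser
  bbsel <- ser_bb$name %in% c("N", "CA", "C", "O", "CB")
  ser_bb$x[bbsel] <- ser_bb$x[bbsel] + 5
  expect_equal(sidechain_rmsd(as_structure(ser_bb),
                              as_structure(ser))$rmsd, 0)
})

test_that("per-sphere evaluation bundles all metrics coherently", {
  sp <- make_sphere_fixture(fixture_spec(seed = 31, n_bridges = 2,
                                         decoy_atoms = 5))
  # rebuilding with the reference itself gives a perfect row
  row <- evaluate_sphere(sp, sp$atoms)
  expect_equal(row$central_deviation, 0)
  expect_equal(row$tp_percent, 100)
  expect_equal(row$fn_percent, 0)
  expect_equal(row$rmsd, 0)
  # a water-free model records a missing prediction and full FN
  dry <- sp$atoms[!sp$atoms$is_water, ]
  row2 <- evaluate_sphere(sp, dry)
  expect_true(row2$no_prediction)
  expect_equal(row2$fn_percent, 100)
  agg <- aggregate_spheres(dplyr::bind_rows(row, row))
  expect_equal(agg$recovery_percent, 100)
  expect_equal(agg$n_spheres, 2)
})
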