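test_that("rotamer enumeration matches the library and chi1 expansion", {
  set.seed(5)
  ala <- aquabridge:::ideal_residue("ALA", c(0, 0, 0), "A", 1L)
  s <- as_structure(ala)
  expect_length(enumerate_rotamers(s, "A", 1L, "ALA"), 1)
  gly <- ala[ala$name %in% c("N", "CA", "C", "O"), ]
  gly$resname <- "GLY"
  sg <- as_structure(gly)
  rg <- enumerate_rotamers(sg, "A", 1L, "GLY")
  expect_length(rg, 1)
  expect_false("CB" %in% rg[[1]]$atoms$name)
  lib <- aquabridge:::rotamer_library()
  n_ser <- sum(lib$resname == "SER")
  expect_length(enumerate_rotamers(s, "A", 1L, "SER"), n_ser)
  expect_length(enumerate_rotamers(s, "A", 1L, "SER", expand_chi1 = TRUE),
                3 * n_ser)
  expect_error(enumerate_rotamers(s, "A", 1L, "XXX"), "not in")
  # built rotamers reproduce their library chi angles
  rots <- enumerate_rotamers(s, "A", 1L, "LEU")
  for (r in rots) {
    expect_equal(measure_chi1(r$atoms, "A", 1L), r$chi[1], tolerance = 1e-6)
  }
})

test_that("pairwise energy: cutoff, steric repulsion and symmetry", {
  set.seed(11)
  a1 <- aquabridge:::ideal_residue("SER", c(0, 0, 0), "A", 1L, chi = c(64))
  a2_far <- aquabridge:::ideal_residue("SER", c(40, 0, 0), "A", 5L, chi = c(64))
  mk_rot <- function(at) {
    structure(list(chain = at$chain[1], resno = at$resno[1],
                   resname = at$resname[1], chi = c(64), freq = 0.5,
                   atoms = as_structure(at), waters = aquabridge:::empty_placements(),
                   bridge_ids = character(0)), class = "aqua_rotamer")
  }
  r1 <- mk_rot(a1); r_far <- mk_rot(a2_far)
  expect_equal(pairwise_energy(r1, r_far), 0)
  # steric overlap: large positive
  a2_close <- a1
  a2_close$resno <- 5L
  a2_close$x <- a2_close$x + 1.0
  r_close <- mk_rot(a2_close)
  expect_gt(pairwise_energy(r1, r_close), 10)
  set.seed(12)
  a2_mid <- aquabridge:::ideal_residue("SER", c(6, 1, 0), "A", 5L, chi = c(-65))
  r_mid <- mk_rot(a2_mid)
  expect_equal(pairwise_energy(r1, r_mid), pairwise_energy(r_mid, r1))
})

test_that("a planted bridge creates duplicated solvated copies and lowers the energy", {
  pair <- make_bridged_asn_pair()
  pb <- packing_problem(pair$atoms, positions = pair$positions)
  n0 <- vapply(pb$rotamers, length, integer(1))
  pb2 <- suppressWarnings(build_solvated_rotamers(pb))
  n1 <- vapply(pb2$rotamers, length, integer(1))
  # both positions gained solvated copies; originals retained
  expect_true(all(n1 > n0))
  solv1 <- Filter(function(r) nrow(r$waters) > 0, pb2$rotamers[[1]])
  solv2 <- Filter(function(r) nrow(r$waters) > 0, pb2$rotamers[[2]])
  expect_gt(length(solv1), 0)
  expect_gt(length(solv2), 0)
  # the duplicated copies carry the same bridge id on both sides
  ids1 <- unlist(lapply(solv1, function(r) r$bridge_ids))
  ids2 <- unlist(lapply(solv2, function(r) r$bridge_ids))
  expect_true(length(intersect(ids1, ids2)) > 0)
  # the planted water is recovered on the solvated copies
  dev <- min(vapply(solv1, function(r)
    aquabridge:::vnorm(c(r$waters$ox[1], r$waters$oy[1], r$waters$oz[1]) -
                         pair$water), numeric(1)))
  expect_lt(dev, 0.1)
  # solvated bridge pair scores below the same pair unsolvated
  shared <- intersect(ids1, ids2)[1]
  ra <- solv1[[which(vapply(solv1, function(r) shared %in% r$bridge_ids,
                            logical(1)))[1]]]
  rb <- solv2[[which(vapply(solv2, function(r) shared %in% r$bridge_ids,
                            logical(1)))[1]]]
  ra_dry <- ra; ra_dry$waters <- aquabridge:::empty_placements()
  ra_dry$bridge_ids <- character(0)
  rb_dry <- rb; rb_dry$waters <- aquabridge:::empty_placements()
  rb_dry$bridge_ids <- character(0)
  e_wet <- pairwise_energy(ra, rb, pos_a = 1, pos_b = 2)
  e_dry <- pairwise_energy(ra_dry, rb_dry, pos_a = 1, pos_b = 2)
  expect_lt(e_wet, e_dry)
})

test_that("Goldstein elimination agrees with exhaustive enumeration", {
  for (seed in 1:15) {
    set.seed(seed)
    sizes <- sample(2:5, sample(2:4, 1), replace = TRUE)
    mp <- make_toy_packing(sizes, seed)
    bf <- toy_brute_force(mp$tables, sizes)
    pruned <- dee_goldstein(mp$problem, mp$tables)
    kept <- attr(pruned, "kept")
    # the GMEC rotamer survives at every position
    for (p in seq_along(sizes)) expect_true(bf$assign[p] %in% kept[[p]])
    fit <- mc_simulated_annealing(pruned, seed = seed, n_steps = 1500)
    expect_equal(fit$energy, bf$energy, tolerance = 1e-9)
  }
  # singleton positions are left untouched
  mp1 <- make_toy_packing(c(1, 1), 99)
  pr <- dee_goldstein(mp1$problem, mp1$tables)
  expect_equal(vapply(pr$rotamers, length, integer(1)), c(1L, 1L))
  fit1 <- mc_simulated_annealing(pr, seed = 1)
  expect_equal(fit1$assignment, c(1L, 1L))
})

test_that("simulated annealing is reproducible for a given seed", {
  pair <- make_bridged_asn_pair()
  pb <- packing_problem(pair$atoms, positions = pair$positions)
  pb <- suppressWarnings(build_solvated_rotamers(pb))
  pb <- dee_goldstein(pb)
  f1 <- mc_simulated_annealing(pb, seed = 42)
  f2 <- mc_simulated_annealing(pb, seed = 42)
  expect_identical(f1$assignment, f2$assignment)
  expect_identical(f1$energy, f2$energy)
})

test_that("adding solvated copies never raises the GMEC energy", {
  pair <- make_bridged_asn_pair()
  pb_dry <- packing_problem(pair$atoms, positions = pair$positions)
  t_dry <- aquabridge:::energy_tables(pb_dry)
  sizes_dry <- vapply(pb_dry$rotamers, length, integer(1))
  grid <- expand.grid(lapply(sizes_dry, seq_len))
  e_dry <- min(apply(grid, 1, function(a)
    aquabridge:::assignment_energy(t_dry, as.integer(a))))
  pb_wet <- suppressWarnings(build_solvated_rotamers(pb_dry))
  t_wet <- aquabridge:::energy_tables(pb_wet)
  sizes_wet <- vapply(pb_wet$rotamers, length, integer(1))
  grid_w <- expand.grid(lapply(sizes_wet, seq_len))
  e_wet <- min(apply(grid_w, 1, function(a)
    aquabridge:::assignment_energy(t_wet, as.integer(a))))
  expect_lte(e_wet, e_dry + 1e-9)
})

test_that("the emitted model collapses duplicated bridges to one water", {
  pair <- make_bridged_asn_pair()
  pb <- packing_problem(pair$atoms, positions = pair$positions)
  pb <- suppressWarnings(build_solvated_rotamers(pb))
  pb <- dee_goldstein(pb)
  fit <- mc_simulated_annealing(pb, seed = 7)
  model <- emit_model(pb, fit$assignment)
  w <- model[model$is_water & model$element == "O", ]
  expect_equal(nrow(w), 1)                     # one physical bridge water
  expect_lt(aquabridge:::vnorm(c(w$x, w$y, w$z) - pair$water), 0.6)
  # waters respect the merge radius in any emitted model
  if (nrow(w) > 1) {
    dd <- as.matrix(stats::dist(as.matrix(w[, c("x", "y", "z")])))
    expect_gt(min(dd[upper.tri(dd)]), pb$params$merge_radius)
  }
  # chosen side chains carry full atom sets
  expect_true(all(c("CG", "OD1", "ND2") %in% model$name[model$resno == 1]))
  # and the planted conformers are recovered
  chi <- chi1_recovery(model, pair$atoms)
  expect_equal(chi$percent, 100)
})

test_that("water-free packing gives a water-free model", {
  pair <- make_bridged_asn_pair()
  prep <- pair$atoms
  attr(prep, "design_positions") <- pair$positions
  run6 <- resolve_preset("run6")
  model <- suppressWarnings(rebuild_model(prep, run6))
  expect_equal(sum(model$is_water), 0)
  run61 <- resolve_preset("run6.1")
  model2 <- suppressWarnings(rebuild_model(prep, run61))
  expect_gte(sum(model2$is_water & model2$element == "O"), 1)
})
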