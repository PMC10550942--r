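fake_site <- function(pos, role = "acceptor", element = "O", resno = 1L) {
  tibble::tibble(
    site_id = resno, atom_idx = resno, element = element, name = "O",
    resname = "GLY", chain = "A", resno = resno,
    x = pos[1], y = pos[2], z = pos[3], role = role, hyb = "sp2",
    ideal_d = if (element == "N") 2.87 else 2.73,
    hydrogens = list(matrix(numeric(0), 0, 3)),
    donor_vecs = list(matrix(numeric(0), 0, 3)),
    acceptor_vecs = list(matrix(numeric(0), 0, 3)))
}

test_that("pair eligibility uses the strict-inequality distance window", {
  p <- geometry_params()
  s0 <- fake_site(c(0, 0, 0))
  expect_true(pair_eligible(s0, fake_site(c(4.61, 0, 0), resno = 2L), p))
  expect_false(pair_eligible(s0, fake_site(c(3.65, 0, 0), resno = 2L), p))
  expect_false(pair_eligible(s0, fake_site(c(5.57, 0, 0), resno = 2L), p))
  ps <- geometry_params(strict = TRUE)
  expect_true(pair_eligible(s0, fake_site(c(5.00, 0, 0), resno = 2L), ps))
  expect_false(pair_eligible(s0, fake_site(c(5.20, 0, 0), resno = 2L), ps))
  # same residue never pairs
  expect_false(pair_eligible(s0, fake_site(c(4.61, 0, 0), resno = 1L), p))
})

test_that("the bridge circle satisfies both sphere equations (Heron)", {
  # numeric two-sphere oracle: r from the intersection of the spheres
  oracle_r <- function(d, di, dj) {
    h <- (d^2 + di^2 - dj^2) / (2 * d)   # distance from Xi to circle centre
    sqrt(di^2 - h^2)
  }
  bc <- bridge_circle(c(0, 0, 0), c(4.61, 0, 0), 2.73, 2.73)
  expect_equal(bc$center, c(2.305, 0, 0), tolerance = 1e-12)
  expect_equal(bc$radius, oracle_r(4.61, 2.73, 2.73), tolerance = 1e-12)
  bc2 <- bridge_circle(c(0, 0, 0), c(4.61, 0, 0), 2.73, 2.87)
  expect_equal(bc2$center[1], (4.61^2 + 2.73^2 - 2.87^2) / (2 * 4.61),
               tolerance = 1e-12)
  expect_equal(bc2$radius, oracle_r(4.61, 2.73, 2.87), tolerance = 1e-12)
  # every sampled perimeter point is at the ideal distances
  e1 <- aquabridge:::any_perp(bc2$normal)
  e2 <- aquabridge:::vcross(bc2$normal, e1)
  for (a in seq(0, 2 * pi, length.out = 13)) {
    p <- bc2$center + bc2$radius * (cos(a) * e1 + sin(a) * e2)
    expect_equal(aquabridge:::vnorm(p - c(0, 0, 0)), 2.73, tolerance = 1e-9)
    expect_equal(aquabridge:::vnorm(p - c(4.61, 0, 0)), 2.87, tolerance = 1e-9)
  }
  # degenerate tangency and the error case
  bc3 <- bridge_circle(c(0, 0, 0), c(5.46, 0, 0), 2.73, 2.73)
  expect_equal(bc3$radius, 0)
  expect_equal(bc3$center, c(2.73, 0, 0))
  expect_error(bridge_circle(c(0, 0, 0), c(6, 0, 0), 2.73, 2.73),
               "no bridging water geometry")
})

test_that("closest-approach midpoint matches direct minimisation", {
  m <- closest_approach_midpoint(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1), c(0, 1, 0))
  expect_equal(as.numeric(m), c(0, 0, 0.5))
  expect_false(attr(m, "parallel"))
  # intersecting lines meet at the intersection
  m2 <- closest_approach_midpoint(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0))
  expect_equal(as.numeric(m2), c(0, 0, 0), tolerance = 1e-12)
  # parallel fallback is flagged and lands midway
  m3 <- closest_approach_midpoint(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(1, 0, 0))
  expect_true(attr(m3, "parallel"))
  expect_equal(as.numeric(m3)[3], 0.5)
  # random instances against a brute-force grid minimiser
  set.seed(31)
  for (k in 1:25) {
    p1 <- runif(3, -3, 3); p2 <- runif(3, -3, 3)
    o1 <- aquabridge:::rand_unit(); o2 <- aquabridge:::rand_unit()
    if (abs(sum(o1 * o2)) > 0.99) next
    m <- closest_approach_midpoint(p1, o1, p2, o2)
    tg <- seq(-10, 10, by = 0.01)
    # oracle: best t1 on a grid, with the optimal t2 solved in closed form
    f <- vapply(tg, function(t1) {
      a <- p1 + t1 * o1
      t2 <- sum((a - p2) * o2)
      sum((a - (p2 + t2 * o2))^2)
    }, numeric(1))
    t1_star <- tg[which.min(f)]
    a <- p1 + t1_star * o1
    t2_star <- sum((a - p2) * o2)
    m_oracle <- (a + p2 + t2_star * o2) / 2
    expect_equal(as.numeric(m), m_oracle, tolerance = 0.02)
  }
})

test_that("oxygen placement is the nearest perimeter point (grid oracle)", {
  set.seed(17)
  worst <- 0
  for (k in 1:200) {
    sp <- random_site_pair()
    bc <- bridge_circle(sp$xi, sp$xj, sp$d_i, sp$d_j)
    mid <- runif(3, -6, 6)
    o <- place_water_oxygen(bc, mid)
    e1 <- aquabridge:::any_perp(bc$normal)
    e2 <- aquabridge:::vcross(bc$normal, e1)
    th <- seq(0, 2 * pi, length.out = 72001)[-72001]
    per <- cbind(bc$center[1] + bc$radius * (cos(th) * e1[1] + sin(th) * e2[1]),
                 bc$center[2] + bc$radius * (cos(th) * e1[2] + sin(th) * e2[2]),
                 bc$center[3] + bc$radius * (cos(th) * e1[3] + sin(th) * e2[3]))
    dist_mid <- sqrt((per[, 1] - mid[1])^2 + (per[, 2] - mid[2])^2 +
                       (per[, 3] - mid[3])^2)
    o_oracle <- per[which.min(dist_mid), ]
    worst <- max(worst, aquabridge:::vnorm(o - o_oracle))
  }
  expect_lt(worst, 1e-3)
})

test_that("degenerate oxygen placements are handled deterministically", {
  bc0 <- bridge_circle(c(0, 0, 0), c(5.46, 0, 0), 2.73, 2.73)
  expect_equal(place_water_oxygen(bc0, c(9, 9, 9)), bc0$center)  # r = 0
  bc <- bridge_circle(c(0, 0, 0), c(4.61, 0, 0), 2.73, 2.73)
  # midpoint in-plane at 2r keeps its azimuth
  e1 <- aquabridge:::any_perp(bc$normal)
  o <- place_water_oxygen(bc, bc$center + 2 * bc$radius * e1)
  expect_equal(o, bc$center + bc$radius * e1, tolerance = 1e-9)
  # projection exactly on the centre: fixed in-plane axis fallback
  o2 <- place_water_oxygen(bc, bc$center + 1.5 * bc$normal)
  expect_equal(aquabridge:::vnorm(o2 - bc$center), bc$radius, tolerance = 1e-9)
})

test_that("hydrogen orientation honours roles and emits the right variants", {
  p <- geometry_params()
  # two acceptors, symmetric: equal angular deviations for both hydrogens
  o <- c(0, 0, 0)
  si <- fake_site(c(2.73 * cos(1), 2.73 * sin(1), 0), resno = 1L)
  sj <- fake_site(c(2.73 * cos(1), -2.73 * sin(1), 0), resno = 2L)
  pl <- orient_hydrogens(o, si, sj, p)
  expect_equal(nrow(pl), 1)
  h <- pl$hydrogens[[1]]
  d1 <- aquabridge:::vangle(h[1, ] - o, c(si$x, si$y, si$z) - o)
  d2 <- aquabridge:::vangle(h[2, ] - o, c(sj$x, sj$y, sj$z) - o)
  expect_equal(d1, d2, tolerance = 1e-9)
  # two donors: hydrogens point away from both partners
  di <- fake_site(c(2.87, 0, 0), role = "donor", element = "N", resno = 1L)
  dj <- fake_site(c(-1.4, 2.5, 0), role = "donor", element = "N", resno = 2L)
  pl2 <- orient_hydrogens(o, di, dj, p)
  expect_equal(nrow(pl2), 1)
  h2 <- pl2$hydrogens[[1]]
  for (r in 1:2) for (s in list(di, dj)) {
    expect_gt(aquabridge:::vangle(h2[r, ] - o, c(s$x, s$y, s$z) - o), 90)
  }
  # mixed donor/acceptor: exactly two variants
  pl3 <- orient_hydrogens(o, di, sj, p)
  expect_equal(nrow(pl3), 2)
  # dual-role plus acceptor: also two variants
  bi <- fake_site(c(2.73, 0, 0), role = "both", resno = 1L)
  pl4 <- orient_hydrogens(o, bi, sj, p)
  expect_equal(nrow(pl4), 2)
  # every variant satisfies rigid water geometry
  for (pl_all in list(pl, pl2, pl3, pl4)) {
    for (r in seq_len(nrow(pl_all))) {
      hh <- pl_all$hydrogens[[r]]
      expect_equal(aquabridge:::vnorm(hh[1, ] - o), 0.96, tolerance = 1e-6)
      expect_equal(aquabridge:::vnorm(hh[2, ] - o), 0.96, tolerance = 1e-6)
      expect_equal(aquabridge:::vangle(hh[1, ] - o, hh[2, ] - o), 104.45,
                   tolerance = 1e-4)
    }
  }
})

test_that("construction is exact and symmetric on random eligible pairs", {
  set.seed(23)
  for (k in 1:100) {
    sp <- random_site_pair()
    bc <- bridge_circle(sp$xi, sp$xj, sp$d_i, sp$d_j)
    mid <- runif(3, -6, 6)
    o1 <- place_water_oxygen(bc, mid)
    expect_equal(aquabridge:::vnorm(o1 - sp$xi), sp$d_i, tolerance = 1e-6)
    expect_equal(aquabridge:::vnorm(o1 - sp$xj), sp$d_j, tolerance = 1e-6)
    # swapping the sites leaves the oxygen position unchanged
    bc_swap <- bridge_circle(sp$xj, sp$xi, sp$d_j, sp$d_i)
    o2 <- place_water_oxygen(bc_swap, mid)
    expect_equal(o1, o2, tolerance = 1e-9)
  }
})

test_that("posterior solvation recovers planted waters and respects the window", {
  fx <- make_bridge_fixture(fixture_spec(seed = 41, n_bridges = 4, decoy_atoms = 6))
  w <- suppressWarnings(solvate_structure(fx$atoms))
  expect_equal(nrow(w), 4)
  for (b in seq_len(nrow(fx$waters))) {
    d <- min(aquabridge:::dist_to_point(
      as.matrix(w[, c("ox", "oy", "oz")]),
      c(fx$waters$ox[b], fx$waters$oy[b], fx$waters$oz[b])))
    expect_lt(d, 0.05)
  }
  # no two emitted waters within the merge radius
  if (nrow(w) > 1) {
    xyz <- as.matrix(w[, c("ox", "oy", "oz")])
    dd <- as.matrix(stats::dist(xyz))
    expect_gt(min(dd[upper.tri(dd)]), geometry_params()$merge_radius)
  }
  # a pair beyond the window yields nothing
  far <- as_structure(dplyr::bind_rows(
    aquabridge:::acceptor_fragment(c(0, 0, 0), c(1, 0, 0), "A", 1L),
    aquabridge:::acceptor_fragment(c(6, 0, 0), c(-1, 0, 0), "A", 5L)))
  expect_equal(nrow(suppressWarnings(solvate_structure(far))), 0)
})

test_that("a rotamer-ligand bridge attaches the water to the rotamer only", {
  pair <- make_bridged_asn_pair()
  atoms <- pair$atoms
  # replace residue 5 by a fixed ligand carbonyl aimed at the same water
  asn1 <- atoms[atoms$resno == 1, ]
  lig_o <- pair$water + 2.73 * aquabridge:::unitv(
    c(atoms$x[atoms$resno == 5 & atoms$name == "ND2"][1],
      atoms$y[atoms$resno == 5 & atoms$name == "ND2"][1],
      atoms$z[atoms$resno == 5 & atoms$name == "ND2"][1]) - pair$water)
  lig <- aquabridge:::acceptor_fragment(lig_o,
    aquabridge:::unitv(pair$water - lig_o), "L", 50L)
  lig$is_ligand <- TRUE
  ctx <- as_structure(dplyr::bind_rows(asn1, lig))
  pos <- tibble::tibble(chain = "A", resno = 1L, resname = "ASN")
  pb <- packing_problem(ctx, positions = pos)
  pb <- suppressWarnings(build_solvated_rotamers(pb))
  solvated <- Filter(function(r) nrow(r$waters) > 0, pb$rotamers[[1]])
  expect_gt(length(solvated), 0)
  expect_true(all(vapply(solvated, function(r)
    all(is.na(r$waters$partner_pos)), logical(1))))
  dev <- min(vapply(solvated, function(r)
    aquabridge:::vnorm(c(r$waters$ox[1], r$waters$oy[1], r$waters$oz[1]) -
                         pair$water), numeric(1)))
  expect_lt(dev, 0.6)
})
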