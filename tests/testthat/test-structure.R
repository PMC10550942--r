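test_that("PDB reading retains records, flags waters and resolves alt-locs", {
  f <- write_mini_pdb(c(
    pdb_atom_line(1, "N", "ALA", "A", 1, c(1, 2, 3)),
    pdb_atom_line(2, "CA", "ALA", "A", 1, c(2.46, 2, 3), occ = 0.6, alt = "A"),
    pdb_atom_line(3, "CA", "ALA", "A", 1, c(2.40, 2.1, 3), occ = 0.4, alt = "B"),
    pdb_atom_line(4, "C", "ALA", "A", 1, c(3.5, 2.5, 3)),
    pdb_atom_line(5, "O", "HOH", "A", 101, c(5, 5, 5), record = "HETATM"),
    "END"))
  s <- read_structure(f)
  expect_equal(nrow(s), 4)                       # alt-loc B dropped
  ca <- s[s$name == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(ca$occ, 0.6)                      # highest occupancy wins
  expect_true(s$is_water[s$resname == "HOH"])
  expect_false(any(s$is_water[s$resname == "ALA"]))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("write/read round-trip preserves names and coordinates to 3 decimals", {
  fx <- make_bridge_fixture(fixture_spec(seed = 5, n_bridges = 2, decoy_atoms = 3))
  st <- fx$atoms
  attr(st, "cell") <- c(a = 50, b = 60, c = 70, alpha = 90, beta = 90, gamma = 90)
  attr(st, "space_group") <- "P 21 21 21"
  f <- tempfile(fileext = ".pdb")
  write_structure(st, f)
  rd <- read_structure(f)
  expect_equal(nrow(rd), nrow(st))
  expect_equal(rd$name, st$name)
  expect_lt(max(abs(rd$x - st$x), abs(rd$y - st$y), abs(rd$z - st$z)), 5e-4)
  expect_equal(attr(rd, "space_group"), "P 21 21 21")
  expect_equal(unname(attr(rd, "cell")["b"]), 60)
})

test_that("symmetry expansion matches a brute-force lattice oracle in P1", {
  at <- tibble::tibble(name = "CA", element = "C", resname = "GLY",
                       chain = "A", resno = 1L, x = 1, y = 1, z = 1)
  s <- as_structure(at, cell = c(a = 10, b = 10, c = 10,
                                 alpha = 90, beta = 90, gamma = 90),
                    space_group = "P 1")
  ex <- expand_symmetry(s, center = c(1, 1, 1), radius = 20)
  n_oracle <- 0
  for (tx in -2:2) for (ty in -2:2) for (tz in -2:2) {
    if (all(c(tx, ty, tz) == 0)) next
    if (sqrt(sum((10 * c(tx, ty, tz))^2)) <= 20) n_oracle <- n_oracle + 1
  }
  expect_equal(nrow(ex) - 1, n_oracle)
  expect_true(all(ex$sym_op[-1] == 1))
})

test_that("P212121 generates the four published operator images", {
  ops <- aquabridge:::lookup_spacegroup("P 21 21 21")
  expect_length(ops, 4)
  frac <- c(0.1, 0.2, 0.3)
  imgs <- t(sapply(ops, function(op) as.numeric(op$R %*% frac + op$t)))
  # the four equivalent positions of the general site (x, y, z)
  expected <- rbind(c(0.1, 0.2, 0.3), c(-0.1 + 0.5, -0.2, 0.3 + 0.5),
                    c(-0.1, 0.2 + 0.5, -0.3 + 0.5), c(0.1 + 0.5, -0.2 + 0.5, -0.3))
  expect_equal(imgs[order(imgs[, 1]), ], expected[order(expected[, 1]), ],
               tolerance = 1e-12)
  expect_error(aquabridge:::lookup_spacegroup("Q 9"), "unknown space-group")
})

test_that("expansion without cell information is a no-op", {
  at <- as_structure(tibble::tibble(name = "CA", element = "C", resname = "GLY",
                                    chain = "A", resno = 1L, x = 0, y = 0, z = 0))
  expect_identical(nrow(expand_symmetry(at, c(0, 0, 0), 20)), 1L)
})

test_that("sphere extraction uses a closed ball and is order-invariant", {
  set.seed(3)
  n <- 10
  at <- tibble::tibble(
    name = "CA", element = "C", resname = "GLY", chain = "A",
    resno = seq_len(n),
    x = c(runif(4, -5, 5), runif(5, 30, 60), 20),  # 4 near, 5 far, 1 at 20
    y = 0, z = 0)
  at$x[10] <- 20
  wat <- tibble::tibble(name = "O", element = "O", resname = "HOH",
                        chain = "W", resno = 99L, x = 0, y = 0, z = 0)
  s <- as_structure(dplyr::bind_rows(at, wat))
  sp <- extract_sphere(s, c(0, 0, 0), radius = 20)
  expect_equal(nrow(sp$atoms), 4 + 1 + 1)       # near + boundary + central water
  expect_true(20 %in% sp$atoms$x)               # atom at exactly the radius kept
  s_shuffled <- as_structure(s[sample(nrow(s)), ])
  sp2 <- extract_sphere(s_shuffled, c(0, 0, 0), radius = 20)
  expect_setequal(paste(sp2$atoms$resno, sp2$atoms$name),
                  paste(sp$atoms$resno, sp$atoms$name))
  sp0 <- extract_sphere(s, c(0, 0, 0), radius = 0)
  expect_equal(nrow(sp0$atoms), 1)              # only the coincident water
})

test_that("rebuild preparation strips waters and truncates the design region", {
  set.seed(1)
  ser <- aquabridge:::ideal_residue("SER", c(7.0, 0, 0), "A", 3L, chi = c(64))
  gly <- aquabridge:::ideal_residue("SER", c(15, 0, 0), "A", 8L, chi = c(64))
  wat <- tibble::tibble(name = "O", element = "O", resname = "HOH",
                        chain = "W", resno = 99L, x = 0, y = 0, z = 0)
  s <- as_structure(dplyr::bind_rows(ser, gly, wat))
  sp <- extract_sphere(s, c(0, 0, 0), radius = 20, design_radius = 8)
  prep <- prepare_for_rebuild(sp)
  expect_false(any(prep$is_water))
  r3 <- prep[prep$resno == 3, ]
  expect_false("OG" %in% r3$name)               # side chain truncated...
  expect_true("CB" %in% r3$name)                # ...but CB kept (alanine)
  expect_equal(unique(r3$resname), "ALA")
  r8 <- prep[prep$resno == 8, ]                 # fully outside 8 A: untouched
  expect_true("OG" %in% r8$name)
  expect_equal(unique(r8$resname), "SER")
  dp <- attr(prep, "design_positions")
  expect_equal(dp$resname, "SER")
  expect_equal(dp$resno, 3L)
})

test_that("glycine in the design region keeps only its backbone", {
  set.seed(9)
  bb <- aquabridge:::ideal_residue("SER", c(5, 0, 0), "A", 2L, chi = c(64))
  bb$resname <- "GLY"
  bb <- bb[bb$name %in% c("N", "CA", "C", "O"), ]
  wat <- tibble::tibble(name = "O", element = "O", resname = "HOH",
                        chain = "W", resno = 99L, x = 0, y = 0, z = 0)
  sp <- extract_sphere(as_structure(dplyr::bind_rows(bb, wat)), c(0, 0, 0), 20)
  prep <- prepare_for_rebuild(sp)
  expect_setequal(prep$name[prep$resno == 2], c("N", "CA", "C", "O"))
  expect_equal(unique(prep$resname[prep$resno == 2]), "GLY")
})

test_that("ligand pockets are truncated at strictly 6 A and the pose is kept", {
  lig <- tibble::tibble(name = "C1", element = "C", resname = "LIG",
                        chain = "L", resno = 50L, x = 0, y = 0, z = 0,
                        is_ligand = TRUE)
  mk <- function(base, resno) {
    r <- aquabridge:::ideal_residue("SER", base, "A", resno, chi = c(64))
    r
  }
  set.seed(4)
  near <- mk(c(4.2, 0, 0), 1L)                  # some atom < 6 A
  set.seed(5)
  far <- mk(c(11, 0, 0), 2L)                    # min distance > 6 A
  s <- as_structure(dplyr::bind_rows(near, far, lig))
  # the far residue's atoms all stay beyond 6 A of the single ligand atom
  expect_gt(min(aquabridge:::dist_to_point(
    as.matrix(far[, c("x", "y", "z")]), c(0, 0, 0))), 6)
  pocket <- prepare_ligand_pocket(s, "LIG")
  expect_false(any(pocket$resname == "LIG"))
  expect_equal(unique(pocket$resname[pocket$resno == 1]), "ALA")
  expect_equal(unique(pocket$resname[pocket$resno == 2]), "SER")
  expect_equal(nrow(attr(pocket, "ligand_pose")), 1)
  expect_error(prepare_ligand_pocket(s, "XXX"), "not found")
})
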