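# helpers shared across test files; everything is generated in code

write_mini_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          occ = 1, alt = " ", record = "ATOM", element = NULL) {
  element <- element %||% substr(gsub("[0-9]", "", name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two asparagine residues whose ND2-H vectors aim exactly at a common water
# point at ideal donor distances and a 111-degree bridging angle; returns the
# atom table, the design positions, and the analytic water position
make_bridged_asn_pair <- function(seed = 7, spin_try = seq(0, 330, by = 30)) {
  set.seed(seed)
  a1 <- aquabridge:::ideal_residue("ASN", c(0, 0, 0), "A", 1L, chi = c(-65, -40))
  s1 <- suppressWarnings(classify_polar_sites(as_structure(a1)))
  nd2 <- s1[s1$name == "ND2", ]
  n1 <- c(nd2$x, nd2$y, nd2$z)
  u <- nd2$donor_vecs[[1]][1, ]
  W <- n1 + 2.87 * u
  # target frame for the second ND2
  v <- aquabridge:::rotate_about(-u, aquabridge:::any_perp(u), 111)
  n2_target <- W + 2.87 * v
  u2_target <- -v                       # N2 -> W direction
  set.seed(seed + 1)
  a2 <- aquabridge:::ideal_residue("ASN", c(30, 0, 0), "A", 5L, chi = c(-65, -40))
  s2 <- suppressWarnings(classify_polar_sites(as_structure(a2)))
  nd2b <- s2[s2$name == "ND2", ]
  n2 <- c(nd2b$x, nd2b$y, nd2b$z)
  u2 <- nd2b$donor_vecs[[1]][1, ]
  # rotate residue 2 so its N-H axis matches the target direction
  ax <- aquabridge:::vcross(u2, u2_target)
  ang <- aquabridge:::vangle(u2, u2_target)
  rot <- function(p) if (aquabridge:::vnorm(ax) < 1e-9) p
    else aquabridge:::rotate_about(p, ax, ang)
  for (spin in spin_try) {
    b2 <- a2
    for (r in seq_len(nrow(b2))) {
      p <- rot(c(b2$x[r], b2$y[r], b2$z[r]) - n2)
      p <- aquabridge:::rotate_about(p, u2_target, spin) + n2_target
      b2$x[r] <- p[1]; b2$y[r] <- p[2]; b2$z[r] <- p[3]
    }
    atoms <- as_structure(dplyr::bind_rows(a1, b2))
    # clearance between the two residues
    xa <- as.matrix(a1[, c("x", "y", "z")]); xb <- as.matrix(b2[, c("x", "y", "z")])
    dmin <- min(apply(xa, 1, function(p) min(aquabridge:::dist_to_point(xb, p))))
    dW <- min(aquabridge:::dist_to_point(rbind(xa, xb), W))
    if (dmin > 3.0 && dW > 2.4) {
      return(list(atoms = atoms,
                  positions = tibble::tibble(chain = "A", resno = c(1L, 5L),
                                             resname = "ASN"),
                  water = W))
    }
  }
  stop("could not build a clash-free bridged pair")
}

# a packing toy with synthetic random energy tables (sizes chosen so the
# assignment space stays exhaustively enumerable)
make_toy_packing <- function(sizes, seed) {
  set.seed(seed)
  rotamers <- lapply(sizes, function(k) lapply(seq_len(k), function(i)
    structure(list(chain = "A", resno = i, resname = "XXX", chi = numeric(0),
                   freq = 1, atoms = as_structure(tibble::tibble(
                     name = "CA", element = "C", resname = "GLY", chain = "A",
                     resno = 1L, x = 0, y = 0, z = 0)),
                   waters = aquabridge:::empty_placements(),
                   bridge_ids = character(0)), class = "aqua_rotamer")))
  problem <- structure(list(
    context = as_structure(tibble::tibble(
      name = character(), element = character(), resname = character(),
      chain = character(), resno = integer(), x = numeric(), y = numeric(),
      z = numeric())),
    positions = tibble::tibble(chain = "A", resno = seq_along(sizes),
                               resname = "XXX"),
    rotamers = rotamers, params = geometry_params(), energy = hbond_params(),
    solvated = FALSE), class = "aqua_packing_problem")
  np <- length(sizes)
  tables <- list(
    self = lapply(sizes, function(k) round(stats::rnorm(k, 0, 3), 2)),
    pair = vector("list", np))
  for (p in seq_len(np)) tables$pair[[p]] <- vector("list", np)
  if (np >= 2) {
    for (p in seq_len(np - 1)) for (q in (p + 1):np) {
      M <- matrix(round(stats::rnorm(sizes[p] * sizes[q], 0, 2), 2),
                  sizes[p], sizes[q])
      tables$pair[[p]][[q]] <- M
      tables$pair[[q]][[p]] <- t(M)
    }
  }
  list(problem = problem, tables = tables)
}

toy_brute_force <- function(tables, sizes) {
  grid <- expand.grid(lapply(sizes, seq_len))
  es <- apply(grid, 1, function(a)
    aquabridge:::assignment_energy(tables, as.integer(a)))
  list(energy = min(es), assign = as.integer(grid[which.min(es), ]))
}

# a random polar-site pair row set (pseudo sites with aimed orbitals) used by
# the construction-exactness property tests
random_site_pair <- function() {
  repeat {
    ow <- stats::runif(3, -5, 5)
    u1 <- aquabridge:::rand_unit()
    alpha <- stats::runif(1, 95, 140)
    u2 <- aquabridge:::rotate_about(
      aquabridge:::any_perp(u1), u1, stats::runif(1, 0, 360))
    uj <- cos(aquabridge:::deg2rad(alpha)) * u1 +
      sin(aquabridge:::deg2rad(alpha)) * u2
    d_i <- sample(c(2.73, 2.87), 1); d_j <- sample(c(2.73, 2.87), 1)
    d <- aquabridge:::vnorm(d_i * u1 - d_j * uj)
    if (d > 3.65 && d < 5.57 && d < d_i + d_j) {
      return(list(xi = ow + d_i * u1, xj = ow + d_j * uj,
                  d_i = d_i, d_j = d_j, water = ow))
    }
  }
}
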