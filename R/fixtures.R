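#' Deterministic synthetic fixtures with analytically known waters
#'
#' The generator plants bridging waters by running the geometric construction
#' in reverse: a water position is chosen first, then donor/acceptor
#' fragments are built around it whose direction vectors point exactly at the
#' planted oxygen, at exactly the ideal hydrogen-bond distances. Forward
#' solvation must therefore recover the planted water analytically. Defaults
#' emulate the observed geometry statistics of protein-bound waters: contact
#' distances near 2.73 Angstrom (oxygen) / 2.87 (nitrogen) and bridging
#' angles drawn from Normal(111, 16.7) degrees, with optional isotropic
#' Gaussian coordinate jitter and apolar carbon decoys.
#'
#' @name fixtures
NULL

#' Fixture specification
#'
#' @param seed integer seed; generation is fully deterministic given it.
#' @param n_bridges number of planted bridges.
#' @param leg_distances fixed hydrogen-bond leg length(s) in Angstrom, or
#'   `NULL` for the ideal per-element distances (2.73 / 2.87).
#' @param bridge_angle fixed Xi-water-Xj angle in degrees, or `NULL` to draw
#'   from Normal(111, 16.7) truncated so that the implied polar-pair distance
#'   falls in the +/- 1 sigma core (4.13-5.09 Angstrom) of the observed
#'   bridged-pair distance distribution: planted bridges are meant to be
#'   unambiguous positives for the standard +/- 2 sigma eligibility window.
#' @param jitter_sd isotropic Gaussian positional noise, Angstrom. Applied
#'   after the ground truth is recorded, as one rigid random translation per
#'   chemical fragment (and per water): refined crystal structures restrain
#'   bond lengths and angles, so coordinate uncertainty displaces groups
#'   while their internal geometry stays near-ideal. Per-atom independent
#'   noise would break that invariant.
#' @param decoy_atoms number of apolar carbon decoy atoms.
#' @return a list of class `aqua_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_bridges = 5, leg_distances = NULL,
                         bridge_angle = NULL, jitter_sd = 0, decoy_atoms = 10) {
  stopifnot(jitter_sd >= 0,
            is.null(bridge_angle) || (bridge_angle > 0 && bridge_angle < 180))
  structure(list(seed = as.integer(seed), n_bridges = n_bridges,
                 leg_distances = leg_distances, bridge_angle = bridge_angle,
                 jitter_sd = jitter_sd, decoy_atoms = decoy_atoms),
            class = "aqua_fixture_spec")
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  force(code)
}

rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x > lo && x < hi) return(x)
  }
  mean
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    if (vnorm(v) > 1e-6) return(unitv(v))
  }
}

# acceptor fragment: carbonyl-like C=O (+ CA for the plane frame), built so
# that one sp2 lone pair of O points exactly along `aim` (unit vector)
acceptor_fragment <- function(o_pos, aim, chain, resno) {
  n <- any_perp(aim)
  c_dir <- rotate_about(aim, n, 120)          # O->C bond direction
  c_pos <- o_pos + 1.23 * c_dir
  ca_dir <- rotate_about(unitv(o_pos - c_pos), n, 122)
  ca_pos <- c_pos + 1.52 * ca_dir
  tibble::tibble(
    name = c("C", "O", "CA"), element = c("C", "O", "C"),
    resname = "GLY", chain = chain, resno = resno,
    x = c(c_pos[1], o_pos[1], ca_pos[1]),
    y = c(c_pos[2], o_pos[2], ca_pos[2]),
    z = c(c_pos[3], o_pos[3], ca_pos[3]))
}

# donor fragment: backbone-amide-like N (with CA and the preceding carbonyl
# C as frame), built so that the rebuilt N-H vector points exactly along
# `aim`; occupies two residue numbers (resno-1 holds the preceding C)
donor_fragment <- function(n_pos, aim, chain, resno) {
  e <- any_perp(aim)
  phi <- deg2rad(59)
  v1 <- -cos(phi) * aim + sin(phi) * e
  v2 <- -cos(phi) * aim - sin(phi) * e
  ca_pos <- n_pos + 1.47 * v1
  c_pos <- n_pos + 1.33 * v2
  tibble::tibble(
    name = c("C", "N", "CA"), element = c("C", "N", "C"),
    resname = "GLY", chain = chain, resno = c(resno - 1L, resno, resno),
    x = c(c_pos[1], n_pos[1], ca_pos[1]),
    y = c(c_pos[2], n_pos[2], ca_pos[2]),
    z = c(c_pos[3], n_pos[3], ca_pos[3]))
}

# one planted bridge around water position `ow`; returns fragment atoms and
# the two site positions
plant_bridge <- function(ow, spec, chain, resno0) {
  kind <- sample(c("AA", "DA", "DD"), 1, prob = c(0.5, 0.3, 0.2))
  u1 <- rand_unit()
  u2 <- any_perp(u1)
  u2 <- rotate_about(u2, u1, stats::runif(1, 0, 360))
  types <- switch(kind, AA = c("A", "A"), DA = c("D", "A"), DD = c("D", "D"))
  d_i <- spec$leg_distances[1] %||% (if (types[1] == "D") 2.87 else 2.73)
  d_j <- (if (length(spec$leg_distances) > 1) spec$leg_distances[2]
          else spec$leg_distances[1]) %||% (if (types[2] == "D") 2.87 else 2.73)
  # angle limits implied by the strict (+/- 1 sigma) pair-distance core
  a_for_d <- function(d) rad2deg(acos(
    pmin(1, pmax(-1, (d_i^2 + d_j^2 - d^2) / (2 * d_i * d_j)))))
  alpha <- spec$bridge_angle %||%
    rnorm_trunc(111, 16.7, a_for_d(4.13), a_for_d(5.09))
  uj <- cos(deg2rad(alpha)) * u1 + sin(deg2rad(alpha)) * u2
  xi <- ow + d_i * u1
  xj <- ow + d_j * uj
  frag <- function(type, pos, aim, resno)
    if (type == "A") acceptor_fragment(pos, aim, chain, resno)
    else donor_fragment(pos, aim, chain, resno)
  f1 <- frag(types[1], xi, unitv(ow - xi), resno0 + 1L)
  f2 <- frag(types[2], xj, unitv(ow - xj), resno0 + 3L)
  f1$fragment <- 1L; f2$fragment <- 2L
  list(atoms = dplyr::bind_rows(f1, f2), xi = xi, xj = xj, kind = kind)
}

#' Generate a bridge fixture
#'
#' Plants `n_bridges` isolated bridges on a coarse spatial grid (16 Angstrom
#' spacing, so sites of different bridges can never pair), plus apolar
#' decoys. The planted waters are returned as ground truth; hydrogens of the
#' ground truth are oriented with the package's own orientation rules on the
#' pre-jitter geometry.
#'
#' @param spec a [fixture_spec()].
#' @return list with `atoms` (structure tibble, jittered if requested),
#'   `waters` (planted placements: ox/oy/oz + hydrogens), `spec`.
#' @export
make_bridge_fixture <- function(spec = fixture_spec()) {
  with_seed(spec$seed, {
    grid_n <- ceiling(spec$n_bridges^(1 / 3))
    offsets <- as.matrix(expand.grid(gx = 0:(grid_n - 1), gy = 0:(grid_n - 1),
                                     gz = 0:(grid_n - 1))) * 16
    parts <- list(); gt <- list()
    for (b in seq_len(spec$n_bridges)) {
      ow <- offsets[b, ] + stats::runif(3, 6, 10)
      pb <- plant_bridge(ow, spec, chain = "A", resno0 = (b - 1L) * 10L)
      pb$atoms$fragment <- pb$atoms$fragment + 2L * b
      parts[[b]] <- pb$atoms
      gt[[b]] <- tibble::tibble(ox = ow[1], oy = ow[2], oz = ow[3],
                                bridge = b, kind = pb$kind)
    }
    atoms <- dplyr::bind_rows(parts)
    # apolar decoys, kept clear of sites and waters
    if (spec$decoy_atoms > 0) {
      gtm <- dplyr::bind_rows(gt)
      all_xyz <- rbind(as.matrix(atoms[, c("x", "y", "z")]),
                       as.matrix(gtm[, c("ox", "oy", "oz")]))
      dec <- list()
      tries <- 0
      while (length(dec) < spec$decoy_atoms && tries < 1000) {
        tries <- tries + 1
        p <- stats::runif(3, 0, max(16 * grid_n, 16))
        if (min(dist_to_point(all_xyz, p)) > 4) {
          dec[[length(dec) + 1]] <- tibble::tibble(
            name = "CA", element = "C", resname = "GLY", chain = "D",
            resno = 900L + length(dec), x = p[1], y = p[2], z = p[3],
            fragment = 1000L + length(dec))
          all_xyz <- rbind(all_xyz, p)
        }
      }
      atoms <- dplyr::bind_rows(atoms, dplyr::bind_rows(dec))
    }
    s <- as_structure(atoms)
    # ground-truth hydrogens from the pre-jitter geometry
    sites <- suppressWarnings(classify_polar_sites(s))
    waters <- purrr::map_dfr(gt, function(g) {
      ow <- c(g$ox, g$oy, g$oz)
      ds <- sqrt((sites$x - ow[1])^2 + (sites$y - ow[2])^2 + (sites$z - ow[3])^2)
      near <- order(ds)[1:2]
      pl <- orient_hydrogens(ow, sites[near[1], ], sites[near[2], ])
      pl <- pl[which.min(pl$energy_i + pl$energy_j), ]
      pl$bridge <- g$bridge; pl$kind <- g$kind
      pl
    })
    if (spec$jitter_sd > 0)
      s <- jitter_rigid(s, atoms$fragment, spec$jitter_sd)
    list(atoms = s, waters = waters, spec = spec)
  })
}

#' Generate a reference-sphere fixture
#'
#' A central planted water with a chosen coordination count (polar fragments
#' aimed at it from near-tetrahedral directions), optional neighbouring
#' planted bridges inside the evaluation border, decoys, and a few full
#' residues in the outer shell. Returned as an `aqua_sphere` whose atom table
#' contains the planted waters as HOH records; the ground truth is attached.
#'
#' @param spec a [fixture_spec()]; `n_bridges` here is the number of
#'   neighbour bridges beyond the central water.
#' @param coordination number of polar fragments coordinating the central
#'   water (2-4).
#' @return an `aqua_sphere` with extra elements `truth` (planted water
#'   tibble) and `spec`.
#' @export
make_sphere_fixture <- function(spec = fixture_spec(n_bridges = 2),
                                coordination = 4) {
  stopifnot(coordination >= 2, coordination <= 4)
  with_seed(spec$seed, {
    center <- c(25, 25, 25)
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
    rot_ax <- rand_unit(); rot_an <- stats::runif(1, 0, 360)
    dirs <- t(apply(tet, 1, rotate_about, k = rot_ax, theta = rot_an))
    parts <- list(); truth <- list()
    # central water's coordinating fragments (acceptors and one donor)
    for (k in seq_len(coordination)) {
      type <- if (k == 2) "D" else "A"
      d0 <- if (type == "D") 2.87 else 2.73
      pos <- center + d0 * dirs[k, ]
      fr <- if (type == "A") acceptor_fragment(pos, unitv(center - pos), "A", k * 10L)
        else donor_fragment(pos, unitv(center - pos), "A", k * 10L)
      fr$fragment <- k
      parts[[length(parts) + 1]] <- fr
    }
    truth[[1]] <- tibble::tibble(ox = center[1], oy = center[2], oz = center[3],
                                 central = TRUE)
    occupied <- as.matrix(dplyr::bind_rows(parts)[, c("x", "y", "z")])
    occupied <- rbind(occupied, center)
    # neighbour bridges inside the evaluation border
    b <- 0; tries <- 0
    while (b < spec$n_bridges && tries < 400) {
      tries <- tries + 1
      ow <- center + stats::runif(1, 3.5, 5.5) * rand_unit()
      pb <- plant_bridge(ow, spec, chain = "B", resno0 = 100L + b * 10L)
      frag_xyz <- as.matrix(pb$atoms[, c("x", "y", "z")])
      if (min(dist_to_point(occupied, ow)) < 2.8) next
      dmin <- min(vapply(seq_len(nrow(frag_xyz)), function(i)
        min(dist_to_point(occupied, frag_xyz[i, ])), numeric(1)))
      if (dmin < 3.0) next
      b <- b + 1
      pb$atoms$fragment <- 50L + 2L * b + pb$atoms$fragment
      parts[[length(parts) + 1]] <- pb$atoms
      truth[[length(truth) + 1]] <- tibble::tibble(ox = ow[1], oy = ow[2],
                                                   oz = ow[3], central = FALSE)
      occupied <- rbind(occupied, frag_xyz, ow)
    }
    # a couple of full outer-shell residues for chi-1 / RMSD bookkeeping
    for (j in 1:2) {
      base <- center + stats::runif(1, 10, 15) * rand_unit()
      rsd <- ideal_residue("SER", base, chain = "C", resno = 200L + j,
                           chi = c(64))
      rsd$fragment <- 80L + j
      parts[[length(parts) + 1]] <- rsd
    }
    atoms <- dplyr::bind_rows(parts)
    truth <- dplyr::bind_rows(truth)
    # decoys
    dec <- 0; tries <- 0
    occ <- rbind(as.matrix(atoms[, c("x", "y", "z")]),
                 as.matrix(truth[, c("ox", "oy", "oz")]))
    while (dec < spec$decoy_atoms && tries < 1000) {
      tries <- tries + 1
      p <- center + stats::runif(1, 4, 18) * rand_unit()
      if (min(dist_to_point(occ, p)) > 4) {
        dec <- dec + 1
        atoms <- dplyr::bind_rows(atoms, tibble::tibble(
          name = "CA", element = "C", resname = "GLY", chain = "D",
          resno = 900L + dec, x = p[1], y = p[2], z = p[3],
          fragment = 900L + dec))
        occ <- rbind(occ, p)
      }
    }
    # planted waters as HOH records (central first)
    wat <- tibble::tibble(
      name = "O", element = "O", resname = "HOH", chain = "W",
      resno = 500L + seq_len(nrow(truth)),
      x = truth$ox, y = truth$oy, z = truth$oz,
      fragment = 500L + seq_len(nrow(truth)))
    atoms <- dplyr::bind_rows(atoms, wat)
    if (spec$jitter_sd > 0) {
      atoms <- jitter_rigid(atoms, atoms$fragment, spec$jitter_sd)
      # keep the central water exactly at the recorded centre
      cw <- atoms$resname == "HOH" & atoms$resno == 501L
      atoms$x[cw] <- truth$ox[1]; atoms$y[cw] <- truth$oy[1]
      atoms$z[cw] <- truth$oz[1]
    }
    sp <- extract_sphere(as_structure(atoms), center, radius = 20)
    sp$truth <- truth
    sp$spec <- spec
    sp
  })
}

# rigid per-group translation noise: one N(0, sd) shift per fragment id
jitter_rigid <- function(s, group, sd) {
  for (g in unique(group)) {
    idx <- which(group == g)
    sh <- stats::rnorm(3, 0, sd)
    s$x[idx] <- s$x[idx] + sh[1]
    s$y[idx] <- s$y[idx] + sh[2]
    s$z[idx] <- s$z[idx] + sh[3]
  }
  s
}

# a full residue built from ideal internal coordinates at an arbitrary frame
ideal_residue <- function(resname, base, chain, resno, chi = numeric(0)) {
  u <- rand_unit(); v <- any_perp(u)
  n_pos <- base
  ca_pos <- base + 1.458 * u
  c_pos <- ca_pos + 1.525 * unitv(rotate_about(u, v, 69))   # 111 deg N-CA-C
  o_pos <- nerf_place(n_pos, ca_pos, c_pos, 1.231, 120.5, 135)
  bb <- tibble::tibble(
    name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    resname = resname, chain = chain, resno = resno,
    x = c(n_pos[1], ca_pos[1], c_pos[1], o_pos[1]),
    y = c(n_pos[2], ca_pos[2], c_pos[2], o_pos[2]),
    z = c(n_pos[3], ca_pos[3], c_pos[3], o_pos[3]))
  sc <- build_sidechain(bb, resname, chi)
  if (nrow(sc)) {
    sc$resname <- resname; sc$chain <- chain; sc$resno <- resno
    bb <- dplyr::bind_rows(bb, sc)
  }
  bb
}
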