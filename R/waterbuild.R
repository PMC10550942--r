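#' Geometric construction of bridging waters
#'
#' For an eligible pair of polar sites Xi, Xj the locus of points at the ideal
#' hydrogen-bond distance from both atoms is a circle perpendicular to the
#' Xi-Xj line; its radius and centre follow from Heron's formula for the
#' triangle (Xi, Xj, water). The water oxygen is placed at the perimeter
#' point nearest the projected midpoint of the closest approach of the two
#' hydrogen-bond direction vectors, hydrogens are attached with rigid water
#' geometry (O-H 0.96 Angstrom, H-O-H 104.45 degrees), and the construction
#' is gated by a directional hydrogen-bond energy.
#'
#' @name waterbuild
NULL

#' Is a polar-site pair eligible for water bridging?
#'
#' True when the heavy-atom separation falls strictly inside the eligibility
#' window (3.65-5.57 Angstrom by default; 4.13-5.09 in strict mode) and the
#' two sites belong to different residues or molecules.
#'
#' @param site_i,site_j single rows of a polar-site tibble.
#' @param params a [geometry_params()] object.
#' @return logical.
#' @export
pair_eligible <- function(site_i, site_j, params = geometry_params()) {
  win <- if (params$strict) params$strict_window else params$pair_window
  d <- vnorm(c(site_i$x - site_j$x, site_i$y - site_j$y, site_i$z - site_j$z))
  same_res <- site_i$chain == site_j$chain & site_i$resno == site_j$resno &
    site_i$resname == site_j$resname
  d > win[1] && d < win[2] && !same_res
}

#' Ideal-distance circle between two polar atoms
#'
#' All points of the returned circle lie at `d_i` from `Xi` and `d_j` from
#' `Xj`. Radius and centre are computed via Heron's formula: with triangle
#' sides (d, d_i, d_j) and area A, the radius is `r = 2A/d` and the centre
#' sits on the Xi-Xj segment at `sqrt(d_i^2 - r^2)` from Xi.
#'
#' @param xi,xj heavy-atom positions (length-3, Angstrom).
#' @param d_i,d_j ideal water distances (2.73 for O, 2.87 for N).
#' @return a list of class `aqua_bridge_circle` with `center`, `radius`,
#'   `normal` (unit vector along Xi to Xj).
#' @export
bridge_circle <- function(xi, xj, d_i = 2.73, d_j = 2.73) {
  d <- vnorm(xj - xi)
  if (d < abs(d_i - d_j) - 1e-9 || d > d_i + d_j + 1e-9)
    stop("no bridging water geometry: |Xi-Xj| = ", round(d, 3),
         " outside [", round(abs(d_i - d_j), 3), ", ", round(d_i + d_j, 3), "]",
         call. = FALSE)
  d <- min(max(d, abs(d_i - d_j)), d_i + d_j)   # clamp the equality cases
  s <- (d + d_i + d_j) / 2
  area2 <- s * (s - d) * (s - d_i) * (s - d_j)  # Heron, squared area
  r <- 2 * sqrt(max(area2, 0)) / d
  h <- sqrt(max(d_i^2 - r^2, 0))
  n <- unitv(xj - xi)
  structure(list(center = xi + h * n, radius = r, normal = n),
            class = "aqua_bridge_circle")
}

#' Midpoint of the closest approach of two direction lines
#'
#' For skew lines the midpoint of the unique shortest connecting segment; for
#' intersecting lines the intersection point. For (near-)parallel directions
#' the midpoint of the mutual projections of the two origins is used and the
#' result is flagged with `attr(, "parallel")`.
#'
#' @param p_i,p_j line origins (polar atom positions).
#' @param o_i,o_j unit direction vectors.
#' @return length-3 point; attributes `parallel` (logical) and `t` (the two
#'   line parameters of the closest points).
#' @export
closest_approach_midpoint <- function(p_i, o_i, p_j, o_j) {
  o_i <- unitv(o_i); o_j <- unitv(o_j)
  w <- p_i - p_j
  b <- sum(o_i * o_j)
  denom <- 1 - b^2
  if (denom < 1e-10) {
    # parallel: project each origin onto the other line, average the feet
    t_j <- sum((p_i - p_j) * o_j)
    t_i <- sum((p_j - p_i) * o_i)
    mid <- ((p_j + t_j * o_j) + (p_i + t_i * o_i)) / 2
    return(structure(mid, parallel = TRUE, t = c(t_i, t_j)))
  }
  d_ <- sum(o_i * w); e_ <- sum(o_j * w)
  t_i <- (b * e_ - d_) / denom
  t_j <- (e_ - b * d_) / denom
  mid <- ((p_i + t_i * o_i) + (p_j + t_j * o_j)) / 2
  structure(mid, parallel = FALSE, t = c(t_i, t_j))
}

#' Shift a point to the ideal-distance circle perimeter
#'
#' The midpoint is projected onto the circle plane and moved to the perimeter
#' along the ray from the centre through the projection; this is the
#' perimeter point closest to the projected midpoint. When the projection
#' coincides with the centre the azimuth is undefined: if the partner sites
#' are supplied, the perimeter is scanned on a 1-degree grid for the point of
#' smallest summed angular deviation from their direction vectors; otherwise
#' a fixed in-plane axis is used (deterministic either way).
#'
#' @param circle an [bridge_circle()] object.
#' @param midpoint length-3 point.
#' @param site_i,site_j optional polar-site rows for the degenerate tie-break.
#' @return length-3 oxygen position on the circle perimeter.
#' @export
place_water_oxygen <- function(circle, midpoint, site_i = NULL, site_j = NULL) {
  if (circle$radius <= 1e-12) return(circle$center)
  v <- midpoint - circle$center
  v_in <- v - sum(v * circle$normal) * circle$normal
  if (vnorm(v_in) < 1e-9) {
    e1 <- any_perp(circle$normal)
    if (is.null(site_i) || is.null(site_j))
      return(circle$center + circle$radius * e1)
    e2 <- vcross(circle$normal, e1)
    best <- NULL; best_dev <- Inf
    for (a in deg2rad(seq(0, 359, by = 1))) {
      p <- circle$center + circle$radius * (cos(a) * e1 + sin(a) * e2)
      dev <- summed_orbital_deviation(p, site_i, site_j)
      if (dev < best_dev - 1e-12) { best_dev <- dev; best <- p }
    }
    return(best)
  }
  circle$center + circle$radius * unitv(v_in)
}

summed_orbital_deviation <- function(p, site_i, site_j) {
  dev_one <- function(site) {
    ov <- orbital_vectors(site)
    if (!nrow(ov)) return(0)
    u <- unitv(p - c(site$x, site$y, site$z))
    min(apply(ov, 1, function(v) vangle(v, u)))
  }
  dev_one(site_i) + dev_one(site_j)
}

#' Orient the water hydrogens towards/away from the partner sites
#'
#' Two acceptor partners: one variant with both hydrogens directed at the
#' acceptors. Two donor partners: one variant with the water lone pairs
#' facing the donors. Mixed pairs: exactly two variants; the hydrogen serving
#' the acceptor partner is fixed on the ideal direction and the second
#' hydrogen's azimuth is optimised (1-degree scan) so that a lone pair faces
#' the donor partner, the mirror-image solution (or the alternative
#' role assignment, for two dual-role sites) giving the second variant.
#'
#' @param oxygen placed oxygen position.
#' @param site_i,site_j polar-site rows.
#' @param params a [geometry_params()] object.
#' @param energy an [hbond_params()] object used to score the legs.
#' @return a water-placement tibble (1 or 2 rows) with columns `ox`, `oy`,
#'   `oz`, list-column `hydrogens` (2 x 3), `orientation_variant`,
#'   `energy_i`, `energy_j`.
#' @export
orient_hydrogens <- function(oxygen, site_i, site_j,
                             params = geometry_params(),
                             energy = hbond_params()) {
  u_i <- unitv(c(site_i$x, site_i$y, site_i$z) - oxygen)
  u_j <- unitv(c(site_j$x, site_j$y, site_j$z) - oxygen)
  half <- params$hoh_angle / 2
  L <- params$oh_length

  can_acc <- c(site_i$role %in% c("acceptor", "both"),
               site_j$role %in% c("acceptor", "both"))
  can_don <- c(site_i$role %in% c("donor", "both"),
               site_j$role %in% c("donor", "both"))
  # assignment = (water donates H to i?, water donates H to j?)
  cand <- list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE), c(FALSE, FALSE))
  valid <- Filter(function(a) {
    ok1 <- if (a[1]) can_acc[1] else can_don[1]
    ok2 <- if (a[2]) can_acc[2] else can_don[2]
    ok1 && ok2
  }, cand)
  if (!length(valid)) return(empty_placements())

  geoms <- list()
  if (length(valid) == 1 && xor(valid[[1]][1], valid[[1]][2])) {
    # single mixed assignment: the two mirror-image optima are the variants
    g <- mixed_orientation(oxygen, u_i, u_j, valid[[1]], half, L, mirror = FALSE)
    gm <- mixed_orientation(oxygen, u_i, u_j, valid[[1]], half, L, mirror = TRUE)
    geoms <- list(g, gm)
  } else {
    for (a in valid[seq_len(min(2, length(valid)))]) {
      geoms[[length(geoms) + 1]] <-
        if (a[1] && a[2]) donate_both(oxygen, u_i, u_j, half, L)
        else if (!a[1] && !a[2]) accept_both(oxygen, u_i, u_j, half, L)
        else mixed_orientation(oxygen, u_i, u_j, a, half, L, mirror = FALSE)
    }
  }

  purrr::imap_dfr(geoms, function(g, v) {
    w <- list(oxygen = oxygen, hydrogens = g$H)
    tibble::tibble(
      ox = oxygen[1], oy = oxygen[2], oz = oxygen[3],
      hydrogens = list(g$H), orientation_variant = v,
      donates_i = g$assign[1], donates_j = g$assign[2],
      energy_i = hbond_energy(w, site_i, energy, donates_h = g$assign[1]),
      energy_j = hbond_energy(w, site_j, energy, donates_h = g$assign[2]))
  })
}

empty_placements <- function() {
  tibble::tibble(ox = numeric(), oy = numeric(), oz = numeric(),
                 hydrogens = list(), orientation_variant = integer(),
                 donates_i = logical(), donates_j = logical(),
                 energy_i = numeric(), energy_j = numeric())
}

# both hydrogens point at the two acceptors, symmetric about their bisector
donate_both <- function(o, u_i, u_j, half, L) {
  su <- u_i + u_j
  b <- if (vnorm(su) > 1e-8) unitv(su) else any_perp(u_i)
  du <- u_i - u_j
  p <- if (vnorm(du) > 1e-8) unitv(du - sum(du * b) * b) else any_perp(b)
  h1 <- o + L * (cos(deg2rad(half)) * b + sin(deg2rad(half)) * p)
  h2 <- o + L * (cos(deg2rad(half)) * b - sin(deg2rad(half)) * p)
  list(H = rbind(h1, h2), assign = c(TRUE, TRUE))
}

# lone pairs face the two donors; hydrogens sit in the perpendicular plane
accept_both <- function(o, u_i, u_j, half, L) {
  su <- u_i + u_j
  b <- if (vnorm(su) > 1e-8) unitv(su) else any_perp(u_i)
  n <- vcross(u_i, u_j)
  n <- if (vnorm(n) > 1e-8) unitv(n) else any_perp(b)
  h1 <- o + L * (cos(deg2rad(half)) * (-b) + sin(deg2rad(half)) * n)
  h2 <- o + L * (cos(deg2rad(half)) * (-b) - sin(deg2rad(half)) * n)
  list(H = rbind(h1, h2), assign = c(FALSE, FALSE))
}

# one H fixed on the acceptor direction; second H's azimuth scanned so a lone
# pair faces the donor; mirror = reflected solution across the Xi-O-Xj plane
mixed_orientation <- function(o, u_i, u_j, assign, half, L, mirror = FALSE) {
  a <- if (assign[1]) u_i else u_j   # acceptor partner direction (gets the H)
  dd <- if (assign[1]) u_j else u_i  # donor partner direction (faces lone pair)
  e1 <- dd - sum(dd * a) * a
  e1 <- if (vnorm(e1) > 1e-8) unitv(e1) else any_perp(a)
  e2 <- vcross(a, e1)
  ang <- deg2rad(2 * half)           # full H-O-H angle
  best_phi <- 0; best <- -Inf
  for (phi in deg2rad(seq(0, 359, by = 1))) {
    h2dir <- cos(ang) * a + sin(ang) * (cos(phi) * e1 + sin(phi) * e2)
    sc <- lp_alignment(a, h2dir, dd)
    if (sc > best + 1e-12) { best <- sc; best_phi <- phi }
  }
  if (mirror) best_phi <- -best_phi
  h2dir <- cos(ang) * a + sin(ang) * (cos(best_phi) * e1 + sin(best_phi) * e2)
  list(H = rbind(o + L * a, o + L * h2dir), assign = assign)
}

# best cosine between a water lone pair (from H directions) and target dir
lp_alignment <- function(h1dir, h2dir, target) {
  m <- -unitv(h1dir + h2dir)
  ax <- unitv(vcross(h1dir, h2dir))
  halft <- deg2rad(109.47 / 2)
  lp1 <- cos(halft) * m + sin(halft) * ax
  lp2 <- cos(halft) * m - sin(halft) * ax
  max(sum(lp1 * target), sum(lp2 * target))
}

# full pipeline for one classified site pair; returns accepted placements
build_water_for_pair <- function(site_i, site_j, params, energy,
                                 heavy_xyz = NULL, exclude_idx = integer(0)) {
  xi <- c(site_i$x, site_i$y, site_i$z)
  xj <- c(site_j$x, site_j$y, site_j$z)
  d_i <- if (site_i$element == "N") params$d_h2o_n else params$d_h2o_x
  d_j <- if (site_j$element == "N") params$d_h2o_n else params$d_h2o_x
  d <- vnorm(xj - xi)
  if (d > d_i + d_j) return(empty_placements())   # no exact construction
  circle <- bridge_circle(xi, xj, d_i, d_j)

  # evaluate every orbital-vector combination: construct the candidate
  # oxygen from each midpoint and keep the one whose perimeter point shows
  # the smallest summed angular deviation from the direction vectors
  ov_i <- orbital_vectors(site_i); ov_j <- orbital_vectors(site_j)
  if (!nrow(ov_i) || !nrow(ov_j)) return(empty_placements())
  oxy <- NULL; best_dev <- Inf; best_par <- FALSE
  for (ki in seq_len(nrow(ov_i))) for (kj in seq_len(nrow(ov_j))) {
    m <- closest_approach_midpoint(xi, ov_i[ki, ], xj, ov_j[kj, ])
    tpar <- attr(m, "t")
    o_cand <- place_water_oxygen(circle, as.numeric(m), site_i, site_j)
    dev <- vangle(ov_i[ki, ], o_cand - xi) + vangle(ov_j[kj, ], o_cand - xj)
    if (any(tpar < 0)) dev <- dev + 1000   # closest point behind the atom
    if (dev < best_dev - 1e-12) {
      best_dev <- dev; oxy <- o_cand
      best_par <- isTRUE(attr(m, "parallel"))
    }
  }

  if (!is.null(heavy_xyz) && nrow(heavy_xyz)) {
    dd <- dist_to_point(heavy_xyz, oxy)
    keep <- rep(TRUE, length(dd)); keep[exclude_idx] <- FALSE
    if (any(dd[keep] < params$clash_distance)) return(empty_placements())
  }

  pl <- orient_hydrogens(oxy, site_i, site_j, params, energy)
  if (!nrow(pl)) return(pl)
  pl <- pl[vapply(seq_len(nrow(pl)), function(r)
    accept_water(pl[r, ], energy), logical(1)), ]
  if (nrow(pl)) {
    pl$site_i <- site_i$site_id; pl$site_j <- site_j$site_id
    pl$atom_i <- site_i$atom_idx; pl$atom_j <- site_j$atom_idx
    pl$parallel <- best_par
  }
  pl
}

#' Solvate a fixed structure (posterior mode)
#'
#' Classifies all polar sites of the structure, constructs a bridging water
#' for every eligible pair, gates by hydrogen-bond energy, removes clashing
#' constructions, and collapses waters closer than the merge radius to the
#' lower-energy one.
#'
#' @param atoms an atom tibble (an all-atom model; existing waters never act
#'   as bridge partners unless `allow_water_partners`).
#' @param params a [geometry_params()] object.
#' @param energy an [hbond_params()] object.
#' @param allow_water_partners let already-present waters participate as
#'   polar sites (off by default).
#' @param sites optionally, a precomputed polar-site tibble.
#' @return a water-placement tibble; one row per predicted water with partner
#'   site identities, orientation variant and both leg energies.
#' @export
solvate_structure <- function(atoms, params = geometry_params(),
                              energy = hbond_params(),
                              allow_water_partners = FALSE, sites = NULL) {
  if (is.null(sites)) sites <- classify_polar_sites(atoms)
  if (!allow_water_partners)
    sites <- sites[!atoms$is_water[sites$atom_idx], ]
  n <- nrow(sites)
  if (n < 2) return(empty_placements())
  heavy_xyz <- atoms_xyz(atoms[atoms$element != "H", ])
  heavy_rows <- which(atoms$element != "H")
  out <- list()
  win <- if (params$strict) params$strict_window else params$pair_window
  xyzs <- as.matrix(sites[, c("x", "y", "z")])
  for (i in seq_len(n - 1)) {
    d_all <- dist_to_point(xyzs[(i + 1):n, , drop = FALSE], xyzs[i, ])
    for (jo in which(d_all > win[1] & d_all < win[2])) {
      j <- i + jo
      if (!pair_eligible(sites[i, ], sites[j, ], params)) next
      excl <- match(c(sites$atom_idx[i], sites$atom_idx[j]), heavy_rows)
      pl <- build_water_for_pair(sites[i, ], sites[j, ], params, energy,
                                 heavy_xyz, excl[!is.na(excl)])
      if (nrow(pl)) out[[length(out) + 1]] <- pl
    }
  }
  if (!length(out)) return(empty_placements())
  merge_waters(dplyr::bind_rows(out), params$merge_radius)
}

# greedy de-duplication: best (lowest summed energy) water wins its
# merge-radius neighbourhood
merge_waters <- function(placements, merge_radius) {
  if (nrow(placements) < 2) {
    placements$water_id <- seq_len(nrow(placements))
    return(placements)
  }
  ord <- order(placements$energy_i + placements$energy_j,
               placements$ox, placements$oy, placements$oz)
  placements <- placements[ord, ]
  xyz <- as.matrix(placements[, c("ox", "oy", "oz")])
  kept <- integer(0)
  for (r in seq_len(nrow(placements))) {
    if (!length(kept) ||
        min(dist_to_point(xyz[kept, , drop = FALSE], xyz[r, ])) >= merge_radius)
      kept <- c(kept, r)
  }
  placements <- placements[kept, ]
  placements$water_id <- seq_len(nrow(placements))
  placements
}
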