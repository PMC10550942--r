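#' Polar-site classification and hydrogen-bond direction vectors
#'
#' Every oxygen and nitrogen of protein side chains, the backbone (carbonyl
#' oxygen as acceptor, amide nitrogen as donor) and ligand molecules is turned
#' into a *polar site*: a record carrying its donor/acceptor role, sp2/sp3
#' hybridisation, rebuilt polar hydrogens and the unit direction vectors along
#' which it ideally donates (X-H axis) or accepts (lone-pair axis) a hydrogen
#' bond. Sulphur is not considered. The assignment is driven by a bundled
#' plain-text chemotype table (`inst/extdata/chemotypes.tsv`) which users can
#' override.
#'
#' @name chemistry
NULL

NH_BOND <- 1.01
OH_BOND <- 0.96

chemotype_table <- local({
  cache <- NULL
  function(path = NULL) {
    if (is.null(path) && !is.null(cache)) return(cache)
    p <- path %||% system.file("extdata", "chemotypes.tsv", package = "aquabridge")
    tab <- utils::read.delim(p, stringsAsFactors = FALSE)
    if (is.null(path)) cache <<- tab
    tab
  }
})

#' Classify polar sites of a structure
#'
#' @param atoms an atom tibble (hydrogens already stripped on read).
#' @param chemotypes optional path to a replacement chemotype table.
#' @param build_hydrogens place polar hydrogens and compute direction vectors
#'   (default `TRUE`; turn off for purely distance-based analyses).
#' @return a tibble with one row per polar site: atom identity and position,
#'   `role` (donor/acceptor/both), `hyb` (sp2/sp3), `ideal_d` (2.73 Angstrom
#'   for oxygen, 2.87 for nitrogen), and list-columns `hydrogens` (k x 3
#'   matrix of rebuilt H positions), `donor_vecs` and `acceptor_vecs`
#'   (unit direction vectors as k x 3 matrices).
#' @export
classify_polar_sites <- function(atoms, chemotypes = NULL, build_hydrogens = TRUE) {
  tab <- chemotype_table(chemotypes)
  xyz <- atoms_xyz(atoms)
  n <- nrow(atoms)
  rows <- list()
  skipped <- character(0)

  protein <- !atoms$is_water & !atoms$is_ligand
  aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

  find_atom <- function(chain, resno, name) {
    i <- which(atoms$chain == chain & atoms$resno == resno & atoms$name == name &
                 is.na(atoms$sym_op))
    if (!length(i)) {
      i <- which(atoms$chain == chain & atoms$resno == resno & atoms$name == name)
    }
    if (length(i)) i[1] else NA_integer_
  }

  for (i in which(protein & atoms$element %in% c("O", "N"))) {
    resname <- atoms$resname[i]; name <- atoms$name[i]
    if (!(resname %in% aa20)) {
      skipped <- c(skipped, paste0(resname, " ", name))
      next
    }
    hit <- tab[tab$resname == resname & tab$atom == name, ]
    if (!nrow(hit)) hit <- tab[tab$resname == "*" & tab$atom == name, ]
    if (!nrow(hit)) next            # apolar by table (e.g. no entry)
    if (resname == "PRO" && name == "N") next  # no amide hydrogen, no lone pair
    hit <- hit[1, ]
    parent <- if (hit$parent == "-") NA_integer_
      else find_atom(atoms$chain[i], atoms$resno[i], hit$parent)
    ref <- if (hit$ref == "-") NA_integer_
      else if (hit$ref == "-C") find_atom(atoms$chain[i], atoms$resno[i] - 1, "C")
      else find_atom(atoms$chain[i], atoms$resno[i], hit$ref)
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom_idx = i, element = atoms$element[i], name = name, resname = resname,
      chain = atoms$chain[i], resno = atoms$resno[i],
      x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3],
      role = hit$role, hyb = hit$hyb, ideal_d = hit$ideal_d,
      nbond = hit$nbond, h_build = hit$h_build,
      parent_idx = parent, ref_idx = ref, is_ligand_site = FALSE)
  }

  # water oxygens: polar, sp3, both roles; no frame (hydrogens unknown)
  for (i in which(atoms$is_water & atoms$element == "O")) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom_idx = i, element = "O", name = atoms$name[i], resname = atoms$resname[i],
      chain = atoms$chain[i], resno = atoms$resno[i],
      x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3],
      role = "both", hyb = "sp3", ideal_d = 2.73, nbond = 0L, h_build = "none",
      parent_idx = NA_integer_, ref_idx = NA_integer_, is_ligand_site = FALSE)
  }

  # ligand polar atoms: chemotype inferred from bonded geometry with
  # element-based fallbacks (O: both/sp3, N: donor/sp2)
  for (i in which(atoms$is_ligand & atoms$element %in% c("O", "N"))) {
    lig <- ligand_chemotype(i, atoms, xyz)
    if (is.null(lig)) {
      skipped <- c(skipped, paste0(atoms$resname[i], " ", atoms$name[i]))
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      atom_idx = i, element = atoms$element[i], name = atoms$name[i],
      resname = atoms$resname[i], chain = atoms$chain[i], resno = atoms$resno[i],
      x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3],
      role = lig$role, hyb = lig$hyb,
      ideal_d = if (atoms$element[i] == "N") 2.87 else 2.73,
      nbond = lig$nbond, h_build = lig$h_build,
      parent_idx = lig$parent, ref_idx = lig$ref, is_ligand_site = TRUE)
  }

  if (length(skipped))
    warning("unknown chemotype, skipped: ", paste(unique(skipped), collapse = ", "),
            call. = FALSE)
  if (!length(rows)) {
    return(tibble::tibble(
      site_id = integer(), atom_idx = integer(), element = character(),
      name = character(), resname = character(), chain = character(),
      resno = integer(), x = numeric(), y = numeric(), z = numeric(),
      role = character(), hyb = character(), ideal_d = numeric(),
      hydrogens = list(), donor_vecs = list(), acceptor_vecs = list(),
      is_ligand_site = logical()))
  }
  sites <- dplyr::bind_rows(rows)
  sites$site_id <- seq_len(nrow(sites))
  if (build_hydrogens) {
    sites <- build_polar_hydrogens(sites, atoms)
    sites <- add_orbital_vectors(sites, atoms)
  } else {
    sites$hydrogens <- rep(list(matrix(numeric(0), 0, 3)), nrow(sites))
    sites$donor_vecs <- rep(list(matrix(numeric(0), 0, 3)), nrow(sites))
    sites$acceptor_vecs <- rep(list(matrix(numeric(0), 0, 3)), nrow(sites))
  }
  sites
}

# bonded-geometry chemotype inference for ligand O/N
ligand_chemotype <- function(i, atoms, xyz) {
  heavy <- which(atoms$element != "H" & seq_len(nrow(atoms)) != i)
  d <- dist_to_point(xyz[heavy, , drop = FALSE], xyz[i, ])
  nb <- heavy[d <= 1.8]
  if (!length(nb)) return(NULL)
  nbd <- d[d <= 1.8]
  parent <- nb[which.min(nbd)]
  # a neighbour of the parent other than the site itself, for the plane frame
  pd <- dist_to_point(xyz, xyz[parent, ])
  cand <- setdiff(which(pd <= 1.8 & pd > 0.1), i)
  ref <- if (length(cand)) cand[1] else NA_integer_
  el <- atoms$element[i]
  if (el == "O") {
    if (length(nb) >= 2)         # ether / ester bridge oxygen
      return(list(role = "acceptor", hyb = "sp3", parent = parent,
                  ref = nb[order(dist_to_point(xyz[nb, , drop = FALSE], xyz[i, ]))][2],
                  nbond = 2L, h_build = "none"))
    if (min(nbd) < 1.28)         # carbonyl-length bond
      return(list(role = "acceptor", hyb = "sp2", parent = parent, ref = ref,
                  nbond = 1L, h_build = "none"))
    return(list(role = "both", hyb = "sp3", parent = parent, ref = ref,
                nbond = 1L, h_build = "hydroxyl1"))
  }
  # nitrogen
  if (length(nb) >= 3) {
    nrm <- unitv(vcross(xyz[nb[2], ] - xyz[nb[1], ], xyz[nb[3], ] - xyz[nb[1], ]))
    h <- abs(sum((xyz[i, ] - xyz[nb[1], ]) * nrm))
    if (h < 0.3) return(NULL)    # planar tertiary N: no H, no free lone pair
    return(list(role = "donor", hyb = "sp3", parent = parent, ref = ref,
                nbond = 3L, h_build = "none"))
  }
  if (length(nb) == 2)           # aromatic ring nitrogen, pyridine-like
    return(list(role = "acceptor", hyb = "sp2", parent = nb[1], ref = nb[2],
                nbond = 2L, h_build = "none"))
  list(role = "donor", hyb = "sp2", parent = parent, ref = ref,
       nbond = 1L, h_build = "amide2")
}

#' Build polar hydrogens for classified sites
#'
#' Amide, guanidinium, ring and ammonium hydrogens are placed at ideal
#' geometry from the site's bonded frame. Rotatable hydroxyls (Ser/Thr/Tyr and
#' ligand hydroxyls) are sampled at staggered torsions (60 degree steps) and
#' fixed at the orientation with the best summed hydrogen-bond energy to
#' neighbouring polar sites; ties and the no-neighbour case take the first
#' staggered position. Sites whose frame atoms are missing are demoted to
#' acceptor-only (or dropped for pure donors) with a warning.
#'
#' @param sites the polar-site tibble from [classify_polar_sites()].
#' @param atoms the atom tibble the sites came from.
#' @return `sites` with the `hydrogens` list-column filled.
#' @export
build_polar_hydrogens <- function(sites, atoms) {
  xyz <- atoms_xyz(atoms)
  n <- nrow(sites)
  hyd <- rep(list(matrix(numeric(0), 0, 3)), n)
  demoted <- character(0)
  drop <- logical(n)
  hydroxyl_rows <- integer(0)

  for (r in seq_len(n)) {
    hb <- sites$h_build[r]
    if (hb == "none") next
    s <- c(sites$x[r], sites$y[r], sites$z[r])
    p_i <- sites$parent_idx[r]; r_i <- sites$ref_idx[r]
    if (is.na(p_i) || is.na(r_i)) {
      demoted <- c(demoted, paste0(sites$resname[r], sites$resno[r], ":", sites$name[r]))
      if (sites$role[r] == "donor") drop[r] <- TRUE else sites$role[r] <- "acceptor"
      sites$h_build[r] <- "none"
      next
    }
    p <- xyz[p_i, ]; rf <- xyz[r_i, ]
    blen <- if (sites$element[r] == "O") OH_BOND else NH_BOND
    hyd[[r]] <- switch(hb,
      backbone_amide = ,
      ring1 = {
        # H on the bisector opposite the two heavy neighbours, in their plane
        u <- -(unitv(p - s) + unitv(rf - s))
        matrix(s + blen * unitv(u), 1, 3)
      },
      amide2 = rbind(
        nerf_place(rf, p, s, blen, 120, 0),
        nerf_place(rf, p, s, blen, 120, 180)),
      amine3 = rbind(
        nerf_place(rf, p, s, blen, 109.5, 60),
        nerf_place(rf, p, s, blen, 109.5, 180),
        nerf_place(rf, p, s, blen, 109.5, 300)),
      hydroxyl1 = {
        hydroxyl_rows <- c(hydroxyl_rows, r)
        matrix(numeric(0), 0, 3)   # placed in the second pass below
      },
      stop("unknown hydrogen-building rule: ", hb))
  }

  # second pass: rotatable hydroxyls, oriented against already-placed sites
  for (r in hydroxyl_rows) {
    if (drop[r]) next
    s <- c(sites$x[r], sites$y[r], sites$z[r])
    p <- xyz[sites$parent_idx[r], ]; rf <- xyz[sites$ref_idx[r], ]
    cand <- lapply(c(60, 120, 180, 240, 300, 360), function(tor)
      nerf_place(rf, p, s, OH_BOND, 109.5, tor))
    scores <- vapply(cand, function(h) hydroxyl_score(s, h, r, sites), numeric(1))
    hyd[[r]] <- matrix(cand[[which.min(scores)]], 1, 3)
  }

  if (length(demoted))
    warning("missing frame atoms; demoted/dropped: ",
            paste(demoted, collapse = ", "), call. = FALSE)
  sites$hydrogens <- hyd
  sites[!drop, ]
}

# summed directional-H-bond score of a candidate hydroxyl H against
# neighbouring polar heavy atoms (lower = better); deterministic
hydroxyl_score <- function(o_pos, h_pos, row, sites) {
  others <- sites[sites$atom_idx != sites$atom_idx[row], ]
  if (!nrow(others)) return(0)
  d <- sqrt((others$x - o_pos[1])^2 + (others$y - o_pos[2])^2 + (others$z - o_pos[3])^2)
  near <- which(d > 0.1 & d <= 3.5 & others$role %in% c("acceptor", "both"))
  if (!length(near)) return(0)
  e <- 0
  for (k in near) {
    xk <- c(others$x[k], others$y[k], others$z[k])
    cosang <- sum(unitv(h_pos - o_pos) * unitv(xk - o_pos))
    if (cosang <= 0) next
    e <- e + hb_distance_term(d[k], 2.73) * cosang^2 * (-5)
  }
  e
}

#' Direction (orbital) vectors of one polar site
#'
#' Donors contribute one unit vector per attached hydrogen (heavy atom to H);
#' sp2 acceptors two in-plane lone pairs at 120 degrees from the parent bond
#' (one bisector lone pair for ring nitrogens with two bonded neighbours);
#' sp3 acceptors the tetrahedral lone pairs completing the valence around the
#' existing bonds and hydrogens. Dual-role sites contribute both sets, the
#' acceptor set computed in relation to the placed hydrogen.
#'
#' @param site one row of the polar-site tibble.
#' @return a k x 3 matrix of unit vectors.
#' @export
orbital_vectors <- function(site) {
  stopifnot(nrow(site) == 1)
  rbind(site$donor_vecs[[1]], site$acceptor_vecs[[1]])
}

add_orbital_vectors <- function(sites, atoms) {
  xyz <- atoms_xyz(atoms)
  n <- nrow(sites)
  dv <- rep(list(matrix(numeric(0), 0, 3)), n)
  av <- rep(list(matrix(numeric(0), 0, 3)), n)
  for (r in seq_len(n)) {
    s <- c(sites$x[r], sites$y[r], sites$z[r])
    H <- sites$hydrogens[[r]]
    if (sites$role[r] %in% c("donor", "both") && nrow(H)) {
      dv[[r]] <- t(apply(H, 1, function(h) unitv(h - s)))
    }
    if (sites$role[r] %in% c("acceptor", "both")) {
      av[[r]] <- acceptor_lone_pairs(s, sites[r, ], xyz)
    }
  }
  sites$donor_vecs <- dv
  sites$acceptor_vecs <- av
  sites
}

acceptor_lone_pairs <- function(s, site, xyz) {
  p_i <- site$parent_idx; r_i <- site$ref_idx
  if (is.na(p_i)) return(matrix(numeric(0), 0, 3))  # e.g. bare water oxygen
  p <- xyz[p_i, ]
  if (site$hyb == "sp2") {
    if (site$nbond >= 2) {
      # ring nitrogen: one in-plane lone pair on the bisector
      rf <- xyz[r_i, ]
      return(matrix(unitv(-(unitv(p - s) + unitv(rf - s))), 1, 3))
    }
    if (is.na(r_i)) {
      # no second frame atom (isolated ligand carbonyl): the lone-pair plane
      # is undetermined; use a deterministic arbitrary plane
      nrm <- any_perp(p - s)
    } else {
      rf <- xyz[r_i, ]
      nrm <- vcross(p - s, rf - p)
      if (vnorm(nrm) < 1e-6)
        stop("degenerate (collinear) frame for sp2 lone pairs at ",
             site$resname, site$resno, ":", site$name, call. = FALSE)
      nrm <- unitv(nrm)
    }
    u <- unitv(p - s)
    return(rbind(rotate_about(u, nrm, 120), rotate_about(u, nrm, -120)))
  }
  # sp3: complete the tetrahedron around existing bonds/hydrogens
  b1 <- unitv(p - s)
  H <- site$hydrogens[[1]]
  b2 <- if (!is.null(H) && nrow(H)) unitv(H[1, ] - s)
        else if (!is.na(r_i) && site$nbond >= 2) unitv(xyz[r_i, ] - s)
        else NULL
  if (is.null(b2)) {
    # single known bond: full cone is open; emit three staggered lone pairs
    perp <- any_perp(b1)
    return(t(vapply(c(0, 120, 240), function(a)
      rotate_about(rotate_about(-b1, perp, 180 - 109.47), b1, a), numeric(3))))
  }
  m <- -unitv(b1 + b2)
  ax <- unitv(vcross(b1, b2))
  half <- deg2rad(109.47 / 2)
  rbind(cos(half) * m + sin(half) * ax,
        cos(half) * m - sin(half) * ax)
}
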