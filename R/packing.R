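#' Side-chain packing with solvated rotamers
#'
#' A deliberately small packing engine: rotamers from the bundled library are
#' enumerated at each design position, bridging waters are constructed for
#' every cross-position rotamer pair (and rotamer-ligand / rotamer-fixed
#' pairs), accepted waters are duplicated onto both bridged rotamers as
#' solvated copies kept alongside the unsolvated originals, and the best
#' assignment is found by Goldstein dead-end elimination followed by
#' Monte-Carlo simulated annealing. The force field is a soft steric term
#' plus the directional hydrogen-bond energy; it makes no claim of parity
#' with any full protein force field.
#'
#' @name packing
NULL

#' Assemble a packing problem
#'
#' @param atoms atom tibble after [prepare_for_rebuild()] /
#'   [prepare_ligand_pocket()]; its `design_positions` attribute (or the
#'   `positions` argument) names the residues to rebuild.
#' @param positions tibble with columns chain, resno, resname; defaults to
#'   the `design_positions` attribute.
#' @param params [geometry_params()].
#' @param energy [hbond_params()].
#' @param expand_chi1 emit each rotamer also at chi1 +/- 10 degrees.
#' @param ligand_pose optional ligand atom tibble reinstated as fixed context
#'   (defaults to the `ligand_pose` attribute, if present).
#' @return a list of class `aqua_packing_problem`.
#' @export
packing_problem <- function(atoms, positions = NULL,
                            params = geometry_params(),
                            energy = hbond_params(),
                            expand_chi1 = FALSE, ligand_pose = NULL) {
  positions <- positions %||% attr(atoms, "design_positions")
  if (is.null(positions) || !nrow(positions))
    stop("no design positions given", call. = FALSE)
  if ("sym_op" %in% names(positions))
    positions <- positions[is.na(positions$sym_op), , drop = FALSE]
  ligand_pose <- ligand_pose %||% attr(atoms, "ligand_pose")
  context <- atoms
  if (!is.null(ligand_pose))
    context <- keep_attrs(dplyr::bind_rows(context, ligand_pose), atoms)
  rotamers <- vector("list", nrow(positions))
  keep <- logical(nrow(positions))
  for (p in seq_len(nrow(positions))) {
    pos <- positions[p, ]
    bb <- atoms[atoms$chain == pos$chain & atoms$resno == pos$resno &
                  atoms$name %in% c("N", "CA", "C"), ]
    if (nrow(bb) < 3) next
    rotamers[[p]] <- enumerate_rotamers(atoms, pos$chain, pos$resno,
                                        pos$resname, expand_chi1)
    keep[p] <- length(rotamers[[p]]) > 0
  }
  structure(list(
    context = context, positions = positions[keep, , drop = FALSE],
    rotamers = rotamers[keep], params = params, energy = energy,
    solvated = FALSE),
    class = "aqua_packing_problem")
}

#' @export
print.aqua_packing_problem <- function(x, ...) {
  cat("Packing problem: ", nrow(x$positions), " design positions, ",
      paste(vapply(x$rotamers, length, integer(1)), collapse = "/"),
      " rotamers", if (x$solvated) " (solvated)", "\n", sep = "")
  invisible(x)
}

# context atoms that are not part of a design position (side chains there
# are represented by the rotamers themselves)
fixed_context <- function(problem) {
  ctx <- problem$context
  key <- paste(ctx$chain, ctx$resno)
  pos_key <- paste(problem$positions$chain, problem$positions$resno)
  ctx[!(key %in% pos_key & is.na(ctx$sym_op) & !ctx$is_ligand), ]
}

#' Solvate one rotamer pair
#'
#' Constructs, gates and clash-filters bridging waters for every eligible
#' cross-rotamer polar-site pair (main-chain atoms included). Waters bridging
#' to a ligand or fixed atom are attributed to the amino-acid rotamer only.
#'
#' @param rot_i,rot_j `aqua_rotamer` objects (from different positions).
#' @param params [geometry_params()].
#' @param energy [hbond_params()].
#' @param context_atoms optional fixed surroundings used for clash checks.
#' @return a water-placement tibble with columns as in
#'   [solvate_structure()] plus `bridge_id`.
#' @export
solvate_pair <- function(rot_i, rot_j, params = geometry_params(),
                         energy = hbond_params(), context_atoms = NULL) {
  sites_i <- rotamer_sites(rot_i)
  sites_j <- rotamer_sites(rot_j)
  if (!nrow(sites_i) || !nrow(sites_j)) return(empty_placements())
  clash_atoms <- dplyr::bind_rows(
    rot_i$atoms, rot_j$atoms,
    if (!is.null(context_atoms)) context_atoms[, names(rot_i$atoms)])
  heavy <- clash_atoms[clash_atoms$element != "H", ]
  heavy_xyz <- atoms_xyz(heavy)
  out <- list()
  for (a in seq_len(nrow(sites_i))) for (b in seq_len(nrow(sites_j))) {
    si <- sites_i[a, ]; sj <- sites_j[b, ]
    if (!pair_eligible(si, sj, params)) next
    excl <- which((abs(heavy$x - si$x) < 1e-9 & abs(heavy$y - si$y) < 1e-9) |
                    (abs(heavy$x - sj$x) < 1e-9 & abs(heavy$y - sj$y) < 1e-9))
    pl <- build_water_for_pair(si, sj, params, energy, heavy_xyz, excl)
    if (nrow(pl)) {
      pl$bridge_id <- paste0(rot_i$chain, rot_i$resno, ":", si$name, "-",
                             rot_j$chain, rot_j$resno, ":", sj$name,
                             "/v", pl$orientation_variant)
      out[[length(out) + 1]] <- pl
    }
  }
  if (!length(out)) return(empty_placements())
  dplyr::bind_rows(out)
}

# polar sites of a single rotamer; frame-atom warnings (chain termini) are
# expected here and silenced
rotamer_sites <- function(rot) {
  suppressWarnings(classify_polar_sites(rot$atoms))
}

#' Attach bridging waters to the rotamer sets of a problem
#'
#' Runs [solvate_pair()] over every cross-position rotamer pair and every
#' rotamer/fixed-context pair. Each accepted rotamer-rotamer water is
#' duplicated: both partner rotamers gain a solvated copy carrying the water,
#' and the unsolvated originals are retained. Waters bridging to ligand or
#' fixed atoms solvate only the amino-acid rotamer.
#'
#' @param problem an `aqua_packing_problem`.
#' @param max_waters_per_rotamer cap on solvated copies spawned per original
#'   rotamer (best-energy waters first).
#' @return the problem with enlarged rotamer sets and `solvated = TRUE`.
#' @export
build_solvated_rotamers <- function(problem, max_waters_per_rotamer = 4) {
  np <- length(problem$rotamers)
  fixed <- fixed_context(problem)
  fixed_sites <- suppressWarnings(classify_polar_sites(fixed))
  fixed_sites <- fixed_sites[!fixed$is_water[fixed_sites$atom_idx], ]
  new_rotamers <- problem$rotamers
  # collect candidate waters per (position, rotamer index)
  cand <- vector("list", np)
  for (p in seq_len(np)) cand[[p]] <- vector("list", length(problem$rotamers[[p]]))

  if (np >= 2) {
    for (p in seq_len(np - 1)) for (q in (p + 1):np) {
      for (a in seq_along(problem$rotamers[[p]])) {
        for (b in seq_along(problem$rotamers[[q]])) {
          ra <- problem$rotamers[[p]][[a]]; rb <- problem$rotamers[[q]][[b]]
          pl <- solvate_pair(ra, rb, problem$params, problem$energy, fixed)
          if (!nrow(pl)) next
          pl$partner_pos <- q; pl$partner_key <- conformer_key(rb)
          cand[[p]][[a]] <- dplyr::bind_rows(cand[[p]][[a]], pl)
          pl2 <- pl
          pl2$partner_pos <- p; pl2$partner_key <- conformer_key(ra)
          # swap leg bookkeeping so energy_i is always the own-rotamer leg
          pl2 <- swap_legs(pl2)
          cand[[q]][[b]] <- dplyr::bind_rows(cand[[q]][[b]], pl2)
        }
      }
    }
  }
  # rotamer vs ligand / fixed backbone: water attached to the rotamer only
  if (nrow(fixed_sites)) {
    for (p in seq_len(np)) for (a in seq_along(problem$rotamers[[p]])) {
      ra <- problem$rotamers[[p]][[a]]
      pl <- solvate_fixed(ra, fixed_sites, fixed, problem$params, problem$energy)
      if (nrow(pl)) {
        pl$partner_pos <- NA_integer_; pl$partner_key <- NA_character_
        cand[[p]][[a]] <- dplyr::bind_rows(cand[[p]][[a]], pl)
      }
    }
  }
  for (p in seq_len(np)) for (a in seq_along(problem$rotamers[[p]])) {
    pl <- cand[[p]][[a]]
    if (is.null(pl) || !nrow(pl)) next
    pl <- pl[!duplicated(pl$bridge_id), , drop = FALSE]
    pl <- pl[order(pl$energy_i + pl$energy_j), , drop = FALSE]
    pl <- utils::head(pl, max_waters_per_rotamer)
    for (r in seq_len(nrow(pl))) {
      solv <- problem$rotamers[[p]][[a]]
      solv$waters <- pl[r, , drop = FALSE]
      solv$bridge_ids <- pl$bridge_id[r]
      new_rotamers[[p]] <- c(new_rotamers[[p]], list(solv))
    }
  }
  problem$rotamers <- new_rotamers
  problem$solvated <- TRUE
  problem
}

swap_legs <- function(pl) {
  tmp <- pl$energy_i; pl$energy_i <- pl$energy_j; pl$energy_j <- tmp
  tmp <- pl$site_i; pl$site_i <- pl$site_j; pl$site_j <- tmp
  tmp <- pl$atom_i; pl$atom_i <- pl$atom_j; pl$atom_j <- tmp
  tmp <- pl$donates_i; pl$donates_i <- pl$donates_j; pl$donates_j <- tmp
  pl
}

# bridges between one rotamer and the fixed context (ligand, backbone,
# non-design side chains)
solvate_fixed <- function(rot, fixed_sites, fixed, params, energy) {
  sites_r <- rotamer_sites(rot)
  if (!nrow(sites_r)) return(empty_placements())
  clash_atoms <- dplyr::bind_rows(rot$atoms, fixed[, names(rot$atoms)])
  heavy <- clash_atoms[clash_atoms$element != "H", ]
  heavy_xyz <- atoms_xyz(heavy)
  out <- list()
  for (a in seq_len(nrow(sites_r))) for (b in seq_len(nrow(fixed_sites))) {
    si <- sites_r[a, ]; sj <- fixed_sites[b, ]
    if (!pair_eligible(si, sj, params)) next
    excl <- which((abs(heavy$x - si$x) < 1e-9 & abs(heavy$y - si$y) < 1e-9) |
                    (abs(heavy$x - sj$x) < 1e-9 & abs(heavy$y - sj$y) < 1e-9))
    pl <- build_water_for_pair(si, sj, params, energy, heavy_xyz, excl)
    if (nrow(pl)) {
      pl$bridge_id <- paste0(rot$chain, rot$resno, ":", si$name, "-fixed:",
                             sj$chain, sj$resno, ":", sj$name,
                             "/v", pl$orientation_variant)
      out[[length(out) + 1]] <- pl
    }
  }
  if (!length(out)) return(empty_placements())
  dplyr::bind_rows(out)
}

# ---- energies -------------------------------------------------------------

LJ_RMIN <- 3.4
LJ_EPS <- 0.1
LJ_CUTOFF <- 6
PAIR_CUTOFF <- 10

steric_energy <- function(xyz_a, xyz_b) {
  if (!nrow(xyz_a) || !nrow(xyz_b)) return(0)
  e <- 0
  for (i in seq_len(nrow(xyz_a))) {
    d <- dist_to_point(xyz_b, xyz_a[i, ])
    d <- d[d < LJ_CUTOFF]
    if (!length(d)) next
    d <- pmax(d, 0.8)            # soft core: cap the singularity
    e <- e + sum(LJ_EPS * ((LJ_RMIN / d)^12 - 2 * (LJ_RMIN / d)^6))
  }
  min(e, 1e4)
}

# side-chain (beyond backbone) heavy atoms plus attached water oxygens
rotamer_interaction_xyz <- function(rot, exclude_partners = NULL) {
  sc <- rot$atoms[!(rot$atoms$name %in% c("N", "CA", "C", "O")) &
                    rot$atoms$element != "H", ]
  xyz <- atoms_xyz(sc)
  if (nrow(rot$waters))
    xyz <- rbind(xyz, as.matrix(rot$waters[, c("ox", "oy", "oz")]))
  xyz
}

#' Pairwise packing energy of two rotamers
#'
#' Soft Lennard-Jones steric term over cross heavy atoms (including attached
#' water oxygens) plus the hydrogen-bond credit of waters bridging between
#' the two rotamers. When both rotamers carry copies of the same duplicated
#' bridge, each copy contributes half of the bridge energy so the physical
#' water is counted once.
#'
#' @param rot_a,rot_b `aqua_rotamer` objects at distinct positions.
#' @param pos_a,pos_b the rotamers' position indices within the problem (used
#'   to recognise bridge partners); optional.
#' @return energy in kcal/mol.
#' @export
pairwise_energy <- function(rot_a, rot_b, pos_a = NA, pos_b = NA) {
  ca <- rotamer_centroid(rot_a); cb <- rotamer_centroid(rot_b)
  if (vnorm(ca - cb) > PAIR_CUTOFF + 8) return(0)
  xa <- rotamer_interaction_xyz(rot_a); xb <- rotamer_interaction_xyz(rot_b)
  if (!nrow(xa) || !nrow(xb)) return(0)
  if (min_cross_dist(xa, xb) > PAIR_CUTOFF) return(0)
  e <- steric_pair_excluding_bridges(rot_a, rot_b, xa, xb)
  e + bridge_credit(rot_a, pos_b, rot_b) + bridge_credit(rot_b, pos_a, rot_a)
}

conformer_key <- function(rot) {
  paste0(rot$resname, "/", paste(round(rot$chi, 1), collapse = ","))
}

min_cross_dist <- function(xa, xb) {
  m <- Inf
  for (i in seq_len(nrow(xa))) m <- min(m, min(dist_to_point(xb, xa[i, ])))
  m
}

# steric term; water-oxygen/partner-site contacts are intentional H-bond
# contacts, so cross pairs closer than 2.4 A to a bridge water are skipped
steric_pair_excluding_bridges <- function(rot_a, rot_b, xa, xb) {
  na_sc <- nrow(xa) - nrow(rot_a$waters)
  nb_sc <- nrow(xb) - nrow(rot_b$waters)
  e <- steric_energy(xa[seq_len(na_sc), , drop = FALSE],
                     xb[seq_len(nb_sc), , drop = FALSE])
  # waters vs partner side chain: only penalise genuine overlap (< 2.2 A)
  wat_a <- xa[setdiff(seq_len(nrow(xa)), seq_len(na_sc)), , drop = FALSE]
  wat_b <- xb[setdiff(seq_len(nrow(xb)), seq_len(nb_sc)), , drop = FALSE]
  for (w in list(list(wat_a, xb[seq_len(nb_sc), , drop = FALSE]),
                 list(wat_b, xa[seq_len(na_sc), , drop = FALSE]))) {
    if (nrow(w[[1]]) && nrow(w[[2]])) {
      for (i in seq_len(nrow(w[[1]]))) {
        d <- dist_to_point(w[[2]], w[[1]][i, ])
        e <- e + sum(50 * pmax(0, 2.2 - d[d < 2.2]))
      }
    }
  }
  e
}

# hydrogen-bond credit of rot's waters whose bridge partner conformer is the
# one actually chosen at the partner position; half weight when the partner
# carries the duplicate copy (so the physical water is counted once)
bridge_credit <- function(rot, partner_pos, partner_rot) {
  if (!nrow(rot$waters)) return(0)
  w <- rot$waters
  cred <- 0
  pk <- conformer_key(partner_rot)
  for (r in seq_len(nrow(w))) {
    if (is.na(w$partner_pos[r])) next       # ligand/fixed bridge: in self energy
    if (!is.na(partner_pos) && w$partner_pos[r] == partner_pos &&
        w$partner_key[r] == pk) {
      dup <- w$bridge_id[r] %in% partner_rot$bridge_ids
      cred <- cred + (if (dup) 0.5 else 1) * (w$energy_i[r] + w$energy_j[r])
    }
  }
  cred
}

rotamer_centroid <- function(rot) {
  colMeans(atoms_xyz(rot$atoms))
}

#' Self energy of a rotamer against the fixed context
#'
#' Steric term versus all fixed atoms outside the rotamer's own residue, a
#' small conformer-frequency term, and the full hydrogen-bond energy of
#' waters bridging to ligand or fixed atoms.
#'
#' @param rot an `aqua_rotamer`.
#' @param fixed fixed-context atom tibble.
#' @return energy in kcal/mol.
#' @export
self_energy <- function(rot, fixed) {
  other <- fixed[!(fixed$chain == rot$chain & fixed$resno == rot$resno &
                     is.na(fixed$sym_op)), ]
  other <- other[other$element != "H" & !other$is_water, ]
  xa <- rotamer_interaction_xyz(rot)
  e <- -0.6 * log(max(rot$freq, 1e-3))
  if (nrow(xa) && nrow(other)) {
    xb <- atoms_xyz(other)
    na_sc <- nrow(xa) - nrow(rot$waters)
    e <- e + steric_energy(xa[seq_len(na_sc), , drop = FALSE], xb)
    if (nrow(rot$waters)) {
      wxyz <- xa[setdiff(seq_len(nrow(xa)), seq_len(na_sc)), , drop = FALSE]
      # waters near fixed atoms: clash filter ran at build time; penalise
      # only strong overlap (e.g. against atoms that were not present then)
      for (i in seq_len(nrow(wxyz))) {
        d <- dist_to_point(xb, wxyz[i, ])
        e <- e + sum(50 * pmax(0, 2.2 - d[d < 2.2]))
      }
    }
  }
  if (nrow(rot$waters)) {
    fix_b <- is.na(rot$waters$partner_pos)
    e <- e + sum((rot$waters$energy_i + rot$waters$energy_j)[fix_b])
  }
  e
}

# precompute self energies and pairwise tables for DEE / MC
energy_tables <- function(problem) {
  np <- length(problem$rotamers)
  fixed <- fixed_context(problem)
  selfE <- lapply(seq_len(np), function(p)
    vapply(problem$rotamers[[p]], self_energy, numeric(1), fixed = fixed))
  pairE <- vector("list", np)
  for (p in seq_len(np)) pairE[[p]] <- vector("list", np)
  if (np >= 2) {
    for (p in seq_len(np - 1)) for (q in (p + 1):np) {
      na_ <- length(problem$rotamers[[p]]); nb_ <- length(problem$rotamers[[q]])
      M <- matrix(0, na_, nb_)
      for (a in seq_len(na_)) for (b in seq_len(nb_)) {
        M[a, b] <- pairwise_energy(problem$rotamers[[p]][[a]],
                                   problem$rotamers[[q]][[b]],
                                   pos_a = p, pos_b = q)
      }
      pairE[[p]][[q]] <- M
      pairE[[q]][[p]] <- t(M)
    }
  }
  list(self = selfE, pair = pairE)
}

assignment_energy <- function(tables, assign) {
  np <- length(assign)
  e <- sum(vapply(seq_len(np), function(p) tables$self[[p]][assign[p]], numeric(1)))
  if (np >= 2) {
    for (p in seq_len(np - 1)) for (q in (p + 1):np)
      e <- e + tables$pair[[p]][[q]][assign[p], assign[q]]
  }
  e
}

#' Goldstein dead-end elimination
#'
#' Iteratively removes rotamers that provably cannot be part of the global
#' minimum energy conformation: rotamer a at position p is eliminated if some
#' competitor b satisfies
#' `E(a) - E(b) + sum_q min_c [E(a,c) - E(b,c)] > 0`.
#'
#' @param problem an `aqua_packing_problem`.
#' @param tables optional precomputed [energy_tables()].
#' @return the problem with pruned rotamer sets (attribute `tables` carries
#'   the corresponding pruned energy tables, attribute `kept` the surviving
#'   rotamer indices per position).
#' @export
dee_goldstein <- function(problem, tables = NULL) {
  tables <- tables %||% energy_tables(problem)
  np <- length(problem$rotamers)
  alive <- lapply(problem$rotamers, function(r) rep(TRUE, length(r)))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    for (p in seq_len(np)) {
      idx <- which(alive[[p]])
      if (length(idx) < 2) next
      for (a in idx) {
        for (b in setdiff(which(alive[[p]]), a)) {
          lhs <- tables$self[[p]][a] - tables$self[[p]][b]
          for (q in seq_len(np)) {
            if (q == p) next
            cs <- which(alive[[q]])
            lhs <- lhs + min(tables$pair[[p]][[q]][a, cs] -
                               tables$pair[[p]][[q]][b, cs])
          }
          if (lhs > 1e-9) {
            alive[[p]][a] <- FALSE
            changed <- TRUE
            break
          }
        }
        if (!alive[[p]][a]) next
      }
      if (!any(alive[[p]])) stop("dead-end elimination emptied position ", p,
                                 call. = FALSE)
    }
  }
  kept <- lapply(alive, which)
  problem$rotamers <- lapply(seq_len(np), function(p)
    problem$rotamers[[p]][kept[[p]]])
  tables$self <- lapply(seq_len(np), function(p) tables$self[[p]][kept[[p]]])
  if (np >= 2) {
    for (p in seq_len(np - 1)) for (q in (p + 1):np) {
      tables$pair[[p]][[q]] <-
        tables$pair[[p]][[q]][kept[[p]], kept[[q]], drop = FALSE]
      tables$pair[[q]][[p]] <- t(tables$pair[[p]][[q]])
    }
  }
  attr(problem, "tables") <- tables
  attr(problem, "kept") <- kept
  problem
}

#' Monte-Carlo simulated annealing over the remaining rotamers
#'
#' Single-rotamer-flip Metropolis chain with a geometric cooling schedule;
#' the best assignment seen is returned. Reproducible given `seed`.
#'
#' @param problem an `aqua_packing_problem` (after [dee_goldstein()]).
#' @param seed integer RNG seed.
#' @param n_steps Metropolis steps.
#' @param t_start,t_end start/end temperatures (kcal/mol).
#' @return list with `assignment` (one rotamer index per position, relative
#'   to the problem's current rotamer lists) and `energy`.
#' @export
mc_simulated_annealing <- function(problem, seed = 1L, n_steps = 2000,
                                   t_start = 10, t_end = 0.05) {
  tables <- attr(problem, "tables") %||% energy_tables(problem)
  np <- length(problem$rotamers)
  sizes <- vapply(problem$rotamers, length, integer(1))
  if (all(sizes == 1))
    return(list(assignment = rep(1L, np),
                energy = assignment_energy(tables, rep(1L, np))))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  assign_cur <- vapply(sizes, function(s) sample.int(s, 1), integer(1))
  e_cur <- assignment_energy(tables, assign_cur)
  best <- assign_cur; e_best <- e_cur
  cool <- (t_end / t_start)^(1 / max(n_steps - 1, 1))
  temp <- t_start
  for (step in seq_len(n_steps)) {
    p <- sample.int(np, 1)
    if (sizes[p] > 1) {
      new_r <- sample.int(sizes[p], 1)
      if (new_r != assign_cur[p]) {
        delta <- tables$self[[p]][new_r] - tables$self[[p]][assign_cur[p]]
        for (q in seq_len(np)) {
          if (q == p) next
          delta <- delta + tables$pair[[p]][[q]][new_r, assign_cur[q]] -
            tables$pair[[p]][[q]][assign_cur[p], assign_cur[q]]
        }
        if (delta <= 0 || stats::runif(1) < exp(-delta / temp)) {
          assign_cur[p] <- new_r
          e_cur <- e_cur + delta
          if (e_cur < e_best - 1e-12) { best <- assign_cur; e_best <- e_cur }
        }
      }
    }
    temp <- temp * cool
  }
  list(assignment = best, energy = e_best)
}

#' Emit the final model for an assignment
#'
#' Backbone/fixed context plus the chosen rotamer side chains, with the
#' attached waters de-duplicated (duplicated bridge copies collapse to one
#' HOH; any remaining waters closer than the merge radius collapse to the
#' lower-energy one).
#'
#' @param problem an `aqua_packing_problem`.
#' @param assignment integer vector, one rotamer index per position.
#' @return atom tibble of the rebuilt model.
#' @export
emit_model <- function(problem, assignment) {
  fixed <- fixed_context(problem)
  np <- length(problem$rotamers)
  parts <- list(fixed)
  waters <- list()
  for (p in seq_len(np)) {
    rot <- problem$rotamers[[p]][[assignment[p]]]
    parts[[length(parts) + 1]] <- rot$atoms
    if (nrow(rot$waters)) waters[[length(waters) + 1]] <- rot$waters
  }
  model <- keep_attrs(dplyr::bind_rows(parts), problem$context)
  if (length(waters)) {
    w <- dplyr::bind_rows(waters)
    w <- w[!duplicated(w$bridge_id), , drop = FALSE]
    w <- merge_waters(w, problem$params$merge_radius)
    model <- add_waters(model, w)
  }
  model
}

#' Rebuild a prepared sphere end to end
#'
#' Enumerate rotamers at the design positions, optionally attach bridging
#' waters (during packing or posterior to it), eliminate, anneal and emit the
#' final model.
#'
#' @param prepared atom tibble from [prepare_for_rebuild()] or
#'   [prepare_ligand_pocket()].
#' @param run a run configuration from [resolve_preset()].
#' @return atom tibble of the rebuilt model with attribute `waters` (the
#'   placement tibble).
#' @export
rebuild_model <- function(prepared, run = resolve_preset("run1")) {
  problem <- packing_problem(prepared, params = run$geometry,
                             energy = run$energy,
                             expand_chi1 = isTRUE(run$expand_chi1))
  if (run$waters && run$mode != "posterior")
    problem <- build_solvated_rotamers(problem)
  problem <- dee_goldstein(problem)
  fit <- mc_simulated_annealing(problem, seed = run$seed)
  model <- emit_model(problem, fit$assignment)
  if (run$waters && run$mode == "posterior") {
    w <- solvate_structure(model, run$geometry, run$energy)
    model <- add_waters(model, w)
    attr(model, "waters") <- w
  } else {
    attr(model, "waters") <- model_waters(model)
  }
  attr(model, "energy") <- fit$energy
  model
}

# recover a placement-like tibble from the HOH records of a model
model_waters <- function(model) {
  w <- model[model$is_water & model$element == "O", ]
  tibble::tibble(ox = w$x, oy = w$y, oz = w$z)
}
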