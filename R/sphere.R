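#' Reference spheres
#'
#' A reference sphere is the 20 Angstrom atom neighbourhood around a central
#' crystallographic water, with an 8 Angstrom design region (residues
#' truncated and rebuilt) and a 6 Angstrom evaluation border for water-mesh
#' scoring.
#'
#' @name sphere
NULL

#' Extract a reference sphere around a central water
#'
#' @param atoms atom tibble (symmetry-expanded if needed).
#' @param center position of the central water oxygen (length-3) or an atom
#'   index into `atoms`.
#' @param radius sphere radius, Angstrom (closed ball: atoms at exactly the
#'   radius are included).
#' @param design_radius residues with any atom inside this radius of the
#'   centre are rebuilt.
#' @param eval_radius border radius for water-mesh evaluation.
#' @return a list of class `aqua_sphere`: `atoms`, `center`, `radius`,
#'   `design_radius`, `eval_radius`.
#' @export
extract_sphere <- function(atoms, center, radius = 20,
                           design_radius = 8, eval_radius = 6) {
  if (length(center) == 1) center <- as.numeric(atoms[center, c("x", "y", "z")])
  d <- dist_to_point(atoms_xyz(atoms), center)
  sub <- keep_attrs(atoms[d <= radius, ], atoms)
  is_central <- sub$is_water & sub$element == "O" &
    dist_to_point(atoms_xyz(sub), center) < 1e-6
  if (sum(is_central) != 1)
    warning("central water present ", sum(is_central), " times in sphere",
            call. = FALSE)
  structure(list(atoms = sub, center = center, radius = radius,
                 design_radius = design_radius, eval_radius = eval_radius),
            class = "aqua_sphere")
}

#' @export
print.aqua_sphere <- function(x, ...) {
  cat("Reference sphere: ", nrow(x$atoms), " atoms within ", x$radius,
      " A of (", paste(round(x$center, 2), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Strip waters and truncate the design region to alanine/glycine
#'
#' Removes all waters and reduces every residue having at least one atom
#' within the design radius of the sphere centre to its backbone plus CB
#' (glycine: backbone only). The original residue types of the truncated
#' positions are kept as the `design_positions` attribute so the side chains
#' can be rebuilt with the correct sequence.
#'
#' @param sphere an `aqua_sphere`.
#' @return atom tibble ready for rebuilding, with attribute
#'   `design_positions` (tibble: chain, resno, resname).
#' @export
prepare_for_rebuild <- function(sphere) {
  atoms <- sphere$atoms
  atoms <- keep_attrs(atoms[!atoms$is_water, ], sphere$atoms)
  d <- dist_to_point(atoms_xyz(atoms), sphere$center)
  res_key <- paste(atoms$chain, atoms$resno, atoms$sym_op)
  in_design <- tapply(d <= sphere$design_radius, res_key, any)
  trunc_res <- names(in_design)[in_design]
  protein <- !atoms$is_ligand
  keep <- !(res_key %in% trunc_res & protein) |
    atoms$name %in% c("N", "CA", "C", "O", "CB", "OXT")
  design <- unique(atoms[res_key %in% trunc_res & protein,
                         c("chain", "resno", "resname", "sym_op")])
  out <- keep_attrs(atoms[keep, ], atoms)
  rk <- paste(out$chain, out$resno, out$sym_op)
  trunc_prot <- rk %in% trunc_res & !out$is_ligand
  out$resname[trunc_prot] <- ifelse(out$resname[trunc_prot] == "GLY", "GLY", "ALA")
  out <- keep_attrs(out[!(trunc_prot & out$resname == "ALA" &
                            !(out$name %in% c("N", "CA", "C", "O", "CB", "OXT"))), ], out)
  attr(out, "design_positions") <- tibble::as_tibble(design)
  attr(out, "sphere_center") <- sphere$center
  out
}

#' Truncate a ligand pocket to alanine and remove the ligand
#'
#' Every amino acid with any atom closer than 6 Angstrom to any ligand atom
#' is substituted by alanine; the ligand is removed from the structure but
#' its pose is retained (attribute `ligand_pose`) as a fixed candidate
#' placement for rebuilding.
#'
#' @param atoms atom tibble containing the ligand.
#' @param ligand residue name of the ligand, or `"chain:resno"`.
#' @param cutoff truncation distance, Angstrom (default 6; strictly closer).
#' @return atom tibble with attributes `ligand_pose` and `design_positions`.
#' @export
prepare_ligand_pocket <- function(atoms, ligand, cutoff = 6) {
  if (grepl(":", ligand)) {
    parts <- strsplit(ligand, ":")[[1]]
    lig_rows <- atoms$chain == parts[1] & atoms$resno == as.integer(parts[2])
  } else {
    lig_rows <- atoms$resname == ligand
  }
  lig_rows <- lig_rows & atoms$is_ligand
  if (!any(lig_rows)) stop("ligand '", ligand, "' not found", call. = FALSE)
  lig <- atoms[lig_rows, ]
  rest <- keep_attrs(atoms[!lig_rows, ], atoms)
  lig_xyz <- atoms_xyz(lig)
  dmin <- apply(atoms_xyz(rest), 1, function(p) min(dist_to_point(lig_xyz, p)))
  res_key <- paste(rest$chain, rest$resno, rest$sym_op)
  near <- tapply(dmin < cutoff, res_key, any)
  trunc_res <- names(near)[near]
  protein <- !rest$is_ligand & !rest$is_water
  keep <- !(res_key %in% trunc_res & protein) |
    rest$name %in% c("N", "CA", "C", "O", "CB", "OXT")
  design <- unique(rest[res_key %in% trunc_res & protein,
                        c("chain", "resno", "resname", "sym_op")])
  out <- keep_attrs(rest[keep, ], rest)
  rk <- paste(out$chain, out$resno, out$sym_op)
  tp <- rk %in% trunc_res & !out$is_ligand & !out$is_water
  out$resname[tp] <- ifelse(out$resname[tp] == "GLY", "GLY", "ALA")
  attr(out, "ligand_pose") <- lig
  attr(out, "design_positions") <- tibble::as_tibble(design)
  out
}
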