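#' Atom tables
#'
#' Structures are ordinary tibbles with one row per atom and the columns
#' `eleno`, `element`, `name`, `resname`, `chain`, `resno`, `alt`, `occ`,
#' `x`, `y`, `z`, `is_water`, `is_ligand`, `sym_op`. Unit-cell parameters and
#' the space-group symbol, when known, travel as the attributes `cell`
#' (named numeric: a, b, c, alpha, beta, gamma) and `space_group`.
#'
#' @param atoms a data frame with at least `element`, `name`, `resname`,
#'   `chain`, `resno`, `x`, `y`, `z`.
#' @param cell unit-cell parameters, named numeric of length 6, or `NULL`.
#' @param space_group Hermann-Mauguin symbol, or `NULL`.
#' @return a tibble of atoms with normalised columns.
#' @export
as_structure <- function(atoms, cell = NULL, space_group = NULL) {
  atoms <- tibble::as_tibble(atoms)
  n <- nrow(atoms)
  has <- function(col) col %in% names(atoms)
  if (!has("eleno")) atoms$eleno <- seq_len(n)
  if (!has("alt")) atoms$alt <- NA_character_
  if (!has("occ")) atoms$occ <- rep(1, n)
  if (!has("element")) atoms$element <- substr(gsub("[0-9]", "", atoms$name), 1, 1)
  if (!has("is_water")) atoms$is_water <- atoms$resname %in% c("HOH", "WAT", "DOD")
  if (!has("is_ligand")) atoms$is_ligand <- rep(FALSE, n)
  if (!has("sym_op")) atoms$sym_op <- rep(NA_integer_, n)
  atoms$is_water[is.na(atoms$is_water)] <-
    atoms$resname[is.na(atoms$is_water)] %in% c("HOH", "WAT", "DOD")
  atoms$is_ligand[is.na(atoms$is_ligand)] <- FALSE
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms <- atoms[, c("eleno", "element", "name", "resname", "chain", "resno",
                     "alt", "occ", "x", "y", "z", "is_water", "is_ligand", "sym_op")]
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)), all(is.finite(atoms$z)))
  if (any(atoms$occ < 0 | atoms$occ > 1, na.rm = TRUE))
    stop("occupancies must lie in [0, 1]", call. = FALSE)
  attr(atoms, "cell") <- cell
  attr(atoms, "space_group") <- space_group
  atoms
}

# carry cell/space-group attributes through dplyr verbs that drop them
keep_attrs <- function(new, old) {
  attr(new, "cell") <- attr(old, "cell")
  attr(new, "space_group") <- attr(old, "space_group")
  new
}

#' Read a structure from PDB or mmCIF
#'
#' All ATOM/HETATM records are retained; waters (HOH/WAT/DOD) are flagged,
#' non-water HETATM records are flagged as ligand atoms. Alternate locations
#' are resolved to the highest-occupancy conformer (ties: first in file).
#' Hydrogen atoms present in the file are discarded; polar hydrogens are
#' rebuilt by [classify_polar_sites()] so that all structures share one
#' hydrogen model.
#'
#' @param path file path.
#' @param dialect `"pdb"` (fixed column) or `"mmcif"`.
#' @return an atom tibble (see [as_structure()]) carrying `cell` and
#'   `space_group` attributes when a CRYST1 / `_cell` block is present.
#' @export
read_structure <- function(path, dialect = c("pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- tryCatch(
    if (dialect == "pdb") bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse ", dialect, " file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))) {
    bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))[1]
    stop("missing coordinates for atom ", a$eleno[bad], " ", a$elety[bad],
         " ", a$resid[bad], a$resno[bad], call. = FALSE)
  }
  atoms <- tibble::tibble(
    eleno = a$eleno,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(gsub("[0-9]", "", a$elety), 1, 1), trimws(a$elesy)),
    name = a$elety,
    resname = a$resid,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno,
    alt = a$alt,
    occ = ifelse(is.na(a$o), 1, a$o),
    x = a$x, y = a$y, z = a$z,
    is_water = a$resid %in% c("HOH", "WAT", "DOD"),
    is_ligand = a$type == "HETATM" & !(a$resid %in% c("HOH", "WAT", "DOD")),
    sym_op = NA_integer_
  )
  atoms <- atoms[!(atoms$element %in% c("H", "D")), ]
  atoms <- resolve_altloc(atoms)
  cellinfo <- if (dialect == "pdb") read_cryst1(path) else read_cif_cell(path)
  as_structure(atoms, cell = cellinfo$cell, space_group = cellinfo$space_group)
}

# highest occupancy wins; ties broken by file order
resolve_altloc <- function(atoms) {
  atoms$.ord <- seq_len(nrow(atoms))
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$resname, .data$name) |>
    dplyr::arrange(dplyr::desc(.data$occ), .data$.ord, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)
  atoms$.ord <- NULL
  atoms
}

read_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl)) return(list(cell = NULL, space_group = NULL))
  cl <- cl[1]
  cell <- c(a = as.numeric(substr(cl, 7, 15)),
            b = as.numeric(substr(cl, 16, 24)),
            c = as.numeric(substr(cl, 25, 33)),
            alpha = as.numeric(substr(cl, 34, 40)),
            beta = as.numeric(substr(cl, 41, 47)),
            gamma = as.numeric(substr(cl, 48, 54)))
  sg <- trimws(substr(cl, 56, 66))
  if (any(!is.finite(cell)) || all(cell[1:3] == 1)) return(list(cell = NULL, space_group = NULL))
  list(cell = cell, space_group = if (nzchar(sg)) sg else NULL)
}

read_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(key) {
    ln <- grep(paste0("^", key, "\\s"), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    as.numeric(strsplit(trimws(ln[1]), "\\s+")[[1]][2])
  }
  cell <- c(a = grab("_cell.length_a"), b = grab("_cell.length_b"),
            c = grab("_cell.length_c"), alpha = grab("_cell.angle_alpha"),
            beta = grab("_cell.angle_beta"), gamma = grab("_cell.angle_gamma"))
  sgl <- grep("^_symmetry.space_group_name_H-M", lines, value = TRUE)
  sg <- if (length(sgl)) gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sgl[1]))) else NULL
  if (any(!is.finite(cell))) return(list(cell = NULL, space_group = NULL))
  list(cell = cell, space_group = sg)
}

#' Write a structure as fixed-column PDB
#'
#' Waters (including predicted ones) are written as HOH HETATM records with
#' occupancy 1.00; water hydrogens, when present in the table, are written too.
#'
#' @param atoms an atom tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path) {
  cell <- attr(atoms, "cell"); sg <- attr(atoms, "space_group")
  type <- ifelse(atoms$is_water | atoms$is_ligand, "HETATM", "ATOM")
  xyz <- as.vector(t(atoms_xyz(atoms)))
  bio3d::write.pdb(file = path, xyz = xyz, type = type,
                   resno = atoms$resno, resid = atoms$resname,
                   eleno = seq_len(nrow(atoms)), elety = atoms$name,
                   chain = atoms$chain, o = ifelse(atoms$is_water, 1, atoms$occ),
                   b = rep(0, nrow(atoms)), elesy = atoms$element)
  if (!is.null(cell)) {
    cl <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
                  cell["a"], cell["b"], cell["c"],
                  cell["alpha"], cell["beta"], cell["gamma"],
                  if (is.null(sg)) "P 1" else sg)
    lines <- readLines(path, warn = FALSE)
    writeLines(c(cl, lines), path)
  }
  invisible(path)
}

#' Append predicted waters to a structure
#'
#' @param atoms an atom tibble.
#' @param waters a water-placement tibble from [solvate_structure()].
#' @param with_hydrogens write the two water hydrogens as well.
#' @return the atom tibble with HOH records appended (incremental residue
#'   numbers, occupancy 1).
#' @export
add_waters <- function(atoms, waters, with_hydrogens = TRUE) {
  if (nrow(waters) == 0) return(atoms)
  res0 <- if (nrow(atoms)) max(atoms$resno) else 0
  rows <- purrr::map_dfr(seq_len(nrow(waters)), function(i) {
    w <- waters[i, ]
    o <- c(w$ox, w$oy, w$oz)
    out <- tibble::tibble(name = "O", element = "O", x = o[1], y = o[2], z = o[3])
    if (with_hydrogens) {
      h <- w$hydrogens[[1]]
      out <- dplyr::bind_rows(out, tibble::tibble(
        name = c("H1", "H2"), element = "H",
        x = h[, 1], y = h[, 2], z = h[, 3]))
    }
    out$resname <- "HOH"; out$chain <- "W"; out$resno <- res0 + i
    out$is_water <- TRUE; out$is_ligand <- FALSE
    out
  })
  keep_attrs(dplyr::bind_rows(atoms, as_structure(rows,
    cell = attr(atoms, "cell"), space_group = attr(atoms, "space_group"))), atoms)
}
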