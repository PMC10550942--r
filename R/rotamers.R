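#' Rotamer building from a bundled backbone-independent library
#'
#' Side chains are grown from the backbone frame (N, CA, C) by internal
#' coordinates using idealised bond lengths and angles; the chi torsions come
#' from a small bundled backbone-independent rotamer library (most frequent
#' conformers per residue, coarse frequencies). The library and template
#' files are plain text under `inst/extdata/` and can be swapped for richer
#' ones.
#'
#' @name rotamers
NULL

rotamer_library <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- utils::read.delim(
      system.file("extdata", "rotamer_library.tsv", package = "aquabridge"),
      stringsAsFactors = FALSE)
    cache
  }
})

sidechain_templates <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- utils::read.delim(
      system.file("extdata", "sidechain_templates.tsv", package = "aquabridge"),
      stringsAsFactors = FALSE)
    cache
  }
})

# resolve a template torsion spec ("chi1", "chi2+180", "123.0") given chis
resolve_torsion <- function(spec, chi) {
  if (grepl("^chi", spec)) {
    k <- as.integer(substr(spec, 4, 4))
    off <- sub("^chi[0-9]", "", spec)
    chi[k] + if (nzchar(off)) as.numeric(off) else 0
  } else as.numeric(spec)
}

n_chi <- function(resname) {
  lib <- rotamer_library()
  rows <- lib[lib$resname == resname, , drop = FALSE]
  if (!nrow(rows)) stop("residue type not in rotamer library: ", resname,
                        call. = FALSE)
  sum(!is.na(unlist(rows[1, c("chi1", "chi2", "chi3", "chi4")])))
}

#' Build one side chain onto a backbone frame
#'
#' @param backbone tibble with the residue's N, CA, C (and optionally O)
#'   atoms.
#' @param resname residue type to build.
#' @param chi chi angles in degrees (length = number of chis of the type).
#' @return tibble of side-chain atoms (name, element, x, y, z).
#' @export
build_sidechain <- function(backbone, resname, chi = numeric(0)) {
  tmpl <- sidechain_templates()
  tmpl <- tmpl[tmpl$resname == resname, , drop = FALSE]
  if (resname == "GLY") return(tibble::tibble(
    name = character(), element = character(),
    x = numeric(), y = numeric(), z = numeric()))
  if (!nrow(tmpl)) stop("no side-chain template for ", resname, call. = FALSE)
  pos <- list()
  for (nm in c("N", "CA", "C", "O")) {
    row <- backbone[backbone$name == nm, ]
    if (nrow(row)) pos[[nm]] <- c(row$x[1], row$y[1], row$z[1])
  }
  if (is.null(pos$N) || is.null(pos$CA) || is.null(pos$C))
    stop("backbone frame incomplete (need N, CA, C)", call. = FALSE)
  out <- list()
  for (r in seq_len(nrow(tmpl))) {
    tr <- tmpl[r, ]
    if (is.null(pos[[tr$a]]) || is.null(pos[[tr$b]]) || is.null(pos[[tr$c]]))
      stop("template frame atom missing for ", resname, " ", tr$atom, call. = FALSE)
    p <- nerf_place(pos[[tr$a]], pos[[tr$b]], pos[[tr$c]],
                    tr$bond, tr$angle, resolve_torsion(tr$torsion, chi))
    pos[[tr$atom]] <- p
    out[[tr$atom]] <- tibble::tibble(
      name = tr$atom, element = substr(gsub("[0-9]", "", tr$atom), 1, 1),
      x = p[1], y = p[2], z = p[3])
  }
  dplyr::bind_rows(out)
}

#' Enumerate rotamers at a design position
#'
#' Builds every library conformer of `resname` onto the position's backbone.
#' With `expand_chi1` each conformer is emitted in three copies (chi1 and
#' chi1 +/- 10 degrees), the fine-tuning used for ligand-pocket rebuilding.
#'
#' @param atoms atom tibble holding at least the backbone of the position.
#' @param chain,resno position identity.
#' @param resname residue type to build (the original sequence identity).
#' @param expand_chi1 triple the set by perturbing chi1 by +/- 10 degrees.
#' @return list of rotamer objects (class `aqua_rotamer`): each a list with
#'   `chain`, `resno`, `resname`, `chi`, `freq`, `atoms` (backbone +
#'   side chain tibble), `waters` (empty placement tibble), `bridge_ids`.
#' @export
enumerate_rotamers <- function(atoms, chain, resno, resname,
                               expand_chi1 = FALSE) {
  lib <- rotamer_library()
  rows <- lib[lib$resname == resname, , drop = FALSE]
  if (!nrow(rows)) stop("residue type not in rotamer library: ", resname,
                        call. = FALSE)
  bb <- atoms[atoms$chain == chain & atoms$resno == resno &
                atoms$name %in% c("N", "CA", "C", "O"), ]
  rots <- list()
  for (r in seq_len(nrow(rows))) {
    chi <- unlist(rows[r, c("chi1", "chi2", "chi3", "chi4")])
    chi <- chi[!is.na(chi)]
    variants <- if (expand_chi1 && length(chi)) {
      lapply(c(0, -10, 10), function(d) { v <- chi; v[1] <- v[1] + d; v })
    } else list(chi)
    for (v in variants) {
      sc <- build_sidechain(bb, resname, v)
      at <- dplyr::bind_rows(
        tibble::tibble(name = bb$name, element = bb$element,
                       x = bb$x, y = bb$y, z = bb$z),
        sc)
      at$resname <- resname; at$chain <- chain; at$resno <- resno
      at$is_water <- FALSE; at$is_ligand <- FALSE
      rots[[length(rots) + 1]] <- structure(list(
        chain = chain, resno = resno, resname = resname,
        chi = as.numeric(v), freq = rows$freq[r],
        atoms = as_structure(at), waters = empty_placements(),
        bridge_ids = character(0)),
        class = "aqua_rotamer")
    }
  }
  rots
}

#' @export
print.aqua_rotamer <- function(x, ...) {
  cat("Rotamer ", x$resname, " ", x$chain, x$resno,
      if (length(x$chi)) paste0(" chi = [", paste(round(x$chi), collapse = ", "), "]"),
      if (nrow(x$waters)) paste0(" + ", nrow(x$waters), " water(s)"), "\n", sep = "")
  invisible(x)
}

#' Measure the chi-1 angle of a residue in an atom table
#'
#' @param atoms atom tibble.
#' @param chain,resno residue identity.
#' @return chi1 in degrees, or `NA` if the residue has no chi1 or atoms are
#'   missing.
#' @export
measure_chi1 <- function(atoms, chain, resno) {
  res <- atoms[atoms$chain == chain & atoms$resno == resno, ]
  if (!nrow(res)) return(NA_real_)
  g_name <- intersect(c("CG", "CG1", "OG", "OG1", "SG"), res$name)
  need <- c("N", "CA", "CB")
  if (!all(need %in% res$name) || !length(g_name)) return(NA_real_)
  get <- function(nm) { r <- res[res$name == nm, ][1, ]; c(r$x, r$y, r$z) }
  dihedral(get("N"), get("CA"), get("CB"), get(g_name[1]))
}
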