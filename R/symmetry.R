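#' Crystallographic symmetry expansion
#'
#' Space-group operators are read from a bundled plain-text table covering the
#' space groups most common for protein crystals; operators are given in
#' triplet notation (e.g. `-X+1/2,-Y,Z+1/2`) and parsed into a 3x3 rotation
#' plus translation in fractional coordinates.
#'
#' @name symmetry
NULL

# parse one triplet such as "-x+1/2, y, z+1/2" -> list(R = 3x3, t = length 3);
# handles multi-axis rows ("x-y") as found in trigonal/hexagonal groups
parse_symop <- function(triplet) {
  parts <- strsplit(gsub("\\s", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry operator: ", triplet, call. = FALSE)
  R <- matrix(0, 3, 3); t <- numeric(3)
  term_re <- "([+-]?)([xyz]|[0-9]+/[0-9]+|[0-9]+)"
  for (i in 1:3) {
    expr <- parts[i]
    mm <- gregexpr(term_re, expr, perl = TRUE)[[1]]
    terms <- regmatches(expr, list(mm))[[1]]
    if (!length(terms) || sum(attr(mm, "match.length")) != nchar(expr))
      stop("malformed symmetry operator: ", triplet, call. = FALSE)
    for (term in terms) {
      sgn <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sgn
      } else if (grepl("/", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        t[i] <- t[i] + sgn * nm[1] / nm[2]
      } else {
        t[i] <- t[i] + sgn * as.numeric(body)
      }
    }
  }
  list(R = R, t = t)
}

spacegroup_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    path <- system.file("extdata", "spacegroups.txt", package = "aquabridge")
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    tab <- list(); current <- NULL
    for (ln in lines) {
      if (grepl("^>", ln)) {
        current <- trimws(sub("^>", "", ln))
        tab[[current]] <- character(0)
      } else {
        tab[[current]] <- c(tab[[current]], trimws(ln))
      }
    }
    cache <<- tab
    tab
  }
})

lookup_spacegroup <- function(symbol) {
  tab <- spacegroup_table()
  key <- toupper(gsub("\\s", "", symbol))
  names_key <- toupper(gsub("\\s", "", names(tab)))
  hit <- match(key, names_key)
  if (is.na(hit))
    stop("unknown space-group symbol '", symbol, "'; known: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  lapply(tab[[hit]], parse_symop)
}

# orthogonalisation matrix (fractional -> cartesian), PDB convention
orth_matrix <- function(cell) {
  a <- cell["a"]; b <- cell["b"]; cc <- cell["c"]
  al <- deg2rad(cell["alpha"]); be <- deg2rad(cell["beta"]); ga <- deg2rad(cell["gamma"])
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 + 2 * cos(al) * cos(be) * cos(ga))
  matrix(c(a, b * cos(ga), cc * cos(be),
           0, b * sin(ga), cc * (cos(al) - cos(be) * cos(ga)) / sin(ga),
           0, 0, cc * v / sin(ga)),
         nrow = 3, byrow = TRUE)
}

#' Expand crystallographic symmetry around a point
#'
#' Applies every space-group operator plus lattice translations in a -2..2
#' cube and appends all symmetry-copy atoms that fall within `radius` of
#' `center`. Copies are tagged with the operator index in `sym_op`; the
#' original atoms keep `sym_op = NA`. Without cell/space-group information the
#' input is returned unchanged (identity-only expansion).
#'
#' @param atoms atom tibble carrying `cell` and `space_group` attributes.
#' @param center numeric length-3, Angstrom.
#' @param radius inclusion radius in Angstrom (closed ball).
#' @return atom tibble with symmetry copies appended.
#' @export
expand_symmetry <- function(atoms, center, radius = 20) {
  cell <- attr(atoms, "cell")
  sg <- attr(atoms, "space_group")
  if (is.null(cell)) return(atoms)
  if (is.null(sg)) sg <- "P 1"
  ops <- lookup_spacegroup(sg)
  M <- orth_matrix(cell); Minv <- solve(M)
  xyz <- atoms_xyz(atoms)
  frac <- xyz %*% t(Minv)
  shifts <- as.matrix(expand.grid(tx = -2:2, ty = -2:2, tz = -2:2))
  orig_key <- paste(round(xyz[, 1], 2), round(xyz[, 2], 2), round(xyz[, 3], 2))
  copies <- list()
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    f1 <- frac %*% t(op$R)
    f1 <- sweep(f1, 2, op$t, "+")
    for (s in seq_len(nrow(shifts))) {
      identity_img <- k == 1 && all(shifts[s, ] == 0) &&
        all(op$t == 0) && all(op$R == diag(3))
      if (identity_img) next
      f2 <- sweep(f1, 2, shifts[s, ], "+")
      cart <- f2 %*% t(M)
      d <- dist_to_point(cart, center)
      keep <- d <= radius
      if (!any(keep)) next
      sub <- atoms[keep, ]
      sub$x <- cart[keep, 1]; sub$y <- cart[keep, 2]; sub$z <- cart[keep, 3]
      sub$sym_op <- k
      # drop copies coinciding with original atoms (special positions)
      key <- paste(round(sub$x, 2), round(sub$y, 2), round(sub$z, 2))
      copies[[length(copies) + 1]] <- sub[!(key %in% orig_key), ]
    }
  }
  out <- dplyr::bind_rows(c(list(atoms), copies))
  keep_attrs(out, atoms)
}
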