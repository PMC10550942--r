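#' Validation metrics for water and side-chain predictions
#'
#' Central-water deviation, recovery-rate curves, unique-match water-mesh
#' scoring (TP/FP/FN), chi-1 recovery and side-chain RMSD.
#'
#' @name evaluation
NULL

#' Number of coordinating polar protein atoms of a water position
#'
#' @param water length-3 position of the water oxygen.
#' @param atoms atom tibble.
#' @param cutoff coordination distance, Angstrom (closed ball).
#' @param sites optional precomputed polar-site tibble.
#' @return integer count of polar (O/N) protein atoms within the cutoff.
#' @export
coordination_count <- function(water, atoms, cutoff = 2.99, sites = NULL) {
  if (is.null(sites)) sites <- classify_polar_sites(atoms, build_hydrogens = FALSE)
  sites <- sites[!atoms$is_water[sites$atom_idx] & !sites$is_ligand_site, ]
  if (!nrow(sites)) return(0L)
  d <- sqrt((sites$x - water[1])^2 + (sites$y - water[2])^2 + (sites$z - water[3])^2)
  sum(d <= cutoff)
}

#' Shortest distance from any predicted water to the central water
#'
#' @param predicted n x 3 matrix (or tibble with ox/oy/oz or x/y/z columns)
#'   of predicted water oxygens.
#' @param central length-3 position of the central reference water.
#' @return minimum Euclidean distance, or `NA` when nothing was predicted
#'   ("no prediction": counts against recovery, excluded from deviation
#'   distributions).
#' @export
central_water_deviation <- function(predicted, central) {
  xyz <- water_xyz(predicted)
  if (!nrow(xyz)) return(NA_real_)
  min(dist_to_point(xyz, central))
}

water_xyz <- function(w) {
  if (is.matrix(w)) return(w[, 1:3, drop = FALSE])
  if (is.data.frame(w)) {
    if (all(c("ox", "oy", "oz") %in% names(w)))
      return(as.matrix(w[, c("ox", "oy", "oz")]))
    return(as.matrix(w[, c("x", "y", "z")]))
  }
  matrix(w, ncol = 3)
}

#' Recovery rate at one or several distance cut-offs
#'
#' Percentage of central waters with any predicted water within the cut-off.
#' Spheres with no prediction (`NA` deviation) count as failures.
#'
#' @param deviations per-sphere central-water deviations (`NA` = no
#'   prediction).
#' @param cutoff numeric vector of cut-offs, Angstrom.
#' @return a tibble with `cutoff` and `recovery_percent`.
#' @export
recovery_rate <- function(deviations, cutoff = 1.4) {
  tibble::tibble(
    cutoff = cutoff,
    recovery_percent = vapply(cutoff, function(ct)
      100 * mean(!is.na(deviations) & deviations <= ct), numeric(1)))
}

#' Unique matching of predicted against reference waters
#'
#' Candidate pairs within the cut-off are matched so that each predicted and
#' each reference water participates in at most one match (no double
#' picking); the default strategy is greedy by ascending pair distance with
#' ties broken by predicted index, `"optimal"` computes a maximum-cardinality
#' matching instead. TP and FP percentages are relative to the number of
#' predicted waters, FN to the number of reference waters; an optional
#' 6 Angstrom border around the sphere centre restricts both sets first.
#'
#' @param predicted,reference water-oxygen coordinates (matrix or tibble).
#' @param cutoff match distance cut-off, Angstrom.
#' @param border_center optional centre for the evaluation border.
#' @param border_radius border radius, Angstrom.
#' @param method `"greedy"` or `"optimal"` (requires igraph).
#' @return a list of class `aqua_match` with `pairs` (tibble: predicted,
#'   reference, deviation), `tp_percent`, `fp_percent`, `fn_percent`,
#'   `mean_deviation`, `n_predicted`, `n_reference`, `cutoff`.
#' @export
match_waters <- function(predicted, reference, cutoff = 1.4,
                         border_center = NULL, border_radius = 6,
                         method = c("greedy", "optimal")) {
  method <- match.arg(method)
  P <- water_xyz(predicted); R <- water_xyz(reference)
  if (!is.null(border_center)) {
    P <- P[dist_to_point(P, border_center) <= border_radius, , drop = FALSE]
    R <- R[dist_to_point(R, border_center) <= border_radius, , drop = FALSE]
  }
  np <- nrow(P); nr <- nrow(R)
  cand <- NULL
  if (np && nr) {
    cand <- purrr::map_dfr(seq_len(np), function(i) {
      d <- dist_to_point(R, P[i, ])
      j <- which(d <= cutoff)
      if (!length(j)) return(NULL)
      tibble::tibble(predicted = i, reference = j, deviation = d[j])
    })
  }
  pairs <- tibble::tibble(predicted = integer(), reference = integer(),
                          deviation = numeric())
  if (!is.null(cand) && nrow(cand)) {
    pairs <- if (method == "greedy") greedy_match(cand)
             else optimal_match(cand, np, nr)
  }
  tp <- nrow(pairs)
  structure(list(
    pairs = pairs,
    tp_percent = if (np) 100 * tp / np else NA_real_,
    fp_percent = if (np) 100 * (np - tp) / np else NA_real_,
    fn_percent = if (nr) 100 * (nr - tp) / nr else NA_real_,
    mean_deviation = if (tp) mean(pairs$deviation) else NA_real_,
    n_predicted = np, n_reference = nr, cutoff = cutoff,
    method = method),
    class = "aqua_match")
}

greedy_match <- function(cand) {
  cand <- cand[order(cand$deviation, cand$predicted, cand$reference), ]
  used_p <- integer(0); used_r <- integer(0); keep <- integer(0)
  for (k in seq_len(nrow(cand))) {
    if (cand$predicted[k] %in% used_p || cand$reference[k] %in% used_r) next
    keep <- c(keep, k)
    used_p <- c(used_p, cand$predicted[k]); used_r <- c(used_r, cand$reference[k])
  }
  cand[keep, ]
}

# maximum-cardinality bipartite matching on the threshold graph
optimal_match <- function(cand, np, nr) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("method = 'optimal' requires the igraph package", call. = FALSE)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, np), rep(TRUE, nr)),
    edges = as.vector(rbind(cand$predicted, np + cand$reference)))
  mm <- igraph::max_bipartite_match(
    g, weights = 1000 - cand$deviation)  # prefer short pairs at equal size
  matched <- mm$matching[seq_len(np)]
  keep <- which(!is.na(matched))
  out <- tibble::tibble(predicted = keep, reference = matched[keep] - np)
  out$deviation <- vapply(seq_len(nrow(out)), function(k) {
    hit <- cand$predicted == out$predicted[k] & cand$reference == out$reference[k]
    cand$deviation[hit][1]
  }, numeric(1))
  out
}

#' @export
print.aqua_match <- function(x, ...) {
  cat(sprintf("Water mesh match (cutoff %.2f A, %s): TP %.1f%%  FP %.1f%%  FN %.1f%%  mean dev %.2f A\n",
              x$cutoff, x$method, x$tp_percent, x$fp_percent, x$fn_percent,
              x$mean_deviation))
  invisible(x)
}

#' chi-1 recovery rate
#'
#' Percentage of chi1-bearing rebuilt residues whose chi-1 deviates (with
#' circular arithmetic) by strictly less than the tolerance from the
#' reference structure. Residues truncated to Ala/Gly in the model, and
#' residues without chi-1, are excluded from the denominator.
#'
#' @param model,reference atom tibbles; residues are paired by chain and
#'   residue number.
#' @param tolerance degrees.
#' @return a list with `percent`, `n_evaluated`, and a per-residue tibble.
#' @export
chi1_recovery <- function(model, reference, tolerance = 20) {
  res <- unique(model[!model$is_water & !model$is_ligand & is.na(model$sym_op),
                      c("chain", "resno", "resname")])
  rows <- list()
  for (r in seq_len(nrow(res))) {
    if (res$resname[r] %in% c("ALA", "GLY")) next
    c1m <- measure_chi1(model, res$chain[r], res$resno[r])
    if (is.na(c1m)) next
    c1r <- measure_chi1(reference, res$chain[r], res$resno[r])
    if (is.na(c1r)) {
      warning("residue ", res$chain[r], res$resno[r],
              " unpaired in reference; skipped", call. = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = res$chain[r], resno = res$resno[r], resname = res$resname[r],
      chi1_model = c1m, chi1_reference = c1r,
      deviation = circ_diff(c1m, c1r))
  }
  tab <- if (length(rows)) dplyr::bind_rows(rows)
    else tibble::tibble(chain = character(), resno = integer(),
                        resname = character(), chi1_model = numeric(),
                        chi1_reference = numeric(), deviation = numeric())
  list(percent = if (nrow(tab)) 100 * mean(tab$deviation < tolerance) else NA_real_,
       n_evaluated = nrow(tab), residues = tab)
}

# atom-name swaps of chemically symmetric side-chain ends
SYMMETRIC_SWAPS <- list(
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  ARG = list(c("NH1", "NH2")))

#' Side-chain heavy-atom RMSD (main chain and CB excluded)
#'
#' Pools squared deviations over all paired side-chain atoms past CB;
#' `per_sphere_median` callers should compute the overall RMSD per sphere
#' and take the median across spheres. Symmetric side chains (Phe/Tyr rings,
#' Asp/Glu carboxylates, Arg NH) are evaluated under both atom-name swaps and
#' the smaller residue contribution is used.
#'
#' @param model,reference atom tibbles paired by chain/residue number/atom
#'   name.
#' @return a list with `rmsd`, `n_atoms`, and a per-residue tibble of
#'   residue RMSDs.
#' @export
sidechain_rmsd <- function(model, reference) {
  excl <- c("N", "CA", "C", "O", "OXT", "CB")
  m <- model[!model$is_water & !model$is_ligand & is.na(model$sym_op) &
               !(model$name %in% excl) & model$element != "H", ]
  rows <- list(); sq <- numeric(0)
  res <- unique(m[, c("chain", "resno", "resname")])
  for (r in seq_len(nrow(res))) {
    mm <- m[m$chain == res$chain[r] & m$resno == res$resno[r], ]
    rr <- reference[reference$chain == res$chain[r] &
                      reference$resno == res$resno[r] &
                      !(reference$name %in% excl) &
                      !reference$is_water & !reference$is_ligand, ]
    if (!nrow(rr)) next
    swaps <- SYMMETRIC_SWAPS[[res$resname[r]]]
    variants <- list(mm$name)
    if (!is.null(swaps)) {
      swapped <- mm$name
      for (sw in swaps) {
        swapped[mm$name == sw[1]] <- sw[2]
        swapped[mm$name == sw[2]] <- sw[1]
      }
      variants <- c(variants, list(swapped))
    }
    best <- NULL
    for (v in variants) {
      idx <- match(v, rr$name)
      ok <- !is.na(idx)
      if (!any(ok)) next
      dev2 <- (mm$x[ok] - rr$x[idx[ok]])^2 + (mm$y[ok] - rr$y[idx[ok]])^2 +
        (mm$z[ok] - rr$z[idx[ok]])^2
      if (is.null(best) || mean(dev2) < mean(best)) best <- dev2
    }
    if (is.null(best)) next
    sq <- c(sq, best)
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = res$chain[r], resno = res$resno[r], resname = res$resname[r],
      rmsd = sqrt(mean(best)), n_atoms = length(best))
  }
  list(rmsd = if (length(sq)) sqrt(mean(sq)) else NA_real_,
       n_atoms = length(sq),
       residues = if (length(rows)) dplyr::bind_rows(rows)
       else tibble::tibble(chain = character(), resno = integer(),
                           resname = character(), rmsd = numeric(),
                           n_atoms = integer()))
}

#' Evaluate one rebuilt sphere against its reference
#'
#' Bundles central-water deviation, the bordered water-mesh match, chi-1
#' recovery and side-chain RMSD into one record.
#'
#' @param sphere the reference `aqua_sphere` (original coordinates incl.
#'   waters).
#' @param rebuilt the rebuilt atom tibble (waters as HOH records or in the
#'   `waters` attribute).
#' @param cutoff water-match distance cut-off, Angstrom.
#' @return one-row tibble with the per-sphere metrics.
#' @export
evaluate_sphere <- function(sphere, rebuilt, cutoff = 1.4) {
  ref_w <- sphere$atoms[sphere$atoms$is_water & sphere$atoms$element == "O", ]
  pred_w <- rebuilt[rebuilt$is_water & rebuilt$element == "O", ]
  dev <- central_water_deviation(pred_w, sphere$center)
  mesh <- match_waters(pred_w, ref_w, cutoff = cutoff,
                       border_center = sphere$center,
                       border_radius = sphere$eval_radius)
  chi <- chi1_recovery(rebuilt, sphere$atoms)
  rms <- sidechain_rmsd(rebuilt, sphere$atoms)
  tibble::tibble(
    central_deviation = dev, no_prediction = is.na(dev),
    tp_percent = mesh$tp_percent, fp_percent = mesh$fp_percent,
    fn_percent = mesh$fn_percent, mesh_mean_deviation = mesh$mean_deviation,
    n_predicted = mesh$n_predicted, n_reference = mesh$n_reference,
    chi1_percent = chi$percent, chi1_n = chi$n_evaluated,
    rmsd = rms$rmsd, cutoff = cutoff)
}

#' Aggregate per-sphere reports into a validation-table row
#'
#' @param per_sphere tibble of [evaluate_sphere()] rows.
#' @param cutoff recovery cut-off, Angstrom.
#' @return one-row tibble: number of spheres, recovery rate, median central
#'   deviation, median RMSD, mean chi-1 recovery, mean TP/FP/FN and mean
#'   mesh deviation.
#' @export
aggregate_spheres <- function(per_sphere, cutoff = 1.4) {
  dev <- per_sphere$central_deviation
  tibble::tibble(
    n_spheres = nrow(per_sphere),
    recovery_percent = recovery_rate(dev, cutoff)$recovery_percent,
    central_deviation_median = stats::median(dev, na.rm = TRUE),
    rmsd_median = stats::median(per_sphere$rmsd, na.rm = TRUE),
    chi1_percent = mean(per_sphere$chi1_percent, na.rm = TRUE),
    tp_percent = mean(per_sphere$tp_percent, na.rm = TRUE),
    fp_percent = mean(per_sphere$fp_percent, na.rm = TRUE),
    fn_percent = mean(per_sphere$fn_percent, na.rm = TRUE),
    mesh_deviation_mean = mean(per_sphere$mesh_mean_deviation, na.rm = TRUE),
    cutoff = cutoff)
}
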