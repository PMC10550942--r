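#' Geometry parameters for water building
#'
#' Defaults come from the geometry statistics of protein-bound waters in high
#' resolution crystal structures: ideal water-oxygen contact distances of
#' 2.73 Angstrom to oxygen and 2.87 to nitrogen, a polar-pair eligibility
#' window of 3.65-5.57 Angstrom (the mean bridged-pair separation 4.61 +/- 2
#' sigma with sigma = 0.48) with a strict +/- 1 sigma variant of
#' 4.13-5.09, a water coordination cut-off of 2.99 Angstrom, and the rigid
#' water geometry O-H = 0.96 Angstrom, H-O-H = 104.45 degrees.
#'
#' @param d_h2o_x ideal water contact distance to oxygen/other elements (A).
#' @param d_h2o_n ideal water contact distance to nitrogen (A).
#' @param pair_window default eligibility window for the polar-polar distance.
#' @param strict_window +/- 1 sigma window used in strict mode.
#' @param strict use the strict window.
#' @param coordination_cutoff distance defining a coordinating polar atom (A).
#' @param oh_length water O-H bond length (A).
#' @param hoh_angle water H-O-H angle (degrees).
#' @param clash_distance minimum allowed distance between a constructed water
#'   oxygen and any heavy atom other than its two partners (A).
#' @param merge_radius posterior de-duplication radius; of two waters closer
#'   than this the lower-energy one is kept (A).
#' @return a list of class `aqua_geometry_params`.
#' @export
geometry_params <- function(d_h2o_x = 2.73, d_h2o_n = 2.87,
                            pair_window = c(3.65, 5.57),
                            strict_window = c(4.13, 5.09),
                            strict = FALSE,
                            coordination_cutoff = 2.99,
                            oh_length = 0.96, hoh_angle = 104.45,
                            clash_distance = 2.4, merge_radius = 1.0) {
  stopifnot(pair_window[1] < pair_window[2], strict_window[1] < strict_window[2],
            d_h2o_x > 0, d_h2o_n > 0, oh_length > 0)
  structure(list(
    d_h2o_x = d_h2o_x, d_h2o_n = d_h2o_n,
    pair_window = pair_window, strict_window = strict_window, strict = strict,
    coordination_cutoff = coordination_cutoff,
    oh_length = oh_length, hoh_angle = hoh_angle,
    clash_distance = clash_distance, merge_radius = merge_radius),
    class = "aqua_geometry_params")
}

#' Directional hydrogen-bond energy parameters
#'
#' A 12-10 hydrogen-bond potential with cosine angular weights:
#' `E = well_depth * (5 (d0/d)^12 - 6 (d0/d)^10) * cos^k(theta_don) * cos^k(theta_acc)`,
#' zero beyond the cut-off or when either angular cosine is non-positive, and
#' clamped to be non-positive (short-range repulsion is reported separately by
#' the packing energy). The acceptance gate retains a water only if both of
#' its hydrogen-bond legs reach `accept_threshold`.
#'
#' @param well_depth well depth at ideal geometry, kcal/mol (negative).
#' @param distance_exponents repulsive/attractive exponents of the radial term.
#' @param angular_weight exponent `k` on the two cosine terms.
#' @param accept_threshold gate energy E_min, kcal/mol; each leg must be at or
#'   below it. `-2` by default, with `-4` and `-5` used as stricter presets.
#' @param cutoff_distance radial cut-off, Angstrom.
#' @param gate `"per_leg"` (default: both legs must pass) or `"sum"`.
#' @return a list of class `aqua_hbond_params`.
#' @export
hbond_params <- function(well_depth = -5, distance_exponents = c(12, 10),
                         angular_weight = 2, accept_threshold = -2,
                         cutoff_distance = 3.5, gate = c("per_leg", "sum")) {
  stopifnot(well_depth < 0, accept_threshold <= 0)
  structure(list(
    well_depth = well_depth, distance_exponents = distance_exponents,
    angular_weight = angular_weight, accept_threshold = accept_threshold,
    cutoff_distance = cutoff_distance, gate = match.arg(gate)),
    class = "aqua_hbond_params")
}

#' Named run presets
#'
#' `run1` default window and gate; `run4` strict +/- 1 sigma distance window;
#' `run5` gate at -4 kcal/mol; `run5.1` gate at -5; `run6` water building
#' disabled; `run6.1` posterior solvation after packing; `ligand` run5-like
#' settings with chi-1 +/- 10 degree rotamer expansion for pocket rebuilding.
#'
#' @param name preset name.
#' @param seed random seed carried into packing.
#' @return a list with elements `geometry`, `energy`, `mode`, `waters`,
#'   `expand_chi1`, `seed`, `preset`.
#' @export
resolve_preset <- function(name = c("run1", "run4", "run5", "run5.1",
                                    "run6", "run6.1", "ligand"),
                           seed = 1L) {
  if (!is.character(name) || !(name[1] %in% c("run1", "run4", "run5", "run5.1",
                                              "run6", "run6.1", "ligand")))
    stop("unknown preset '", name[1],
         "'; valid: run1, run4, run5, run5.1, run6, run6.1, ligand",
         call. = FALSE)
  name <- name[1]
  geo <- geometry_params(strict = name == "run4")
  emin <- switch(name, run5 = -4, run5.1 = -5, ligand = -4, -2)
  list(
    preset = name,
    geometry = geo,
    energy = hbond_params(accept_threshold = emin),
    mode = if (name == "run6.1") "posterior" else "packing",
    waters = name != "run6",
    expand_chi1 = name == "ligand",
    seed = as.integer(seed))
}

#' Read a run configuration from YAML
#'
#' Top-level keys `preset`, `geometry`, `energy`, `packing`; unknown keys are
#' rejected. Values override the preset's defaults.
#'
#' @param path YAML file.
#' @return a run configuration list as from [resolve_preset()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("preset", "geometry", "energy", "packing")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  run <- resolve_preset(cfg$preset %||% "run1",
                        seed = cfg$packing$seed %||% 1L)
  for (k in names(cfg$geometry)) run$geometry[[k]] <- cfg$geometry[[k]]
  for (k in names(cfg$energy)) run$energy[[k]] <- cfg$energy[[k]]
  if (!is.null(cfg$packing$expand_chi1)) run$expand_chi1 <- cfg$packing$expand_chi1
  run
}
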