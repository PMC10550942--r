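#' Directional hydrogen-bond energy
#'
#' The radial term is a 12-10 well with its minimum at the ideal contact
#' distance; the angular weight is the product of cosine powers of the donor
#' deviation (angle between the donor X-H axis and the donor-to-partner
#' direction) and the acceptor deviation (angle between the best acceptor
#' lone pair and the acceptor-to-partner direction). At ideal geometry the
#' energy equals the well depth.
#'
#' @name energy
NULL

# radial 12-10 well shape: 1 at d == d0, negative (repulsive once multiplied
# by the negative well depth) at short range, 0+ at long range
hb_distance_term <- function(d, d0, exponents = c(12, 10)) {
  6 * (d0 / d)^exponents[2] - 5 * (d0 / d)^exponents[1]
}

#' Hydrogen-bond energy between a placed water and one polar site
#'
#' @param water one row of a water-placement tibble (columns `ox`, `oy`, `oz`
#'   and list-column `hydrogens`), or a list with elements `oxygen`
#'   (length-3) and `hydrogens` (2 x 3 matrix).
#' @param site one row of the polar-site tibble.
#' @param params an [hbond_params()] object.
#' @param donates_h does the water donate a hydrogen to this site
#'   (`NA`: choose the more favourable of the feasible directions given the
#'   site's role).
#' @return energy in kcal/mol (non-positive; 0 beyond the cut-off).
#' @export
hbond_energy <- function(water, site, params = hbond_params(), donates_h = NA) {
  w <- as_water_geom(water)
  xs <- c(site$x, site$y, site$z)
  d <- vnorm(w$oxygen - xs)
  if (d > params$cutoff_distance || d < 1e-6) return(0)
  k <- params$angular_weight
  legs <- c()
  if (is.na(donates_h) || isTRUE(donates_h)) {
    if (site$role %in% c("acceptor", "both"))
      legs <- c(legs, leg_energy_donating(w, site, xs, d, params, k))
  }
  if (is.na(donates_h) || isFALSE(donates_h)) {
    if (site$role %in% c("donor", "both"))
      legs <- c(legs, leg_energy_accepting(w, site, xs, d, params, k))
  }
  if (!length(legs)) return(0)
  min(0, min(legs))
}

# water donates one of its hydrogens to the site (site is the acceptor)
leg_energy_donating <- function(w, site, xs, d, params, k) {
  u <- unitv(xs - w$oxygen)
  cd <- max(apply(w$hydrogens, 1, function(h) sum(unitv(h - w$oxygen) * u)))
  lps <- site$acceptor_vecs[[1]]
  ca <- if (!is.null(lps) && nrow(lps))
    max(apply(lps, 1, function(v) sum(v * unitv(w$oxygen - xs)))) else 1
  if (cd <= 0 || ca <= 0) return(0)
  params$well_depth * hb_distance_term(d, site$ideal_d, params$distance_exponents) *
    cd^k * ca^k
}

# the site donates to the water (water is the acceptor)
leg_energy_accepting <- function(w, site, xs, d, params, k) {
  dvs <- site$donor_vecs[[1]]
  if (is.null(dvs) || !nrow(dvs)) return(0)
  cd <- max(apply(dvs, 1, function(v) sum(v * unitv(w$oxygen - xs))))
  lp <- water_lone_pairs(w)
  ca <- max(apply(lp, 1, function(v) sum(v * unitv(xs - w$oxygen))))
  if (cd <= 0 || ca <= 0) return(0)
  params$well_depth * hb_distance_term(d, site$ideal_d, params$distance_exponents) *
    cd^k * ca^k
}

# the two tetrahedral lone pairs of a placed water
water_lone_pairs <- function(w) {
  b1 <- unitv(w$hydrogens[1, ] - w$oxygen)
  b2 <- unitv(w$hydrogens[2, ] - w$oxygen)
  m <- -unitv(b1 + b2)
  ax <- unitv(vcross(b1, b2))
  half <- deg2rad(109.47 / 2)
  rbind(cos(half) * m + sin(half) * ax,
        cos(half) * m - sin(half) * ax)
}

as_water_geom <- function(water) {
  if (is.list(water) && !is.data.frame(water) && !is.null(water$oxygen))
    return(list(oxygen = as.numeric(water$oxygen),
                hydrogens = water$hydrogens))
  stopifnot(nrow(water) == 1)
  list(oxygen = c(water$ox, water$oy, water$oz),
       hydrogens = water$hydrogens[[1]])
}

#' Acceptance gate for a constructed water
#'
#' A water is retained only if it genuinely bridges: with the default
#' `per_leg` gate both partner energies must reach the threshold; with
#' `gate = "sum"` their sum must.
#'
#' @param water one row of a water-placement tibble with `energy_i`,
#'   `energy_j` filled, or a numeric length-2 vector of leg energies.
#' @param params an [hbond_params()] object.
#' @return logical.
#' @export
accept_water <- function(water, params = hbond_params()) {
  e <- if (is.numeric(water)) water else c(water$energy_i, water$energy_j)
  if (params$gate == "sum") return(sum(e) <= params$accept_threshold)
  all(e <= params$accept_threshold)
}
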