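#' Water-geometry statistics
#'
#' Replicates the geometric analysis behind the water-building parameters:
#' water-protein contact distances, bridged polar-pair distances and
#' protein-water-protein angles, normal/log-normal fits and the sigma windows
#' used as distance cut-offs.
#'
#' @name geomstats
NULL

# polar protein sites of a sphere, and which waters they coordinate
sphere_water_env <- function(sphere, hbond_cutoff = 3.5) {
  atoms <- sphere$atoms
  sites <- suppressWarnings(classify_polar_sites(atoms, build_hydrogens = FALSE))
  sites <- sites[!atoms$is_water[sites$atom_idx] & !sites$is_ligand_site, ]
  waters <- atoms[atoms$is_water & atoms$element == "O", ]
  list(atoms = atoms, sites = sites, waters = waters)
}

#' Water-protein contact distances
#'
#' For every central water whose nearest hydrogen-bonded heavy-atom partner
#' (within 3.5 Angstrom) is a polar protein atom, emits the distances to all
#' coordinating polar atoms of the requested element.
#'
#' @param spheres a list of `aqua_sphere` objects.
#' @param element_filter `"all"`, `"O"` or `"N"`.
#' @param hbond_cutoff heavy-atom H-bond search distance, Angstrom.
#' @param coordination_cutoff coordination distance, Angstrom.
#' @return numeric vector of distances, Angstrom.
#' @export
water_contact_distances <- function(spheres, element_filter = c("all", "O", "N"),
                                    hbond_cutoff = 3.5,
                                    coordination_cutoff = 2.99) {
  element_filter <- match.arg(element_filter)
  out <- numeric(0)
  for (sp in spheres) {
    env <- sphere_water_env(sp)
    if (!nrow(env$sites)) next
    w <- sp$center
    heavy <- env$atoms[env$atoms$element != "H", ]
    hx <- atoms_xyz(heavy)
    d_all <- dist_to_point(hx, w)
    near <- which(d_all > 1e-6 & d_all <= hbond_cutoff)
    if (!length(near)) next
    nearest <- near[which.min(d_all[near])]
    key <- paste(heavy$chain[nearest], heavy$resno[nearest], heavy$name[nearest])
    site_keys <- paste(env$sites$chain, env$sites$resno, env$sites$name)
    if (!(key %in% site_keys)) next     # nearest partner is apolar: excluded
    ds <- sqrt((env$sites$x - w[1])^2 + (env$sites$y - w[2])^2 +
                 (env$sites$z - w[3])^2)
    sel <- ds <= coordination_cutoff
    if (element_filter != "all") sel <- sel & env$sites$element == element_filter
    out <- c(out, unname(ds[sel]))
  }
  out
}

#' Bridging distances and angles
#'
#' For every central water coordinated by at least two polar protein atoms,
#' emits for each unordered coordinating pair the Xi-Xj distance and the
#' Xi-water-Xj angle.
#'
#' @param spheres list of `aqua_sphere` objects.
#' @param coordination_cutoff coordination distance, Angstrom.
#' @return tibble with columns `distance` (Angstrom) and `angle` (degrees).
#' @export
bridging_geometry <- function(spheres, coordination_cutoff = 2.99) {
  rows <- list()
  for (sp in spheres) {
    env <- sphere_water_env(sp)
    if (!nrow(env$sites)) next
    w <- sp$center
    ds <- sqrt((env$sites$x - w[1])^2 + (env$sites$y - w[2])^2 +
                 (env$sites$z - w[3])^2)
    co <- which(ds <= coordination_cutoff)
    if (length(co) < 2) next
    for (a in seq_along(co)[-length(co)]) for (b in (a + 1):length(co)) {
      xi <- c(env$sites$x[co[a]], env$sites$y[co[a]], env$sites$z[co[a]])
      xj <- c(env$sites$x[co[b]], env$sites$y[co[b]], env$sites$z[co[b]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        distance = vnorm(xi - xj), angle = vangle(xi - w, xj - w))
    }
  }
  if (!length(rows)) return(tibble::tibble(distance = numeric(), angle = numeric()))
  dplyr::bind_rows(rows)
}

#' Fit a normal distribution
#'
#' Maximum-likelihood fit via [MASS::fitdistr()].
#'
#' @param samples numeric vector, n >= 2, non-constant.
#' @return a list of class `aqua_fit`: `family`, `mu`, `sigma`, `n`.
#' @export
fit_normal <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (stats::sd(samples) < 1e-12)
    stop("constant samples: sigma would be zero", call. = FALSE)
  f <- MASS::fitdistr(samples, "normal")
  structure(list(family = "normal",
                 mu = unname(f$estimate["mean"]),
                 sigma = unname(f$estimate["sd"]),
                 n = length(samples), samples = samples),
            class = "aqua_fit")
}

#' Fit a log-normal distribution
#'
#' MLE on the log scale; the derived median is `exp(mu)` and the mode
#' (probability maximum) `exp(mu - sigma^2)`.
#'
#' @param samples positive numeric vector, n >= 2.
#' @return a list of class `aqua_fit`: `family`, `mu`, `sigma` (log scale),
#'   `median`, `mode`, `n`.
#' @export
fit_lognormal <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(samples <= 0)) stop("log-normal fit requires positive samples",
                              call. = FALSE)
  if (stats::sd(log(samples)) < 1e-12)
    stop("constant samples: sigma would be zero", call. = FALSE)
  f <- MASS::fitdistr(samples, "lognormal")
  mu <- unname(f$estimate["meanlog"]); sg <- unname(f$estimate["sdlog"])
  structure(list(family = "lognormal", mu = mu, sigma = sg,
                 median = exp(mu), mode = exp(mu - sg^2),
                 n = length(samples), samples = samples),
            class = "aqua_fit")
}

#' @export
print.aqua_fit <- function(x, ...) {
  if (x$family == "normal")
    cat(sprintf("Normal fit: mu = %.4g, sigma = %.4g (n = %d)\n",
                x$mu, x$sigma, x$n))
  else
    cat(sprintf("Log-normal fit: meanlog = %.4g, sdlog = %.4g, median = %.3g, mode = %.3g (n = %d)\n",
                x$mu, x$sigma, x$median, x$mode, x$n))
  invisible(x)
}

#' Symmetric sigma window around a normal fit
#'
#' @param fit an `aqua_fit` of family normal, or a list with `mu`, `sigma`.
#' @param k sigma multiplier.
#' @return numeric length-2: `(mu - k sigma, mu + k sigma)`.
#' @export
sigma_window <- function(fit, k = 2) {
  c(fit$mu - k * fit$sigma, fit$mu + k * fit$sigma)
}

#' Gaussian probability mass inside the k-sigma window
#'
#' @param k sigma multiplier.
#' @return percentage of the normal mass within mu +/- k sigma.
#' @export
sigma_coverage <- function(k) {
  100 * (stats::pnorm(k) - stats::pnorm(-k))
}
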