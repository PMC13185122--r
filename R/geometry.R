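# Bilayer geometry: density profile, thickness via per-leaflet Gaussian
# fits, area per lipid, sphere-fit curvature, edge headgroup count.

#' Geometry analysis parameters
#'
#' @param density_bin z-bin width for the density profile (Angstrom,
#'   default 0.5).
#' @param core_radius radius of the core cylinder restricting most
#'   bilayer-property analyses (Angstrom, default 40).
#' @param edge_slab thickness of the midplane slab for the edge headgroup
#'   count (Angstrom, default 10).
#' @return list of class `dln_geometry_params`.
#' @export
geometry_params <- function(density_bin = 0.5, core_radius = 40,
                            edge_slab = 10) {
  stopifnot(density_bin > 0, core_radius > 0, edge_slab > 0)
  structure(list(density_bin = density_bin, core_radius = core_radius,
                 edge_slab = edge_slab), class = "dln_geometry_params")
}

#' Number density profile along the bilayer normal
#'
#' Counts of the selected atoms per z-bin, restricted to the core
#' cylinder, normalized to a density per Angstrom.
#'
#' @param frame aligned coordinate matrix.
#' @param idx 1-based indices of the profiled atoms.
#' @param params a [geometry_params()].
#' @return data.frame `z` (bin centers), `density` (atoms per Angstrom).
#' @export
density_profile <- function(frame, idx, params = geometry_params()) {
  if (length(idx) == 0) stop("empty selection")
  pos <- frame[idx, , drop = FALSE]
  keep <- pos[, 1]^2 + pos[, 2]^2 <= params$core_radius^2
  z <- pos[keep, 3]
  if (!length(z)) stop("no selected atoms inside the core cylinder")
  h <- params$density_bin
  # bins aligned so that z = 0 is a bin boundary
  b <- floor(z / h)
  rng <- range(b)
  counts <- tabulate(b - rng[1] + 1L, nbins = rng[2] - rng[1] + 1L)
  data.frame(z = (seq(rng[1], rng[2]) + 0.5) * h, density = counts / h)
}

fit_gaussian <- function(z, dens) {
  w <- dens / sum(dens)
  mu0 <- sum(w * z)
  s0 <- sqrt(max(sum(w * (z - mu0)^2), 1e-4))
  a0 <- max(dens)
  if (sum(dens > 0) < 3) {
    # fewer occupied bins than free parameters: fall back to moments
    return(c(a = a0, mu = mu0, s = s0))
  }
  span <- max(diff(range(z)), 1)
  fit <- try(minpack.lm::nlsLM(
    dens ~ a * exp(-(z - mu)^2 / (2 * s^2)),
    start = list(a = a0, mu = mu0, s = s0),
    lower = c(0, min(z) - span, 1e-4),
    upper = c(Inf, max(z) + span, 2 * span),
    control = minpack.lm::nls.lm.control(maxiter = 500),
    data = data.frame(z = z, dens = dens)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("Gaussian leaflet fit did not converge: ", attr(fit, "condition")$message)
  coef(fit)
}

#' Bilayer thickness from per-leaflet Gaussian fits
#'
#' The profile is split at z = 0; a Gaussian (amplitude, mean, width) is
#' least-squares fitted to each side (initialized from empirical
#' moments); thickness = mu_upper - mu_lower.
#'
#' @param profile result of [density_profile()].
#' @return thickness (Angstrom), with attribute `fits` (the two
#'   coefficient vectors).
#' @export
thickness <- function(profile) {
  up <- profile[profile$z > 0, ]
  lo <- profile[profile$z < 0, ]
  if (sum(up$density) == 0 || sum(lo$density) == 0)
    stop("density profile is one-sided; cannot fit both leaflets")
  fu <- fit_gaussian(up$z, up$density)
  fl <- fit_gaussian(lo$z, lo$density)
  structure(unname(fu["mu"] - fl["mu"]), fits = list(upper = fu, lower = fl))
}

#' Area per lipid in the core cylinder
#'
#' Per leaflet, APL = pi * core_radius^2 / (number of that leaflet's C2
#' atoms inside the cylinder); the two leaflet values are averaged.
#' If the core cylinder extends beyond the patch the count is an
#' undercount; this is flagged with a warning, not an error.
#'
#' @param frame aligned coordinate matrix.
#' @param atoms atom table.
#' @param sel selection configuration.
#' @param params a [geometry_params()].
#' @return area per lipid (Angstrom^2).
#' @export
area_per_lipid <- function(frame, atoms, sel, params = geometry_params()) {
  lf <- assign_leaflets(frame, atoms, sel)
  lf <- lf[lf$role == "lipid", ]
  rho2 <- lf$x^2 + lf$y^2
  if (max(sqrt(rho2)) < params$core_radius)
    warning("core cylinder (", params$core_radius,
            " A) extends beyond the patch; area per lipid will be overestimated")
  core <- rho2 <= params$core_radius^2
  n_up <- sum(core & lf$leaflet == "upper")
  n_lo <- sum(core & lf$leaflet == "lower")
  if (n_up == 0 || n_lo == 0) stop("no C2 atoms in the core cylinder")
  mean(pi * params$core_radius^2 / c(n_up, n_lo))
}

sag <- function(rho2, c0) {
  if (c0 == 0) return(rep(0, length(rho2)))
  c0 * rho2 / (1 + sqrt(pmax(0, 1 - c0^2 * rho2)))
}

fit_cap <- function(x, y, z, label) {
  rho2 <- x^2 + y^2
  cmax <- 0.999 / sqrt(max(rho2))
  fit <- try(minpack.lm::nlsLM(
    z ~ z0 + c0 * rho2 / (1 + sqrt(pmax(1e-12, 1 - c0^2 * rho2))),
    start = list(z0 = mean(z), c0 = 0),
    lower = c(-Inf, -cmax), upper = c(Inf, cmax),
    control = minpack.lm::nls.lm.control(maxiter = 500),
    data = data.frame(z = z, rho2 = rho2)), silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("sphere fit failed for ", label, " leaflet: ",
         attr(fit, "condition")$message)
  coef(fit)[["c0"]]
}

#' Sphere-fit curvature of the bilayer
#'
#' Per leaflet, the spherical-cap model
#' `z(rho) = z0 + c*rho^2 / (1 + sqrt(1 - c^2 rho^2))`
#' is fitted to the C2 atoms in the core cylinder by nonlinear least
#' squares with the normal shift `z0` and the curvature `c` as the free
#' parameters (the sag parameterization keeps the flat limit c -> 0
#' well-defined); the two leaflets' curvatures are averaged. Positive c
#' means the rim sits above the patch center (+z side) after alignment.
#'
#' @param frame aligned coordinate matrix.
#' @param atoms atom table.
#' @param sel selection configuration.
#' @param params a [geometry_params()]; set `core_radius` large to fit
#'   the whole patch.
#' @return signed curvature (1/Angstrom), attribute `per_leaflet`.
#' @export
fit_curvature <- function(frame, atoms, sel, params = geometry_params()) {
  lf <- assign_leaflets(frame, atoms, sel)
  lf <- lf[lf$role == "lipid", ]
  core <- lf$x^2 + lf$y^2 <= params$core_radius^2
  cs <- vapply(c("upper", "lower"), function(side) {
    s <- lf[core & lf$leaflet == side, ]
    if (nrow(s) < 10) stop("fewer than 10 headgroup atoms in ", side, " leaflet")
    fit_cap(s$x, s$y, s$z, side)
  }, numeric(1))
  structure(mean(cs), per_leaflet = cs)
}

#' Edge headgroup count
#'
#' Number of lipid C2 atoms in the slab |z| <= edge_slab/2 centered on
#' the bilayer midplane, with no radial restriction. Lipids lying flat in
#' the bilayer edge populate this slab.
#'
#' @inheritParams area_per_lipid
#' @return integer count.
#' @export
edge_headgroup_count <- function(frame, atoms, sel, params = geometry_params()) {
  ref <- select_atoms(atoms, sel, "reference", roles = "lipid")
  sum(abs(frame[ref, 3]) <= params$edge_slab / 2)
}

#' Per-frame bilayer geometry series
#'
#' @param traj aligned `dln_trajectory`.
#' @param sel selection configuration.
#' @param params a [geometry_params()].
#' @param block optional block-average window (ns).
#' @return data.frame: `time`, `thickness`, `apl`, `curvature`,
#'   `edge_count`.
#' @export
geometry_series <- function(traj, sel, params = geometry_params(),
                            block = NULL) {
  atoms <- traj$atoms
  ref <- select_atoms(atoms, sel, "reference", roles = "lipid")
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    prof <- density_profile(fr, ref, params)
    data.frame(time = traj$times[f],
               thickness = as.numeric(thickness(prof)),
               apl = suppressWarnings(area_per_lipid(fr, atoms, sel, params)),
               curvature = as.numeric(fit_curvature(fr, atoms, sel, params)),
               edge_count = edge_headgroup_count(fr, atoms, sel, params))
  })
  out <- do.call(rbind, rows)
  if (!is.null(block)) {
    out <- data.frame(
      time = block_average(out$time, out$thickness, block)$time,
      thickness = block_average(out$time, out$thickness, block)$value,
      apl = block_average(out$time, out$apl, block)$value,
      curvature = block_average(out$time, out$curvature, block)$value,
      edge_count = block_average(out$time, out$edge_count, block)$value)
  }
  out
}
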