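# Solvent-accessible surface area (Shrake-Rupley) and the occluded
# fraction of the lipid-tail surface.

#' Quasi-uniform unit sphere points (Fibonacci lattice)
#'
#' @param n number of points (default 960).
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n = 960) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area of a target atom set in context
#'
#' Shrake-Rupley estimate: for each target atom, the fraction of sphere
#' points at radius `r_i + probe` not inside any other context atom's
#' inflated sphere, times `4*pi*(r_i+probe)^2`. Neighbor lookup uses a
#' spatial grid, so cost is near-linear in the context size.
#'
#' @param frame `n x 3` coordinate matrix.
#' @param atoms atom table (provides radii).
#' @param target 1-based indices of the atoms whose area is measured.
#' @param context 1-based indices of atoms present (must contain
#'   `target`); atoms outside `context` are treated as solvent.
#' @param probe_radius probe radius (Angstrom, default 2.0).
#' @param n_sphere_points sampling density (default 960; >= 92).
#' @return total area (Angstrom^2) with attribute `per_atom`.
#' @export
sasa <- function(frame, atoms, target, context = target,
                 probe_radius = 2.0, n_sphere_points = 960) {
  stopifnot(probe_radius > 0, n_sphere_points >= 92)
  if (length(target) == 0) stop("empty target selection")
  if (!all(target %in% context)) stop("target must be a subset of context")
  r <- atoms$vdw_radius[context]
  if (any(!is.finite(r)) || any(r <= 0)) stop("atom with no usable radius")
  pts <- fibonacci_sphere(n_sphere_points)
  tpos <- match(target, context) - 1L
  a <- sasa_cpp(frame[context, , drop = FALSE], r, tpos, probe_radius, pts)
  structure(sum(a), per_atom = a)
}

#' Occluded fraction of the lipid-tail surface
#'
#' The tail area is computed twice: once with only lipid atoms present
#' (occluders treated as part of the solvent) and once with the occluder
#' atoms (polymer + detergent species) included in the context. The
#' difference is the tail area occluded by the occluders; dividing by the
#' occluder-free area gives the occluded fraction.
#'
#' @param frame coordinate matrix.
#' @param atoms atom table.
#' @param sel a `dln_selection`; targets are the tail atoms of
#'   lipid-role species, occluders all atoms of polymer/detergent species.
#' @param probe_radius,n_sphere_points see [sasa()].
#' @return list with `area_free`, `area_in_context`, `occluded_area`,
#'   `occluded_fraction`.
#' @export
occluded_fraction <- function(frame, atoms, sel, probe_radius = 2.0,
                              n_sphere_points = 960) {
  tails <- select_atoms(atoms, sel, "tails", roles = "lipid")
  if (length(tails) == 0) stop("empty target (tail) selection")
  lipid <- select_role_atoms(atoms, sel, "lipid")
  occl <- select_role_atoms(atoms, sel, c("polymer", "detergent"))
  a_free <- as.numeric(sasa(frame, atoms, tails, lipid,
                            probe_radius, n_sphere_points))
  a_ctx <- as.numeric(sasa(frame, atoms, tails, sort(c(lipid, occl)),
                           probe_radius, n_sphere_points))
  occ <- a_free - a_ctx
  list(area_free = a_free, area_in_context = a_ctx, occluded_area = occ,
       occluded_fraction = if (a_free > 0) occ / a_free else 0)
}

#' Occlusion time series over a trajectory
#'
#' @param traj a `dln_trajectory` (aligned or not; SASA is
#'   rigid-body invariant).
#' @param sel selection configuration.
#' @param probe_radius,n_sphere_points see [sasa()].
#' @param block optional block-average window (ns); `NULL` for raw series.
#' @return data.frame: `time`, `area_free`, `area_in_context`,
#'   `occluded_fraction` (block-averaged when `block` is given).
#' @export
occlusion_series <- function(traj, sel, probe_radius = 2.0,
                             n_sphere_points = 960, block = NULL) {
  res <- lapply(seq_len(n_frames(traj)), function(f)
    occluded_fraction(get_frame(traj, f), traj$atoms, sel,
                      probe_radius, n_sphere_points))
  out <- data.frame(time = traj$times,
                    area_free = vapply(res, `[[`, 1, "area_free"),
                    area_in_context = vapply(res, `[[`, 1, "area_in_context"),
                    occluded_fraction = vapply(res, `[[`, 1, "occluded_fraction"))
  if (!is.null(block)) {
    out <- data.frame(
      time = block_average(out$time, out$area_free, block)$time,
      area_free = block_average(out$time, out$area_free, block)$value,
      area_in_context = block_average(out$time, out$area_in_context, block)$value,
      occluded_fraction = block_average(out$time, out$occluded_fraction, block)$value)
  }
  out
}
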