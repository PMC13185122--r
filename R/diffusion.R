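# Lateral diffusion: in-plane mean-square displacement of the lipid
# reference atoms, diffusion coefficients from the MSD slope, and the
# expected diffusion displacement.

#' Diffusion analysis parameters
#'
#' @param strides lag times (ns); default 1, 2, 4, ..., 128 (powers of
#'   two).
#' @param core_radius membership cylinder radius (Angstrom, default 40).
#' @param membership "initial-frame" (default; a lipid contributes a
#'   displacement if it is inside the core at the time origin) or
#'   "both-endpoints".
#' @return list of class `dln_diffusion_params`.
#' @export
diffusion_params <- function(strides = 2^(0:7), core_radius = 40,
                             membership = c("initial-frame", "both-endpoints")) {
  stopifnot(all(strides > 0), all(diff(strides) > 0), core_radius > 0)
  structure(list(strides = strides, core_radius = core_radius,
                 membership = match.arg(membership)),
            class = "dln_diffusion_params")
}

#' In-plane mean-square displacement of a species
#'
#' For each stride tau, the average over all time origins t and all
#' molecules of `species` satisfying the membership criterion of
#' |r_xy(t+tau) - r_xy(t)|^2, displacements projected into the bilayer
#' plane (x, y after alignment).
#'
#' @param traj aligned `dln_trajectory` with uniform frame spacing.
#' @param species species key.
#' @param sel selection configuration.
#' @param params a [diffusion_params()].
#' @return data.frame: `stride` (ns), `msd` (Angstrom^2), `n_pairs`.
#'   Strides with no valid origin are omitted with a warning.
#' @export
msd <- function(traj, species, sel, params = diffusion_params()) {
  ref <- select_atoms(traj$atoms, sel, "reference",
                      roles = c("lipid", "detergent"), species = species)
  if (length(ref) == 0) stop("species ", species, " absent")
  nf <- n_frames(traj)
  dt <- diff(traj$times)
  if (max(dt) - min(dt) > 1e-9 * max(dt))
    stop("msd requires uniform frame spacing")
  dt <- dt[1]
  x <- traj$coords[ref, 1, , drop = FALSE][, 1, ]   # n_mol x nf
  y <- traj$coords[ref, 2, , drop = FALSE][, 1, ]
  if (length(ref) == 1) { x <- matrix(x, 1); y <- matrix(y, 1) }
  incore <- x^2 + y^2 <= params$core_radius^2
  rows <- list()
  for (tau in params$strides) {
    s <- as.integer(round(tau / dt))
    if (s < 1 || s >= nf) {
      warning("stride ", tau, " ns outside trajectory span; omitted")
      next
    }
    o <- seq_len(nf - s)
    dx <- x[, o + s, drop = FALSE] - x[, o, drop = FALSE]
    dy <- y[, o + s, drop = FALSE] - y[, o, drop = FALSE]
    mem <- incore[, o, drop = FALSE]
    if (params$membership == "both-endpoints")
      mem <- mem & incore[, o + s, drop = FALSE]
    n <- sum(mem)
    if (n == 0) {
      warning("no valid origin for stride ", tau, " ns; omitted")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      stride = s * dt, msd = sum((dx^2 + dy^2)[mem]) / n, n_pairs = n)
  }
  if (!length(rows)) stop("no stride could be evaluated")
  do.call(rbind, rows)
}

#' Diffusion coefficient from an MSD table
#'
#' Ordinary least-squares slope of MSD versus stride over all strides;
#' D = slope / 4 (two-dimensional diffusion). An additive offset in the
#' MSD (e.g. localization noise) is absorbed by the intercept.
#'
#' @param msd_table result of [msd()].
#' @return D (Angstrom^2/ns) with attributes `r_squared` and `slope`.
#' @export
diffusion_coefficient <- function(msd_table) {
  if (nrow(msd_table) < 2) stop("need at least 2 strides to fit a slope")
  fit <- lm(msd ~ stride, data = msd_table)
  # summary.lm warns on exact fits (zero residual); that case is fine here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(unname(coef(fit)[2] / 4),
            r_squared = r2,
            slope = unname(coef(fit)[2]))
}

#' Expected diffusion displacement
#'
#' Root-mean-square in-plane displacement sqrt(4 D t) of a
#' two-dimensional random walk, reported to 2 significant figures.
#'
#' @param D diffusion coefficient (Angstrom^2/ns).
#' @param t time horizon (ns).
#' @return displacement (Angstrom, 2 significant figures).
#' @export
expected_displacement <- function(D, t) {
  stopifnot(D >= 0, t >= 0)
  signif(sqrt(4 * D * t), 2)
}
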