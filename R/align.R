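# Frame preprocessing: center the lipid reference atoms (C2) at the origin
# and rotate their principal axes onto the Cartesian axes so that the
# bilayer normal is z. All downstream analyses assume aligned frames.

#' Align trajectory frames to the bilayer principal axes
#'
#' Per frame, translates the center of mass of the lipid reference atoms
#' (the C2 atoms; unit masses) to the origin and rotates the frame so that
#' the principal axes of the reference atoms coincide with the Cartesian
#' axes, mapping the smallest-spatial-extent axis to z (the bilayer
#' normal). Axis signs: for the first frame each principal axis is
#' oriented so its largest-magnitude component is positive, with the
#' z-axis then flipped if needed for a proper (det = +1) rotation;
#' subsequent frames choose signs for continuity with the previous frame,
#' which keeps leaflet labels stable across frames.
#'
#' @param traj a `dln_trajectory`.
#' @param sel a `dln_selection`; reference atoms are the
#'   `reference_atom` of every lipid-role species.
#' @details The bilayer normal (smallest principal axis) is determined
#'   independently for every frame. The in-plane axes, however, are only
#'   taken from the eigenvectors in the first frame: for a nearly
#'   isotropic disc the two in-plane eigenvalues are almost degenerate
#'   and their eigenvectors swing randomly from frame to frame, which
#'   would inject spurious rigid rotation into every lateral observable
#'   (most damagingly the MSD). Later frames instead carry the previous
#'   frame's in-plane axes forward, projected onto the current normal
#'   plane and re-orthonormalized — a smooth gauge with no eigen noise.
#' @return the aligned `dln_trajectory`.
#' @export
preprocess_align <- function(traj, sel) {
  ref_idx <- select_atoms(traj$atoms, sel, "reference", roles = "lipid")
  if (length(ref_idx) < 3) stop("need >= 3 reference atoms to align")
  coords <- traj$coords
  prev_axes <- NULL
  for (f in seq_len(n_frames(traj))) {
    fr <- coords[, , f]
    ref <- fr[ref_idx, , drop = FALSE]
    com <- colMeans(ref)
    ref <- sweep(ref, 2, com)
    cv <- crossprod(ref) / nrow(ref)
    eg <- eigen(cv, symmetric = TRUE)  # values already decreasing
    if (eg$values[2] <= 1e-10 * max(eg$values[1], 1))
      stop("degenerate (collinear) reference configuration")
    if (is.null(prev_axes)) {
      # columns: largest variance -> x, middle -> y, smallest -> z
      axes <- eg$vectors[, order(eg$values, decreasing = TRUE)]
      axes <- orient_axes(axes, ref)
    } else {
      n <- eg$vectors[, which.min(eg$values)]
      if (sum(n * prev_axes[, 3]) < 0) n <- -n
      x <- prev_axes[, 1] - sum(prev_axes[, 1] * n) * n
      x <- x / sqrt(sum(x^2))
      y <- c(n[2] * x[3] - n[3] * x[2],   # z cross x
             n[3] * x[1] - n[1] * x[3],
             n[1] * x[2] - n[2] * x[1])
      axes <- cbind(x, y, n, deparse.level = 0)
    }
    prev_axes <- axes
    coords[, , f] <- sweep(fr, 2, com) %*% axes
  }
  trajectory(traj$atoms, coords, times = traj$times, box = traj$box)
}

# First-frame axis-sign convention: orient each axis by the sign of the
# third moment of the reference-atom projections (a rotation-invariant
# functional of the point set, so a rigidly rotated trajectory aligns to
# the identical output); axes with negligible third moment fall back to
# the largest-magnitude-component rule; determinant forced to +1 by
# flipping an in-plane axis (never z, so the normal keeps its
# orientation and leaflet labels agree with an already-aligned input).
orient_axes <- function(axes, ref) {
  scale3 <- mean(rowSums(ref^2))^1.5 * nrow(ref)
  s3 <- numeric(3)
  for (k in 1:3) {
    p <- ref %*% axes[, k]
    s3[k] <- sum(p^3)
    if (abs(s3[k]) > 1e-8 * scale3) {
      if (s3[k] < 0) axes[, k] <- -axes[, k]
    } else {
      j <- which.max(abs(axes[, k]))
      if (axes[j, k] < 0) axes[, k] <- -axes[, k]
    }
  }
  if (det(axes) < 0) {
    k <- which.min(abs(s3[1:2]))
    axes[, k] <- -axes[, k]
  }
  axes
}
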