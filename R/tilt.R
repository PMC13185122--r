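# Tilt collective variable: least-RMSD rotation of the lipid C2 atoms
# onto a reference, decomposed (swing-twist) into a spin about the
# bilayer normal and a tilt about an in-plane axis.

#' Least-RMSD rotation between two point sets
#'
#' Quaternion (Horn) method: the proper rotation R minimizing
#' sum |R p_i - q_i|^2 after removing both centroids, where p = current
#' and q = reference. Deterministic; always a proper rotation.
#'
#' @param current,reference `n x 3` matrices, equal n >= 3,
#'   non-collinear.
#' @return 3 x 3 rotation matrix with attribute `quaternion`
#'   (w, x, y, z).
#' @export
best_fit_rotation <- function(current, reference) {
  stopifnot(nrow(current) == nrow(reference), nrow(current) >= 3)
  P <- sweep(current, 2, colMeans(current))
  Q <- sweep(reference, 2, colMeans(reference))
  if (svd(P)$d[2] < 1e-9 * max(svd(P)$d[1], 1) ||
      svd(Q)$d[2] < 1e-9 * max(svd(Q)$d[1], 1))
    stop("degenerate (collinear) point set")
  S <- crossprod(P, Q)   # sum p_i q_i^T
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  eg <- eigen(K, symmetric = TRUE)
  q <- eg$vectors[, 1]
  if (q[1] < 0) q <- -q
  structure(quat_to_matrix(q), quaternion = q)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
    3, 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  w <- sqrt(max(0, 1 + R[1,1] + R[2,2] + R[3,3])) / 2
  if (w > 1e-8) {
    q <- c(w, (R[3,2] - R[2,3]) / (4*w), (R[1,3] - R[3,1]) / (4*w),
           (R[2,1] - R[1,2]) / (4*w))
  } else {
    # near 180 degrees: take the dominant diagonal branch
    k <- which.max(diag(R))
    if (k == 1) {
      x <- sqrt(max(0, 1 + R[1,1] - R[2,2] - R[3,3])) / 2
      q <- c((R[3,2]-R[2,3])/(4*x), x, (R[1,2]+R[2,1])/(4*x), (R[1,3]+R[3,1])/(4*x))
    } else if (k == 2) {
      y <- sqrt(max(0, 1 - R[1,1] + R[2,2] - R[3,3])) / 2
      q <- c((R[1,3]-R[3,1])/(4*y), (R[1,2]+R[2,1])/(4*y), y, (R[2,3]+R[3,2])/(4*y))
    } else {
      z <- sqrt(max(0, 1 - R[1,1] - R[2,2] + R[3,3])) / 2
      q <- c((R[2,1]-R[1,2])/(4*z), (R[1,3]+R[3,1])/(4*z), (R[2,3]+R[3,2])/(4*z), z)
    }
  }
  q / sqrt(sum(q^2))
}

#' Swing-twist decomposition of a rotation
#'
#' Factors a proper rotation as R = R_tilt %*% R_spin where R_spin
#' (twist) is about the bilayer normal (z) and R_tilt (swing) is about an
#' axis in the xy-plane. Returns the spin and tilt angles, cos(tilt),
#' and the tilt-axis azimuth (0 by convention when tilt ~ 0). A 180
#' degree tilt (w = z = 0) takes the identity-twist branch.
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return list of class `dln_tilt_state`: `spin_angle`, `tilt_angle`
#'   (degrees), `cos_tilt`, `tilt_axis_azimuth` (degrees), `R_spin`,
#'   `R_tilt`.
#' @export
decompose_spin_tilt <- function(R) {
  q <- attr(R, "quaternion")
  if (is.null(q)) q <- matrix_to_quat(R)
  wz <- sqrt(q[1]^2 + q[4]^2)
  if (wz < 1e-12) {
    q_tw <- c(1, 0, 0, 0)          # 180-degree tilt branch: no twist
  } else {
    q_tw <- c(q[1], 0, 0, q[4]) / wz
  }
  # swing = q * conj(q_tw)
  q_sw <- quat_mul(q, c(q_tw[1], 0, 0, -q_tw[4]))
  if (q_sw[1] < 0) q_sw <- -q_sw
  vnorm <- sqrt(sum(q_sw[2:4]^2))
  tilt <- 2 * atan2(vnorm, q_sw[1])
  spin <- 2 * atan2(q_tw[4], q_tw[1])
  if (spin > pi) spin <- spin - 2 * pi
  az <- if (vnorm < 1e-9) 0 else atan2(q_sw[3], q_sw[2])
  structure(list(spin_angle = spin * 180 / pi,
                 tilt_angle = tilt * 180 / pi,
                 cos_tilt = cos(tilt),
                 tilt_axis_azimuth = az * 180 / pi,
                 R_spin = quat_to_matrix(q_tw),
                 R_tilt = quat_to_matrix(q_sw)),
            class = "dln_tilt_state")
}

quat_mul <- function(a, b) {
  c(a[1]*b[1] - a[2]*b[2] - a[3]*b[3] - a[4]*b[4],
    a[1]*b[2] + a[2]*b[1] + a[3]*b[4] - a[4]*b[3],
    a[1]*b[3] - a[2]*b[4] + a[3]*b[1] + a[4]*b[2],
    a[1]*b[4] + a[2]*b[3] - a[3]*b[2] + a[4]*b[1])
}

#' Tilt collective variable over a trajectory
#'
#' Per frame: best-fit rotation of a subsampled set of lipid C2 atoms
#' onto the reference frame (default: the first frame), then the
#' swing-twist decomposition. Including every `subsample`-th lipid
#' (default 4) mirrors the restraint definition used during the
#' simulations.
#'
#' @param traj `dln_trajectory`.
#' @param sel selection configuration.
#' @param subsample keep every k-th lipid C2 atom (default 4).
#' @param reference_frame index of the reference frame (default 1).
#' @return data.frame: `time`, `cos_tilt`, `tilt_deg`, `spin_deg`,
#'   `azimuth_deg`.
#' @export
tilt_series <- function(traj, sel, subsample = 4, reference_frame = 1) {
  ref_idx <- select_atoms(traj$atoms, sel, "reference", roles = "lipid")
  ref_idx <- ref_idx[seq(1, length(ref_idx), by = subsample)]
  if (length(ref_idx) < 3) stop("subsampled reference set too small")
  ref <- get_frame(traj, reference_frame)[ref_idx, , drop = FALSE]
  rows <- lapply(seq_len(n_frames(traj)), function(f) {
    cur <- get_frame(traj, f)[ref_idx, , drop = FALSE]
    st <- decompose_spin_tilt(best_fit_rotation(cur, ref))
    data.frame(time = traj$times[f], cos_tilt = st$cos_tilt,
               tilt_deg = st$tilt_angle, spin_deg = st$spin_angle,
               azimuth_deg = st$tilt_axis_azimuth)
  })
  do.call(rbind, rows)
}

#' Harmonic restraint energy on the cosine of the tilt
#'
#' E = k/2 * (cos(tilt) - target)^2, the restraint used to guide the
#' bilayer normal back to the box axis.
#'
#' @param state a `dln_tilt_state` (or a number, taken as cos_tilt).
#' @param spring_constant k (energy per unit cos^2; default 10000).
#' @param target_cos restraint target (default 1, i.e. untilted).
#' @return energy (same units as k).
#' @export
restraint_energy <- function(state, spring_constant = 10000, target_cos = 1) {
  stopifnot(spring_constant >= 0, abs(target_cos) <= 1)
  ct <- if (is.list(state)) state$cos_tilt else state
  0.5 * spring_constant * (ct - target_cos)^2
}
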