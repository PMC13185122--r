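# Independent oracles used to validate the package's accelerated
# implementations. These deliberately use different algorithms:
# latitude-longitude quadrature instead of a Fibonacci lattice for SASA,
# chunked all-pairs distances instead of a cell list for contacts, a
# plain nested loop for MSD, and a forward per-frame scan for debounced
# flip detection.

# Fine-grid surface integration SASA oracle (per-target-atom sum).
oracle_sasa <- function(frame, radii, target, context, probe,
                        n_theta = 60, n_phi = 120) {
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  dirs <- cbind(rep(sin(th), n_phi) * cos(rep(ph, each = n_theta)),
                rep(sin(th), n_phi) * sin(rep(ph, each = n_theta)),
                rep(cos(th), n_phi))
  w <- rep(sin(th), n_phi) * (pi / n_theta) * (2 * pi / n_phi)
  total <- 0
  cpos <- frame[context, , drop = FALSE]
  crad <- radii[context] + probe
  for (i in target) {
    ri <- radii[i] + probe
    ci <- frame[i, ]
    d2c <- colSums((t(cpos) - ci)^2)
    nbr <- which(d2c < (ri + crad)^2 & d2c > 1e-12)
    pts <- sweep(dirs * ri, 2, ci, `+`)
    acc <- rep(TRUE, nrow(pts))
    for (j in nbr) {
      dj2 <- (pts[, 1] - cpos[j, 1])^2 + (pts[, 2] - cpos[j, 2])^2 +
        (pts[, 3] - cpos[j, 3])^2
      acc <- acc & dj2 >= crad[j]^2
      if (!any(acc)) break
    }
    total <- total + ri^2 * sum(w[acc])
  }
  total
}

oracle_occluded_fraction <- function(frame, atoms, sel, probe = 2.0, ...) {
  tails <- select_atoms(atoms, sel, "tails", roles = "lipid")
  lipid <- select_role_atoms(atoms, sel, "lipid")
  occl <- select_role_atoms(atoms, sel, c("polymer", "detergent"))
  a_free <- oracle_sasa(frame, atoms$vdw_radius, tails, lipid, probe, ...)
  a_ctx <- oracle_sasa(frame, atoms$vdw_radius, tails, sort(c(lipid, occl)),
                       probe, ...)
  list(area_free = a_free, area_in_context = a_ctx,
       occluded_fraction = (a_free - a_ctx) / a_free)
}

# O(N^2) all-pairs contact count, chunked to bound memory.
oracle_contacts <- function(frame, groupA, groupB, cutoff, chunk = 500) {
  A <- frame[groupA, , drop = FALSE]
  B <- frame[groupB, , drop = FALSE]
  total <- 0
  for (s in seq(1, nrow(A), by = chunk)) {
    e <- min(s + chunk - 1, nrow(A))
    d2 <- outer(rowSums(A[s:e, , drop = FALSE]^2), rowSums(B^2), `+`) -
      2 * A[s:e, , drop = FALSE] %*% t(B)
    total <- total + sum(d2 <= cutoff^2 + 1e-9)
  }
  total
}

# Plain nested-loop MSD over all origins, initial-frame core membership.
oracle_msd <- function(traj, species, sel, strides, core_radius) {
  ref <- select_atoms(traj$atoms, sel, "reference",
                      roles = c("lipid", "detergent"), species = species)
  dt <- diff(traj$times)[1]
  nf <- n_frames(traj)
  out <- data.frame(stride = numeric(), msd = numeric(), n_pairs = numeric())
  for (tau in strides) {
    s <- round(tau / dt)
    if (s < 1 || s >= nf) next
    acc <- 0; n <- 0
    for (m in ref) {
      for (o in seq_len(nf - s)) {
        x0 <- traj$coords[m, 1, o]; y0 <- traj$coords[m, 2, o]
        if (x0^2 + y0^2 > core_radius^2) next
        dx <- traj$coords[m, 1, o + s] - x0
        dy <- traj$coords[m, 2, o + s] - y0
        acc <- acc + dx^2 + dy^2
        n <- n + 1
      }
    }
    if (n > 0) out <- rbind(out, data.frame(stride = s * dt, msd = acc / n,
                                            n_pairs = n))
  }
  out
}

# Forward-scan debounced flip oracle on a per-molecule label series.
oracle_flips_one <- function(labels, times, persistence) {
  nf <- length(labels)
  persists <- function(f) {
    g <- f
    while (g < nf && labels[g + 1] == labels[f]) g <- g + 1
    (times[g] - times[f] >= persistence) || g == nf
  }
  confirmed <- NA
  events <- integer()
  f <- 1
  while (f <= nf) {
    if (is.na(confirmed)) {
      if (persists(f)) confirmed <- labels[f]
    } else if (labels[f] != confirmed && (f == 1 || labels[f] != labels[f - 1])) {
      if (persists(f)) {
        events <- c(events, f)
        confirmed <- labels[f]
      }
    }
    f <- f + 1
  }
  events
}

rot_about <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# A modest jittered patch used by several suites (big enough that the
# in-plane extent dominates the leaflet separation, as in the real
# system).
test_patch <- function(radius = 45, seed = 2, jitter = 0.3, jseed = 9) {
  p <- build_patch(patch_spec(radius = radius, seed = seed))
  if (jitter > 0) {
    set.seed(jseed)
    p$frame <- p$frame + matrix(rnorm(length(p$frame), sd = jitter),
                                nrow = nrow(p$frame))
  }
  p
}
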