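# Synthetic bilayer-patch generator. Produces coarse pseudo-atom lipid
# stacks on a jittered triangular lattice inside a disc, rim-hugging
# amphiphilic polymer chains, and seeded Brownian lateral dynamics with
# scripted leaflet flips, optional spherical-cap curvature and rigid
# tilt. Every stochastic step is seeded, so trajectories are
# bit-reproducible and carry known ground truth for the analyses.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Per-species pseudo-atom templates: name, element, z-offset from the C2
# reference (positive = toward the water, i.e. away from the midplane)
# and lateral offset (Angstrom, applied along a per-lipid random azimuth;
# the two tail chains of a diacyl lipid sit on opposite sides).
species_templates <- function() {
  two_chains <- list(c("C3A", "C", -4.5, 2.2), c("C4A", "C", -9.0, 2.2),
                     c("C5A", "C", -13.5, 2.2), c("C6A", "C", -16.5, 2.2),
                     c("C3B", "C", -4.5, -2.2), c("C4B", "C", -9.0, -2.2),
                     c("C5B", "C", -13.5, -2.2), c("C6B", "C", -16.5, -2.2))
  head_pcpe <- list(c("N", "N", 4.0, 0), c("P", "P", 2.5, 0),
                    c("O21", "O", 1.0, 0), c("C2", "C", 0.0, 0))
  list(
    DMPC = c(head_pcpe, two_chains),
    DMPE = c(head_pcpe, two_chains),
    DMTAP = c(list(c("N", "N", 2.5, 0), c("O21", "O", 1.0, 0),
                   c("C2", "C", 0.0, 0)), two_chains),
    DTAB = list(c("N", "N", 2.0, 0), c("C2", "C", 0.0, 0),
                c("C3A", "C", -4.5, 1.1), c("C4A", "C", -9.0, -1.1))
  )
}

#' Specify a circular bilayer patch
#'
#' Defaults reproduce the simulated nanodisc membrane: a 79 Angstrom
#' radius patch of 90% DMPC, 9% DMTAP and 1% DMPE at 69.5 Angstrom^2 per
#' lipid (282 lipids per leaflet, 564 total) with the two C2 planes 35
#' Angstrom apart.
#'
#' @param radius patch radius (Angstrom).
#' @param area_per_lipid area per lipid (Angstrom^2).
#' @param species_fractions named fractions summing to 1.
#' @param leaflet_separation C2-plane-to-C2-plane distance (Angstrom).
#' @param seed integer seed for lattice jitter and species assignment.
#' @return list of class `dln_patch_spec`.
#' @export
patch_spec <- function(radius = 79, area_per_lipid = 69.5,
                       species_fractions = c(DMPC = 0.90, DMTAP = 0.09,
                                             DMPE = 0.01),
                       leaflet_separation = 35, seed = 1) {
  stopifnot(radius > 0, area_per_lipid > 0, leaflet_separation > 0)
  if (abs(sum(species_fractions) - 1) > 1e-9)
    stop("species fractions must sum to 1")
  structure(list(radius = radius, area_per_lipid = area_per_lipid,
                 species_fractions = species_fractions,
                 leaflet_separation = leaflet_separation, seed = seed),
            class = "dln_patch_spec")
}

# Triangular lattice points sorted by distance from the origin.
tri_lattice <- function(spacing, n_needed, radius) {
  m <- ceiling((radius + 3 * spacing) / spacing) + 2
  ij <- expand.grid(i = -m:m, j = -m:m)
  x <- spacing * (ij$i + 0.5 * ij$j)
  y <- spacing * (sqrt(3) / 2) * ij$j
  ord <- order(x^2 + y^2)
  cbind(x[ord], y[ord])[seq_len(n_needed), , drop = FALSE]
}

#' Build the initial patch configuration
#'
#' Per leaflet, `round(pi * radius^2 / area_per_lipid)` lipids are placed
#' on a jittered triangular lattice at the requested density; species are
#' assigned by a seeded multinomial draw; each lipid is a vertical
#' pseudo-atom stack (head motifs above the C2 reference, tail atoms
#' below, mirrored in the lower leaflet).
#'
#' @param spec a [patch_spec()].
#' @return list with elements `atoms` (atom table) and `frame`
#'   (`n x 3` coordinate matrix).
#' @export
build_patch <- function(spec) {
  n_per_leaflet <- max(1L, as.integer(round(pi * spec$radius^2 / spec$area_per_lipid)))
  if (pi * spec$radius^2 / spec$area_per_lipid < 0.5)
    stop("area_per_lipid too large: cannot place a lipid in the patch")
  spacing <- sqrt(2 * spec$area_per_lipid / sqrt(3))
  tmpl <- species_templates()
  sps <- names(spec$species_fractions)
  if (!all(sps %in% names(tmpl)))
    stop("no template for species: ",
         paste(setdiff(sps, names(tmpl)), collapse = ", "))
  with_seed(spec$seed, {
    rows <- list(); coords <- list(); rid <- 0L
    for (leaf in c(1, -1)) {
      xy <- tri_lattice(spacing, n_per_leaflet, spec$radius)
      xy <- xy + matrix(rnorm(2 * n_per_leaflet, sd = 0.12 * spacing),
                        ncol = 2)
      # keep every lipid inside the disc (small patches spill otherwise)
      rho <- sqrt(rowSums(xy^2))
      out <- rho > spec$radius
      if (any(out)) xy[out, ] <- xy[out, ] * ((spec$radius - 1e-6) / rho[out])
      species <- sample(sps, n_per_leaflet, replace = TRUE,
                        prob = spec$species_fractions)
      z0 <- leaf * spec$leaflet_separation / 2
      psi <- runif(n_per_leaflet, 0, 2 * pi)  # tail-plane azimuth per lipid
      for (k in seq_len(n_per_leaflet)) {
        rid <- rid + 1L
        tm <- tmpl[[species[k]]]
        for (a in tm) {
          rows[[length(rows) + 1L]] <- c(a[1], a[2], species[k], rid)
          lat <- as.numeric(a[4])
          coords[[length(coords) + 1L]] <-
            c(xy[k, 1] + lat * cos(psi[k]), xy[k, 2] + lat * sin(psi[k]),
              z0 + leaf * as.numeric(a[3]))
        }
      }
    }
    rows <- do.call(rbind, rows)
    atoms <- atom_table(atom_name = rows[, 1], element = rows[, 2],
                        residue_name = rows[, 3],
                        residue_id = as.integer(rows[, 4]),
                        segment = "MEMB")
    list(atoms = atoms, frame = do.call(rbind, coords))
  })
}

#' Add rim-hugging polymer chains to a patch
#'
#' Chains of alternating methylene (CP) / ether-oxygen (OP) pseudo-atoms
#' (first atom a linker carbon, CL) are grown as jittered arcs just
#' outside the patch rim, between the leaflet planes, emulating the PEG
#' corona that occludes the lipid tails at the nanodisc edge. All chain
#' atoms stay within 6 Angstrom of the rim cylinder.
#'
#' @param atoms patch atom table.
#' @param frame patch coordinate matrix.
#' @param n_chains number of chains (evenly spaced start azimuths).
#' @param n_monomers atoms per chain.
#' @param radius patch radius the chains hug (Angstrom).
#' @param seed integer seed.
#' @param monomer_spacing arc length between consecutive atoms (Angstrom).
#' @param z_halfwidth half-height of the rim band the chains wander over
#'   (Angstrom; default 17.5, the leaflet-plane height of the standard
#'   patch, so chains sample the whole edge).
#' @return list with updated `atoms` and `frame`.
#' @export
add_edge_polymers <- function(atoms, frame, n_chains, n_monomers, radius,
                              seed = 1, monomer_spacing = 3.5,
                              z_halfwidth = 17.5) {
  if (n_chains == 0) return(list(atoms = atoms, frame = frame))
  stopifnot(n_monomers >= 1)
  with_seed(seed, {
    rid0 <- max(atoms$residue_id)
    nm <- list(); coords <- list()
    for (ch in seq_len(n_chains)) {
      th0 <- 2 * pi * (ch - 1) / n_chains + runif(1, 0, 0.1)
      z <- runif(1, -0.7 * z_halfwidth, 0.7 * z_halfwidth)
      dr <- 0
      for (m in seq_len(n_monomers)) {
        th <- th0 + (m - 1) * monomer_spacing / (radius + 2)
        # radial jitter is a bounded random walk so consecutive monomers
        # stay bonded-distance apart
        dr <- max(-2.5, min(2.5, dr + rnorm(1, sd = 0.4)))
        r <- radius + 2 + dr
        dz <- max(-2.5, min(2.5, rnorm(1, sd = 1.2)))
        z <- max(-z_halfwidth, min(z_halfwidth, z + dz))
        name <- if (m == 1) "CL" else if (m %% 2 == 0) "OP" else "CP"
        nm[[length(nm) + 1L]] <- name
        coords[[length(coords) + 1L]] <- c(r * cos(th), r * sin(th), z)
      }
    }
    n_new <- length(nm)
    chain_id <- rep(seq_len(n_chains), each = n_monomers)
    ele <- ifelse(unlist(nm) == "OP", "O", "C")
    new_atoms <- atom_table(atom_name = unlist(nm), element = ele,
                            residue_name = rep("PEG", n_new),
                            residue_id = rid0 + chain_id,
                            segment = "PEG")
    atoms2 <- rbind(as.data.frame(atoms), as.data.frame(new_atoms))
    atoms2$atom_id <- seq_len(nrow(atoms2)) - 1L
    class(atoms2) <- c("dln_atoms", "data.frame")
    list(atoms = atoms2, frame = rbind(frame, do.call(rbind, coords)))
  })
}

#' Specify the synthetic dynamics
#'
#' @param D_per_species named lateral diffusion coefficients
#'   (Angstrom^2/ns); species without an entry stay static.
#' @param frame_interval frame spacing (ns).
#' @param n_frames number of frames (first frame = initial configuration).
#' @param flip_schedule `data.frame(residue_id, frame)`: at `frame`
#'   (1-based) the lipid with that residue id is mirrored to the opposite
#'   leaflet (instantaneous, all its atoms).
#' @param curvature signed spherical-cap curvature c (1/Angstrom); every
#'   atom is displaced by `z += c*rho^2 / (1 + sqrt(1 - c^2 rho^2))`.
#'   Positive c places the rim above the patch center.
#' @param tilt_schedule `data.frame(frame, tilt_deg, azimuth_deg)`: rigid
#'   rotation of the whole frame about the in-plane axis at the given
#'   azimuth; frames without an entry are untilted.
#' @param seed integer seed for the Brownian steps.
#' @return list of class `dln_dynamics_spec`.
#' @export
dynamics_spec <- function(D_per_species, frame_interval, n_frames,
                          flip_schedule = NULL, curvature = 0,
                          tilt_schedule = NULL, seed = 1) {
  stopifnot(all(D_per_species >= 0), frame_interval > 0, n_frames >= 1)
  if (!is.null(flip_schedule))
    stopifnot(all(flip_schedule$frame >= 1), all(flip_schedule$frame <= n_frames))
  structure(list(D_per_species = D_per_species,
                 frame_interval = frame_interval, n_frames = n_frames,
                 flip_schedule = flip_schedule, curvature = curvature,
                 tilt_schedule = tilt_schedule, seed = seed),
            class = "dln_dynamics_spec")
}

rodrigues <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Simulate seeded lateral dynamics of a patch
#'
#' Molecules of species listed in `D_per_species` perform rigid 2D
#' Brownian steps (per-axis variance `2*D*dt`), reflecting at the patch
#' radius; z stays at the leaflet structure except for scheduled flips,
#' which mirror the lipid about the midplane. Curvature displacement and
#' scheduled rigid tilt are applied after lateral placement. Fully
#' deterministic given the seed.
#'
#' @param atoms patch atom table (possibly with polymers).
#' @param frame0 initial coordinates.
#' @param dyn a [dynamics_spec()].
#' @param radius reflecting patch radius (Angstrom).
#' @return a `dln_trajectory`.
#' @export
simulate_dynamics <- function(atoms, frame0, dyn, radius) {
  nf <- dyn$n_frames
  na <- nrow(atoms)
  mol <- molecule_index(atoms)
  mol_species <- atoms$residue_name[!duplicated(mol)]
  mol_rid <- atoms$residue_id[!duplicated(mol)]
  nmol <- max(mol)
  D_pos <- dyn$D_per_species[dyn$D_per_species > 0]
  moving <- which(mol_species %in% names(D_pos))
  Dm <- D_pos[mol_species[moving]]
  # per-molecule center = mean in-plane position; per-atom offsets fixed
  cx <- tapply(frame0[, 1], mol, mean)[as.character(seq_len(nmol))]
  cy <- tapply(frame0[, 2], mol, mean)[as.character(seq_len(nmol))]
  offx <- frame0[, 1] - cx[mol]
  offy <- frame0[, 2] - cy[mol]
  zbase <- frame0[, 3]
  flip_sign <- rep(1, nmol)
  fs <- dyn$flip_schedule
  coords <- array(NA_real_, dim = c(na, 3, nf))
  sdstep <- sqrt(2 * Dm * dyn$frame_interval)
  with_seed(dyn$seed, {
    px <- cx; py <- cy
    for (f in seq_len(nf)) {
      if (f > 1 && length(moving)) {
        # Metropolis-style boundary: steps that would leave the disc are
        # rejected, which keeps the uniform stationary density exact
        # (a radial fold would pump density inward at O(step/radius))
        nx <- px[moving] + rnorm(length(moving), sd = sdstep)
        ny <- py[moving] + rnorm(length(moving), sd = sdstep)
        ok <- nx^2 + ny^2 <= radius^2
        px[moving[ok]] <- nx[ok]
        py[moving[ok]] <- ny[ok]
      }
      if (!is.null(fs)) {
        hit <- fs$residue_id[fs$frame == f]
        if (length(hit)) flip_sign[match(hit, mol_rid)] <-
            -flip_sign[match(hit, mol_rid)]
      }
      x <- px[mol] + offx
      y <- py[mol] + offy
      z <- flip_sign[mol] * zbase
      if (dyn$curvature != 0) {
        c0 <- dyn$curvature
        rho2 <- pmin(x^2 + y^2, (1 - 1e-9) / c0^2)
        z <- z + c0 * rho2 / (1 + sqrt(pmax(0, 1 - c0^2 * rho2)))
      }
      fr <- cbind(x, y, z)
      ts <- dyn$tilt_schedule
      if (!is.null(ts) && any(ts$frame == f)) {
        row <- ts[ts$frame == f, ][1, ]
        if (row$tilt_deg != 0) {
          az <- row$azimuth_deg * pi / 180
          R <- rodrigues(c(cos(az), sin(az), 0), row$tilt_deg * pi / 180)
          fr <- fr %*% t(R)
        }
      }
      coords[, , f] <- fr
    }
  })
  trajectory(atoms, coords, times = (seq_len(nf) - 1) * dyn$frame_interval)
}
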