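# Leaflet assignment, volumetric surface extraction, edge distances,
# regional composition, and debounced lipid flip counting.

#' Per-lipid leaflet labels
#'
#' A lipid is in the upper (lower) leaflet if its C2 reference atom lies
#' above (below) the plane z = center of mass of all lipid C2 atoms,
#' recomputed for each frame. Detergent molecules are labelled too (their
#' reference atoms participate in regional composition) but are excluded
#' from the midplane estimate.
#'
#' @param frame aligned coordinate matrix (bilayer normal = z).
#' @param atoms atom table.
#' @param sel selection configuration.
#' @return data.frame: `residue_id`, `species`, `role`, `x`, `y`, `z`,
#'   `leaflet` ("upper"/"lower"), one row per lipid/detergent molecule.
#' @export
assign_leaflets <- function(frame, atoms, sel) {
  ref_lip <- select_atoms(atoms, sel, "reference", roles = "lipid")
  if (length(ref_lip) == 0) stop("no lipid reference atoms")
  ref_all <- select_atoms(atoms, sel, "reference",
                          roles = c("lipid", "detergent"))
  zmid <- mean(frame[ref_lip, 3])
  roles <- vapply(sel$species, `[[`, "", "role")
  out <- data.frame(
    residue_id = atoms$residue_id[ref_all],
    species = atoms$residue_name[ref_all],
    role = unname(roles[atoms$residue_name[ref_all]]),
    x = frame[ref_all, 1], y = frame[ref_all, 2], z = frame[ref_all, 3],
    leaflet = ifelse(frame[ref_all, 3] > zmid, "upper", "lower"),
    stringsAsFactors = FALSE)
  attr(out, "z_mid") <- zmid
  out
}

#' Grid parameters for surface extraction and edge distances
#'
#' @param voxel_edge voxel edge length (Angstrom; the "resolution",
#'   default 6).
#' @param density_isovalue occupancy threshold (default 0.01).
#' @param slab_thickness_projection slab collapsed along z for the 2D
#'   edge map (Angstrom, default 20).
#' @param slab_thickness_edge_count slab used for the edge headgroup
#'   count (Angstrom, default 10).
#' @return list of class `dln_grid_params`.
#' @export
grid_params <- function(voxel_edge = 6, density_isovalue = 0.01,
                        slab_thickness_projection = 20,
                        slab_thickness_edge_count = 10) {
  stopifnot(voxel_edge > 0, density_isovalue > 0)
  structure(list(voxel_edge = voxel_edge, density_isovalue = density_isovalue,
                 slab_thickness_projection = slab_thickness_projection,
                 slab_thickness_edge_count = slab_thickness_edge_count),
            class = "dln_grid_params")
}

#' Volumetric occupancy mask of the lipid surface
#'
#' Gaussian-smeared atom density on a voxel grid (per-atom kernel width =
#' its van der Waals radius); a voxel is inside the molecular surface iff
#' the density at its center reaches the isovalue. The grid spans the
#' selected atoms' bounding box padded by `pad` voxels.
#'
#' @param frame aligned coordinate matrix.
#' @param atoms atom table.
#' @param idx 1-based indices of the atoms defining the surface
#'   (all lipid atoms, detergent excluded, in the standard analysis).
#' @param params a [grid_params()].
#' @param pad padding in voxels (default 2).
#' @return list: `inside` (3D logical array), `origin` (corner of voxel
#'   [1,1,1]), `edge` (voxel edge), plus axis center vectors `xc`,`yc`,`zc`.
#' @export
extract_surface_mask <- function(frame, atoms, idx, params = grid_params(),
                                 pad = 2L) {
  if (length(idx) == 0) stop("empty selection for surface extraction")
  h <- params$voxel_edge
  pos <- frame[idx, , drop = FALSE]
  rad <- atoms$vdw_radius[idx]
  lo <- apply(pos, 2, min) - pad * h
  hi <- apply(pos, 2, max) + pad * h
  nv <- pmax(1L, as.integer(ceiling((hi - lo) / h)))
  xc <- lo[1] + (seq_len(nv[1]) - 0.5) * h
  yc <- lo[2] + (seq_len(nv[2]) - 0.5) * h
  zc <- lo[3] + (seq_len(nv[3]) - 0.5) * h
  dens <- array(0, dim = nv)
  # each atom contributes exp(-d^2 / (2 sigma^2)), sigma = vdw radius,
  # truncated at the distance where the kernel falls below isovalue/10
  for (a in seq_along(idx)) {
    s <- rad[a]
    lv <- 2 * log(10 / params$density_isovalue)
    if (lv <= 0) next   # isovalue unreachably high: atom contributes nothing
    rcut <- s * sqrt(lv)
    ix <- which(abs(xc - pos[a, 1]) <= rcut)
    iy <- which(abs(yc - pos[a, 2]) <= rcut)
    iz <- which(abs(zc - pos[a, 3]) <= rcut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xc[ix] - pos[a, 1])^2
    dy2 <- (yc[iy] - pos[a, 2])^2
    dz2 <- (zc[iz] - pos[a, 3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    dens[ix, iy, iz] <- dens[ix, iy, iz, drop = FALSE] + exp(-d2 / (2 * s^2))
  }
  list(inside = dens >= params$density_isovalue, origin = lo, edge = h,
       xc = xc, yc = yc, zc = zc)
}

#' In-plane distance of each lipid from the bilayer edge
#'
#' The occupancy mask is collapsed to a 2D pixel map by averaging the
#' inside-indicator along z over the slab |z| <= projection-slab/2; a
#' pixel is outside iff its average is < 0.5. Each molecule's edge
#' distance is the in-plane distance from its C2 atom to the nearest
#' outside-pixel center (ties broken by pixel index order).
#'
#' @param mask result of [extract_surface_mask()].
#' @param leaflets result of [assign_leaflets()] (provides C2 positions).
#' @param params a [grid_params()].
#' @return `leaflets` with an `edge_distance` column added.
#' @export
edge_distance <- function(mask, leaflets, params = grid_params()) {
  half <- params$slab_thickness_projection / 2
  zsel <- which(abs(mask$zc) <= half)
  if (!length(zsel)) stop("projection slab contains no voxel layer")
  frac <- apply(mask$inside[, , zsel, drop = FALSE], c(1, 2), mean)
  out_pix <- which(frac < 0.5, arr.ind = TRUE)
  if (nrow(out_pix) == 0)
    stop("no outside pixel: grid padding too small for the patch")
  px <- mask$xc[out_pix[, 1]]
  py <- mask$yc[out_pix[, 2]]
  d <- sqrt(outer(leaflets$x, px, `-`)^2 + outer(leaflets$y, py, `-`)^2)
  leaflets$edge_distance <- apply(d, 1, min)
  leaflets
}

region_label <- function(leaflets, edge_threshold) {
  paste0(leaflets$leaflet, "-",
         ifelse(leaflets$edge_distance < edge_threshold, "edge", "interior"))
}

#' Regional composition of a species over a trajectory
#'
#' Per frame, the four regions are leaflet x {edge, interior} with
#' edge = edge_distance below the threshold. The fraction in a region is
#' (number of `species` reference atoms in the region) / (number of all
#' lipid reference atoms in the region, detergent excluded by default).
#' The system-wide fraction is also reported.
#'
#' @param traj aligned `dln_trajectory`.
#' @param species species key whose enrichment is measured (e.g. "DMTAP").
#' @param sel selection configuration.
#' @param edge_threshold edge/interior boundary (Angstrom, default 10).
#' @param params a [grid_params()].
#' @param include_detergent count detergent molecules in the denominator
#'   (default FALSE).
#' @return data.frame: `time`, `region`, `fraction`, plus the attribute
#'   `global_fraction` (per-frame mean system fraction). Empty regions
#'   yield NaN fractions for that frame.
#' @export
region_composition <- function(traj, species, sel, edge_threshold = 10,
                               params = grid_params(),
                               include_detergent = FALSE) {
  atoms <- traj$atoms
  lip_idx <- select_role_atoms(atoms, sel, "lipid")
  regions <- c("upper-edge", "upper-interior", "lower-edge", "lower-interior")
  out <- list()
  gfrac <- numeric(n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    fr <- get_frame(traj, f)
    lf <- assign_leaflets(fr, atoms, sel)
    if (!include_detergent) lf <- lf[lf$role == "lipid", ]
    mask <- extract_surface_mask(fr, atoms, lip_idx, params)
    lf <- edge_distance(mask, lf, params)
    lf$region <- region_label(lf, edge_threshold)
    gfrac[f] <- mean(lf$species == species)
    for (rg in regions) {
      inr <- lf$region == rg
      frac <- if (any(inr)) mean(lf$species[inr] == species) else NaN
      out[[length(out) + 1L]] <- data.frame(time = traj$times[f],
                                            region = rg, fraction = frac)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "global_fraction") <- mean(gfrac)
  res
}

#' Count leaflet flips with a persistence debounce
#'
#' A flip is recorded when a molecule's leaflet label changes and the new
#' label persists for at least `persistence` ns (or to the end of the
#' trajectory). Without the debounce, thermal jitter across the midplane
#' would inflate counts.
#'
#' @param traj aligned `dln_trajectory`.
#' @param sel selection configuration.
#' @param persistence debounce duration (ns, default 15).
#' @return list: `events` (data.frame residue_id, species, frame, time,
#'   direction) and `counts` (data.frame species, lower_to_upper,
#'   upper_to_lower).
#' @export
count_flips <- function(traj, sel, persistence = 15) {
  nf <- n_frames(traj)
  labs <- vapply(seq_len(nf), function(f) {
    lf <- assign_leaflets(get_frame(traj, f), traj$atoms, sel)
    lf$leaflet
  }, character(nrow(assign_leaflets(get_frame(traj, 1), traj$atoms, sel))))
  labs <- matrix(labs, ncol = nf)
  meta <- assign_leaflets(get_frame(traj, 1), traj$atoms, sel)
  events <- list()
  for (m in seq_len(nrow(labs))) {
    r <- rle(labs[m, ])
    starts <- cumsum(c(1, head(r$lengths, -1)))
    ends <- cumsum(r$lengths)
    dur <- traj$times[ends] - traj$times[starts]
    # a run is an accepted (persistent) state if it spans >= persistence
    # ns or runs to the trajectory end
    ok <- dur >= persistence | ends == nf
    av <- r$values[ok]; af <- starts[ok]
    if (length(av) < 2) next
    chg <- which(av[-1] != av[-length(av)]) + 1
    for (k in chg) {
      events[[length(events) + 1L]] <- data.frame(
        residue_id = meta$residue_id[m], species = meta$species[m],
        frame = af[k], time = traj$times[af[k]],
        direction = if (av[k] == "upper") "lower_to_upper" else "upper_to_lower",
        stringsAsFactors = FALSE)
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(residue_id = integer(), species = character(),
               frame = integer(), time = numeric(), direction = character())
  events <- events[order(events$time, events$residue_id), , drop = FALSE]
  sps <- unique(meta$species)
  counts <- data.frame(
    species = sps,
    lower_to_upper = vapply(sps, function(s) sum(events$species == s &
      events$direction == "lower_to_upper"), numeric(1)),
    upper_to_lower = vapply(sps, function(s) sum(events$species == s &
      events$direction == "upper_to_lower"), numeric(1)),
    row.names = NULL)
  list(events = events, counts = counts)
}
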