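# Leaflet labels, surface mask, edge distances, regional composition,
# and debounced flip counting.

test_that("leaflet labels partition molecules by the C2 midplane", {
  p <- build_patch(patch_spec(radius = 45, seed = 2))
  sel <- default_selection()
  lf <- assign_leaflets(p$frame, p$atoms, sel)
  expect_equal(nrow(lf), 2 * round(pi * 45^2 / 69.5))
  expect_equal(sum(lf$leaflet == "upper"), nrow(lf) / 2)
  # moving one C2 below the plane relabels exactly that lipid
  i <- which(p$atoms$atom_name == "C2" & p$atoms$residue_id == 1)
  fr2 <- p$frame
  fr2[i, 3] <- -fr2[i, 3]
  lf2 <- assign_leaflets(fr2, p$atoms, sel)
  changed <- which(lf$leaflet != lf2$leaflet)
  expect_equal(lf$residue_id[changed], 1)
})

test_that("surface mask spans the patch footprint within one voxel", {
  p <- build_patch(patch_spec(radius = 40, seed = 3))
  sel <- default_selection()
  lip <- select_role_atoms(p$atoms, sel, "lipid")
  mask <- extract_surface_mask(p$frame, p$atoms, lip, grid_params())
  ins <- which(mask$inside, arr.ind = TRUE)
  max_rho <- max(sqrt(mask$xc[ins[, 1]]^2 + mask$yc[ins[, 2]]^2))
  expect_lt(abs(max_rho - 40), 6 + 3)   # one voxel + lattice discreteness
  # isovalue -> infinity empties the mask
  m2 <- extract_surface_mask(p$frame, p$atoms, lip,
                             grid_params(density_isovalue = 1e9))
  expect_false(any(m2$inside))
  # a single atom produces a compact blob containing its own voxel
  at <- atom_table("C2", "C", "DMPC", 1)
  m3 <- extract_surface_mask(matrix(c(1, 2, 3), 1), at, 1,
                             grid_params(voxel_edge = 2))
  expect_true(any(m3$inside))
  ins3 <- which(m3$inside, arr.ind = TRUE)
  ctr <- c(m3$xc[ins3[, 1]], m3$yc[ins3[, 2]], m3$zc[ins3[, 3]])
  expect_lt(min(sqrt((m3$xc[ins3[, 1]] - 1)^2 + (m3$yc[ins3[, 2]] - 2)^2 +
                     (m3$zc[ins3[, 3]] - 3)^2)), 2)
})

test_that("edge distances reflect generator geometry and ignore padding", {
  p <- build_patch(patch_spec(radius = 40, seed = 3))
  sel <- default_selection()
  lip <- select_role_atoms(p$atoms, sel, "lipid")
  gp <- grid_params()
  mask <- extract_surface_mask(p$frame, p$atoms, lip, gp)
  lf <- edge_distance(mask, assign_leaflets(p$frame, p$atoms, sel), gp)
  ctr <- which.min(lf$x^2 + lf$y^2)
  rim <- which.max(lf$x^2 + lf$y^2)
  expect_lt(abs(lf$edge_distance[ctr] - 40), 6 + 3)
  expect_lte(lf$edge_distance[rim], 6 * sqrt(2) + 3)
  # distances are monotone-ish with radial position: interior > rim
  expect_gt(lf$edge_distance[ctr], lf$edge_distance[rim])
  # doubling the grid padding leaves distances unchanged
  mask2 <- extract_surface_mask(p$frame, p$atoms, lip, gp, pad = 4L)
  lf2 <- edge_distance(mask2, assign_leaflets(p$frame, p$atoms, sel), gp)
  expect_equal(lf2$edge_distance, lf$edge_distance, tolerance = 1e-12)
})

test_that("region fractions of a uniform patch match the global fraction", {
  p <- build_patch(patch_spec(seed = 11))   # 564 lipids, 9% DMTAP
  tr <- trajectory(p$atoms, p$frame)
  rc <- region_composition(tr, "DMTAP", default_selection())
  g <- attr(rc, "global_fraction")
  expect_equal(length(unique(rc$region)), 4)
  for (k in seq_len(nrow(rc))) {
    # binomial error with the observed per-region counts is ~0.02-0.03
    expect_lt(abs(rc$fraction[k] - g), 4 * sqrt(g * (1 - g) / 100))
  }
})

test_that("absent species give zero fractions; constructed enrichment shows up", {
  p <- build_patch(patch_spec(radius = 45,
                              species_fractions = c(DMPC = 1.0), seed = 5))
  tr <- trajectory(p$atoms, p$frame)
  rc <- region_composition(tr, "DMTAP", default_selection())
  expect_true(all(rc$fraction[is.finite(rc$fraction)] == 0))
  # relabel all lipids in the upper rim band as DMTAP
  sel <- default_selection()
  lip <- select_role_atoms(p$atoms, sel, "lipid")
  mask <- extract_surface_mask(p$frame, p$atoms, lip, grid_params())
  lf <- edge_distance(mask, assign_leaflets(p$frame, p$atoms, sel),
                      grid_params())
  rim_up <- lf$residue_id[lf$leaflet == "upper" & lf$edge_distance < 10]
  atoms2 <- p$atoms
  atoms2$residue_name[atoms2$residue_id %in% rim_up] <- "DMTAP"
  rc2 <- region_composition(trajectory(atoms2, p$frame), "DMTAP",
                            default_selection())
  up_edge <- rc2$fraction[rc2$region == "upper-edge"]
  lo <- rc2$fraction[grepl("lower", rc2$region)]
  expect_gt(up_edge, attr(rc2, "global_fraction"))
  expect_true(all(lo[is.finite(lo)] == 0))
})

test_that("scripted flips are recovered exactly; jitter is debounced", {
  p <- build_patch(patch_spec(radius = 45, seed = 2))
  sel <- default_selection()
  sched <- data.frame(residue_id = c(5, 17, 30, 30),
                      frame = c(10, 25, 15, 35))
  dyn <- dynamics_spec(c(DMPC = 0.2, DMTAP = 0.2, DMPE = 0.2),
                       frame_interval = 1, n_frames = 50,
                       flip_schedule = sched, seed = 8)
  tr <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 45)
  fl <- count_flips(tr, sel, persistence = 5)
  expect_equal(nrow(fl$events), 4)
  expect_equal(sort(fl$events$frame), sort(sched$frame))
  expect_setequal(unique(fl$events$residue_id), c(5, 17, 30))
  expect_equal(sum(fl$counts$lower_to_upper + fl$counts$upper_to_lower), 4)
  # lipid 30 flipped out and back: one event in each direction
  e30 <- fl$events[fl$events$residue_id == 30, ]
  expect_setequal(e30$direction, c("lower_to_upper", "upper_to_lower"))
})

test_that("brief midplane crossings below the persistence are not flips", {
  # hand-built label series via z coordinates of a 12-lipid toy patch
  p <- build_patch(patch_spec(radius = 18, seed = 3))
  nf <- 40
  co <- array(rep(p$frame, nf), dim = c(nrow(p$frame), 3, nf))
  i <- which(p$atoms$atom_name == "C2" & p$atoms$residue_id == 1)
  all1 <- which(p$atoms$residue_id == 1)
  # dip across the midplane for 2 frames (< persistence of 5 ns)
  co[all1, 3, 20:21] <- -co[all1, 3, 20:21]
  tr <- trajectory(p$atoms, co, times = 0:(nf - 1))
  fl <- count_flips(tr, default_selection(), persistence = 5)
  expect_equal(nrow(fl$events), 0)
  # and a persistent change is one flip, agreeing with the scan oracle
  co[all1, 3, 25:nf] <- -co[all1, 3, 25:nf]
  tr2 <- trajectory(p$atoms, co, times = 0:(nf - 1))
  fl2 <- count_flips(tr2, default_selection(), persistence = 5)
  expect_equal(nrow(fl2$events), 1)
  expect_equal(fl2$events$frame, 25)
  labs <- ifelse(co[i, 3, ] > 0, "upper", "lower")
  expect_equal(oracle_flips_one(labs, 0:(nf - 1), 5), 25)
})

test_that("flip counting equals the forward-scan oracle on noisy series", {
  p <- build_patch(patch_spec(radius = 18, seed = 3))
  nf <- 120
  n_mol <- max(molecule_index(p$atoms))
  co <- array(rep(p$frame, nf), dim = c(nrow(p$frame), 3, nf))
  set.seed(55)
  # random sign-jitter streams per lipid
  for (rid in seq_len(n_mol)) {
    rows <- which(p$atoms$residue_id == rid)
    flips <- sort(sample(5:(nf - 5), sample(0:6, 1)))
    sgn <- 1
    for (f in seq_len(nf)) {
      if (f %in% flips) sgn <- -sgn
      co[rows, 3, f] <- sgn * p$frame[rows, 3]
    }
  }
  tr <- trajectory(p$atoms, co, times = 0:(nf - 1))
  sel <- default_selection()
  for (pers in c(3, 10, 25)) {
    fl <- count_flips(tr, sel, persistence = pers)
    got <- split(fl$events$frame, fl$events$residue_id)
    ref_meta <- assign_leaflets(get_frame(tr, 1), p$atoms, sel)
    for (rid in seq_len(n_mol)) {
      i <- which(p$atoms$residue_id == rid & p$atoms$atom_name == "C2")
      labs <- ifelse(co[i, 3, ] > 0, "upper", "lower")
      want <- oracle_flips_one(labs, 0:(nf - 1), pers)
      have <- got[[as.character(rid)]]
      if (is.null(have)) have <- integer()
      expect_equal(sort(have), sort(want),
                   info = sprintf("rid=%d pers=%d", rid, pers))
    }
  }
})
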