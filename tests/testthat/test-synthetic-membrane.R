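# Generator contracts: counts, determinism, scripted events, polymers.

test_that("patch lipid count follows round(pi r^2 / APL) per leaflet", {
  p <- build_patch(patch_spec(radius = 79, area_per_lipid = 69.5, seed = 1))
  n_mol <- max(molecule_index(p$atoms))
  expect_equal(n_mol, 564)          # 2 * round(pi*79^2/69.5) = 2 * 282
  z <- p$frame[p$atoms$atom_name == "C2", 3]
  expect_equal(sum(z > 0), 282)
  expect_equal(sum(z < 0), 282)
  # all lipids inside the disc
  rho <- sqrt(p$frame[, 1]^2 + p$frame[, 2]^2)
  expect_lt(max(rho), 79 + 10)
})

test_that("tiny patches floor at one lipid per leaflet", {
  p <- build_patch(patch_spec(radius = 5, area_per_lipid = 69.5, seed = 1))
  expect_equal(max(molecule_index(p$atoms)), 2)
  expect_error(build_patch(patch_spec(radius = 3, area_per_lipid = 1e4)),
               "area_per_lipid")
})

test_that("species assignment is a seeded multinomial respecting fractions", {
  sp <- patch_spec(radius = 60, species_fractions = c(DMPC = 0.5, DMTAP = 0.5),
                   seed = 42)
  p1 <- build_patch(sp)
  p2 <- build_patch(sp)
  expect_identical(p1$atoms, p2$atoms)
  expect_identical(p1$frame, p2$frame)
  frac <- mean(p1$atoms$residue_name[p1$atoms$atom_name == "C2"] == "DMTAP")
  n <- sum(p1$atoms$atom_name == "C2")
  expect_lt(abs(frac - 0.5), 4 * sqrt(0.25 / n))
})

test_that("zero-diffusion, event-free dynamics are static", {
  p <- build_patch(patch_spec(radius = 20, seed = 2))
  dyn <- dynamics_spec(c(DMPC = 0, DMTAP = 0, DMPE = 0), frame_interval = 1,
                       n_frames = 5, seed = 3)
  tr <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 20)
  for (f in 2:5)
    expect_identical(get_frame(tr, f), get_frame(tr, 1))
})

test_that("a scripted flip changes the lipid's C2 z sign exactly once", {
  p <- build_patch(patch_spec(radius = 20, seed = 2))
  dyn <- dynamics_spec(c(DMPC = 0), frame_interval = 1, n_frames = 8,
                       flip_schedule = data.frame(residue_id = 2, frame = 5),
                       seed = 3)
  tr <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 20)
  i <- which(tr$atoms$residue_id == 2 & tr$atoms$atom_name == "C2")
  z <- tr$coords[i, 3, ]
  sign_changes <- which(diff(sign(z)) != 0)
  expect_equal(sign_changes, 4L)   # between frames 4 and 5
  # species composition is conserved through the flip
  expect_identical(tr$atoms$residue_name,
                   p$atoms$residue_name)
})

test_that("trajectories are bit-identical under identical seeds", {
  p <- build_patch(patch_spec(radius = 25, seed = 7))
  dyn <- dynamics_spec(c(DMPC = 0.8, DMTAP = 0.8, DMPE = 0.8),
                       frame_interval = 0.5, n_frames = 20, seed = 9)
  t1 <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 25)
  t2 <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 25)
  expect_identical(t1$coords, t2$coords)
  dyn2 <- dynamics_spec(c(DMPC = 0.8, DMTAP = 0.8, DMPE = 0.8),
                        frame_interval = 0.5, n_frames = 20, seed = 10)
  t3 <- simulate_dynamics(p$atoms, p$frame, dyn2, radius = 25)
  expect_false(identical(t1$coords, t3$coords))
})

test_that("Brownian steps stay inside the reflecting rim", {
  p <- build_patch(patch_spec(radius = 15, seed = 2))
  dyn <- dynamics_spec(c(DMPC = 5, DMTAP = 5, DMPE = 5), frame_interval = 1,
                       n_frames = 100, seed = 4)
  tr <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 15)
  ref <- which(tr$atoms$atom_name == "C2")
  rho <- sqrt(tr$coords[ref, 1, ]^2 + tr$coords[ref, 2, ]^2)
  expect_lt(max(rho), 15 + 1e-9)
})

test_that("edge polymers hug the rim cylinder and extend the atom table", {
  p <- build_patch(patch_spec(radius = 30, seed = 2))
  n0 <- nrow(p$atoms)
  same <- add_edge_polymers(p$atoms, p$frame, n_chains = 0, n_monomers = 10,
                            radius = 30)
  expect_identical(same$frame, p$frame)
  pp <- add_edge_polymers(p$atoms, p$frame, n_chains = 1, n_monomers = 10,
                          radius = 30, seed = 5)
  expect_equal(nrow(pp$atoms) - n0, 10)
  peg <- pp$atoms$residue_name == "PEG"
  expect_equal(sum(peg), 10)
  rho <- sqrt(pp$frame[peg, 1]^2 + pp$frame[peg, 2]^2)
  expect_true(all(abs(rho - 30) <= 6))
  expect_equal(pp$atoms$atom_id, seq_len(nrow(pp$atoms)) - 1L)
})

test_that("curvature displacement follows the spherical-cap sag", {
  p <- build_patch(patch_spec(radius = 40, seed = 2))
  c0 <- 0.004
  dyn <- dynamics_spec(c(DMPC = 0), frame_interval = 1, n_frames = 1,
                       curvature = c0, seed = 3)
  tr <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 40)
  rho2 <- p$frame[, 1]^2 + p$frame[, 2]^2
  expected <- p$frame[, 3] + c0 * rho2 / (1 + sqrt(1 - c0^2 * rho2))
  expect_equal(tr$coords[, 3, 1], expected, tolerance = 1e-12)
})
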