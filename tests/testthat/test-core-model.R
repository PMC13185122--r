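# Topology/trajectory I/O, alignment, and time-series utilities.

test_that("atom tables assign radii from the element table and validate", {
  at <- atom_table(c("C2", "O21"), c("C", "O"), c("DMPC", "DMPC"), c(1, 1))
  expect_equal(nrow(at), 2)
  expect_equal(at$atom_id, 0:1)
  expect_equal(at$vdw_radius, c(1.70, 1.52))
  expect_error(atom_table("XX", "XX", "DMPC", 1), "radius")
  at2 <- atom_table("C2", "C", "DMPC", 1, radii = c(C = 2.0))
  expect_equal(at2$vdw_radius, 2.0)
})

test_that("PDB topology and multi-model trajectory round-trip", {
  p <- build_patch(patch_spec(radius = 15, seed = 3))
  dyn <- dynamics_spec(c(DMPC = 0.3, DMTAP = 0.3, DMPE = 0.3),
                       frame_interval = 0.5, n_frames = 3, seed = 4)
  tr <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 15)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tr, tf)
  at2 <- read_topology(tf)
  expect_equal(at2$atom_name, p$atoms$atom_name)
  expect_equal(at2$residue_name, p$atoms$residue_name)
  expect_equal(at2$residue_id, p$atoms$residue_id)
  expect_equal(at2$vdw_radius, p$atoms$vdw_radius)
  tr2 <- read_trajectory(tf, at2, frame_interval = 0.5, check_bonds = FALSE)
  expect_equal(n_frames(tr2), 3)
  expect_equal(tr2$times, tr$times)
  # PDB stores 3 decimals
  expect_lt(max(abs(tr2$coords - tr$coords)), 1e-3)
})

test_that("DCD write/read round-trips coordinates at single precision", {
  p <- build_patch(patch_spec(radius = 12, seed = 5))
  dyn <- dynamics_spec(c(DMPC = 0.5), frame_interval = 0.01,
                       n_frames = 10, seed = 6)
  tr <- simulate_dynamics(p$atoms, p$frame, dyn, radius = 12)
  tf <- withr::local_tempfile(fileext = ".dcd")
  write_dcd(tr, tf)
  expect_error(read_trajectory(tf, p$atoms), "frame_interval")
  tr2 <- read_trajectory(tf, p$atoms, frame_interval = 0.01,
                         check_bonds = FALSE)
  expect_equal(n_frames(tr2), 10)
  expect_equal(tr2$times, seq(0, 0.09, by = 0.01))
  expect_lt(max(abs(tr2$coords - tr$coords)), 1e-4)
})

test_that("trajectory constructor enforces its invariants", {
  at <- atom_table(c("C2", "C2", "C2"), "C", rep("DMPC", 3), 1:3)
  co <- array(rnorm(18), dim = c(3, 3, 2))
  expect_error(trajectory(at, co, times = c(1, 1)), "increasing")
  expect_error(trajectory(at, co[1:2, , ]), "atom count")
  co[1, 1, 1] <- NA
  expect_error(trajectory(at, co), "finite")
})

test_that("alignment removes rigid-body motion and is idempotent", {
  sel <- default_selection()
  p <- test_patch()
  tr <- trajectory(p$atoms, p$frame)
  a1 <- preprocess_align(tr, sel)
  # translation invariance
  sh <- sweep(p$frame, 2, c(5, 5, 5), `+`)
  a_sh <- preprocess_align(trajectory(p$atoms, sh), sel)
  expect_lt(max(abs(a1$coords - a_sh$coords)), 1e-9)
  # seeded random rotation + translation is fully removed
  set.seed(13)
  R <- rot_about(rnorm(3), runif(1, 10, 170))
  moved <- sweep(p$frame %*% t(R), 2, c(-8, 3, 12), `+`)
  a_rot <- preprocess_align(trajectory(p$atoms, moved), sel)
  expect_lt(max(abs(a1$coords - a_rot$coords)), 1e-6)
  # idempotence
  a2 <- preprocess_align(a1, sel)
  expect_lt(max(abs(a1$coords - a2$coords)), 1e-6)
  # reference-atom COM at origin, normal along z (smallest extent)
  ref <- select_atoms(p$atoms, sel, "reference")
  fr <- get_frame(a1, 1)
  expect_lt(max(abs(colMeans(fr[ref, ]))), 1e-9)
  v <- apply(fr[ref, ], 2, var)
  expect_true(v[3] < v[1] && v[3] < v[2])
})

test_that("alignment rejects collinear reference configurations", {
  at <- atom_table(rep("C2", 5), "C", rep("DMPC", 5), 1:5)
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(preprocess_align(trajectory(at, line), default_selection()),
               "collinear")
})

test_that("block averaging matches per-block brute force", {
  expect_equal(block_average(c(0, 10), c(3, 3), 15)$value, 3)
  b <- block_average(c(0, 10), c(0, 2), 15)
  expect_equal(b$value, 1)
  set.seed(21)
  t <- seq(0, 99, by = 0.5)
  v <- rnorm(length(t))
  got <- block_average(t, v, 15)
  blk <- floor(t / 15)
  expect_equal(got$value, as.numeric(tapply(v, blk, mean)))
  # full blocks are reported at their centers
  expect_equal(got$time[1:6], 15 * (0:5) + 7.5)
  expect_error(block_average(numeric(), numeric()), "empty")
})

test_that("interval means default to skipping the first quarter", {
  t <- 0:99
  v <- c(rep(100, 25), rep(2, 75))
  expect_equal(interval_mean(t, v), mean(v[t >= 24.75]))
  expect_equal(interval_mean(t, v, start = 50), 2)
})
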