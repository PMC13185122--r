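# Density profile, thickness, area per lipid, curvature, edge count.

make_c2_atoms <- function(n) atom_table(rep("C2", n), "C", rep("DMPC", n),
                                        seq_len(n))

test_that("density profile histograms selected atoms in the core cylinder", {
  at <- make_c2_atoms(10)
  fr <- cbind(0, 0, rep(1.2, 10))
  pr <- density_profile(fr, 1:10)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$density, 10 / 0.5)
  expect_equal(pr$z, 1.25)
  # two symmetric planes give two symmetric peaks
  fr2 <- cbind(0, 0, rep(c(17.4, -17.6), 20))
  pr2 <- density_profile(fr2, 1:40)
  occ <- pr2[pr2$density > 0, ]
  expect_equal(nrow(occ), 2)
  expect_equal(occ$density[1], occ$density[2])
  # atoms outside the core cylinder are excluded
  fr3 <- rbind(cbind(0, 0, 1.2), cbind(100, 0, 1.2))
  pr3 <- density_profile(fr3, 1:2, geometry_params(core_radius = 40))
  expect_equal(sum(pr3$density) * 0.5, 1)
})

test_that("Gaussian-sampled leaflets recover their histogram density", {
  set.seed(61)
  z <- rnorm(2000, 17, 2)
  fr <- cbind(0, 0, z)
  pr <- density_profile(fr, 1:2000)
  # compare occupied-bin heights to the sampling density within Poisson error
  expect_true(all(abs(pr$density - 2000 * dnorm(pr$z, 17, 2)) <
                  5 * sqrt(pmax(pr$density / 0.5, 1)) / 0.5 + 5))
})

test_that("thickness is exact for delta planes and recovers Gaussian means", {
  fr <- cbind(runif(200, -5, 5), runif(200, -5, 5), rep(c(17.5, -17.5), 100))
  pr <- density_profile(fr, 1:200)
  expect_equal(as.numeric(thickness(pr)), 35.0)
  set.seed(62)
  z <- c(rnorm(500, 17, 2), rnorm(500, -17, 2))
  fr2 <- cbind(runif(1000, -10, 10), runif(1000, -10, 10), z)
  th <- as.numeric(thickness(density_profile(fr2, 1:1000)))
  expect_lt(abs(th - 34.0), 0.4)
  # one-sided profiles are rejected
  expect_error(thickness(density_profile(cbind(0, 0, rep(5, 10)), 1:10)),
               "one-sided")
})

test_that("area per lipid recovers the generator density and scales inversely", {
  sel <- default_selection()
  # measured over the whole patch, recovery is exact up to the one-lipid
  # rounding in the construction, across APL 50-80
  for (apl in c(50, 69.5, 80)) {
    p <- build_patch(patch_spec(radius = 79, area_per_lipid = apl, seed = 13))
    n_leaf <- round(pi * 79^2 / apl)
    got <- suppressWarnings(
      area_per_lipid(p$frame, p$atoms, sel, geometry_params(core_radius = 79)))
    expect_lt(abs(got - apl), apl / n_leaf + 1e-9)   # one lipid-equivalent
    # inside the standard 4 nm core the count is a statistical sample:
    # recovery within 3 standard deviations of the occupancy fluctuation
    got40 <- suppressWarnings(
      area_per_lipid(p$frame, p$atoms, sel, geometry_params(core_radius = 40)))
    n40 <- pi * 40^2 / apl
    sd40 <- sqrt(n40 * (1 - (40 / 79)^2))
    expect_lt(abs(pi * 40^2 / got40 - n40), 3 * sd40 / sqrt(2))
  }
  # halving the count doubles the APL (pure arithmetic contract)
  gp <- geometry_params(core_radius = 40)
  p <- build_patch(patch_spec(radius = 79, seed = 13))
  lf <- assign_leaflets(p$frame, p$atoms, sel)
  full <- area_per_lipid(p$frame, p$atoms, sel, gp)
  keep <- lf$residue_id[seq(1, nrow(lf), by = 2)]
  sub <- p$atoms$residue_id %in% keep
  atoms2 <- p$atoms[sub, ]
  atoms2$atom_id <- seq_len(nrow(atoms2)) - 1L
  half <- area_per_lipid(p$frame[sub, ], atoms2, sel, gp)
  expect_equal(half / full, 2, tolerance = 0.15)
  # core larger than the patch is flagged
  small <- build_patch(patch_spec(radius = 20, seed = 3))
  expect_warning(area_per_lipid(small$frame, small$atoms, sel,
                                geometry_params(core_radius = 40)),
                 "beyond the patch")
})

test_that("curvature fit is exact on a sphere cap and zero on flat leaflets", {
  set.seed(63)
  n <- 200
  rho <- sqrt(runif(n)) * 40
  phi <- runif(n, 0, 2 * pi)
  R <- 100
  sag <- rho^2 / (R + sqrt(R^2 - rho^2))
  at <- make_c2_atoms(2 * n)
  fr <- rbind(cbind(rho * cos(phi), rho * sin(phi), 17.5 + sag),
              cbind(rho * cos(phi), rho * sin(phi), -17.5 + sag))
  cv <- fit_curvature(fr, at, default_selection(),
                      geometry_params(core_radius = 45))
  expect_lt(abs(as.numeric(cv) - 0.01), 1e-4)
  # mirror image flips the sign
  fr2 <- fr; fr2[, 3] <- -fr2[, 3]
  cv2 <- fit_curvature(fr2, at, default_selection(),
                       geometry_params(core_radius = 45))
  expect_lt(abs(as.numeric(cv2) + 0.01), 1e-4)
  # exactly flat leaflets give |c| < 1e-5
  p <- build_patch(patch_spec(radius = 45, seed = 3))
  c0 <- fit_curvature(p$frame, p$atoms, default_selection(),
                      geometry_params(core_radius = 45))
  expect_lt(abs(as.numeric(c0)), 1e-5)
})

test_that("thickness and curvature are invariant under in-plane rotation", {
  p <- test_patch(radius = 45, seed = 4)
  sel <- default_selection()
  gp <- geometry_params(core_radius = 40)
  ref <- select_atoms(p$atoms, sel, "reference")
  th1 <- as.numeric(thickness(density_profile(p$frame, ref, gp)))
  cv1 <- as.numeric(fit_curvature(p$frame, p$atoms, sel, gp))
  Rz <- rot_about(c(0, 0, 1), 73)
  fr2 <- p$frame %*% t(Rz)
  th2 <- as.numeric(thickness(density_profile(fr2, ref, gp)))
  cv2 <- as.numeric(fit_curvature(fr2, p$atoms, sel, gp))
  expect_equal(th2, th1, tolerance = 1e-6)
  expect_equal(cv2, cv1, tolerance = 1e-6)
})

test_that("edge headgroup count sees only midplane-slab C2 atoms", {
  p <- build_patch(patch_spec(radius = 40, seed = 3))
  sel <- default_selection()
  expect_equal(edge_headgroup_count(p$frame, p$atoms, sel), 0)
  fr2 <- p$frame
  i <- which(p$atoms$atom_name == "C2" & p$atoms$residue_id == 7)
  fr2[i, 3] <- 0
  expect_equal(edge_headgroup_count(fr2, p$atoms, sel), 1)
  # scripted: move k rim lipids' C2 into the slab
  k <- 5
  rids <- order(-(p$frame[p$atoms$atom_name == "C2", 1]^2 +
                  p$frame[p$atoms$atom_name == "C2", 2]^2))[1:k]
  rid_ids <- p$atoms$residue_id[p$atoms$atom_name == "C2"][rids]
  fr3 <- p$frame
  for (r in rid_ids)
    fr3[p$atoms$atom_name == "C2" & p$atoms$residue_id == r, 3] <- 2
  expect_equal(edge_headgroup_count(fr3, p$atoms, sel), k)
})
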