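test_that("radial density integrates back to the selected bead count", {
  st <- build_bulk(0.025, box = 10, seed = 1)
  ctr <- st$box / 2
  prof <- radial_density(st, types = "W", bin_width = 0.25, center = ctr)
  # count of W beads within the profiled sphere
  r <- sqrt(rowSums(sweep(st$pos, 2, ctr)^2))
  n_in <- sum(st$type == 3L & r < max(prof$r) + prof$bin_width / 2)
  integral <- sum(prof$value * 4 * pi * prof$r^2 * prof$bin_width)
  expect_equal(integral, n_in, tolerance = 0.02)
  # far-field density of a uniform solution is rho * (1 - Phi_S)
  mid <- prof$r > 2 & prof$r < 4.5
  expect_equal(mean(prof$value[mid]), 3 * 0.975, tolerance = 0.05)
})

test_that("solute density of a uniform bulk is 3 Phi_S per d^3", {
  st <- build_bulk(0.016, box = 12, seed = 2)
  prof <- radial_density(st, types = "S", bin_width = 0.5,
                         center = st$box / 2)
  plateau <- bulk_plateau(prof, r_min = 2)
  expect_equal(plateau, 3 * 0.016, tolerance = 0.05)
})

test_that("empty selections yield a zero profile with a warning", {
  st <- build_bulk(0, box = 6, seed = 3)
  expect_warning(prof <- radial_density(st, types = "S"), "no beads")
  expect_true(all(prof$value == 0))
})

test_that("plateau, excess and coverage behave on synthetic profiles", {
  bw <- 0.25
  r <- seq(bw / 2, 20, by = bw)
  flat <- radial_profile(r, rep(0.075, length(r)), bw)
  expect_equal(bulk_plateau(flat), 0.075)
  expect_error(bulk_plateau(radial_profile(r[1:3], rep(1, 3), bw),
                            r_min = 0.7), "fewer than 3")

  # adsorption peak then plateau
  peaked <- radial_profile(r, 0.075 + 2 * exp(-(r - 10)^2 / 0.5), bw)
  expect_equal(bulk_plateau(peaked, r_min = 16), 0.075, tolerance = 1e-6)
  exc <- excess_profile(peaked, 0.075)
  expect_equal(exc$value, 2 * exp(-(r - 10)^2 / 0.5), tolerance = 1e-12)
  # uniform profile has identically zero excess
  expect_true(all(abs(excess_profile(flat)$value) < 1e-12))
})

test_that("coverage equals shell count over midsurface area", {
  # K excess beads smeared on a thin shell at radius R_s > R_mid
  bw <- 0.1
  r <- seq(bw / 2, 15, by = bw)
  K <- 500
  R_s <- 10
  val <- numeric(length(r))
  k <- which.min(abs(r - R_s))
  val[k] <- K / (4 * pi * r[k]^2 * bw)
  exc <- radial_profile(r, val, bw)
  R_mid <- 8
  cov <- coverage(exc, R_mid)
  expect_equal(cov$Gamma, K / (4 * pi * R_mid^2), tolerance = 1e-10)
  expect_equal(cov$A_0, 4 * pi * 64)
  # zero excess -> zero coverage
  expect_equal(coverage(radial_profile(r, 0 * r, bw), R_mid)$Gamma, 0)
  expect_error(coverage(exc, -1), "> 0")
})

test_that("coverage from bead shells matches the closed form", {
  # beads placed directly on a geometric shell; profile route must
  # recover K/(4 pi R_mid^2) independent of binning
  box <- 30
  K <- 400
  st <- shell_state(K, R = 10, box = box, seed = 4)
  for (bw in c(0.25, 0.125)) {
    prof <- radial_density(st, types = "S", bin_width = bw,
                           center = rep(box / 2, 3))
    exc <- excess_profile(prof, 0)
    gam <- coverage(exc, R_mid = 8)$Gamma
    expect_equal(gam, K / (4 * pi * 64), tolerance = 0.02)
  }
})

test_that("midsurface radius is the refined chain-density peak", {
  bw <- 0.25
  r <- seq(bw / 2, 30, by = bw)
  gauss <- radial_profile(r, exp(-(r - 22.5)^2 / 2), bw)
  expect_equal(midsurface_radius(gauss), 22.5, tolerance = 0.01)
  expect_error(midsurface_radius(radial_profile(r, rep(1, length(r)), bw)),
               "flat|multimodal")
  bimodal <- radial_profile(r, exp(-(r - 8)^2) + 0.95 * exp(-(r - 20)^2), bw)
  expect_error(midsurface_radius(bimodal), "multimodal")
})

test_that("membrane thickness is the full width at half maximum", {
  bw <- 0.1
  r <- seq(bw / 2, 40, by = bw)
  tophat <- radial_profile(r, as.numeric(r >= 20 & r <= 25), bw)
  expect_equal(membrane_thickness(tophat), 5, tolerance = 0.11)
  expect_error(membrane_thickness(radial_profile(r, 0 * r, bw)),
               "no bilayer")
})

test_that("a relaxed planar bilayer is about five bead diameters thick", {
  st <- build_planar_bilayer(64, box = c(8.95, 8.95, 20), seed = 5)
  rel <- relax_state(st, good_ff(), n_steps = 400, seed = 6)
  run <- dpd_run(rel, good_ff(), dpd_config(seed = 7), n_steps = 800,
                 frame_stride = 200, obs_stride = 0)
  # z histogram of membrane beads as a pseudo radial profile
  bw <- 0.25
  edges <- seq(0, st$box[3], by = bw)
  counts <- numeric(length(edges) - 1)
  for (fr in as_frames(run$traj)) {
    zm <- fr$pos[fr$mol > 0L, 3]
    counts <- counts + tabulate(findInterval(zm, edges), length(edges) - 1)
  }
  prof <- radial_profile(edges[-1] - bw / 2, counts, bw)
  expect_equal(membrane_thickness(prof), 5, tolerance = 0.1)
})
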