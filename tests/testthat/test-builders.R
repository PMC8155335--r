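test_that("bulk builder places the right bead budget", {
  st <- build_bulk(0, box = 10, seed = 1)
  expect_equal(nrow(st$pos), 3000)
  expect_equal(sum(st$type == 4L), 0)

  st2 <- build_bulk(0.025, box = 10, seed = 2)
  expect_equal(nrow(st2$pos), 3000)
  expect_equal(sum(st2$type == 4L), 75)
  expect_true(all(st2$pos >= 0 & st2$pos < 10))
  expect_error(build_bulk(1.2, box = 10), "0, 1")
})

test_that("vesicle bookkeeping is exact and the interior is solute-free", {
  spec <- vesicle_spec(N_il = 180, N_ol = 810, Phi_S = 0.05)
  st <- build_vesicle(spec, seed = 3)
  m <- st$meta
  expect_equal(m$membrane_beads, 15 * (180 + 810))
  expect_equal(sum(st$type <= 2L), m$membrane_beads)
  # partitions tile the system
  expect_equal(m$membrane_beads + length(m$idx_interior) +
                 length(m$idx_exterior), nrow(st$pos))
  expect_equal(length(m$idx_interior), spec$N_W_in)
  # interior all water, exterior at the requested mole fraction
  expect_true(all(st$type[m$idx_interior] == 3L))
  expect_equal(sum(st$type[m$idx_exterior] == 4L),
               round(0.05 * length(m$idx_exterior)))
  # heads inward/outward: outer-leaflet heads sit beyond the chains
  expect_equal(nrow(st$bonds), 14 * 990)
  expect_equal(nrow(st$angles), 10 * 990)
})

test_that("the full-scale reference spec reproduces the published counts", {
  spec <- reference_vesicle_spec()
  expect_equal(spec$membrane_beads, 151500L)
  expect_equal(spec$total_solvent_beads, 1440400L)
  expect_equal(spec$membrane_beads + spec$total_solvent_beads, 1591900L)
  expect_equal(spec$N_W_isp, 90400L)
  expect_equal(spec$asymmetry, 6100 / 4000)
})

test_that("deflation relocates interior waters and conserves the total", {
  spec <- vesicle_spec(N_il = 180, N_ol = 810)
  st <- build_vesicle(spec, seed = 4)
  n0 <- nrow(st$pos)
  n_isp <- st$meta$N_W_isp
  st75 <- set_volume(st, 0.75, seed = 5)
  expect_equal(length(st75$meta$idx_interior), round(0.75 * n_isp))
  expect_equal(nrow(st75$pos), n0)
  expect_true(all(st75$type[st75$meta$idx_interior] == 3L))
  # deflation arithmetic at the published reference numbers
  expect_equal(round(0.75 * 90400), 67800)
  # identity protocol
  st1 <- set_volume(st, 1)
  expect_identical(st1$pos, st$pos)
  # reinflation restores the count
  st_back <- set_volume(st75, 1, seed = 6)
  expect_equal(length(st_back$meta$idx_interior), n_isp)
  expect_error(set_volume(st, -0.1), "> 0")
})

test_that("solute titration converts identities without moving beads", {
  spec <- vesicle_spec(N_il = 180, N_ol = 810, Phi_S = 0.025)
  st <- build_vesicle(spec, seed = 7)
  n_ext <- length(st$meta$idx_exterior)
  expect_equal(solute_fraction(st), round(0.025 * n_ext) / n_ext)
  st2 <- set_solute_fraction(st, 0.1, seed = 8)
  expect_identical(st2$pos, st$pos)
  expect_equal(sum(st2$type == 4L), round(0.1 * n_ext))
  st0 <- set_solute_fraction(st2, 0, seed = 9)
  expect_equal(sum(st0$type == 4L), 0)
  expect_true(all(st0$type[st0$meta$idx_interior] == 3L))
  expect_error(set_solute_fraction(st, 2), "0, 1")
})

test_that("slab builder seeds all solute in the central third", {
  st <- build_slab(0.5, box = c(10, 10, 30), seed = 10)
  expect_equal(nrow(st$pos), 9000)
  expect_equal(sum(st$type == 4L), 4500)
  z_s <- st$pos[st$type == 4L, 3]
  expect_true(all(z_s >= 10 & z_s <= 20))
  pure <- build_slab(0, box = c(8, 8, 16), seed = 11)
  expect_equal(sum(pure$type == 4L), 0)
  expect_error(build_slab(0.5, box = c(10, 10, 15)), "elongated")
})

test_that("planar bilayer is symmetric and solvated at bulk density", {
  st <- build_planar_bilayer(128, box = c(12.65, 12.65, 22), seed = 12)
  expect_equal(sum(st$mol > 0), 128 * 2 * 15)
  # symmetric leaflets: mean head-bead z offset about the midplane ~ 0
  zh <- st$pos[st$type == 1L, 3] - st$meta$z_mid
  expect_lt(abs(mean(zh)), 0.05)
  # after a short relaxation the far-field solvent density is ~ 3/d^3
  rel <- relax_state(st, good_ff(), n_steps = 400, seed = 13)
  run <- dpd_run(rel, good_ff(), dpd_config(seed = 14), n_steps = 600,
                 frame_stride = 600, obs_stride = 0)
  fin <- run$state
  far <- abs(fin$pos[, 3] - fin$meta$z_mid) > 6.5
  vol_far <- prod(fin$box[1:2]) * (fin$box[3] - 13)
  rho_far <- sum(far & fin$mol == 0L) / vol_far
  expect_equal(rho_far, 3.0, tolerance = 0.02)
})
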