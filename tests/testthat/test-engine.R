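test_that("two-bead conservative force matches the pair law", {
  box <- c(6, 6, 6)
  st <- dpd_state(box, rbind(c(2, 3, 3), c(2.5, 3, 3)),
                  vel = matrix(0, 2, 3), type = c("W", "W"))
  f <- compute_forces(st, good_ff())
  expect_equal(f[1, ], c(-12.5, 0, 0), tolerance = 1e-12)
  expect_equal(f[2, ], c(12.5, 0, 0), tolerance = 1e-12)
  # virial of the pair: F . r = 12.5 * 0.5
  expect_equal(attr(f, "virial"), 6.25, tolerance = 1e-12)
})

test_that("pair forces obey Newton's third law in aggregate", {
  st <- build_bulk(0.2, box = 5, seed = 42)
  f <- compute_forces(st, good_ff())
  expect_lt(max(abs(colSums(f))), 1e-9)
  f2 <- compute_forces(st, good_ff(), thermo = TRUE, seed = 3)
  expect_lt(max(abs(colSums(f2))), 1e-9)
})

test_that("cell-list forces equal the all-pairs brute-force oracle", {
  set.seed(7)
  # solvated mini bilayer patch exercises bonds as well
  st <- build_planar_bilayer(8, box = c(3.2, 3.2, 13), seed = 8)
  expect_lt(nrow(st$pos), 500)
  f_cells <- compute_forces(st, good_ff(), neighbours = "cells")
  f_oracle <- oracle_forces(st, good_ff())
  scale <- max(abs(f_oracle))
  expect_lt(max(abs(f_cells - f_oracle)) / scale, 1e-10)
  expect_equal(attr(f_cells, "virial"), attr(f_oracle, "virial"),
               tolerance = 1e-10)
  # and the internal all-pairs path agrees too
  f_ap <- compute_forces(st, good_ff(), neighbours = "all-pairs")
  expect_lt(max(abs(f_cells - f_ap)) / scale, 1e-12)
})

test_that("a free bead moves ballistically", {
  st <- dpd_state(c(6, 6, 6), matrix(c(1, 1, 1), 1), vel = rbind(c(1, 0, 0)),
                  type = "W")
  out <- dpd_step(st, good_ff(), dpd_config(dt = 0.01, seed = 1))
  expect_equal(out$pos[1, ], c(1.01, 1, 1), tolerance = 1e-12)
  expect_equal(out$vel[1, ], c(1, 0, 0), tolerance = 1e-12)
})

test_that("ideal-gas thermostat conserves momentum exactly and P_total = rho kBT", {
  ff0 <- dpd_forcefield(matrix(0, 4, 4,
    dimnames = list(bead_types(), bead_types())))
  st <- build_bulk(0, box = 5, seed = 5)
  run <- dpd_run(st, ff0, dpd_config(seed = 6), n_steps = 1000,
                 obs_stride = 100)
  expect_lt(max(run$obs$momentum), 1e-9)
  p <- virial_pressure(run$state, ff0)
  expect_equal(unname(p["P_excess"]), 0)
  # without interactions the pressure is purely kinetic
  expect_equal(unname(p["P_total"]),
               sum(run$state$vel^2) / (3 * prod(st$box)),
               tolerance = 1e-12)
  rho <- nrow(st$pos) / prod(st$box)
  expect_equal(mean(run$obs$P_total), rho, tolerance = 0.05)
})

test_that("thermostat holds the fluid at unit temperature", {
  st <- build_bulk(0, box = 7, seed = 10)
  run <- dpd_run(st, good_ff(), dpd_config(seed = 11), n_steps = 2500,
                 obs_stride = 50)
  o <- run$obs[run$obs$step > 500, ]
  expect_equal(mean(o$T), 1.0, tolerance = 0.02)
  expect_lt(max(run$obs$momentum), 1e-9)
})

test_that("runs are deterministic for a fixed seed", {
  st <- build_bulk(0.1, box = 5, seed = 20)
  r1 <- dpd_run(st, good_ff(), dpd_config(seed = 21), n_steps = 100,
                frame_stride = 100, obs_stride = 0)
  r2 <- dpd_run(st, good_ff(), dpd_config(seed = 21), n_steps = 100,
                frame_stride = 100, obs_stride = 0)
  expect_identical(r1$traj$frames[[1]], r2$traj$frames[[1]])
  expect_identical(r1$state$vel, r2$state$vel)
  r3 <- dpd_run(st, good_ff(), dpd_config(seed = 22), n_steps = 100,
                frame_stride = 100, obs_stride = 0)
  expect_false(identical(r1$traj$frames[[1]], r3$traj$frames[[1]]))
})

test_that("NVT preserves the box; NPT drives pure water to density 3", {
  st <- build_bulk(0, box = 6, seed = 30)
  r_nvt <- dpd_run(st, good_ff(), dpd_config("NVT", seed = 31),
                   n_steps = 200, obs_stride = 100)
  expect_identical(r_nvt$state$box, st$box)

  # start 7% below the target density; the barostat must compress the
  # box toward the density where P_total = 23.7
  sparse <- build_bulk(0, box = 6, rho = 2.8, seed = 32)
  r_npt <- dpd_run(sparse, good_ff(),
                   dpd_config("NPT", p_target = 23.7, seed = 33),
                   n_steps = 4000, obs_stride = 100)
  o <- r_npt$obs[r_npt$obs$step > 2000, ]
  rho_end <- nrow(sparse$pos) / mean(o$L)^3
  expect_equal(rho_end, 3.0, tolerance = 0.02)
})

test_that("non-finite coordinates abort the run naming the step", {
  st <- build_bulk(0, box = 5, seed = 40)
  st$vel[1, 1] <- Inf
  expect_error(
    dpd_run(st, good_ff(), dpd_config(seed = 41),
            n_steps = 100, obs_stride = 10),
    "diverged.*step")
})

test_that("virial pressure requires beads", {
  st <- dpd_state(c(5, 5, 5), matrix(numeric(), 0, 3), type = integer())
  expect_error(virial_pressure(st, good_ff()), "empty")
})
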