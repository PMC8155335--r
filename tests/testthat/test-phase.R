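test_that("a symmetric mixture stays uniform in a slab run", {
  # f_WS = f_WW = f_SS = 25: an ideal mixture cannot demix
  f <- default_force_table("good")$f
  f["W", "S"] <- f["S", "W"] <- 25
  ff <- dpd_forcefield(f)
  st <- build_slab(0.5, box = c(6, 6, 14), seed = 1)
  run <- dpd_run(st, ff, dpd_config(seed = 2), n_steps = 8000,
                 frame_stride = 1000, obs_stride = 0)
  res <- coexistence_from_slab(as_frames(run$traj)[5:8],
                               zeta = solubility(25, 25, 25))
  expect_false(res$phase_separated)
  expect_true(is.na(res$Phi_dilute))
  # the initially seeded central slab has fully mixed away
  rng <- range(res$profile$Phi_S)
  expect_lt(diff(rng), 0.25)
})

test_that("slab analysis recovers the branches of a synthetic profile", {
  # hand-built two-phase trajectory: dense slab in the centre
  box <- c(8, 8, 24)
  set.seed(3)
  n <- 4000
  z <- runif(n, 0, 24)
  dense <- z > 8 & z < 16
  type <- ifelse(dense & runif(n) < 0.8, "S",
                 ifelse(!dense & runif(n) < 0.05, "S", "W"))
  st <- dpd_state(box, cbind(runif(n, 0, 8), runif(n, 0, 8), z),
                  vel = matrix(0, n, 3), type = type)
  res <- coexistence_from_slab(st, zeta = 0.625)
  expect_true(res$phase_separated)
  expect_equal(res$Phi_dilute, 0.05, tolerance = 0.35)
  expect_equal(res$Phi_dense, 0.8, tolerance = 0.1)
  expect_lt(res$Phi_dilute, res$Phi_dense)
  # lever rule: the overall fraction lies between the branches
  overall <- mean(st$type == 4L)
  expect_gt(overall, res$Phi_dilute)
  expect_lt(overall, res$Phi_dense)
})

test_that("solvent classification follows the scan separation flags", {
  mk <- function(sep, dil = NA, den = NA)
    structure(list(zeta = 0.625, Phi_dilute = dil, Phi_dense = den,
                   phase_separated = sep, profile = NULL),
              class = "coexistence_result")
  uniform <- list(mk(FALSE), mk(FALSE), mk(FALSE))
  out <- classify_solvent(uniform, c(0.1, 0.3, 0.5))
  expect_identical(out$condition, "good")
  expect_true(is.na(out$binodal))

  mixed <- list(mk(FALSE), mk(TRUE, 0.028, 0.9), mk(TRUE, 0.03, 0.92))
  out2 <- classify_solvent(mixed, c(0.01, 0.2, 0.5))
  expect_identical(out2$condition, "poor")
  expect_equal(out2$binodal, 0.028)
  expect_error(classify_solvent(mixed[1:2], c(0.1, 0.2)), ">= 3")
})
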