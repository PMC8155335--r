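test_that("tension integral matches the analytic spike evaluation", {
  R_mid <- 22.5
  bw <- 0.2
  # single-bin spike of height c at the midsurface: the geometric
  # weight (r/R_mid)^2 is 1 there
  sp0 <- spike_stress(R_mid, 3.5, bw)
  r0 <- sp0$r[which.min(abs(sp0$r - R_mid))]
  expect_equal(bilayer_tension(sp0, R_mid), 3.5 * bw * (r0 / R_mid)^2,
               tolerance = 1e-12)
  # spike off the midsurface picks up the spherical weight
  sp1 <- spike_stress(25, 2, bw)
  r1 <- sp1$r[which.min(abs(sp1$r - 25))]
  expect_equal(bilayer_tension(sp1, R_mid), 2 * bw * (r1 / R_mid)^2,
               tolerance = 1e-12)
  # zero stress integrates to zero tension
  null <- stress_profile(sp0$r, numeric(length(sp0$r)),
                         numeric(length(sp0$r)), bw)
  expect_equal(bilayer_tension(null, R_mid), 0)
  expect_error(bilayer_tension(sp0, R_mid = 300), "cover")
})

test_that("first moment is the (r - R_mid)-weighted integral", {
  R_mid <- 22.5
  bw <- 0.2
  sp <- spike_stress(25, 2, bw)
  r1 <- sp$r[which.min(abs(sp$r - 25))]
  expect_equal(first_moment(sp, R_mid), (r1 - R_mid) * 2 * bw,
               tolerance = 1e-12)
  # linearity: negating s flips the sign
  neg <- stress_profile(sp$r, -sp$s, numeric(length(sp$r)), bw)
  expect_equal(first_moment(neg, R_mid), -first_moment(sp, R_mid))
  # zero profile, zero moment
  null <- stress_profile(sp$r, numeric(length(sp$r)),
                         numeric(length(sp$r)), bw)
  expect_equal(first_moment(null, R_mid), 0)
  # refuses away from the tensionless state
  expect_error(first_moment(sp, R_mid, Sigma = 0.5), "tensionless")
  expect_silent(first_moment(sp, R_mid, Sigma = 0.05))
})

test_that("spontaneous curvature inverts the moment relation", {
  # zero moment: the relation pins m at 1/R_mid
  expect_equal(spontaneous_curvature(0, kappa = 10, R_mid = 22.5),
               1 / 22.5)
  # consistency: m computed from a moment constructed for a known m
  m_true <- 0.089
  R_mid <- 22.5
  kappa <- 12
  mom <- 2 * kappa * (1 / R_mid - m_true)
  expect_equal(spontaneous_curvature(mom, kappa, R_mid), m_true,
               tolerance = 1e-12)
  expect_error(spontaneous_curvature(1, kappa = 0, R_mid = 10), "kappa")
  expect_error(spontaneous_curvature(1, kappa = 5, R_mid = 0), "R_mid")
})

test_that("area compressibility is the tension-dilation slope", {
  x <- c(-0.02, -0.01, 0, 0.01, 0.02)
  expect_equal(area_compressibility(x, 20 * x), 20, tolerance = 1e-10)
  # noisy but exactly linear-in-mean data
  expect_equal(area_compressibility(x, 20 * x + 0.5), 20,
               tolerance = 1e-10)
  # two-point fallback equals the finite difference
  expect_equal(area_compressibility(c(0, 0.01), c(0, 0.17)), 17)
  expect_error(area_compressibility(c(0.01, 0.01), c(0, 1)),
               "degenerate")
})

test_that("bending rigidity follows the K_A l^2 / 48 relation", {
  expect_equal(bending_rigidity(48, 5), 25)
  expect_equal(bending_rigidity(20, 5), 20 * 25 / 48)
  # doubling the thickness quadruples kappa
  expect_equal(bending_rigidity(30, 10) / bending_rigidity(30, 5), 4)
  expect_error(bending_rigidity(-1, 5), "> 0")
})

test_that("tensionless search interpolates the zero crossing", {
  # synthetic linear Sigma(N) crossing zero at N* = 61000
  n_star <- 61000
  lin_eval <- function(n) 2e-4 * (n - n_star)
  st <- structure(list(meta = list(N_W_isp = 60000)), class = "dpd_state")
  out <- find_tensionless(st, good_ff(),
                          N_W_in_grid = c(55000, 60000, 65000),
                          evaluate = lin_eval)
  expect_equal(out$N_W0_in, n_star)
  expect_equal(out$nu_0, n_star / 60000)
  expect_equal(nrow(out$scan), 3)
  # no sign change in the bracket is an error reporting the bracket
  expect_error(
    find_tensionless(st, good_ff(), N_W_in_grid = c(70000, 75000, 80000),
                     evaluate = lin_eval),
    "bracket")
  expect_error(
    find_tensionless(st, good_ff(), N_W_in_grid = c(1, 2),
                     evaluate = lin_eval),
    "at least 3")
})

test_that("bulk fluid stress is isotropic and consistent with the virial", {
  st <- build_bulk(0, box = 8, seed = 20)
  run <- dpd_run(st, good_ff(), dpd_config(seed = 21), n_steps = 2500,
                 frame_stride = 100, obs_stride = 500)
  frames <- as_frames(run$traj)[6:25]
  sp <- spherical_stress_profile(frames, good_ff(), center = st$box / 2)
  # volume-averaged shell pressure matches the global virial within 1%
  expect_lt(abs(attr(sp, "virial_check")), 0.01)
  # s(r) is statistically zero bin by bin: per-frame profiles give the
  # sampling error of each bin mean
  per_frame <- sapply(frames, function(fr)
    spherical_stress_profile(fr, good_ff(), center = st$box / 2)$s)
  # skip tiny-volume central shells and the box-edge bin, where the
  # minimum-image environment is anisotropic
  sel <- sp$r > 1.5 & sp$r < max(sp$r)
  mu <- rowMeans(per_frame)[sel]
  sem <- apply(per_frame, 1, stats::sd)[sel] / sqrt(ncol(per_frame))
  # ~5% of bins may exceed 2 SEM by chance; require the bulk of them in
  expect_lt(mean(abs(mu) > 3 * sem), 0.05)
  expect_lt(abs(sum(mu * sp$r[sel]^2) / sum(sp$r[sel]^2)), 0.3)
})
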