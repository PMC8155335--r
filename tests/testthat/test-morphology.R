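test_that("neck diameter matches the sphere-sphere intersection circle", {
  # two shells of radius R with centres 1.6 R apart intersect in a
  # circle of radius R sqrt(1 - 0.8^2) = 0.6 R
  st <- make_fixture("dumbbell_shells", seed = 1)
  R <- st$meta$R
  nk <- neck_diameter(st)
  expect_true(nk$has_neck)
  br <- neck_bracket(R, st$meta$sep)
  expect_gt(nk$D_ne, br["lo"])
  expect_lt(nk$D_ne, br["hi"])
  expect_identical(nk$state, "closed")  # analytic 8.4 d < 10 d

  # wider overlap: intersection diameter 2 R sqrt(1 - 0.6^2) = 1.6 R,
  # an open neck at R = 7
  wide <- make_fixture("dumbbell_shells", seed = 2,
                       separation_factor = 1.2)
  nk2 <- neck_diameter(wide)
  br2 <- neck_bracket(wide$meta$R, wide$meta$sep)
  expect_gt(nk2$D_ne, br2["lo"])
  expect_lt(nk2$D_ne, br2["hi"])
  expect_identical(nk2$state, "open")
})

test_that("neck diameter is invariant under rigid rotation", {
  st <- make_fixture("dumbbell_shells", seed = 3)
  d0 <- neck_diameter(st)$D_ne
  for (s in 1:3) {
    q <- random_rotation(seed = s)
    rot <- st
    ctr <- st$box / 2
    rot$pos <- sweep(sweep(st$pos, 2, ctr) %*% t(q), 2, ctr, "+")
    expect_equal(neck_diameter(rot)$D_ne, d0, tolerance = 0.08)
  }
})

test_that("near-spherical shapes carry a no-neck flag", {
  st <- shell_state(2000, R = 8, box = 30, type = "H", seed = 4)
  st$mol <- seq_len(nrow(st$pos))
  nk <- neck_diameter(st)
  expect_false(nk$has_neck)
})

test_that("division detection counts membrane components by linkage", {
  whole <- make_fixture("dumbbell_shells", seed = 5)
  expect_equal(detect_division(whole)$n_components, 1)

  apart <- make_fixture("separated_shells", seed = 6)
  div <- detect_division(apart)
  expect_equal(div$n_components, 2)
  expect_equal(length(div$lipids), 2)

  # shells 0.5 d apart merge under a 1.0 d cutoff
  near <- make_fixture("separated_shells", seed = 7, gap = 0.5)
  expect_equal(detect_division(near)$n_components, 1)
  # cutoff semantics on a minimal pair: 0.5 d apart links at 1.0 d,
  # splits at 0.3 d
  two <- dpd_state(c(5, 5, 5), rbind(c(2, 2, 2), c(2.5, 2, 2)),
                   vel = matrix(0, 2, 3), type = c("H", "H"),
                   mol = 1:2)
  expect_equal(detect_division(two)$n_components, 1)
  expect_equal(detect_division(two, cutoff = 0.3)$n_components, 2)
})

test_that("contact area of parallel patches recovers the patch area", {
  # two L x L square grids of head beads at gap 2 d
  L <- 10
  delta <- 0.5
  gx <- seq(delta / 2, L - delta / 2, by = delta)
  grid <- as.matrix(expand.grid(gx, gx))
  box <- c(30, 30, 30)
  p1 <- cbind(grid + 10, 14)
  p2 <- cbind(grid + 10, 16)
  pos <- rbind(p1, p2)
  n <- nrow(pos)
  st <- dpd_state(box, pos, vel = matrix(0, n, 3), type = rep("H", n),
                  mol = seq_len(n))
  segments <- c(rep(1L, nrow(p1)), rep(2L, nrow(p2)))
  area <- contact_area(st, segments = segments,
                       area_per_head = delta^2)
  expect_equal(area, L^2, tolerance = 0.1)

  # pull the patches far apart: no contacts
  st2 <- st
  st2$pos[segments == 2L, 3] <- 25
  expect_equal(contact_area(st2, segments = segments,
                            area_per_head = delta^2), 0)
})

test_that("a single convex shell has zero contact area", {
  st <- shell_state(2000, R = 8, box = 30, type = "H", seed = 8)
  st$mol <- seq_len(nrow(st$pos))
  expect_equal(contact_area(st), 0)
})

test_that("morphology trace reports per-frame observables", {
  st <- make_fixture("dumbbell_shells", seed = 9)
  tr <- morphology_trace(list(st, st))
  expect_equal(nrow(tr), 2)
  expect_identical(tr$neck_state[1], "closed")
  expect_equal(tr$components, c(1, 1))
})
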