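test_that("conservative pair force is linear, repulsive and cut off at d", {
  expect_equal(pair_force_magnitude(25, 1.0), 0)
  expect_equal(pair_force_magnitude(25, 0.5), 12.5)
  expect_equal(pair_force_magnitude(75, 0), 75)
  expect_equal(pair_force_magnitude(25, 2.0), 0)
  # continuity across the cutoff
  eps <- 1e-9
  expect_lt(pair_force_magnitude(25, 1 - eps), 1e-6)
  expect_error(pair_force_magnitude(25, -0.1), "non-negative")
  expect_error(pair_force_magnitude(-1, 0.5), "non-negative")
})

test_that("solubility reduces to 25/f_WS at the published parameters", {
  expect_equal(solubility(25, 25, 32), 25 / 32)
  expect_equal(solubility(25, 25, 40), 0.625)
  expect_equal(solubility(25, 25, 25), 1)
  expect_error(solubility(25, 25, 0), "> 0")
  expect_error(solubility(0, 25, 32), "> 0")
})

test_that("default force table matches the published parameter set", {
  good <- default_force_table("good")
  poor <- default_force_table("poor")
  expect_equal(good$f["H", "C"], 50)
  expect_equal(good$f["H", "S"], 15)
  expect_equal(good$f["C", "W"], 75)
  expect_equal(good$f["W", "S"], 32)
  expect_equal(poor$f["W", "S"], 40)
  for (ff in list(good, poor)) {
    expect_true(isSymmetric(ff$f))
    expect_true(all(ff$f >= 0))
  }
  # deleting the S row/column leaves the same solute-free table for both
  # solvent conditions
  expect_identical(good$f[1:3, 1:3], poor$f[1:3, 1:3])
  expect_equal(unname(good$f[1:3, 1:3]),
               matrix(c(30, 50, 30, 50, 10, 75, 30, 75, 25), 3))
  expect_error(default_force_table("medium"))
})

test_that("fluctuation-dissipation ties sigma to gamma for any table", {
  for (g in c(2, 4.5, 9)) {
    ff <- default_force_table("good", gamma = g)
    expect_equal(ff$sigma^2, 2 * g * ff$kBT)
  }
  expect_error(dpd_forcefield(matrix(-1, 4, 4,
    dimnames = list(bead_types(), bead_types()))), ">= 0")
  asym <- default_force_table("good")$f
  asym[1, 2] <- 99
  expect_error(dpd_forcefield(asym), "symmetric")
})

test_that("lipid topology has 15 beads in a connected 3H + 2x6C layout", {
  lt <- lipid_topology()
  expect_equal(lt$n_beads, 15L)
  expect_equal(sum(lt$types == "H"), 3)
  expect_equal(sum(lt$types == "C"), 12)
  # connectivity of the bond graph by breadth-first search
  adj <- vector("list", 15)
  for (b in seq_len(nrow(lt$bonds))) {
    i <- lt$bonds[b, 1]; j <- lt$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(15)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
  }
  expect_true(all(seen))
  # every angle triple is a path of bonds
  bond_key <- paste(pmin(lt$bonds[, 1], lt$bonds[, 2]),
                    pmax(lt$bonds[, 1], lt$bonds[, 2]))
  for (a in seq_len(nrow(lt$angles))) {
    tr <- lt$angles[a, ]
    expect_true(paste(min(tr[1:2]), max(tr[1:2])) %in% bond_key)
    expect_true(paste(min(tr[2:3]), max(tr[2:3])) %in% bond_key)
  }
})
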