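sp <- polyApGProfile()
base <- defaultRemodelerParams()

test_that("effectiveParams switches the chemical-state parameters", {
  atp <- effectiveParams(base, sp, "ATP")
  expect_equal(atp@epsLobes, 1.0)
  expect_equal(atp@grip1, 1.8)
  expect_equal(atp@grip2, 1.8)
  expect_gt(atp@strain, 0)

  adp <- effectiveParams(base, sp, "ADP")
  expect_equal(adp@grip2, 1.44)           # 0.8 weakening after hydrolysis
  expect_equal(adp@epsLobes, 0.17)        # coupling reverts to apo
  expect_equal(adp@strain, 0)

  apo <- effectiveParams(base, sp, "APO")
  expect_equal(apo@epsLobes, 0.17)
  expect_equal(apo@grip1, 1.8 * sp@g1)

  # determinism: same inputs give identical parameter sets
  expect_identical(effectiveParams(base, sp, "APO"),
                   effectiveParams(base, sp, "APO"))
  expect_error(effectiveParams(base, sp, "GTP"), "unknown chemical state")
})

test_that("twistEnergy has wells at -1, 0, +1 with the declared energies", {
  expect_equal(twistEnergy(0, 15, 3, 3), 0, tolerance = 1e-8)
  expect_equal(twistEnergy(1, 15, 3, 2), 3, tolerance = 1e-8)
  expect_equal(twistEnergy(-1, 15, 3, 2), 2, tolerance = 1e-8)
  # off-well value agrees with an independent evaluation of the softmin
  expect_equal(twistEnergy(0.5, 15, 3, 3), oracleTwist(0.5, 15, 3, 3),
               tolerance = 1e-12)
  # clamped branches: far outside the wells the outermost harmonic rules
  expect_equal(twistEnergy(3, 15, 3, 3), 3 + 0.5 * 15 * 4, tolerance = 1e-6)
  expect_error(twistEnergy(0, -1, 3, 3))
})

test_that("totalEnergy equals the term-by-term scalar oracle", {
  set.seed(42)
  for (chem in c("APO", "ATP", "ADP")) {
    ps <- effectiveParams(base, sp, chem)
    for (rep in 1:20) {
      s <- randomState()
      expect_equal(totalEnergy(s, ps), oracleEnergy(s, ps),
                   tolerance = 1e-10)
    }
  }
})

test_that("uniform untilted profile gives translational symmetry", {
  ps <- effectiveParams(base, sp, "APO")
  set.seed(7)
  for (rep in 1:10) {
    s <- randomState()
    expect_equal(totalEnergy(s + 1, ps), totalEnergy(s, ps),
                 tolerance = 1e-10)
    expect_equal(totalEnergy(s - 1, ps), totalEnergy(s, ps),
                 tolerance = 1e-10)
  }
})

test_that("electrostatic spring contributes -epsElec exactly at reference", {
  wt <- effectiveParams(base, sp, "APO")
  mut <- effectiveParams(defaultRemodelerParams(epsElec = 0), sp, "APO")
  dE <- totalEnergy(systemState(), wt) - totalEnergy(systemState(), mut)
  expect_equal(dE, -base@epsElec, tolerance = 1e-12)
})

test_that("gradient matches central finite differences on random states", {
  set.seed(11)
  h <- 1e-5
  nchecked <- 0
  for (chem in c("APO", "ATP", "ADP")) {
    ps <- effectiveParams(base, sp, chem)
    for (rep in 1:40) {
      s <- randomState()
      g <- energyGradient(s, ps)
      fd <- vapply(1:16, function(i) {
        e <- rep(0, 16); e[i] <- h
        (totalEnergy(s + e, ps) - totalEnergy(s - e, ps)) / (2 * h)
      }, numeric(1))
      expect_equal(unname(g), fd, tolerance = 1e-4)
      nchecked <- nchecked + 1
    }
  }
  expect_gte(nchecked, 100)
})

test_that("tilt adds exactly its slope to the gradient", {
  tilted <- sp
  tilted@contacts$tilt[9] <- 1.75
  ps0 <- effectiveParams(base, sp, "APO")
  ps1 <- effectiveParams(base, tilted, "APO")
  s <- systemState(x = rnorm(14, 0, 0.3), y1 = 0.1, y2 = -0.1)
  expect_equal(energyGradient(s, ps1) - energyGradient(s, ps0),
               setNames(c(rep(0, 8), 1.75, rep(0, 7)), coordNames()),
               tolerance = 1e-10)
})

test_that("gradient vanishes at the symmetric reference minimum", {
  # all coordinates at well centres, u = 0, r1 = 0: every term is at a
  # stationary point
  ps <- effectiveParams(base, sp, "APO")
  g <- energyGradient(systemState(), ps)
  expect_equal(unname(g[1:14]), rep(0, 14), tolerance = 1e-8)
  # the lobes feel only the linear coupling-offset slope at u = 0
  expect_equal(unname(g["y1"]), ps@couplingOffset, tolerance = 1e-8)
  expect_equal(unname(g["y2"]), -ps@couplingOffset, tolerance = 1e-8)
})

test_that("forward-slid closed state is downhill for the WT ratchet", {
  atp <- effectiveParams(base, sp, "ATP")
  slid <- systemState(x = rep(1, 14), y1 = 1, y2 = 0)
  unslid <- systemState(y1 = 1, y2 = 0)
  expect_lt(totalEnergy(slid, atp), totalEnergy(unslid, atp))
  # without the spring and tilt the two registrations are equivalent
  mut <- effectiveParams(defaultRemodelerParams(epsElec = 0), sp, "ATP")
  expect_equal(totalEnergy(slid, mut), totalEnergy(unslid, mut),
               tolerance = 0.2)
})

test_that("steric wall penalizes remodeler-body excursions", {
  apo <- effectiveParams(base, sp, "APO")   # u = 0 set
  noWall <- twistslide:::setTerms(apo, wall = FALSE)
  for (sgn in c(-1, 1)) {
    s <- systemState()
    s[c("x_1.5", "x_2.5")] <- sgn           # |xbar - ybar| = 1
    expect_equal(totalEnergy(s, apo) - totalEnergy(s, noWall),
                 base@wallHeight * (1 - base@wallHalfwidth)^2,
                 tolerance = 1e-10)
  }
})
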