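sp <- polyApGProfile()
base <- defaultRemodelerParams()

test_that("single Euler-Maruyama step has the documented drift and noise", {
  ps <- effectiveParams(base, sp, "APO")
  # at the reference minimum with noise disabled, x coordinates are fixed
  s1 <- stepState(systemState(), ps, noise = FALSE)
  expect_equal(unname(s1[1:14]), rep(0, 14), tolerance = 1e-12)

  # constant force: displacement f * D * dt per step (tilt supplies f)
  tilted <- sp
  tilted@contacts$tilt[3] <- 2.5
  pst <- effectiveParams(base, tilted, "APO")
  cfg <- integratorConfig()
  s2 <- stepState(systemState(), pst, cfg, noise = FALSE)
  expect_equal(unname(s2[3]), -2.5 * cfg$D_dna * cfg$dt, tolerance = 1e-10)

  # frozen blocks do not move
  psf <- twistslide:::setTerms(pst, freeze_dna = TRUE)
  s3 <- stepState(systemState(), psf, cfg, noise = TRUE)
  expect_equal(unname(s3[1:14]), rep(0, 14))
})

test_that("free diffusion has variance 2 D t", {
  # lobes with all wells/couplings switched off diffuse freely
  free <- defaultRemodelerParams(epsLobeDna = c(0, 0), couplingBarrier = 0,
                                 couplingScale = 0, lobe1Strain = 0,
                                 adpRelease = 0)
  ps <- twistslide:::setTerms(effectiveParams(free, sp, "APO"),
                              octamer = FALSE, wall = FALSE, elec = FALSE,
                              freeze_dna = TRUE)
  pl <- twistslide:::asPhaseList(ps)
  n <- 1e4
  set.seed(123)
  fin <- twistslide:::cpp_simulate(rep(0, 16), list(pl), 100L, 5e-4, 1, 1,
                                   100L)$coords
  # one trajectory only samples one endpoint; use many short replicas
  d <- vapply(1:n, function(i) {
    twistslide:::cpp_simulate(rep(0, 16), list(pl), 40L, 5e-4, 1, 1,
                              40L)$final[15]
  }, numeric(1))
  t <- 40 * 5e-4
  v <- var(d)
  se <- sqrt(2) * (2 * t) / sqrt(n)   # SE of a variance estimate
  expect_lt(abs(v - 2 * t), 3 * se)
})

test_that("a decoupled coordinate samples its Boltzmann distribution", {
  # lobe 1 alone in its cosine grip well, compared against quadrature
  solo <- defaultRemodelerParams(epsLobeDna = c(3, 0), gripScale = c(1, 1),
                                 couplingBarrier = 0, couplingScale = 0,
                                 lobe1Strain = 0, adpRelease = 0)
  ps <- twistslide:::setTerms(effectiveParams(solo, sp, "APO"),
                              octamer = FALSE, wall = FALSE, elec = FALSE,
                              freeze_dna = TRUE)
  pl <- twistslide:::asPhaseList(ps)
  set.seed(99)
  res <- twistslide:::cpp_simulate(rep(0, 16), list(pl), 1000000L, 5e-4,
                                   1, 1, 20L)
  y <- res$coords[-(1:2000), 15]
  y <- y[abs(y) < 0.5]                      # rare well hops excluded
  breaks <- seq(-0.5, 0.5, 0.05)
  h <- table(cut(y, breaks))
  p_obs <- as.numeric(h) / sum(h)
  # quadrature of exp(-U) over each bin
  U <- function(z) 3 * (1 - cos(2 * pi * z)) / 2
  p_exp <- vapply(seq_len(length(breaks) - 1), function(i) {
    integrate(function(z) exp(-U(z)), breaks[i], breaks[i + 1])$value
  }, numeric(1))
  p_exp <- p_exp / sum(p_exp)
  # effective sample size is reduced by autocorrelation (~tau/stride)
  neff <- length(y) / 10
  se <- sqrt(p_exp * (1 - p_exp) / neff)
  expect_true(all(abs(p_obs - p_exp) < 3.5 * se + 0.004))
})

test_that("trajectories are bit-reproducible and schedule-aware", {
  sched <- schedule(c("APO", "ATP"), c(1, 1))
  tr1 <- runSchedule(sched = sched, seed = 42)
  tr2 <- runSchedule(sched = sched, seed = 42)
  expect_identical(tr1@coords, tr2@coords)
  expect_identical(tr1@final, tr2@final)
  expect_equal(tr1@phaseBounds, 1)
  expect_equal(unique(tr1@chem), c("APO", "ATP"))
  # phase boundaries respected snapshot-wise
  expect_true(all(tr1@chem[tr1@times <= 1] == "APO"))
  expect_true(all(tr1@chem[tr1@times > 1] == "ATP"))
})

test_that("no drift under a fixed chemical state", {
  # equilibrium run of the full system in the apo state: the sliding
  # coordinate stays put (no ratchet without potential switching)
  tr <- runSchedule(sched = schedule("APO", 60), seed = 77)
  xb <- shl2Coordinate(tr)$shl2
  xb <- xb[tr@times > 5]
  se <- sd(xb) / sqrt(length(xb) / 100)   # generous autocorrelation factor
  expect_lt(abs(mean(xb)), max(3 * se, 0.15))
  expect_equal(unname(round(tail(xb, 1))), 0)
})

test_that("naked mode freezes the DNA and keeps only lobe terms", {
  tr <- runNaked(sched = schedule("APO", 2), seed = 5)
  expect_equal(max(abs(tr@coords[, 1:14])), 0)
  expect_gt(sd(tr@coords[, "y1"]), 0)
})

test_that("ensembles are seed-disjoint and mergeable", {
  sched <- schedule(c("APO", "ATP"), c(0.5, 0.5))
  a <- runEnsemble(2, seed0 = 1, sched = sched)
  b <- runEnsemble(2, seed0 = 3, sched = sched)
  ab <- runEnsemble(4, seed0 = 1, sched = sched)
  expect_equal(rbind(a$summary, b$summary), ab$summary)
  # n = 1 reduces to runSchedule
  one <- runEnsemble(1, seed0 = 9, sched = sched, keepTrajectories = TRUE)
  direct <- runSchedule(sched = sched, seed = 9)
  expect_identical(one$trajectories[[1]]@coords, direct@coords)
})
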