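test_that("Boltzmann inversion recovers known distributions", {
  # uniform samples: flat profile near 0
  set.seed(1)
  f1 <- boltzmannInvert(runif(2e4), seq(0, 1, 0.1))
  expect_lt(max(f1@F, na.rm = TRUE), 0.15)

  # standard Gaussian: F(x) ~ x^2/2 within sampling error
  x <- rnorm(2e5)
  f2 <- boltzmannInvert(x, seq(-2.4, 2.4, 0.2))
  mid <- f2@centers[[1]]
  keep <- !is.na(f2@F)
  expect_lt(max(abs(f2@F[keep] - (mid[keep]^2 / 2 - min(mid[keep]^2 / 2)))),
            0.12)

  # two-state 75/25: dF = ln 3 exactly from the counts
  f3 <- boltzmannInvert(c(rep(0.5, 75), rep(1.5, 25)), c(0, 1, 2),
                        minCount = 5)
  expect_equal(f3@F[2] - f3@F[1], log(3), tolerance = 1e-12)

  expect_warning(boltzmannInvert(rep(0.5, 100), c(0, 1, 2)), "degenerate")
})

strip <- function(C) matrix(as.integer(C), nrow(C))

test_that("count matrix accumulates sliding-window lagged pairs", {
  C <- countMatrix(c(1, 1, 2, 2), lag = 1)
  expect_equal(strip(C), matrix(c(1L, 0L, 1L, 1L), 2))
  # lag 2 by brute-force pair enumeration
  d <- c(1, 1, 2, 2)
  C2 <- countMatrix(d, lag = 2)
  brute <- matrix(0L, 2, 2)
  for (t in 1:2) brute[d[t], d[t + 2]] <- brute[d[t], d[t + 2]] + 1L
  expect_equal(strip(C2), brute)
  # random series, several lags, against the same brute-force oracle
  set.seed(4)
  d3 <- sample(1:3, 200, replace = TRUE)
  for (lag in c(1, 3, 7)) {
    Cb <- matrix(0L, 3, 3)
    for (t in seq_len(200 - lag)) {
      Cb[d3[t], d3[t + lag]] <- Cb[d3[t], d3[t + lag]] + 1L
    }
    expect_equal(strip(countMatrix(d3, lag)), Cb)
  }
  # segments never bridged
  Cseg <- countMatrix(list(c(1, 1), c(2, 2)), lag = 1)
  expect_equal(strip(Cseg), matrix(c(1L, 0L, 0L, 1L), 2))
  expect_warning(countMatrix(c(1, 2), lag = 5), "empty")
  expect_error(countMatrix(c(1, 2), lag = 0.5, stride = 1), "multiple")
})

test_that("transition matrix estimation is row-stochastic and reversible", {
  m <- transitionMatrix(matrix(c(9, 1, 1, 9), 2), states = c("a", "b"),
                        lag = 1)
  expect_equal(unname(m@T), matrix(c(0.9, 0.1, 0.1, 0.9), 2))
  expect_equal(unname(m@pi), c(0.5, 0.5))
  expect_equal(unname(rowSums(m@T)), c(1, 1), tolerance = 1e-12)
  # detailed balance identity
  flux <- unname(m@pi * m@T)
  expect_equal(flux, t(flux), tolerance = 1e-10)
})

test_that("sampled chains recover the true transition matrix", {
  T_true <- matrix(c(0.87, 0.08, 0.05,
                     0.05, 0.90, 0.05,
                     0.05, 0.02, 0.93), 3, byrow = TRUE)
  d <- markovSampler(T_true, 1e5, seed = 9)
  m <- transitionMatrix(countMatrix(d, 1), symmetrize = FALSE)
  # each entry within 3 binomial standard errors
  nvis <- table(factor(d[-length(d)], levels = 1:3))
  se <- sqrt(T_true * (1 - T_true) / as.numeric(nvis))
  expect_true(all(abs(m@T - T_true) < pmax(3 * se, 1e-3)))
})

test_that("implied timescales match the analytic two-state value", {
  # switch probabilities 0.1 / 0.2: lambda_2 = 1 - 0.1 - 0.2 = 0.7
  Tm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  C <- round(1e6 * c(2 / 3, 1 / 3) * Tm)  # counts consistent with pi
  m <- transitionMatrix(C, lag = 1)
  it <- impliedTimescales(m)
  expect_equal(it$timescale[1], -1 / log(0.7), tolerance = 1e-4)

  # identity chain: disconnected states collapse, no finite timescales
  mid <- suppressMessages(
    transitionMatrix(diag(c(10, 10)) + 0, symmetrize = TRUE, lag = 1))
  itid <- impliedTimescales(mid)
  expect_true(nrow(itid) == 0 || all(is.na(itid$timescale)))

  # timescales non-increasing in rank
  set.seed(6)
  C4 <- matrix(rpois(16, 30), 4) + diag(200, 4)
  it4 <- impliedTimescales(transitionMatrix(C4, lag = 2))
  expect_true(all(diff(it4$timescale) <= 1e-12))
  # and proportional to the lag through the eigenvalue relation
  expect_equal(it4$lag, rep(2, nrow(it4)))
})

test_that("Chapman-Kolmogorov holds on a sampled fixture chain", {
  T_true <- matrix(c(0.95, 0.05, 0.10, 0.90), 2, byrow = TRUE)
  d <- markovSampler(T_true, 2e5, seed = 21)
  m1 <- transitionMatrix(countMatrix(d, 1), lag = 1)
  m2 <- transitionMatrix(countMatrix(d, 2), lag = 2)
  expect_equal(m2@T, m1@T %*% m1@T, tolerance = 0.02)
})

test_that("MFPT linear solve matches geometric law and simulation", {
  # source = target
  Tm <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  C <- round(1e6 * c(2 / 3, 1 / 3) * Tm)
  m <- transitionMatrix(C, lag = 1, symmetrize = FALSE)
  expect_equal(unname(mfpt(m, 1)[1]), 0)
  # two-state: MFPT = lag / p_exit
  expect_equal(unname(mfpt(m, 2)[1]), 1 / 0.1, tolerance = 1e-4)
  m5 <- transitionMatrix(C, lag = 2.5, symmetrize = FALSE)
  expect_equal(unname(mfpt(m5, 2)[1]), 2.5 / 0.1, tolerance = 1e-4)

  # 5-state chain vs brute-force first-passage simulation
  set.seed(13)
  A <- matrix(runif(25, 0.02, 1), 5)
  T5 <- A / rowSums(A)
  m5s <- transitionMatrix(round(T5 * 1e6), lag = 1, symmetrize = FALSE)
  target <- 5
  analytic <- mfpt(m5s, target)
  nrep <- 2e4
  set.seed(14)
  # vectorized brute force: propagate all replicas until absorption
  state <- rep(1L, nrep)
  steps <- rep(0L, nrep)
  alive <- state != target
  cum <- t(apply(T5, 1, cumsum))
  while (any(alive)) {
    u <- runif(sum(alive))
    idx <- which(alive)
    nxt <- vapply(seq_along(idx), function(j) {
      findInterval(u[j], cum[state[idx[j]], ]) + 1L
    }, integer(1))
    state[idx] <- nxt
    steps[idx] <- steps[idx] + 1L
    alive <- state != target
  }
  se <- sd(steps) / sqrt(nrep)
  expect_lt(abs(mean(steps) - analytic[1]), 3 * se + 1e-9)
})

test_that("stationary free energies invert the stationary distribution", {
  m <- transitionMatrix(matrix(c(9, 1, 1, 9), 2), lag = 1)
  expect_equal(unname(stationaryFreeEnergy(m)@F), c(0, 0))
  mskew <- transitionMatrix(round(matrix(c(75, 12.5, 12.5, 0), 2) * 10),
                            lag = 1)
  f <- stationaryFreeEnergy(mskew)@F
  expect_equal(unname(f[2] - f[1]), log(875 / 125), tolerance = 1e-9)
  # recovery of a constructed Boltzmann chain: counts C_ij from pi_i T_ij
  E <- c(0, 1.3, 2.4)
  piB <- exp(-E) / sum(exp(-E))
  Tb <- matrix(0.05, 3, 3)
  # Metropolis rates give detailed balance w.r.t. piB
  for (i in 1:3) for (j in 1:3) if (i != j)
    Tb[i, j] <- 0.1 * min(1, exp(E[i] - E[j]))
  diag(Tb) <- 0; diag(Tb) <- 1 - rowSums(Tb)
  Cb <- round(1e7 * piB * Tb)
  fb <- stationaryFreeEnergy(transitionMatrix(Cb, lag = 1))@F
  expect_equal(unname(fb), E, tolerance = 1e-3)
})

test_that("minimax path matches exhaustive enumeration on a 4x4 grid", {
  set.seed(19)
  F <- matrix(round(runif(16, 0, 6), 2), 4)
  fep <- new("FreeEnergyProfile",
             centers = list(1:4, 1:4), F = F - min(F),
             counts = matrix(100L, 4, 4))
  res <- minEnergyPath(fep, c(1, 1), c(4, 4))
  # exhaustive search over all simple 8-connected paths
  best <- list(bn = Inf, sum = Inf)
  Fz <- fep@F
  recurse <- function(r, c, seen, bn, s) {
    bn <- max(bn, Fz[r, c]); s <- s + Fz[r, c]
    if (r == 4 && c == 4) {
      if (bn < best$bn || (bn == best$bn && s < best$sum))
        best <<- list(bn = bn, sum = s)
      return()
    }
    for (dr in -1:1) for (dc in -1:1) {
      r2 <- r + dr; c2 <- c + dc
      if ((dr | dc) && r2 >= 1 && r2 <= 4 && c2 >= 1 && c2 <= 4 &&
          !seen[r2, c2]) {
        seen[r2, c2] <- TRUE
        recurse(r2, c2, seen, bn, s)
        seen[r2, c2] <- FALSE
      }
    }
  }
  seen <- matrix(FALSE, 4, 4); seen[1, 1] <- TRUE
  recurse(1, 1, seen, -Inf, 0)
  expect_equal(res$bottleneck, best$bn)
  expect_equal(max(res$profile), best$bn)
  # path is 8-connected and simple
  steps <- abs(diff(res$path))
  expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
  expect_equal(anyDuplicated(res$path), 0)
})

test_that("minEnergyPath handles degenerate and masked cases", {
  flat <- new("FreeEnergyProfile", centers = list(1:3, 1:3),
              F = matrix(0, 3, 3), counts = matrix(10L, 3, 3))
  r1 <- minEnergyPath(flat, c(2, 2), c(2, 2))
  expect_equal(nrow(r1$path), 1)
  expect_equal(r1$profile, 0)
  # flat grid: deterministic tie-break picks a unique, repeatable path
  r2 <- minEnergyPath(flat, c(1, 1), c(3, 3))
  r3 <- minEnergyPath(flat, c(1, 1), c(3, 3))
  expect_identical(r2$path, r3$path)
  # fully masked barrier: unreachable
  Fm <- matrix(0, 3, 3); Fm[, 2] <- NA
  fepm <- new("FreeEnergyProfile", centers = list(1:3, 1:3), F = Fm,
              counts = matrix(10L, 3, 3))
  expect_error(minEnergyPath(fepm, c(1, 1), c(1, 3)), "unreachable")
})

test_that("discretization maps trajectories deterministically", {
  tr <- scriptedTrajectory(c("o0", "cB0", "cD1"), dwell = 1, noise = 0,
                           seed = 2)
  d <- discretizeTrajectory(tr, "label")
  expect_true(all(c("o0", "cB0", "cD1") %in% d$dict))
  # scripted labels recovered frame by frame
  lab <- d$dict[unlist(d$dtrajs)]
  expect_equal(unique(lab), c("o0", "cB0", "cD1"))
  # closed-only filtering drops the open frames
  d2 <- discretizeTrajectory(tr, "label", closedOnly = TRUE)
  expect_false("o0" %in% d2$dict[unlist(d2$dtrajs)])
  # grid discretization covers out-of-range values via boundary cells
  d3 <- discretizeTrajectory(tr, "grid2d")
  expect_equal(length(unlist(d3$dtrajs)), length(tr@times))
})
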