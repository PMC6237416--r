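test_that("defect series implements d_i = x[i+0.5] - x[i-0.5]", {
  s <- systemState()
  s["x_1.5"] <- 1
  d <- defectSeries(matrix(s, 1))
  expect_equal(unname(d[1, "d_1"]), 1)    # +1 bp defect at SHL 1
  expect_equal(unname(d[1, "d_2"]), -1)   # -1 bp defect at SHL 2
  expect_equal(sum(abs(d)), 2)

  expect_equal(unname(defectSeries(matrix(systemState(), 1))[1, ]),
               rep(0, 13))
})

test_that("defects telescope exactly to the end-to-end sliding", {
  set.seed(3)
  co <- matrix(rnorm(50 * 16), 50)
  d <- defectSeries(co)
  expect_equal(rowSums(d), co[, 14] - co[, 1], tolerance = 1e-12)
})

test_that("shl2Coordinate returns the sliding and projection coordinates", {
  s <- systemState(); s[c("x_1.5", "x_2.5")] <- 1
  expect_equal(shl2Coordinate(matrix(s, 1))$shl2, 1)
  s2 <- systemState(); s2["x_1.5"] <- 1
  expect_equal(shl2Coordinate(matrix(s2, 1))$shl2, 0.5)
  # cD1-like snapshot: (y1 + y2 + x_1.5 + x_2.5, x_1.5 - x_-1.5) = (3, 1)
  s3 <- systemState(y1 = 1, y2 = 0)
  s3[c("x_1.5", "x_2.5")] <- c(1, 1)
  cv <- shl2Coordinate(matrix(s3, 1))
  expect_equal(cv$site_sum, 3)
  expect_equal(cv$dyad_defects, 1)
})

test_that("frame labels follow the metastable-state grammar", {
  expect_equal(labelFrame(systemState()), "o0")
  expect_equal(labelFrame(systemState(y1 = 0.6)), "cA0")
  expect_equal(labelFrame(systemState(y1 = 1)), "cB0")
  s <- systemState(y1 = 1); s["x_1.5"] <- 1
  expect_equal(labelFrame(s), "cC1")
  s["x_2.5"] <- 1
  expect_equal(labelFrame(s), "cD1")
  # digit counts near-dyad +1 bp defects, clamped to 0..2
  s2 <- systemState(y1 = 1); s2["x_1.5"] <- 1; s2["x_-1.5"] <- -1
  expect_equal(labelFrame(s2), "cC2")
  expect_equal(labelFrame(systemState(y1 = 1, y2 = 1)), "o0")
})

test_that("canonical label targets reproduce their own labels", {
  for (lab in c("o0", "o1", "o2", "cA0", "cA1", "cB0", "cB1",
                "cC1", "cC2", "cD0", "cD1", "cD2")) {
    expect_equal(labelFrame(labelTargets(lab)), lab)
  }
  expect_error(labelTargets("cB2"), "canonical")
  expect_error(labelTargets("x9"), "valid")
})

test_that("labelPath debounces flickers and condenses runs", {
  tr <- scriptedTrajectory(c("o0", "cB0", "o0"), dwell = c(3, 0.1, 3),
                           noise = 0, seed = 1)
  lp <- labelPath(tr, dwell_min = 0.25)
  expect_equal(lp$label, "o0")            # flicker absorbed, runs merged

  tr2 <- scriptedTrajectory(c("o0", "cB0"), dwell = 3, noise = 0)
  lp2 <- labelPath(tr2)
  expect_equal(lp2$label, c("o0", "cB0"))
  expect_equal(lp2$entry[1], tr2@stride)

  tr3 <- scriptedTrajectory("cD1", dwell = 2, noise = 0)
  expect_equal(labelPath(tr3)$label, "cD1")
})

test_that("cycleOutcome rounds the final coordinates and is stride-blind", {
  tr <- scriptedTrajectory(c("o0", "o1"), dwell = 2, noise = 0, seed = 5)
  out <- cycleOutcome(tr)
  expect_equal(unname(out["dna_step"]), 1)
  expect_equal(unname(out["lobe_step"]), 1)
  # stride invariance: thin the snapshots, keep the final state
  thin <- tr
  keep <- seq(1, length(tr@times), by = 4)
  thin@times <- tr@times[keep]; thin@coords <- tr@coords[keep, ]
  thin@chem <- tr@chem[keep]
  expect_equal(cycleOutcome(thin)[c("dna_step", "lobe_step")],
               out[c("dna_step", "lobe_step")])
  # rounding: 0.98 -> 1, 0.02 -> 0
  tr@final[c("x_1.5", "x_2.5")] <- 0.98
  expect_equal(unname(cycleOutcome(tr)["dna_step"]), 1)
  tr@final[c("x_1.5", "x_2.5")] <- 0.02
  expect_equal(unname(cycleOutcome(tr)["dna_step"]), 0)
})

test_that("ensembleProbability matches exhaustive counting with Wilson CI", {
  out <- c(rep(1, 98), rep(0, 2))
  p <- ensembleProbability(out)
  expect_equal(p$p[p$outcome == 1], 0.98)
  expect_equal(p$count, as.integer(c(2, 98)))
  # brute-force count agreement on an arbitrary list
  set.seed(8)
  o2 <- sample(-1:2, 57, replace = TRUE)
  p2 <- ensembleProbability(o2)
  for (i in seq_len(nrow(p2))) {
    expect_equal(p2$p[i], sum(o2 == p2$outcome[i]) / length(o2))
  }
  expect_true(all(p2$lower <= p2$p & p2$p <= p2$upper))
  # single outcome: p = 1 with a documented (sub-unit) lower bound
  p3 <- ensembleProbability(5)
  expect_equal(p3$p, 1)
  expect_lt(p3$lower, 1)
})

test_that("label transitions on scripted pathways obey the adjacency", {
  tr <- scriptedTrajectory(c("o0", "cA0", "cB0", "cC1", "cD1", "o1", "o0"),
                           dwell = 2, noise = 0.04, seed = 2)
  lp <- labelPath(tr)
  expect_equal(lp$label, c("o0", "cA0", "cB0", "cC1", "cD1", "o1", "o0"))
  allowed <- function(a, b) {
    la <- substr(a, 1, 2); lb <- substr(b, 1, 2)
    adj <- list(o = c("cA", "cD"), cA = c("o", "cB"), cB = c("cA", "cC"),
                cC = c("cB", "cD"), cD = c("cC", "o"))
    key <- if (startsWith(a, "o")) "o" else la
    tgt <- if (startsWith(b, "o")) "o" else lb
    diga <- as.integer(substr(a, nchar(a), nchar(a)))
    digb <- as.integer(substr(b, nchar(b), nchar(b)))
    (tgt %in% adj[[key]] || key == tgt) && abs(diga - digb) <= 1
  }
  for (i in seq_len(nrow(lp) - 1)) {
    expect_true(allowed(lp$label[i], lp$label[i + 1]))
  }
})
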