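#' Free-energy profile along the SHL 2 sliding coordinate by umbrella
#' sampling
#'
#' Barriers of several kBT make unbiased barrier crossings rare, so the
#' sliding profiles are computed from a ladder of harmonically restrained
#' windows on \code{(x_1.5 + x_2.5)/2}, recombined by standard 1-D WHAM
#' (self-consistent histogram reweighting).  Each window runs an
#' independent equilibrium trajectory under a fixed chemical-state
#' parameter set.
#'
#' @param base \code{\linkS4class{RemodelerParams}}.
#' @param seq \code{\linkS4class{SequenceProfile}}.
#' @param chem chemical state held fixed ("ATP" for the closed ensemble).
#' @param mode "nucleosome" or "spontaneous" (no remodeler).
#' @param centers window centres (bp) on the sliding coordinate.
#' @param biasK restraint stiffness (kBT/bp^2).
#' @param windowTime sampled time per window (time units) after
#'   \code{burnin}.
#' @param burnin discarded equilibration time per window.
#' @param breaks histogram bin boundaries (bp).
#' @param clampLobes hold the lobes at their starting registration, used to
#'   sample the metastable closed ensemble (y1 = 1, y2 = 0) without
#'   conformational reopening.
#' @param y0 starting lobe registration \code{c(y1, y2)}.
#' @param cfg \code{\link{integratorConfig}}.
#' @param seed base RNG seed (window i uses seed + i - 1).
#' @return a \code{\linkS4class{FreeEnergyProfile}} along the sliding
#'   coordinate.
#' @export
umbrellaProfile <- function(base = defaultRemodelerParams(),
                            seq = profileFromSequence(buildSequence("polyApG")),
                            chem = "ATP", mode = "nucleosome",
                            centers = seq(-0.4, 1.4, by = 0.1), biasK = 60,
                            windowTime = 70, burnin = 15,
                            breaks = seq(-0.55, 1.55, by = 0.1),
                            clampLobes = TRUE, y0 = c(1, 0),
                            cfg = integratorConfig(), seed = 1L) {
  nwin <- length(centers)
  nb <- length(breaks) - 1
  mids <- (head(breaks, -1) + tail(breaks, -1)) / 2
  H <- matrix(0, nwin, nb)       # histogram per window
  N <- numeric(nwin)
  sched1 <- schedule(chem, burnin + windowTime)
  # Two sequentially seeded ladders (ascending from the reference register
  # and descending from the slid register), each window starting from its
  # predecessor's final state.  The unbiased coordinates relax along the
  # ladder, and averaging both sweep directions in WHAM brackets the
  # residual hysteresis of slowly interconverting defect configurations.
  runLadder <- function(ord, x0, seedOff) {
    state <- systemState(x = x0, y1 = y0[1], y2 = y0[2])
    for (w in ord) {
      s0 <- state
      s0[contactIndex(1.5)] <- centers[w]
      s0[contactIndex(2.5)] <- centers[w]
      tr <- runSchedule(s0, sched1, base, seq, cfg,
                        seed = seed + seedOff + w - 1L, mode = mode,
                        clampLobes = clampLobes,
                        bias = c(biasK, centers[w]))
      state <- systemState(x = tr@final[1:14], y1 = y0[1], y2 = y0[2])
      cv <- shl2Coordinate(tr)$shl2[tr@times > burnin]
      h <- table(cut(cv, breaks, include.lowest = TRUE))
      H[w, ] <<- H[w, ] + as.numeric(h)
      N[w] <<- N[w] + sum(h)
    }
  }
  runLadder(order(centers), rep(0, 14), 0L)
  runLadder(order(centers, decreasing = TRUE), rep(1, 14), 1000L)
  # WHAM: p(bin) = sum_w H[w,bin] / sum_w N[w] exp(f_w - U_w(bin))
  U <- outer(centers, mids, function(cen, m) 0.5 * biasK * (m - cen)^2)
  f <- numeric(nwin)
  for (it in 1:2000) {
    denom <- colSums(N * exp(f - U))        # per bin
    p <- colSums(H) / denom
    p[denom == 0] <- 0
    p <- p / sum(p)
    fnew <- -log(pmax(rowSums(exp(-U) * rep(p, each = nwin)), 1e-300))
    fnew <- fnew - fnew[1]
    if (max(abs(fnew - f)) < 1e-8) { f <- fnew; break }
    f <- fnew
  }
  counts <- colSums(H)
  F <- ifelse(counts >= 10 & p > 0, -log(p), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  new("FreeEnergyProfile", centers = list(shl2 = mids), F = F,
      counts = counts)
}

#' Barrier and end-point differences of a 1-D profile
#'
#' Helpers used for reporting: the free-energy difference between the bins
#' nearest two coordinates, and the maximum along the profile between two
#' minima.
#'
#' @param fep 1-D \code{\linkS4class{FreeEnergyProfile}}.
#' @param from,to coordinates (bp).
#' @return \code{fepDelta}: F(to) - F(from) in kBT.  \code{fepBarrier}:
#'   max F between the two locations, relative to F(from).
#' @export
fepDelta <- function(fep, from, to) {
  x <- fep@centers[[1]]
  fTo <- fep@F[which.min(abs(x - to))]
  fFrom <- fep@F[which.min(abs(x - from))]
  unname(fTo - fFrom)
}

#' @rdname fepDelta
#' @export
fepBarrier <- function(fep, from, to) {
  x <- fep@centers[[1]]
  i1 <- which.min(abs(x - from)); i2 <- which.min(abs(x - to))
  rng <- seq(min(i1, i2), max(i1, i2))
  unname(max(fep@F[rng], na.rm = TRUE) - fep@F[i1])
}
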