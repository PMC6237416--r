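#' Canonical coordinate targets for a metastable-state label
#'
#' Inverse of \code{\link{labelFrame}} on the canonical configurations:
#' the state each label describes, as exact coordinate values (no noise).
#' Used by \code{\link{scriptedTrajectory}} to build label-true fixtures.
#'
#' @param label a label string ("o0", "cA0", ..., "cD2").
#' @return a \code{\link{systemState}} vector.
#' @examples
#' labelFrame(labelTargets("cC1"))   # "cC1"
#' @export
labelTargets <- function(label) {
  m <- regmatches(label, regexec("^([oc])([A-D]?)([0-2])$", label))[[1]]
  if (length(m) != 4 || (m[2] == "c" && m[3] == "") ||
      (m[2] == "o" && m[3] != ""))
    stop("not a valid state label: ", label)
  digit <- as.integer(m[4])
  x <- rep(0, 14)
  entry <- contactIndex(seq(-6.5, -1.5))   # dyad-distal (entry) contacts
  exit15 <- contactIndex(1.5)
  exit25 <- contactIndex(seq(2.5, 6.5))    # remodeler-to-exit contacts
  if (m[2] == "o") {
    # open states: o1/o2 have the exit side already advanced by one step;
    # a digit-2 open state additionally has a backward-slid entry side
    if (digit >= 1) { x[c(exit15, exit25)] <- 1; y1 <- 1; y2 <- 1 }
    else { y1 <- 0; y2 <- 0 }
    if (digit == 2) x[entry] <- -1
  } else {
    stage <- m[3]
    y1 <- if (stage == "A") 0.6 else 1
    y2 <- 0
    if (stage %in% c("C", "D")) x[exit15] <- 1
    if (stage == "D") x[exit25] <- 1
    # the digit counts +1bp defects near the dyad; realized by the
    # entry-side registration (a pre-existing defect at SHL -1 = entry -1)
    need_entry <- digit - (if (stage %in% c("C", "D")) 1L else 0L)
    if (stage == "D" && digit == 0) {
      x[] <- 1                             # fully slid, defect-free
      need_entry <- 0L
    }
    if (need_entry == 1L) x[entry] <- x[entry] - 1
    if (need_entry < 0L || need_entry > 1L)
      stop("label ", label, " has no canonical coordinate target")
  }
  systemState(x = x, y1 = y1, y2 = y2)
}

#' Scripted label-path trajectory
#'
#' Builds a synthetic trajectory that dwells at the canonical coordinates
#' of each scripted label for the given duration, plus i.i.d. Gaussian
#' noise.  With noise well below the labelling thresholds,
#' \code{\link{labelPath}} recovers the script exactly; targets that do not
#' reproduce their own label are rejected.
#'
#' @param labels character vector of state labels.
#' @param dwell dwell duration per label (time units; scalar or vector).
#' @param noise Gaussian noise s.d. (bp).
#' @param stride snapshot interval.
#' @param seed RNG seed.
#' @param targets optional list of explicit coordinate targets per label
#'   (defaults to \code{\link{labelTargets}}).
#' @return a \code{\linkS4class{Trajectory}} (chemical state annotated
#'   "ATP" for closed labels, "APO" otherwise).
#' @examples
#' tr <- scriptedTrajectory(c("o0", "cA0", "cB0", "cC1", "cD1", "o1", "o0"))
#' labelPath(tr)$label
#' @export
scriptedTrajectory <- function(labels, dwell = 2, noise = 0.05,
                               stride = 0.05, seed = 1L, targets = NULL) {
  stopifnot(length(labels) >= 1, all(dwell > 0))
  dwell <- rep_len(dwell, length(labels))
  if (is.null(targets)) targets <- lapply(labels, labelTargets)
  for (i in seq_along(labels)) {
    got <- labelFrame(targets[[i]])
    if (got != labels[i])
      stop("target for '", labels[i], "' labels as '", got, "'")
  }
  set.seed(as.integer(seed))
  nper <- pmax(1L, as.integer(round(dwell / stride)))
  coords <- do.call(rbind, lapply(seq_along(labels), function(i) {
    matrix(rep(targets[[i]], each = nper[i]), nrow = nper[i]) +
      matrix(rnorm(nper[i] * 16, sd = noise), nper[i])
  }))
  colnames(coords) <- coordNames()
  n <- nrow(coords)
  chem <- rep(ifelse(startsWith(labels, "c"), "ATP", "APO"), nper)
  new("Trajectory", times = seq_len(n) * stride, coords = coords,
      chem = chem, phaseBounds = numeric(0), final = coords[n, ],
      seed = as.integer(seed), paramsDigest = paramDigest(labels, dwell,
                                                          noise, seed),
      stride = stride)
}

#' Sample a discrete Markov chain with known transition matrix
#'
#' @param T_true row-stochastic transition matrix.
#' @param n chain length.
#' @param seed RNG seed.
#' @param start initial state index.
#' @return integer state series (a dtraj).
#' @examples
#' markovSampler(matrix(c(0.9, 0.2, 0.1, 0.8), 2), 100, seed = 1)
#' @export
markovSampler <- function(T_true, n, seed = 1L, start = 1L) {
  stopifnot(is.matrix(T_true), nrow(T_true) == ncol(T_true))
  if (any(T_true < 0) || any(abs(rowSums(T_true) - 1) > 1e-10))
    stop("T_true must be row-stochastic")
  set.seed(as.integer(seed))
  k <- nrow(T_true)
  cum <- t(apply(T_true, 1, cumsum))
  s <- integer(n)
  s[1] <- as.integer(start)
  u <- runif(n)
  for (i in 2:n) s[i] <- findInterval(u[i], cum[s[i - 1], ]) + 1L
  s
}

#' Exact i.i.d. samples from a 1-D Boltzmann distribution
#'
#' Inverse-CDF sampling of \code{p(x) proportional to exp(-U(x))} on a fine
#' quadrature grid; the potential must be normalizable on the given range.
#'
#' @param U vectorized potential function (kBT).
#' @param n number of samples.
#' @param seed RNG seed.
#' @param lower,upper support.
#' @param ngrid quadrature resolution.
#' @return numeric samples.
#' @examples
#' x <- toyWellSampler(function(x) 8 * x^2 / 2, 1000, seed = 1)
#' var(x)   # ~ 1/8
#' @export
toyWellSampler <- function(U, n, seed = 1L, lower = -5, upper = 5,
                           ngrid = 20001) {
  g <- seq(lower, upper, length.out = ngrid)
  w <- exp(-(U(g) - min(U(g))))
  boundary <- max(w[1], w[ngrid])
  if (!all(is.finite(w)) || sum(w) <= 0 ||
      boundary > 100 * stats::median(w))
    stop("potential not normalizable on [", lower, ", ", upper, "]")
  cdf <- cumsum(w); cdf <- cdf / cdf[length(cdf)]
  set.seed(as.integer(seed))
  u <- runif(n)
  # invert the CDF by interpolation on strictly increasing knots
  keep <- c(TRUE, diff(cdf) > 0)
  approx(cdf[keep], g[keep], xout = u, rule = 2)$y
}
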