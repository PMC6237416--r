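#' @title Free-energy profile over bins or states
#' @description Free energies (kBT, shifted so the minimum is 0) with the
#' underlying counts retained for error estimates; empty or under-sampled
#' bins are masked (NA), never imputed.
#' @slot centers list of bin-centre vectors (length 1 or 2) or state names.
#' @slot F numeric vector (1-D / states) or matrix (2-D).
#' @slot counts same shape as F.
#' @export
setClass("FreeEnergyProfile", representation(
  centers = "list", F = "ANY", counts = "ANY"))

setValidity("FreeEnergyProfile", function(object) {
  msg <- character()
  if (any(object@F < -1e-9, na.rm = TRUE)) msg <- c(msg, "F must be >= 0")
  if (!identical(dim(object@F), dim(object@counts)) ||
      length(object@F) != length(object@counts))
    msg <- c(msg, "F and counts must have the same shape")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FreeEnergyProfile", function(object) {
  cat("FreeEnergyProfile: ", length(object@F), " bins (",
      sum(!is.na(object@F)), " retained), range ",
      signif(max(object@F, na.rm = TRUE), 3), " kBT\n", sep = "")
})

#' Free-energy profile by Boltzmann inversion of a sample histogram
#'
#' \code{F = -ln p_hat - min} over retained bins.  Bins with fewer than
#' \code{minCount} samples are masked; counting errors on a retained bin
#' are ~1/sqrt(count) kBT.
#'
#' @param samples numeric vector (1-D) or 2-column matrix (2-D).
#' @param breaks bin-boundary vector, or list of two such vectors in 2-D.
#' @param minCount minimum samples for a bin to be retained.
#' @return a \code{\linkS4class{FreeEnergyProfile}}.
#' @examples
#' boltzmannInvert(rnorm(1e5), seq(-4, 4, 0.25))
#' @export
boltzmannInvert <- function(samples, breaks, minCount = 10) {
  if (is.matrix(samples) && ncol(samples) == 2) {
    stopifnot(is.list(breaks), length(breaks) == 2)
    cx <- cut(samples[, 1], breaks[[1]], include.lowest = TRUE)
    cy <- cut(samples[, 2], breaks[[2]], include.lowest = TRUE)
    counts <- table(cx, cy)
    counts <- matrix(as.integer(counts), nrow = nrow(counts))
    centers <- lapply(breaks, function(b) (head(b, -1) + tail(b, -1)) / 2)
  } else {
    samples <- as.numeric(samples)
    counts <- as.integer(table(cut(samples, breaks, include.lowest = TRUE)))
    centers <- list((head(breaks, -1) + tail(breaks, -1)) / 2)
  }
  if (sum(counts > 0) <= 1)
    warning("all samples fall in one bin: degenerate profile")
  f <- ifelse(counts >= minCount, -log(counts / sum(counts)), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  if (is.matrix(counts)) dim(f) <- dim(counts)
  new("FreeEnergyProfile", centers = centers, F = f, counts = counts)
}

#' Discretize a trajectory into an integer state series
#'
#' Either metastable-state labels (\code{\link{labelFrame}}) or cells of
#' the default 2-D landscape grid over the SHL 2 sliding coordinate and
#' the near-dyad defect count.  The series is split at chemical-state
#' switches so that downstream transition counts never bridge a potential
#' switch; frames outside the grid map to the boundary cell.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param states "label" or "grid2d".
#' @param closedOnly keep only closed-translocase frames (u >= 0.5),
#'   mirroring the closed-ensemble analyses.
#' @param ref registration passed to \code{\link{labelFrame}}.
#' @param grid list of two bin-boundary vectors for "grid2d".
#' @param coreDwell core-set assignment time (time units): a frame adopts a
#'   new state only once the raw label has persisted this long, otherwise it
#'   keeps the previous core state.  This suppresses spurious
#'   threshold-grazing transitions; 0 disables coring.
#' @return list: \code{dtrajs} (list of integer vectors, one per
#'   uninterrupted segment), \code{dict} (state name per integer code),
#'   \code{stride}.
#' @export
discretizeTrajectory <- function(traj, states = c("label", "grid2d"),
                                 closedOnly = FALSE, ref = systemState(),
                                 grid = landscapeGrid(), coreDwell = 0) {
  states <- match.arg(states)
  stopifnot(is(traj, "Trajectory"))
  if (!length(traj@times)) stop("empty trajectory")
  if (states == "label") {
    lab <- frameLabels(traj, ref)
  } else {
    cv <- shl2Coordinate(traj)
    ix <- pmin(pmax(findInterval(cv$shl2, grid[[1]], all.inside = TRUE), 1),
               length(grid[[1]]) - 1)
    iy <- pmin(pmax(findInterval(cv$dyad_defects, grid[[2]],
                                 all.inside = TRUE), 1),
               length(grid[[2]]) - 1)
    lab <- paste0(ix, ",", iy)
  }
  if (coreDwell > 0) {
    need <- max(1L, as.integer(round(coreDwell / traj@stride)))
    r <- rle(lab)
    core <- character(length(r$lengths))
    cur <- r$values[1]
    for (j in seq_along(r$lengths)) {
      if (r$lengths[j] >= need) cur <- r$values[j]
      core[j] <- cur
    }
    lab <- rep(core, r$lengths)
  }
  keep <- rep(TRUE, length(lab))
  if (closedOnly) {
    u <- traj@coords[, "y1"] - traj@coords[, "y2"]
    keep <- u >= 0.5
  }
  seg <- cumsum(c(TRUE, diff(match(traj@chem, unique(traj@chem))) != 0) |
                c(TRUE, diff(keep) != 0))
  dict <- sort(unique(lab[keep]))
  code <- match(lab, dict)
  dtrajs <- split(code[keep], seg[keep])
  dtrajs <- unname(dtrajs[lengths(dtrajs) > 0])
  list(dtrajs = dtrajs, dict = dict, stride = traj@stride)
}

#' Default 2-D landscape grid
#'
#' 0.1-bp bins over the SHL 2 sliding coordinate (x_1.5 + x_2.5)/2 in
#' [-0.5, 1.5] and the near-dyad defect count x_1.5 - x_-1.5 in
#' [-0.5, 2.5].
#' @return list of two bin-boundary vectors.
#' @export
landscapeGrid <- function() {
  list(shl2 = seq(-0.5, 1.5, by = 0.1),
       dyad_defects = seq(-0.5, 2.5, by = 0.1))
}

#' Lagged transition counts
#'
#' Sliding-window counts \code{C[i, j] = #(s(t) = i, s(t + lag) = j)}
#' accumulated within — never across — the supplied segments.
#'
#' @param dtrajs list of integer state series (or a single vector).
#' @param lag lag time (same units as \code{stride}).
#' @param stride time per frame; \code{lag} must be a multiple of it.
#' @param nstates number of states (defaults to the largest code seen).
#' @return integer count matrix.
#' @examples
#' countMatrix(c(1, 1, 2, 2), lag = 1)
#' @export
countMatrix <- function(dtrajs, lag, stride = 1, nstates = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  lf <- lag / stride
  if (abs(lf - round(lf)) > 1e-8)
    stop("lag must be a multiple of the snapshot stride")
  lf <- as.integer(round(lf))
  if (lf < 1) stop("lag must be at least one frame")
  if (is.null(nstates)) nstates <- max(unlist(dtrajs))
  C <- matrix(0L, nstates, nstates)
  npairs <- 0L
  for (d in dtrajs) {
    n <- length(d)
    if (n <= lf) next
    i <- d[1:(n - lf)]; j <- d[(1 + lf):n]
    t <- table(factor(i, levels = 1:nstates), factor(j, levels = 1:nstates))
    C <- C + matrix(as.integer(t), nstates)
    npairs <- npairs + (n - lf)
  }
  if (npairs == 0L) warning("lag >= segment length everywhere: empty counts")
  attr(C, "lag") <- lag
  C
}

#' @title Markov state model
#' @description Row-stochastic transition matrix estimated from lagged
#' counts, with stationary distribution.  With symmetrized counts the model
#' satisfies detailed balance by construction.
#' @slot states character state names.
#' @slot lag lag time.
#' @slot counts count matrix (after restriction to the active set).
#' @slot T row-stochastic transition matrix.
#' @slot pi stationary distribution.
#' @slot symmetrized logical.
#' @export
setClass("MarkovModel", representation(
  states = "character", lag = "numeric", counts = "matrix", T = "matrix",
  pi = "numeric", symmetrized = "logical"))

setValidity("MarkovModel", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@T) - 1) > 1e-12))
    msg <- c(msg, "rows of T must sum to 1 within 1e-12")
  if (any(object@pi < -1e-12) || abs(sum(object@pi) - 1) > 1e-10)
    msg <- c(msg, "pi must be a probability vector")
  if (object@symmetrized) {
    db <- object@pi * object@T - t(object@pi * object@T)
    if (max(abs(db)) > 1e-10)
      msg <- c(msg, "detailed balance violated beyond 1e-10")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MarkovModel", function(object) {
  cat("MarkovModel: ", length(object@states), " states, lag ", object@lag,
      if (object@symmetrized) ", reversible (symmetrized counts)", "\n",
      sep = "")
})

#' Estimate a Markov state model from transition counts
#'
#' States without any counts are dropped to the largest connected set
#' (reported via a message).  With \code{symmetrize = TRUE} the counts are
#' replaced by (C + t(C))/2 before row normalization, enforcing detailed
#' balance; the stationary distribution is then proportional to the
#' symmetrized row sums (equal to the leading left eigenvector).
#'
#' @param counts square count matrix (from \code{\link{countMatrix}}).
#' @param symmetrize enforce reversibility (default TRUE).
#' @param states optional state names.
#' @param lag lag time (defaults to the \code{lag} attribute of counts).
#' @return a \code{\linkS4class{MarkovModel}}.
#' @examples
#' transitionMatrix(matrix(c(9, 1, 1, 9), 2), states = c("a", "b"), lag = 1)
#' @export
transitionMatrix <- function(counts, symmetrize = TRUE, states = NULL,
                             lag = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (is.null(lag)) lag <- attr(counts, "lag")
  if (is.null(lag)) lag <- 1
  n <- nrow(counts)
  if (is.null(states)) states <- rownames(counts)
  if (is.null(states)) states <- as.character(seq_len(n))
  Cs <- if (symmetrize) (counts + t(counts)) / 2 else counts
  g <- igraph::graph_from_adjacency_matrix(
    (Cs > 0) * 1, mode = if (symmetrize) "undirected" else "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership)
  keepc <- which.max(sizes)
  keep <- which(comp$membership == keepc & rowSums(Cs) > 0)
  if (length(keep) < n)
    message("dropping ", n - length(keep),
            " state(s) outside the largest connected set: ",
            paste(states[setdiff(seq_len(n), keep)], collapse = ", "))
  if (length(keep) < 1) stop("no connected states with outgoing counts")
  Cs <- Cs[keep, keep, drop = FALSE]
  if (any(rowSums(Cs) == 0))
    stop("reducible retained chain; component sizes: ",
         paste(sizes, collapse = ", "))
  T <- Cs / rowSums(Cs)
  if (symmetrize) {
    pi <- rowSums(Cs) / sum(Cs)
  } else {
    ev <- eigen(t(T))
    i <- which.min(abs(ev$values - 1))
    pi <- Re(ev$vectors[, i])
    pi <- pi / sum(pi)
  }
  new("MarkovModel", states = states[keep], lag = as.numeric(lag),
      counts = Cs, T = T, pi = pi, symmetrized = symmetrize)
}

msmEigenvalues <- function(model) {
  # symmetrized models have real spectra; use the similarity transform
  if (model@symmetrized) {
    s <- sqrt(model@pi)
    A <- (s * model@T) %*% diag(1 / s, length(s))
    A <- (A + t(A)) / 2
    sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
         decreasing = TRUE)
  } else {
    ev <- sort(Mod(eigen(model@T, only.values = TRUE)$values),
               decreasing = TRUE)
    ev
  }
}

#' Implied relaxation timescales
#'
#' \code{t_i(lag) = -lag / ln(lambda_i)} for the leading non-unit
#' eigenvalues.  Given a fitted model, returns its timescales; given
#' discretized trajectories plus a vector of candidate lags, returns the
#' lag-dependence table used to pick a lag beyond which the timescales
#' plateau.  Eigenvalues <= 0 give undefined (masked) timescales.
#'
#' @param x a \code{\linkS4class{MarkovModel}} or a dtrajs list.
#' @param lags candidate lag times (dtrajs input only).
#' @param stride time per frame (dtrajs input only).
#' @param nTimescales how many timescales to report.
#' @param ... passed to \code{\link{transitionMatrix}}.
#' @return data.frame with columns \code{lag}, \code{rank},
#'   \code{timescale}.
#' @export
impliedTimescales <- function(x, lags = NULL, stride = 1, nTimescales = 4,
                              ...) {
  one <- function(model) {
    ev <- msmEigenvalues(model)[-1]
    ev <- ev[seq_len(min(nTimescales, length(ev)))]
    if (!length(ev)) {
      return(data.frame(lag = numeric(0), rank = integer(0),
                        timescale = numeric(0)))
    }
    ts <- ifelse(ev > 0 & ev < 1, -model@lag / log(ev), NA_real_)
    data.frame(lag = model@lag, rank = seq_along(ts) + 1, timescale = ts)
  }
  if (is(x, "MarkovModel")) return(one(x))
  stopifnot(!is.null(lags))
  do.call(rbind, lapply(lags, function(l) {
    one(transitionMatrix(countMatrix(x, l, stride), ...))
  }))
}

#' Mean first-passage times to a target state set
#'
#' Solves \code{(I - T_Q) m = lag * 1} over the non-target states Q, with
#' m = 0 on the targets.  States that cannot reach the target set get
#' infinite MFPT (flagged by a warning).
#'
#' @param model a \code{\linkS4class{MarkovModel}}.
#' @param targets state names or indices.
#' @return named numeric vector of MFPTs (time units), one per state.
#' @export
mfpt <- function(model, targets) {
  stopifnot(is(model, "MarkovModel"))
  if (is.character(targets)) {
    idx <- match(targets, model@states)
    if (anyNA(idx)) stop("unknown target state(s): ",
                         paste(targets[is.na(idx)], collapse = ", "))
  } else idx <- as.integer(targets)
  if (!length(idx)) stop("targets must be nonempty")
  n <- length(model@states)
  Q <- setdiff(seq_len(n), idx)
  m <- setNames(numeric(n), model@states)
  if (length(Q)) {
    TQ <- model@T[Q, Q, drop = FALSE]
    sol <- tryCatch(solve(diag(length(Q)) - TQ, rep(model@lag, length(Q))),
                    error = function(e) rep(Inf, length(Q)))
    if (any(!is.finite(sol)) || any(sol < 0)) {
      warning("some states cannot reach the target set; MFPT set to Inf")
      sol[!is.finite(sol) | sol < 0] <- Inf
    }
    m[Q] <- sol
  }
  m
}

#' Stationary free energies of the model states
#'
#' \code{F_i = -ln pi_i - min}, the state free energies implied by the
#' stationary distribution.
#'
#' @param model a \code{\linkS4class{MarkovModel}}.
#' @return a \code{\linkS4class{FreeEnergyProfile}} over the model states.
#' @export
stationaryFreeEnergy <- function(model) {
  stopifnot(is(model, "MarkovModel"))
  f <- -log(model@pi)
  f <- f - min(f)
  new("FreeEnergyProfile", centers = list(states = model@states), F = f,
      counts = rowSums(model@counts))
}

#' Minimum-energy path across a 2-D free-energy landscape
#'
#' 8-connected grid path from source to sink minimizing the maximum free
#' energy along the path (minimax / bottleneck criterion, Dijkstra on the
#' bottleneck metric); among minimax ties the path with the smallest summed
#' free energy is chosen, with a deterministic lexicographic cell-order
#' tie-break.  Masked (NA) cells are impassable.
#'
#' @param fep a 2-D \code{\linkS4class{FreeEnergyProfile}}.
#' @param source,sink cell indices \code{c(row, col)}.
#' @return list of class \code{PathResult}: \code{path} (matrix of cells),
#'   \code{profile} (free energy along the path), \code{bottleneck}.
#' @export
minEnergyPath <- function(fep, source, sink) {
  stopifnot(is(fep, "FreeEnergyProfile"), is.matrix(fep@F))
  F <- fep@F
  nr <- nrow(F); nc <- ncol(F)
  id <- function(rc) (rc[2] - 1L) * nr + rc[1]
  src <- id(source); snk <- id(sink)
  if (is.na(F[src]) || is.na(F[snk]))
    stop("source or sink is a masked cell")
  n <- nr * nc
  INF <- Inf
  best <- rep(INF, n)      # bottleneck value
  bsum <- rep(INF, n)      # summed F among bottleneck ties
  prev <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  best[src] <- F[src]; bsum[src] <- F[src]
  repeat {
    cand <- which(!done & is.finite(best))
    if (!length(cand)) break
    # deterministic selection: smallest (bottleneck, sum, index)
    o <- cand[order(best[cand], bsum[cand], cand)[1]]
    if (o == snk) break
    done[o] <- TRUE
    r <- (o - 1L) %% nr + 1L; cc <- (o - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      o2 <- (c2 - 1L) * nr + r2
      if (done[o2] || is.na(F[o2])) next
      nb <- max(best[o], F[o2])
      ns <- bsum[o] + F[o2]
      if (nb < best[o2] || (nb == best[o2] && ns < bsum[o2])) {
        best[o2] <- nb; bsum[o2] <- ns; prev[o2] <- o
      }
    }
  }
  if (!is.finite(best[snk]))
    stop("sink unreachable; reachable cells: ",
         sum(is.finite(best)), " of ", sum(!is.na(F)))
  cells <- snk
  while (cells[1] != src) cells <- c(prev[cells[1]], cells)
  path <- cbind(row = (cells - 1L) %% nr + 1L,
                col = (cells - 1L) %/% nr + 1L)
  structure(list(path = path, profile = F[cells], bottleneck = best[snk]),
            class = "PathResult")
}
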