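#' Twist-defect timeline of a trajectory
#'
#' The defect at integer SHL i is the difference of the flanking contact
#' indexes, \code{d_i = x[i + 0.5] - x[i - 0.5]} (bp): ~+1 for an extra
#' base pair, ~-1 for a missing one.  Summed over all 13 sites the defects
#' telescope exactly to \code{x_6.5 - x_-6.5}.
#'
#' @param traj a \code{\linkS4class{Trajectory}} (or bare coords matrix).
#' @return matrix (snapshots x 13) with columns \code{d_-6 ... d_6}.
#' @export
defectSeries <- function(traj) {
  co <- if (is(traj, "Trajectory")) traj@coords else traj
  d <- co[, 2:14, drop = FALSE] - co[, 1:13, drop = FALSE]
  colnames(d) <- paste0("d_", defectShls())
  d
}

#' Sliding and projection coordinates at the remodeler site
#'
#' Returns the mean contact index at SHL 2, \code{(x_1.5 + x_2.5)/2} — the
#' primary nucleosomal-DNA sliding coordinate — together with the 2-D
#' projection pair separating the metastable states: the summed contact
#' indexes around the binding site, \code{y1 + y2 + x_1.5 + x_2.5}, and the
#' near-dyad defect count, \code{x_1.5 - x_-1.5}.
#'
#' @inheritParams defectSeries
#' @return data.frame with columns \code{time} (if available), \code{shl2},
#'   \code{site_sum}, \code{dyad_defects}.
#' @export
shl2Coordinate <- function(traj) {
  co <- if (is(traj, "Trajectory")) traj@coords else traj
  i15 <- contactIndex(1.5); i25 <- contactIndex(2.5)
  im15 <- contactIndex(-1.5)
  out <- data.frame(
    shl2 = (co[, i15] + co[, i25]) / 2,
    site_sum = co[, 15] + co[, 16] + co[, i15] + co[, i25],
    dyad_defects = co[, i15] - co[, im15])
  if (is(traj, "Trajectory")) out <- cbind(time = traj@times, out)
  out
}

#' Metastable-state label of one snapshot
#'
#' Grammar: first letter o/c for open/closed translocase (closed when
#' u = y1 - y2 >= 0.5); among closed frames a stage letter for the
#' configuration at the SHL 2 binding site — A partial lobe-1 motion
#' (0.3 <= lobe-1 advance < 0.8), B completed lobe-1 motion, C DNA slid at
#' contact 1.5, D DNA slid at contact 2.5 — and a final digit 0/1/2
#' counting the +1 bp defects near the dyad,
#' \code{clamp(round(x_1.5 - x_-1.5), 0, 2)}.  Advances are measured
#' against the cycle-start registration \code{ref}.
#'
#' @param state numeric(16).
#' @param ref reference registration (default: the zero registration).
#' @return a label string such as "o0", "cB0", "cD1".
#' @examples
#' labelFrame(systemState())                    # "o0"
#' labelFrame(systemState(y1 = 0.6))            # "cA0"
#' @export
labelFrame <- function(state, ref = systemState()) {
  s <- asState(state); r <- asState(ref)
  i15 <- contactIndex(1.5); i25 <- contactIndex(2.5)
  im15 <- contactIndex(-1.5)
  digit <- min(max(round(s[i15] - s[im15]), 0), 2)
  u <- s[15] - s[16]
  if (u < 0.5) return(paste0("o", digit))
  y1adv <- s[15] - r[15]
  x15adv <- s[i15] - r[i15]
  x25adv <- s[i25] - r[i25]
  letter <- if (x25adv >= 0.5) "D" else if (x15adv >= 0.5) "C"
            else if (y1adv >= 0.8) "B" else "A"
  paste0("c", letter, digit)
}

frameLabels <- function(traj, ref = systemState()) {
  co <- traj@coords
  vapply(seq_len(nrow(co)), function(i) labelFrame(co[i, ], ref),
         character(1))
}

#' Debounced label path of a trajectory
#'
#' Frame labels are debounced — a label must persist for at least
#' \code{dwell_min} before it counts — and then run-length condensed, so
#' flickers across a threshold do not register as transitions.
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param dwell_min minimum dwell (time units).
#' @param ref cycle-start registration.
#' @return data.frame with columns \code{label}, \code{entry} (time),
#'   \code{dwell} (duration).
#' @export
labelPath <- function(traj, dwell_min = 0.25, ref = systemState()) {
  stopifnot(is(traj, "Trajectory"), dwell_min >= 0)
  lab <- frameLabels(traj, ref)
  t <- traj@times
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  entry <- t[starts]
  dwell <- t[ends] - t[starts] + traj@stride
  keep <- dwell >= dwell_min
  lab2 <- r$values[keep]; entry2 <- entry[keep]; dwell2 <- dwell[keep]
  if (!length(lab2))  # everything flickered: keep the longest-dwelled run
    return(data.frame(label = r$values[which.max(dwell)],
                      entry = entry[which.max(dwell)],
                      dwell = max(dwell)))
  # merge consecutive identical survivors
  keep2 <- c(TRUE, lab2[-1] != head(lab2, -1))
  grp <- cumsum(keep2)
  data.frame(label = lab2[keep2],
             entry = entry2[keep2],
             dwell = as.numeric(tapply(dwell2, grp, sum)))
}

#' Repositioning outcome of one ATP cycle
#'
#' \code{dna_step}: nearest integer to the final mean contact index at
#' SHL 2; \code{lobe_step}: nearest integer to the final mean lobe index
#' (y1 + y2)/2 — both computed from the final state only, hence invariant
#' to snapshot stride.  \code{dna_step_atp} evaluates the DNA step at the
#' end of the ATP phase instead (both time points are used in reporting).
#'
#' @param traj a \code{\linkS4class{Trajectory}} covering a full cycle.
#' @return named numeric: \code{dna_step}, \code{lobe_step},
#'   \code{dna_step_atp} (NA when the trajectory has no ATP phase).
#' @export
cycleOutcome <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  fin <- traj@final
  i15 <- contactIndex(1.5); i25 <- contactIndex(2.5)
  dna <- round((fin[i15] + fin[i25]) / 2)
  lobe <- round((fin["y1"] + fin["y2"]) / 2)
  atp <- NA_real_
  iatp <- which(traj@chem == "ATP")
  if (length(iatp)) {
    last <- traj@coords[max(iatp), ]
    atp <- round((last[i15] + last[i25]) / 2)
  }
  c(dna_step = unname(dna), lobe_step = unname(lobe),
    dna_step_atp = unname(atp))
}

#' Translocase closure event within a cycle
#'
#' Detects the first time u = y1 - y2 exceeds \code{threshold} during the
#' ATP phase and classifies the closure by which lobe's registration moved
#' by ~1 bp at that moment (lobe 1 forward in the canonical inchworm;
#' lobe 2 backward when its grip is weakened).
#'
#' @param traj a \code{\linkS4class{Trajectory}}.
#' @param threshold closure level on u (bp).
#' @return list: \code{closed_before_adp} (logical), \code{time},
#'   \code{lobe} ("L1"/"L2"/NA).
#' @export
closureEvent <- function(traj, threshold = 0.8) {
  stopifnot(is(traj, "Trajectory"))
  u <- traj@coords[, "y1"] - traj@coords[, "y2"]
  inATP <- traj@chem == "ATP"
  hit <- which(u >= threshold & inATP)
  if (!length(hit)) {
    return(list(closed_before_adp = FALSE, time = NA_real_,
                lobe = NA_character_))
  }
  i <- hit[1]
  y0 <- traj@coords[1, c("y1", "y2")]
  dy <- traj@coords[i, c("y1", "y2")] - y0
  # closure advances u by ~1: either lobe 1 forward or lobe 2 backward
  list(closed_before_adp = TRUE, time = traj@times[i],
       lobe = if (dy[1] >= -dy[2]) "L1" else "L2")
}

#' Outcome probabilities with Wilson 95\% confidence intervals
#'
#' @param outcomes integer vector of per-cycle outcomes (e.g. DNA steps).
#' @return data.frame with one row per distinct outcome: \code{outcome},
#'   \code{count}, \code{p}, \code{lower}, \code{upper} (Wilson interval).
#' @examples
#' ensembleProbability(c(rep(1, 98), rep(0, 2)))
#' @export
ensembleProbability <- function(outcomes) {
  outcomes <- outcomes[!is.na(outcomes)]
  stopifnot(length(outcomes) >= 1)
  n <- length(outcomes)
  tab <- table(outcomes)
  z <- qnorm(0.975)
  p <- as.numeric(tab) / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  data.frame(outcome = as.numeric(names(tab)), count = as.integer(tab),
             p = p, lower = pmax(0, centre - half),
             upper = pmin(1, centre + half))
}
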