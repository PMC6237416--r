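#' Chemical-state schedule of the ATP cycle
#'
#' One reduced time unit corresponds to 1e5 steps of the underlying
#' residue-level dynamics this model coarse-grains (a declared mapping
#' constant).  The default cycle is 200 units of apo-state equilibration,
#' 100 units ATP-bound and 100 units ADP-bound; the short-hydrolysis
#' variant cuts the ATP phase to one tenth.  The final switch back to apo
#' only relabels the interactions, so it adds no phase.
#'
#' @param chem character vector of states ("APO", "ATP", "ADP").
#' @param duration numeric vector of phase durations (time units), > 0.
#' @return a data.frame with columns \code{chem}, \code{duration}.
#' @examples
#' defaultSchedule()
#' defaultSchedule(short = TRUE)
#' @export
schedule <- function(chem, duration) {
  chem <- match.arg(chem, c("APO", "ATP", "ADP"), several.ok = TRUE)
  stopifnot(length(chem) == length(duration), all(duration > 0))
  data.frame(chem = chem, duration = as.numeric(duration))
}

#' @rdname schedule
#' @param short use the short-hydrolysis variant (ATP phase 10 units).
#' @export
defaultSchedule <- function(short = FALSE) {
  schedule(c("APO", "ATP", "ADP"), c(200, if (short) 10 else 100, 100))
}

#' Integrator configuration
#'
#' Overdamped Euler-Maruyama settings.  The defaults (dt = 5e-4 time units,
#' unit diffusion coefficients) keep the update stable under the steep
#' steric wall while resolving the grip and contact wells.
#'
#' @param dt time step (time units).
#' @param D_dna,D_lobe diffusion coefficients of the DNA contact and lobe
#'   coordinates (bp^2 / time unit).
#' @param stride snapshot interval (time units; must be a multiple of dt).
#' @return a list of class \code{IntegratorConfig}.
#' @export
integratorConfig <- function(dt = 5e-4, D_dna = 1, D_lobe = 1, stride = 0.05) {
  stopifnot(dt > 0, D_dna > 0, D_lobe > 0, stride >= dt)
  sf <- stride / dt
  if (abs(sf - round(sf)) > 1e-8) stop("stride must be a multiple of dt")
  structure(list(dt = dt, D_dna = D_dna, D_lobe = D_lobe, stride = stride),
            class = "IntegratorConfig")
}

#' @title Simulated trajectory of the reduced system
#' @description Time-stamped snapshots of the 16 coordinates with the
#' active chemical state per snapshot.  Metadata (seed, parameter digest,
#' phase boundaries) suffice to reproduce the trajectory bit-exactly.
#' @slot times numeric: snapshot times (time units), strictly increasing.
#' @slot coords matrix (snapshots x 16), columns named as
#'   \code{x_-6.5 ... x_6.5, y1, y2}.
#' @slot chem character: chemical state per snapshot.
#' @slot phaseBounds numeric: times of the potential switches.
#' @slot final numeric(16): exact final state.
#' @slot seed integer RNG seed.
#' @slot paramsDigest character: digest of all model parameters.
#' @slot stride numeric snapshot interval.
#' @export
setClass("Trajectory", representation(
  times = "numeric", coords = "matrix", chem = "character",
  phaseBounds = "numeric", final = "numeric", seed = "integer",
  paramsDigest = "character", stride = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  if (ncol(object@coords) != 16) msg <- c(msg, "coords must have 16 columns")
  if (nrow(object@coords) != length(object@times))
    msg <- c(msg, "times/coords length mismatch")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@chem) != length(object@times))
    msg <- c(msg, "chem must annotate every snapshot")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory: ", length(object@times), " snapshots over ",
      signif(max(object@times), 4), " time units (stride ", object@stride,
      "), phases: ", paste(rle(object@chem)$values, collapse = " -> "),
      ", seed ", object@seed, "\n", sep = "")
})

# short content digest (FNV-1a over the serialized object)
paramDigest <- function(...) {
  raw <- serialize(list(...), NULL, version = 2)
  h <- 5381
  for (b in as.integer(raw)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

modeTerms <- function(ps, mode) {
  switch(mode,
    nucleosome  = ps,
    naked       = setTerms(ps, octamer = FALSE, wall = FALSE, elec = FALSE,
                           freeze_dna = TRUE),
    spontaneous = setTerms(ps, remodeler = FALSE, wall = FALSE, elec = FALSE,
                           freeze_lobes = TRUE),
    stop("unknown mode: ", mode))
}

#' One Euler-Maruyama step
#'
#' \code{q <- q - dE/dq * D * dt + sqrt(2 * D * dt) * xi} per coordinate,
#' with standard-normal xi; DNA coordinates use \code{D_dna}, lobes
#' \code{D_lobe}.  Exposed mainly for testing; production runs use the
#' compiled propagator inside \code{\link{runSchedule}}.
#'
#' @param state numeric(16).
#' @param ps a \code{\linkS4class{ParameterSet}}.
#' @param cfg an \code{\link{integratorConfig}}.
#' @param noise disable to obtain the deterministic drift part.
#' @return the updated state.
#' @export
stepState <- function(state, ps, cfg = integratorConfig(), noise = TRUE) {
  s <- asState(state)
  g <- cpp_gradient(s, asPhaseList(ps))
  D <- rep(c(cfg$D_dna, cfg$D_lobe), c(14, 2))
  D[c(rep(ps@terms["freeze_dna"], 14), rep(ps@terms["freeze_lobes"], 2))] <- 0
  s2 <- s - g * D * cfg$dt
  if (noise) s2 <- s2 + sqrt(2 * D * cfg$dt) * rnorm(16)
  if (!all(is.finite(s2)))
    stop("non-finite state after step; state dump: ",
         paste(signif(s, 6), collapse = " "))
  setNames(s2, coordNames())
}

#' Simulate the system under a chemical-state schedule
#'
#' Propagates the state by overdamped Langevin dynamics, switching the
#' potential instantaneously (no mixing ramp) at each phase boundary via
#' \code{\link{effectiveParams}}.  Snapshots are recorded at the configured
#' stride; identical seed and configuration reproduce the trajectory
#' bit-exactly.
#'
#' @param s0 initial state (\code{\link{systemState}}).
#' @param sched a \code{\link{schedule}}.
#' @param base \code{\linkS4class{RemodelerParams}}.
#' @param seq \code{\linkS4class{SequenceProfile}}.
#' @param cfg \code{\link{integratorConfig}}.
#' @param seed RNG seed for this trajectory.
#' @param mode "nucleosome" (all terms), "naked" (lobes only: grip wells and
#'   coupling, DNA frozen), or "spontaneous" (octamer terms only, lobes
#'   frozen: no remodeler).
#' @param clampLobes freeze y1, y2 at their initial values (used for
#'   closed-ensemble equilibrium sampling).
#' @param bias optional \code{c(k, center)} harmonic umbrella restraint on
#'   the SHL 2 sliding coordinate (x_1.5 + x_2.5)/2.
#' @return a \code{\linkS4class{Trajectory}}.
#' @examples
#' sp <- profileFromSequence(buildSequence("polyApG"))
#' tr <- runSchedule(systemState(), schedule("APO", 2),
#'                   defaultRemodelerParams(), sp, seed = 1)
#' tr
#' @export
runSchedule <- function(s0 = systemState(), sched = defaultSchedule(),
                        base = defaultRemodelerParams(),
                        seq = profileFromSequence(buildSequence("polyApG")),
                        cfg = integratorConfig(), seed = 1L,
                        mode = "nucleosome", clampLobes = FALSE,
                        bias = NULL) {
  stopifnot(nrow(sched) >= 1)
  phases <- lapply(seq_len(nrow(sched)), function(i) {
    ps <- modeTerms(effectiveParams(base, seq, sched$chem[i]), mode)
    if (clampLobes) ps <- setTerms(ps, freeze_lobes = TRUE)
    asPhaseList(ps)
  })
  psteps <- round(sched$duration / cfg$dt)
  stride <- round(cfg$stride / cfg$dt)
  g0 <- cpp_gradient(asState(s0), phases[[1]])
  if (max(abs(g0)) * max(cfg$D_dna, cfg$D_lobe) * cfg$dt > 0.2)
    warning("initial |force|*D*dt exceeds 0.2 bp; decrease dt")
  seed <- as.integer(seed)
  set.seed(seed)
  res <- cpp_simulate(asState(s0), phases, as.integer(psteps), cfg$dt,
                      cfg$D_dna, cfg$D_lobe, as.integer(stride),
                      noise = TRUE,
                      bias_k = if (is.null(bias)) 0 else bias[1],
                      bias_c = if (is.null(bias)) 0 else bias[2])
  coords <- res$coords
  colnames(coords) <- coordNames()
  new("Trajectory",
      times = res$time, coords = coords, chem = sched$chem[res$phase],
      phaseBounds = cumsum(sched$duration)[-nrow(sched)],
      final = setNames(res$final, coordNames()), seed = seed,
      paramsDigest = paramDigest(base, seq, sched, cfg, mode, clampLobes,
                                 bias),
      stride = cfg$stride)
}

#' Simulate the translocase on naked DNA
#'
#' Only the lobe coordinates evolve, under grip wells and the lobe-lobe
#' coupling (no octamer, steric wall or electrostatic spring).  The cycle
#' outcome is the net change of the mean lobe index (y1 + y2)/2.
#'
#' @inheritParams runSchedule
#' @return a \code{\linkS4class{Trajectory}}.
#' @export
runNaked <- function(sched = defaultSchedule(),
                     base = defaultRemodelerParams(),
                     seq = profileFromSequence(buildSequence("polyApG")),
                     cfg = integratorConfig(), seed = 1L) {
  runSchedule(systemState(), sched, base, seq, cfg, seed, mode = "naked")
}

#' Run an ensemble of ATP cycles
#'
#' Trajectories use seeds \code{seed0, seed0 + 1, ...}, each with its own
#' generator state, so disjoint seed ranges yield disjoint, mergeable
#' summaries.  Per-trajectory failures are recorded (NA row) rather than
#' fatal.
#'
#' @param n number of cycles.
#' @param seed0 first seed.
#' @param keepTrajectories also return the full trajectories (memory!).
#' @param closureThreshold u = y1 - y2 level defining translocase closure.
#' @inheritParams runSchedule
#' @return list with \code{summary} (data.frame: seed, dna_step, lobe_step,
#'   dna_step_atp, closed_before_adp, closure_time, closure_lobe,
#'   label_path) and, optionally, \code{trajectories}.
#' @export
runEnsemble <- function(n, seed0 = 1L, sched = defaultSchedule(),
                        base = defaultRemodelerParams(),
                        seq = profileFromSequence(buildSequence("polyApG")),
                        cfg = integratorConfig(), mode = "nucleosome",
                        keepTrajectories = FALSE, closureThreshold = 0.8) {
  stopifnot(n >= 1)
  seeds <- seed0 + seq_len(n) - 1L
  rows <- vector("list", n)
  trajs <- if (keepTrajectories) vector("list", n) else NULL
  for (i in seq_len(n)) {
    row <- tryCatch({
      tr <- if (mode == "naked") {
        runNaked(sched, base, seq, cfg, seed = seeds[i])
      } else {
        runSchedule(systemState(), sched, base, seq, cfg, seed = seeds[i],
                    mode = mode)
      }
      if (keepTrajectories) trajs[[i]] <- tr
      out <- cycleOutcome(tr)
      cl <- closureEvent(tr, threshold = closureThreshold)
      lp <- labelPath(tr)
      data.frame(seed = seeds[i], dna_step = out["dna_step"],
                 lobe_step = out["lobe_step"],
                 dna_step_atp = out["dna_step_atp"],
                 closed_before_adp = cl$closed_before_adp,
                 closure_time = cl$time, closure_lobe = cl$lobe,
                 label_path = paste(lp$label, collapse = ">"),
                 row.names = NULL)
    }, error = function(e) {
      warning("cycle with seed ", seeds[i], " failed: ", conditionMessage(e))
      data.frame(seed = seeds[i], dna_step = NA_real_, lobe_step = NA_real_,
                 dna_step_atp = NA_real_, closed_before_adp = NA,
                 closure_time = NA_real_, closure_lobe = NA_character_,
                 label_path = NA_character_, row.names = NULL)
    })
    rows[[i]] <- row
  }
  out <- list(summary = do.call(rbind, rows))
  if (keepTrajectories) out$trajectories <- trajs
  out
}
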