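#!/usr/bin/env Rscript
# One-time calibration procedure behind the shipped defaults.
#
# The reduced model cannot inherit its constants from the residue-level
# energetics it coarse-grains, so the free parameters were tuned, in the
# order below, until the headline observables matched their intended
# values; the resulting numbers are frozen in defaultRemodelerParams() and
# defaultMappingRules().  Re-running this script re-measures every
# observable under the current defaults (plus any overrides given as
# name=value arguments) and prints them next to their calibration targets,
# so the procedure is reproducible and auditable.
#
#   Rscript scripts/calibrate.R [seed] [name=value ...]
#
# Calibration order (each step has a dominant knob):
#   1. contact depth + twist k, mu        -> spontaneous barrier ~6 kBT
#      (umbrella + WHAM route: unbiased crossings are too rare to measure
#      the barrier directly, so all profile observables use the biased-
#      then-unbiased estimate)
#   2. epsElec, elecWidth                 -> closed-state drop F(0)-F(1) ~4
#   3. tilt601                            -> mutant 601 sliding cost ~3
#   4. couplingBarrier (+ strain)         -> closure rate: ~64% close
#                                            within a 10-unit ATP phase
#   5. gripScale[2] (vs strain)           -> lobe-2 closures rare on
#                                            polyApG; g2TpA -> ~28% with
#                                            the TpA element at SHL 2
#   6. adpRelease, gripScale[1]           -> naked-DNA stepping ~0.45 and
#                                            fast forward opening on the
#                                            nucleosome
#   7. wallHeight/halfwidth               -> step retention through the
#                                            ADP phase (nucleosome ~0.98)
#   8. dMuPlusApA, dMuMinusTpA, kMultTpA  -> closed-ensemble MFPT ratios
#                                            ~2.4 (ApA@SHL1), ~1.3
#                                            (TpA@SHL2)
#
# Structural defect-propensity profile (structDefectProfile) is part of
# step 1: it pins the productive defect pair to SHLs 1/2 and sets the
# end-entry defect cost that the spontaneous barrier measures.

suppressPackageStartupMessages(library(twistslide))

args <- commandArgs(trailingOnly = TRUE)
seed <- 1L
over <- list()
for (a in args) {
  if (grepl("=", a)) {
    kv <- strsplit(a, "=")[[1]]
    over[[kv[1]]] <- as.numeric(strsplit(kv[2], ",")[[1]])
  } else seed <- as.integer(a)
}
base <- do.call(defaultRemodelerParams, over)
rules <- defaultMappingRules()
sp <- profileFromSequence(buildSequence("polyApG"), rules)
s0 <- seed * 1000L
line <- function(name, value, target) {
  cat(sprintf("%-42s %8.3f   (target %s)\n", name, value, target))
}

# -- profiles ---------------------------------------------------------------
f7 <- umbrellaProfile(base, sp, chem = "APO", mode = "spontaneous",
                      y0 = c(0, 0), seed = s0 + 1L)
line("spontaneous sliding barrier [kBT]", fepBarrier(f7, 0, 1), "~6")
f8 <- umbrellaProfile(base, sp, chem = "ATP", clampLobes = TRUE,
                      y0 = c(1, 0), seed = s0 + 2L)
line("ATP closed drop F(0)-F(1) [kBT]", -fepDelta(f8, 0, 1), "~4")
sp601 <- profileFromSequence(buildSequence("601"), rules)
f9 <- umbrellaProfile(defaultRemodelerParams(epsElec = 0), sp601,
                      chem = "ATP", clampLobes = TRUE, y0 = c(1, 0),
                      seed = s0 + 3L)
line("mutant 601 cost F(1)-F(0) [kBT]", fepDelta(f9, 0, 1), "~3")

# -- cycle statistics -------------------------------------------------------
e1 <- runEnsemble(60, seed0 = s0 + 10L, base = base, seq = sp)
line("nucleosome stepping P(+1)", mean(e1$summary$lobe_step == 1,
                                       na.rm = TRUE), "~0.98")
line("  lobe-2 closure fraction (polyApG)",
     mean(e1$summary$closure_lobe == "L2", na.rm = TRUE), "~0")
e2 <- runEnsemble(40, seed0 = s0 + 110L, base = base, seq = sp,
                  mode = "naked")
line("naked stepping P(+1)", mean(e2$summary$lobe_step == 1, na.rm = TRUE),
     "~0.45")
e3 <- runEnsemble(60, seed0 = s0 + 160L, base = base, seq = sp,
                  sched = defaultSchedule(short = TRUE))
closed <- e3$summary$closed_before_adp %in% TRUE
line("short-ATP closure fraction", mean(closed), "~0.64")
line("short-ATP completion | closed",
     mean(e3$summary$dna_step[closed] == 1, na.rm = TRUE), "~0.36")
spT <- profileFromSequence(buildSequence("polyApG", element = "TpA",
                                         shl = 2), rules)
eT <- runEnsemble(60, seed0 = s0 + 230L, base = base, seq = spT)
line("lobe-2 closure fraction (TpA@SHL2)",
     mean(eT$summary$closure_lobe == "L2", na.rm = TRUE), "~0.28")

# -- MSM sequence kinetics --------------------------------------------------
closedMfpt <- function(sqp, sd) {
  starts <- list(labelTargets("cB1"), labelTargets("cD1"))
  parts <- lapply(1:24, function(i) {
    tr <- runSchedule(starts[[1 + (i %% 2)]], schedule("ATP", 250), base,
                      sqp, seed = sd + i, clampLobes = TRUE)
    discretizeTrajectory(tr, "label", closedOnly = TRUE, coreDwell = 0.25)
  })
  dict <- sort(unique(unlist(lapply(parts, `[[`, "dict"))))
  dtrajs <- unlist(lapply(parts, function(d)
    lapply(d$dtrajs, function(v) match(d$dict[v], dict))),
    recursive = FALSE)
  C <- countMatrix(dtrajs, lag = 2.5, stride = 0.05, nstates = length(dict))
  rownames(C) <- colnames(C) <- dict
  unname(mfpt(suppressMessages(transitionMatrix(C, lag = 2.5)),
              "cD1")["cB1"])
}
mP <- closedMfpt(sp, s0 + 300L)
spA <- profileFromSequence(buildSequence("polyApG", element = "ApA",
                                         shl = 1), rules)
line("MFPT ratio ApA@SHL1 / polyApG", closedMfpt(spA, s0 + 400L) / mP,
     "~2.4")
line("MFPT ratio TpA@SHL2 / polyApG", closedMfpt(spT, s0 + 500L) / mP,
     "~1.3")
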