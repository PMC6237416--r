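---
title: "A reduced ratchet model of ATP-driven nucleosome sliding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced ratchet model of ATP-driven nucleosome sliding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twistslide)
```

## The system and its reduction

Snf2-family chromatin remodelers reposition nucleosomes by walking their
two-lobe ATPase (translocase) domain along nucleosomal DNA from its binding
site at superhelical location (SHL) +2 toward the dyad.  `twistslide`
models this machine with 16 reduced coordinates:

* **14 contact indexes** `x_i` — how many base pairs the DNA has slid, at
  each of the strong histone–DNA contact points (the half-integer SHLs
  −6.5 … +6.5), relative to a reference registration;
* **2 lobe registrations** `y1`, `y2` — the base-pair positions of the two
  ATPase lobes on the DNA.

Differences of adjacent contact indexes are **twist defects**:
`d_i = x[i+0.5] − x[i−0.5]` is ≈ +1 when an extra base pair is stored
between the contacts flanking integer SHL `i`, ≈ −1 when one is missing.
All energies are in units of kBT (kBT = 1), lengths in bp, and one reduced
time unit stands for 1e5 steps of the residue-level dynamics this model
coarse-grains (a declared convention, not a measured mapping).

## The potential

`totalEnergy()` is a sum of seven closed-form terms
(`effectiveParams()` resolves the numbers for one chemical state):

1. **Contact wells** `depth · (1 − cos 2πx)/2` per contact: the 1-bp
   periodicity of the histone-DNA interface.  Default depth 2.8 kBT.
2. **Positioning tilt** `tilt · x` at contacts +1.5 and +2.5 only, used for
   the 601-like construct started 3 bp off its optimal register
   (total 2.4 kBT/bp, split over the two contacts).
3. **Twist-defect energies**: at each integer SHL a three-well function of
   `d` with minima at −1, 0, +1 of energies `mu_minus`, 0, `mu_plus` and
   stiffness `k` (default 15 kBT/bp²), joined by a softmin (log-sum-exp at
   0.2 kBT) of the three shifted harmonics, so the gradient is continuous.
   Sequence-derived penalties (default 5.4 kBT) are augmented by a
   *structural* propensity profile (`structDefectProfile()`): extra base
   pairs are resisted at the dyad and at |SHL| = 2 (+3 kBT) and mildly in
   the outer turns (+2 kBT), but not at SHL ±1; missing base pairs are
   resisted at |SHL| = 1 (+3 kBT).  This concentrates defects where
   nucleosome structures accommodate them: extra base pairs at SHL ±1,
   missing base pairs at SHL ±2.  On top of this, the *closed* translocase
   stabilizes its productive defect pair (`defectStab`, 2.8 kBT, gated by
   a logistic in u): the +1 bp penalty at SHL +1 and the −1 bp penalty at
   SHL +2 drop while the machine is closed, so the active machine creates
   defects that remain expensive for the bare nucleosome.  Because the
   stabilization follows the conformation rather than the nucleotide,
   defects present at the moment of hydrolysis are not suddenly stranded.
4. **Lobe grip wells** `G_k (1 − cos 2πy_k)/2`.  The per-contact strengths
   are the chemically switched quantities (1.8 kBT per contact in the apo
   state; lobe 2 weakened ×0.8 after hydrolysis); each lobe binds through
   many contacts, so the well depth is `1.8 · gripScale` with
   cooperativity factors 4.15 and 7.2 for lobes 1 and 2.  Lobe 1 is the
   weakly bound lobe, as in the inchworm picture.
5. **Lobe–lobe coupling**: a quartic double well in `u = y1 − y2` with
   minima at `u = 0` (open) and `u = 1` (closed), barrier 4.2 kBT, plus a
   linear offset mapped affinely from the coupling strengths
   (0.17 kBT apo/ADP, 1.0 kBT ATP), so ATP biases the closed form and
   apo/ADP the open form.
6. **Steric wall** `wallHeight · max(0, |ρ| − halfwidth)²` on the body
   coordinate `ρ = (x_1.5 + x_2.5)/2 − (y1 + y2)/2`: the remodeler body
   cannot move relative to the DNA at its binding site beyond ~0.35 bp
   without steric strain (height 120 kBT/bp²).  This is what blocks
   sliding in the open state in either direction and forces the opening
   step after successful sliding to proceed by the lobe-2 forward motion.
7. **Electrostatic spring** `−epsElec · exp(−r1²/2w²)` with
   `r1 = (x_1.5 + x_2.5)/2 − y1`: the attraction between the lobe-1 basic
   patch and the DNA gyre at SHL −6 (depth 4.55 kBT, range 0.42 bp).
   Setting `epsElec = 0` emulates the charge-reversal mutant.

Two register-switched destabilization terms implement the
conformational-change kinetics:

* **ATP strain** (9.0 kBT): while lobe 1 is still at its pre-closure
  register (a logistic switch of width 0.1 bp around a half step), its
  grip well is flattened — the destabilized lobe-1/DNA interface that
  makes closure proceed by lobe-1 motion.  Once closed, lobe 1 re-grips.
* **ADP release** (8.4 kBT): the same construction on lobe 2's pre-opening
  register, the kinetic face of the 0.8 weakening, which lets opening
  proceed by the lobe-2 forward step.

## The ATP cycle and what makes it a ratchet

`runSchedule()` switches the parameter set instantaneously along
apo (200) → ATP (100) → ADP (100 time units) while propagating all
coordinates by overdamped Euler–Maruyama dynamics (`dt = 5e-4`, unit
diffusion coefficients; the compiled kernel keeps 100 cycles of 8e5 steps
each within a couple of minutes).  The final switch back to apo changes
interactions only, so it adds no phase.  The cycle works as follows:

* apo: a single free-energy minimum — the wall blocks sliding toward the
  dyad (body clash) and away from it (gyre clash), and the spring holds
  lobe 1 at its registration.
* ATP: the coupling drives closure; the strained lobe-1 interface makes
  lobe 1 (not lobe 2) step forward.  Closure stretches the electrostatic
  spring (`r1 = −1`), and the spring tension plus the steric wall then
  pull the DNA at SHL 2 toward the dyad: a +1 bp defect forms at SHL 1
  and a −1 bp defect at SHL 2, the −1 defect is released through the
  exit-side contacts, and the system reaches the slid closed state with
  the spring relaxed again.
* ADP: the closed form is destabilized; with the DNA slid, the wall
  forbids lobe 1 from stepping back (it would stretch the spring and
  clash), so opening proceeds by the lobe-2 forward step and the cycle
  ends one base pair ahead.  If the DNA failed to slide, the same wall
  forbids the lobe-2 step and the translocase simply drops back — an
  unproductive cycle, the dominant failure mode when hydrolysis comes too
  early.

## Calibration and what the defaults mean

The residue-level simulations this model reduces cannot be rerun here, so
all depths, stiffnesses and rates above are *calibration products*: a
documented one-time procedure (`scripts/calibrate.R`) tuned them so that
the reduced model reproduces the printed headline behaviour — stepping
probabilities on nucleosomal and naked DNA, closure and completion
statistics under a shortened ATP phase, spontaneous and remodeler-modified
sliding free-energy profiles, and the sequence effects below — after which
the defaults were frozen.  Only the chemically switched per-contact
strengths (1.8, ×0.8, 0.17/1.0) are taken directly from the source
energetics.  Every default is config-overridable (`readConfig()`).

The sequence rules (`defaultMappingRules()`) map a 10-bp poly(dA:dT) tract
to a +2.5 kBT extra-base-pair penalty at its SHL window (stiff tracts
resist over-twisting), and a TpA repeat at |SHL| = 2 to a +3.2 kBT
missing-base-pair penalty, a 0.95 stiffness multiplier and a 0.70 lobe-2
grip multiplier
(weakened lobe-2/DNA interactions on the flexible repeat).  The 601-like
construct enters phenomenologically as the positioning tilt; its base
composition is not modelled base by base.

## Analyses

* `defectSeries()`, `shl2Coordinate()`: twist-defect timelines and the
  sliding/projection coordinates; the defects telescope exactly to the
  end-to-end sliding.
* `labelFrame()`/`labelPath()`: the metastable-state grammar
  (o/c, A–D stage at the binding site, 0–2 near-dyad defect count) with
  debouncing (default 0.25 time units).  Thresholds sit at the midpoints
  (0.5 bp; 0.3/0.8 for the partial-closure stage, bracketing the ~0.6 bp
  intermediate).
* `cycleOutcome()`/`ensembleProbability()`: integer step calls from the
  final state (and at the end of the ATP phase), with Wilson intervals.
* `boltzmannInvert()`, `umbrellaProfile()`: free-energy profiles by direct
  histogram inversion, or — for the sliding profiles, whose several-kBT
  barriers make unbiased crossings rare — by a ladder of harmonic
  umbrella windows on `(x_1.5 + x_2.5)/2` recombined with 1-D WHAM
  (19 windows, 0.1 bp apart, 60 time units each after 10 of burn-in).
  Closed-ensemble profiles hold the lobes at the closed registration
  (y1 = 1, y2 = 0): the closed conformation is metastable on the sampling
  timescale and the analysis deliberately excludes reopening.
* `discretizeTrajectory()`, `countMatrix()`, `transitionMatrix()`,
  `impliedTimescales()`, `mfpt()`, `minEnergyPath()`: Markov state models
  at the default lag of 2.5 time units, with count symmetrization for
  detailed balance (simple and adequate at this scale; maximum-likelihood
  reversible estimation is deliberately out of scope), core-set label
  assignment (0.25 time units) so threshold-grazing does not register as
  transitions, and bottleneck-Dijkstra minimum-energy paths with
  deterministic tie-breaks (minimax, then path sum, then lexicographic
  cell order).

The mean first-passage analysis of sequence effects runs 42 closed-state
equilibrium trajectories of 300 time units per construct (half started in
the cB1 configuration, half in cD1, so both basins are populated), builds
the label MSM and reports `mfpt(cB1 → cD1)` ratios variant/baseline.

## Synthetic fixtures

`scriptedTrajectory()` (piecewise-constant label targets plus Gaussian
noise), `markovSampler()` (chains with known transition matrices) and
`toyWellSampler()` (exact inverse-CDF Boltzmann samples) let every
analysis stage be tested with zero dynamics code in the loop; all are
seed-deterministic.

## What the model does and does not capture

The generator emulates the *mechanism*: chemically driven potential
switching, defect-mediated sliding, the steric/electrostatic ratchet, and
sequence modulation of defect costs and lobe grip.  It does not model
residue-level structure, explicit electrostatics, DNA helical phase
(SHL n sits exactly at 10·n bp from the dyad), histone-tail contacts, or
octamer deformations; the diffusion coefficients and the time-unit mapping
are conventions, so absolute times are not predictions.  Passing tests
therefore validate the ratchet logic and the analysis pipeline, not
quantitative kinetics of real remodelers.  Known limitations: the
entropic multiplicity of partially slid configurations makes the
spontaneous-sliding marginal barrier come out below the bare defect-pair
cost; a few percent of cycles lose a completed step when hydrolysis
catches the system with an unreleased near-dyad defect; closed-ensemble
mean first-passage times to the repositioned state are dominated by
defect traffic across the dyad, which damps the sensitivity to sequence
elements placed at single SHLs; and the label grammar lumps all near-dyad
defect positions into one digit.

## Numerical choices

Euler–Maruyama with `dt = 5e-4` keeps `max |force|·D·dt` well below 0.2 bp
even at the steric wall (a warning fires otherwise); trajectories are
bit-reproducible given a seed, and ensembles use one generator per
trajectory (seeds `seed0, seed0+1, …`), so partial ensembles merge.
Snapshots default to every 0.05 time units.  Degenerate inputs are
handled explicitly: empty landscape bins are masked and impassable, states
outside the largest connected set are dropped from MSMs with a message,
unreachable MFPT targets come back infinite with a warning, and
trajectories that diverge abort with a state dump.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script use 100-cycle ensembles
(40 on naked DNA), 24 × 250-time-unit closed-ensemble runs per sequence
for the MSM analyses, and 19 × 70-time-unit umbrella windows per
free-energy profile — sizes chosen so the full suite completes on a
single CPU in minutes while keeping binomial and counting errors within
the tolerances the checks assert.
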