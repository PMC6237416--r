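#' @title Remodeler and chemical-state parameters
#'
#' @description \code{RemodelerParams} holds the chemical-state-independent
#' parameters of the translocase model.  Energies are in units of kBT
#' (kBT = 1), lengths in bp.
#'
#' @slot epsLobeDna numeric(2): apo-state grip well depths of lobes 1 and 2
#'   (kBT).  Sequence grip multipliers \code{g1}, \code{g2} scale these.
#' @slot epsLobes named numeric(3): lobe-1/lobe-2 coupling strength for APO,
#'   ATP, ADP (kBT).  ADP reverts to the apo value (hydrolysis weakens the
#'   inter-lobe attraction).
#' @slot adpGrip2Factor numeric(1): ATP hydrolysis weakens the lobe-2 grip by
#'   this factor (0.8).
#' @slot adpRelease numeric(1): ADP-state destabilization of the lobe-2/DNA
#'   interface (kBT), active while lobe 2 is at its pre-opening register;
#'   the kinetic counterpart of the 0.8 thermodynamic weakening, letting
#'   translocase opening proceed by the lobe-2 forward step.
#' @slot gripScale numeric(2): effective number of cooperatively-breaking
#'   DNA contacts per lobe.  Each lobe binds DNA through many individual
#'   contacts of strength \code{epsLobeDna}; the 1-bp sliding barrier of a
#'   lobe is \code{epsLobeDna * gripScale}, while the per-contact strengths
#'   remain the quantities switched by the chemical state.
#' @slot lobe1Strain numeric(1): ATP-state destabilization of the lobe-1/DNA
#'   interface (kBT).  It removes up to the full lobe-1 grip barrier; any
#'   excess acts as a forward tilt on the lobe-1 coordinate, so translocase
#'   closure proceeds via lobe-1 motion with high probability.
#' @slot couplingBarrier numeric(1): barrier (kBT) of the lobe-lobe double
#'   well in u = y1 - y2, with minima at u = 0 (open) and u = 1 (closed).
#' @slot couplingScale,couplingRef numeric(1): the closed-minus-open energy
#'   offset is \code{couplingScale * (couplingRef - epsLobes[chem])}, mapping
#'   the coupling strengths onto a thermodynamic bias (negative = closed
#'   favoured, as under ATP).
#' @slot epsElec numeric(1): depth (kBT) of the electrostatic spring between
#'   the lobe-1 basic patch and the DNA gyre at SHL -6; 0 emulates the
#'   charge-reversal (K855E-R880E-K885E-like) mutant.
#' @slot elecWidth numeric(1): range (bp) of the electrostatic spring.
#' @slot wallHalfwidth,wallHeight numeric(1): allowed excursion (bp) and
#'   steric penalty scale (kBT/bp^2) of the remodeler body relative to the
#'   DNA at its binding site.
#' @slot defectStab numeric(1): stabilization (kBT) of the productive
#'   twist-defect pair by the closed translocase: while u = y1 - y2 is
#'   closed (logistic gate around u = 0.5), the +1 bp penalty at SHL +1
#'   and the -1 bp penalty at SHL +2 are reduced by this amount.  This is
#'   the mechanism that lets the active machine create, at its binding
#'   site, defects that are expensive for the bare nucleosome, so active
#'   sliding is fast while spontaneous sliding stays slow; the
#'   stabilization follows the conformation, so defects present at
#'   hydrolysis are not suddenly stranded.
#' @slot structMuPlus,structMuMinus numeric(13): structural
#'   (octamer-geometry) extra penalties (kBT) per integer SHL for extra and
#'   missing base pairs, added on top of the sequence-derived twist
#'   energetics.  The defaults encode the defect propensities of the
#'   nucleosome: extra base pairs are accommodated at SHL +/-1 but resisted
#'   at the dyad (SHL 0) and at the SHL +/-2 contacts, while missing base
#'   pairs are accommodated at SHL +/-2 but resisted at SHL +/-1 and +/-3.
#'   This concentrates the productive defect pair (+1 bp at SHL 1, -1 bp at
#'   SHL 2) at the translocase site and sets the spontaneous-sliding
#'   barrier.
#' @slot smooth numeric(1): softmin temperature (kBT) joining the three
#'   twist-defect wells.
#' @export
setClass("RemodelerParams", representation(
  epsLobeDna = "numeric", epsLobes = "numeric", adpGrip2Factor = "numeric",
  adpRelease = "numeric", gripScale = "numeric",
  lobe1Strain = "numeric", couplingBarrier = "numeric",
  couplingScale = "numeric", couplingRef = "numeric",
  epsElec = "numeric", elecWidth = "numeric",
  wallHalfwidth = "numeric", wallHeight = "numeric",
  defectStab = "numeric",
  structMuPlus = "numeric", structMuMinus = "numeric",
  smooth = "numeric"))

setValidity("RemodelerParams", function(object) {
  msg <- character()
  if (length(object@epsLobeDna) != 2 || any(object@epsLobeDna < 0))
    msg <- c(msg, "epsLobeDna must be 2 non-negative depths")
  if (length(object@gripScale) != 2 || any(object@gripScale <= 0))
    msg <- c(msg, "gripScale must be 2 positive factors")
  if (length(object@structMuPlus) != 13 || length(object@structMuMinus) != 13 ||
      any(object@structMuPlus < 0) || any(object@structMuMinus < 0))
    msg <- c(msg, "structMuPlus/structMuMinus must be 13 non-negative values")
  if (!all(c("APO", "ATP", "ADP") %in% names(object@epsLobes)))
    msg <- c(msg, "epsLobes must be named APO, ATP, ADP")
  for (s in c("adpGrip2Factor", "adpRelease", "lobe1Strain",
              "couplingBarrier", "epsElec",
              "elecWidth", "wallHalfwidth", "wallHeight", "defectStab", "smooth")) {
    v <- slot(object, s)
    if (length(v) != 1 || !is.finite(v) || v < 0)
      msg <- c(msg, paste(s, "must be a single non-negative finite number"))
  }
  if (length(msg)) msg else TRUE
})

#' Structural defect-propensity profile of the nucleosome
#'
#' Extra penalties (kBT) per integer SHL (-6 ... +6) added to the
#' sequence-derived twist-defect energetics: extra base pairs are resisted
#' at the dyad and the |SHL| = 2 contacts, missing base pairs at |SHL| = 1
#' and |SHL| = 3, so that defects localize where nucleosome structures
#' accommodate them (+1 bp at SHL +/-1, -1 bp at SHL +/-2).
#'
#' @return list with numeric(13) elements \code{plus} and \code{minus}.
#' @export
structDefectProfile <- function() {
  shl <- defectShls()
  list(plus = ifelse(abs(shl) == 1, 0, ifelse(abs(shl) >= 3, 2, 3)),
       minus = ifelse(abs(shl) == 1, 3, 0))
}

#' Default translocase parameters
#'
#' The shipped values reproduce the calibrated desk-scale behaviour of the
#' model: apo-state grips of 1.8 kBT on both lobes, lobe-lobe coupling
#' 0.17 kBT (apo/ADP) vs 1.0 kBT (ATP), a 0.8 weakening of the lobe-2 grip
#' after hydrolysis, and an electrostatic spring anchoring lobe 1 to the
#' SHL -6 gyre.  Every value can be overridden (see \code{\link{readConfig}}).
#'
#' @param ... named slot overrides.
#' @return a \code{\linkS4class{RemodelerParams}} object.
#' @examples
#' defaultRemodelerParams()
#' defaultRemodelerParams(epsElec = 0)  # charge-mutant mode
#' @export
defaultRemodelerParams <- function(...) {
  p <- new("RemodelerParams",
    epsLobeDna = c(1.8, 1.8),
    epsLobes = c(APO = 0.17, ATP = 1.0, ADP = 0.17),
    adpGrip2Factor = 0.8,
    adpRelease = 8.4,
    gripScale = c(4.15, 7.2),
    lobe1Strain = 9.0,
    couplingBarrier = 4.2,
    couplingScale = 19.4,
    couplingRef = 0.582,
    epsElec = 4.55,
    elecWidth = 0.42,
    wallHalfwidth = 0.35,
    wallHeight = 120,
    defectStab = 2.8,
    structMuPlus = structDefectProfile()$plus,
    structMuMinus = structDefectProfile()$minus,
    smooth = 0.2)
  override <- list(...)
  for (nm in names(override)) slot(p, nm) <- override[[nm]]
  validObject(p)
  p
}

#' @title Fully resolved parameters for one chemical state
#' @description A \code{ParameterSet} is the deterministic product of
#' \code{\link{effectiveParams}}: base translocase parameters plus a
#' \code{\linkS4class{SequenceProfile}} resolved for one chemical state.
#' @slot chem "APO", "ATP" or "ADP".
#' @slot depth,tilt numeric(14): periodic contact-well amplitudes and linear
#'   positioning biases per contact SHL (kBT, kBT/bp).
#' @slot k,muPlus,muMinus numeric(13): twist stiffness (kBT/bp^2) and +1/-1
#'   bp defect penalties (kBT) per defect SHL.
#' @slot grip1,grip2 numeric(1): per-contact lobe grip strengths (kBT);
#'   the lobe sliding-well depth is \code{grip * gripScale}.
#' @slot gripScale numeric(2): contacts-per-lobe cooperativity factors.
#' @slot release numeric(1): active lobe-2 interface destabilization
#'   (kBT; ADP state only), analogous switch on the lobe-2 pre-opening
#'   register.
#' @slot strain numeric(1): active lobe-1 interface destabilization (kBT;
#'   nonzero in the ATP state only).  It reduces the lobe-1 grip well depth
#'   by \code{strain} while lobe 1 is at its pre-closure register
#'   (a logistic switch around a half-step forward), so the first forward
#'   step is facilitated and lobe 1 re-grips once closure is complete.
#' @slot epsLobes,couplingBarrier,couplingOffset numeric(1): lobe-lobe
#'   coupling strength, double-well barrier and resolved linear offset.
#' @slot epsElec,elecWidth,wallHalfwidth,wallHeight,smooth numeric(1).
#' @slot terms named logical: which energy terms are active
#'   (octamer, remodeler, wall, elec) and which coordinate blocks are frozen
#'   (freeze_dna, freeze_lobes).
#' @export
setClass("ParameterSet", representation(
  chem = "character", depth = "numeric", tilt = "numeric",
  k = "numeric", muPlus = "numeric", muMinus = "numeric",
  grip1 = "numeric", grip2 = "numeric", gripScale = "numeric",
  strain = "numeric", release = "numeric", defectStab = "numeric",
  epsLobes = "numeric", couplingBarrier = "numeric",
  couplingOffset = "numeric", epsElec = "numeric", elecWidth = "numeric",
  wallHalfwidth = "numeric", wallHeight = "numeric", smooth = "numeric",
  terms = "logical"))

termNames <- c("octamer", "remodeler", "wall", "elec",
               "freeze_dna", "freeze_lobes")

setValidity("ParameterSet", function(object) {
  msg <- character()
  if (!object@chem %in% c("APO", "ATP", "ADP"))
    msg <- c(msg, "chem must be APO, ATP or ADP")
  if (length(object@depth) != 14 || length(object@tilt) != 14)
    msg <- c(msg, "depth and tilt must have length 14")
  if (length(object@k) != 13 || length(object@muPlus) != 13 ||
      length(object@muMinus) != 13)
    msg <- c(msg, "k, muPlus, muMinus must have length 13")
  if (any(object@depth < 0) || any(object@k <= 0) ||
      any(object@muPlus < 0) || any(object@muMinus < 0))
    msg <- c(msg, "depths/penalties must be >= 0 and k > 0")
  if (length(object@gripScale) != 2 || any(object@gripScale <= 0))
    msg <- c(msg, "gripScale must be 2 positive factors")
  if (!identical(sort(names(object@terms)), sort(termNames)))
    msg <- c(msg, "terms must be named octamer/remodeler/wall/elec/freeze_dna/freeze_lobes")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ParameterSet", function(object) {
  cat("ParameterSet (", object@chem, ")\n", sep = "")
  cat("  grips:", signif(object@grip1, 3), "/", signif(object@grip2, 3),
      "kBT per contact (x", paste(object@gripScale, collapse = "/"),
      "), strain", object@strain, "; coupling", object@epsLobes,
      "kBT (offset", signif(object@couplingOffset, 3), ")\n")
  cat("  elec:", object@epsElec, "kBT, width", object@elecWidth, "bp; wall",
      object@wallHeight, "beyond", object@wallHalfwidth, "bp\n")
  cat("  active terms:", paste(names(object@terms)[object@terms],
                               collapse = ", "), "\n")
})

#' Resolve the effective potential for a chemical state
#'
#' Implements the chemical-state switching of the inchworm cycle:
#' \describe{
#'   \item{APO}{grips \code{epsLobeDna * c(g1, g2)}, weak lobe-lobe coupling.}
#'   \item{ATP}{grips unchanged; coupling raised to its ATP value, tilting
#'     the double well toward the closed form; the lobe-1 strain removes the
#'     lobe-1 grip barrier (excess becomes a forward tilt).}
#'   \item{ADP}{lobe-2 grip scaled by \code{adpGrip2Factor} (0.8); coupling
#'     reverts to the apo value.}
#' }
#'
#' @param base a \code{\linkS4class{RemodelerParams}}.
#' @param seq a \code{\linkS4class{SequenceProfile}}.
#' @param chem "APO", "ATP" or "ADP".
#' @return a \code{\linkS4class{ParameterSet}}.
#' @examples
#' sp <- profileFromSequence(buildSequence("polyApG"))
#' effectiveParams(defaultRemodelerParams(), sp, "ATP")
#' @export
effectiveParams <- function(base, seq, chem = c("APO", "ATP", "ADP")) {
  stopifnot(is(base, "RemodelerParams"), is(seq, "SequenceProfile"))
  if (length(chem) == 1 && !chem %in% c("APO", "ATP", "ADP"))
    stop("unknown chemical state: ", chem)
  chem <- match.arg(chem)
  g1 <- base@epsLobeDna[1] * seq@g1
  g2 <- base@epsLobeDna[2] * seq@g2
  strain <- 0
  release <- 0
  if (chem == "ATP") {
    strain <- base@lobe1Strain
  } else if (chem == "ADP") {
    g2 <- g2 * base@adpGrip2Factor
    release <- base@adpRelease
  }
  eps12 <- unname(base@epsLobes[chem])
  muPlus <- seq@defects$mu_plus + base@structMuPlus
  muMinus <- seq@defects$mu_minus + base@structMuMinus

  new("ParameterSet",
    chem = chem,
    depth = seq@contacts$depth, tilt = seq@contacts$tilt,
    k = seq@defects$k, muPlus = muPlus,
    muMinus = muMinus,
    grip1 = g1, grip2 = g2, gripScale = base@gripScale, strain = strain,
    release = release, defectStab = base@defectStab,
    epsLobes = eps12, couplingBarrier = base@couplingBarrier,
    couplingOffset = base@couplingScale * (base@couplingRef - eps12),
    epsElec = base@epsElec, elecWidth = base@elecWidth,
    wallHalfwidth = base@wallHalfwidth, wallHeight = base@wallHeight,
    smooth = base@smooth,
    terms = setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), termNames))
}

# flat list consumed by the C++ kernel
asPhaseList <- function(ps) {
  stopifnot(is(ps, "ParameterSet"))
  list(depth = ps@depth, tilt = ps@tilt, k = ps@k,
       mu_plus = ps@muPlus, mu_minus = ps@muMinus, smooth = ps@smooth,
       grip1 = ps@grip1 * ps@gripScale[1],
       grip2 = ps@grip2 * ps@gripScale[2],
       strain = ps@strain, release = ps@release, stab = ps@defectStab,
       coup_off = ps@couplingOffset, coup_h = ps@couplingBarrier,
       eps_elec = ps@epsElec, elec_width = ps@elecWidth,
       wall_halfwidth = ps@wallHalfwidth, wall_height = ps@wallHeight,
       octamer = unname(ps@terms["octamer"]),
       remodeler = unname(ps@terms["remodeler"]),
       wall = unname(ps@terms["wall"]), elec = unname(ps@terms["elec"]),
       freeze_dna = unname(ps@terms["freeze_dna"]),
       freeze_lobes = unname(ps@terms["freeze_lobes"]))
}

# modified copy with some energy terms switched off / coordinates frozen
setTerms <- function(ps, ...) {
  on <- list(...)
  for (nm in names(on)) {
    if (!nm %in% termNames) stop("unknown term flag: ", nm)
    ps@terms[nm] <- on[[nm]]
  }
  validObject(ps)
  ps
}
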