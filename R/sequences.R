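#' @title Nucleosomal DNA sequences and their energetic profiles
#'
#' @description \code{BaseSequence} stores a nucleosomal DNA sequence with a
#' declared dyad position.  The model maps SHL n to the base-pair offset
#' 10 * n from the dyad (an integer convention: the reduced model carries no
#' helical phase, so the ~10.17 bp/turn periodicity is rounded to 10).
#'
#' @slot dna a \code{Biostrings::DNAString} (A/C/G/T only).
#' @slot dyad 1-based index of the dyad base pair.
#' @slot positioning logical: TRUE for a strong-positioning (601-like)
#'   construct shifted off its optimal register, modelled phenomenologically
#'   as a linear free-energy tilt at the contacts flanking the translocase.
#' @export
setClass("BaseSequence", representation(
  dna = "ANY", dyad = "integer", positioning = "logical"))

setValidity("BaseSequence", function(object) {
  msg <- character()
  s <- as.character(object@dna)
  if (nchar(s) < 1) msg <- c(msg, "empty sequence")
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0)
    msg <- c(msg, paste0("invalid nucleotide at position ", bad))
  if (object@dyad < 1 || object@dyad > nchar(s))
    msg <- c(msg, "dyad index outside the sequence")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BaseSequence", function(object) {
  cat("BaseSequence: ", length(object@dna), " bp, dyad at ", object@dyad,
      if (object@positioning) ", positioning construct", "\n", sep = "")
})

#' @title Sequence-to-energetics mapping rules
#' @description Baseline DNA energetics plus the per-element increments the
#' model applies where a sequence element occupies a defect SHL window.
#' The shipped increments are calibration products (the underlying
#' residue-level energetics are not part of this model) and are
#' config-overridable.
#' @slot baseDepth,baseK,baseMu numeric(1): baseline contact well depth
#'   (kBT), twist stiffness (kBT/bp^2) and +/-1 bp defect penalty (kBT) of a
#'   uniform intermediate-flexibility sequence.
#' @slot dMuPlusApA numeric(1): extra +1 bp penalty where a poly(dA:dT)
#'   tract sits (stiff tracts resist over-twisting).
#' @slot dMuMinusTpA numeric(1): extra -1 bp penalty where a TpA repeat
#'   sits at |SHL| = 2.
#' @slot kMultTpA numeric(1): twist-stiffness multiplier of the flexible
#'   TpA repeat.
#' @slot g2TpA numeric(1): lobe-2 grip multiplier when a TpA repeat
#'   occupies the SHL +2 binding site (weakened lobe-2/DNA interactions).
#' @slot tilt601 numeric(1): total positioning tilt (kBT/bp) of a 601-like
#'   construct shifted off register, split over contacts +1.5 and +2.5.
#' @export
setClass("MappingRules", representation(
  baseDepth = "numeric", baseK = "numeric", baseMu = "numeric",
  dMuPlusApA = "numeric", dMuMinusTpA = "numeric", kMultTpA = "numeric",
  g2TpA = "numeric", tilt601 = "numeric"))

#' Default sequence mapping rules
#' @param ... named slot overrides.
#' @return a \code{\linkS4class{MappingRules}} object.
#' @export
defaultMappingRules <- function(...) {
  r <- new("MappingRules",
    baseDepth = 2.8, baseK = 15, baseMu = 5.4,
    dMuPlusApA = 2.5, dMuMinusTpA = 3.2, kMultTpA = 0.95,
    g2TpA = 0.70, tilt601 = 2.4)
  override <- list(...)
  for (nm in names(override)) slot(r, nm) <- override[[nm]]
  validObject(r)
  r
}

#' @title Per-site energetic profile derived from a DNA sequence
#' @description One row per grid site: twist-defect energetics at the 13
#' integer SHLs, contact well/tilt parameters at the 14 half-integer SHLs,
#' plus the two lobe-grip multipliers.
#' @slot defects data.frame(shl, k, mu_plus, mu_minus).
#' @slot contacts data.frame(shl, depth, tilt).
#' @slot g1,g2 lobe grip multipliers in (0, 2].
#' @export
setClass("SequenceProfile", representation(
  defects = "data.frame", contacts = "data.frame",
  g1 = "numeric", g2 = "numeric"))

setValidity("SequenceProfile", function(object) {
  msg <- character()
  if (!identical(object@defects$shl, defectShls()))
    msg <- c(msg, "defects must have one row per integer SHL -6..6")
  if (!identical(object@contacts$shl, contactShls()))
    msg <- c(msg, "contacts must have one row per half-integer SHL -6.5..6.5")
  for (g in c(object@g1, object@g2))
    if (g <= 0 || g > 2) msg <- c(msg, "grip multipliers must be in (0, 2]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SequenceProfile", function(object) {
  cat("SequenceProfile: g1 =", object@g1, ", g2 =", object@g2, "\n")
  alt <- object@defects[object@defects$mu_plus != object@defects$mu_plus[1] |
                        object@defects$k != object@defects$k[1] |
                        object@defects$mu_minus != object@defects$mu_minus[1], ]
  if (nrow(alt)) {
    cat("  non-baseline defect sites at SHL:",
        paste(alt$shl, collapse = ", "), "\n")
  } else cat("  uniform defect energetics\n")
  if (any(object@contacts$tilt != 0)) cat("  positioning tilt active\n")
})

#' Build one of the model's DNA constructs
#'
#' \code{"polyApG"} is the uniform reference: the 2-bp periodic repeat of
#' ApG steps.  An \code{element} replaces the 10 bp centred at
#' \code{dyad + 10 * shl} with a poly(dA:dT) tract ("ApA") or a TpA repeat
#' ("TpA").  \code{"601"} marks a strong-positioning construct started 3 bp
#' off its optimal register; its base composition is kept polyApG (the
#' positioning signal enters only as a free-energy tilt, see
#' \code{\link{profileFromSequence}}).
#'
#' @param kind "polyApG" or "601".
#' @param length sequence length in bp (>= 147 unless only a fragment is
#'   wanted for inspection).
#' @param element optional "ApA" or "TpA".
#' @param shl integer SHL at which the element is centred.
#' @param dyad dyad index; defaults to the central base pair.
#' @return a \code{\linkS4class{BaseSequence}}.
#' @examples
#' buildSequence("polyApG", length = 8)
#' buildSequence("polyApG", element = "TpA", shl = 2)
#' @export
buildSequence <- function(kind = c("polyApG", "601"), length = 147L,
                          element = NULL, shl = NULL, dyad = NULL) {
  kind <- match.arg(kind)
  length <- as.integer(length)
  s <- strrep("AG", ceiling(length / 2))
  s <- substr(s, 1, length)
  if (is.null(dyad)) dyad <- as.integer(ceiling(length / 2))
  if (!is.null(element)) {
    element <- match.arg(element, c("ApA", "TpA"))
    if (is.null(shl)) stop("element insertion needs an shl")
    off <- 10L * as.integer(shl)
    pos <- dyad + (off - 5L):(off + 4L)
    if (any(pos < 1 | pos > length) || abs(off) > 73)
      stop("element centre at SHL ", shl, " lies outside the wrapped region")
    ins <- if (element == "ApA") strrep("A", 10) else strrep("TA", 5)
    substr(s, min(pos), max(pos)) <- ins
  }
  new("BaseSequence", dna = Biostrings::DNAString(s), dyad = as.integer(dyad),
      positioning = (kind == "601"))
}

# classify the 10-bp window centred at a defect SHL
classifyWindow <- function(win) {
  if (nchar(win) < 10) return("baseline")
  ch <- strsplit(win, "")[[1]]
  if (mean(ch == "A") >= 0.9) return("ApA")
  pairs <- paste0(head(ch, -1), tail(ch, -1))
  if (all(pairs %in% c("TA", "AT")) && any(ch == "T")) return("TpA")
  "baseline"
}

#' Map a DNA sequence to the model's energetic profile
#'
#' Each defect SHL i owns the 10-bp window at offsets 10i - 5 ... 10i + 4
#' from the dyad.  A window fully occupied by a poly(dA:dT) tract raises the
#' +1 bp defect penalty there; a TpA-repeat window softens the twist
#' stiffness, and at |SHL| = 2 additionally raises the -1 bp penalty.  A TpA
#' window at the SHL +2 translocase site also weakens the lobe-2 grip
#' (multiplier \code{g2TpA}).  A positioning construct adds the tilt
#' \code{tilt601} split equally over contacts +1.5 and +2.5, biasing the
#' DNA back toward its pre-shift register.
#'
#' @param seq a \code{\linkS4class{BaseSequence}}.
#' @param rules a \code{\linkS4class{MappingRules}}.
#' @param mirror also apply each element's rule at the mirrored -SHL site
#'   (off by default: elements are placed on the remodeler-proximal side).
#' @return a \code{\linkS4class{SequenceProfile}}.
#' @examples
#' profileFromSequence(buildSequence("polyApG"))
#' profileFromSequence(buildSequence("polyApG", element = "TpA", shl = 2))
#' @export
profileFromSequence <- function(seq, rules = defaultMappingRules(),
                                mirror = FALSE) {
  stopifnot(is(seq, "BaseSequence"), is(rules, "MappingRules"))
  s <- as.character(seq@dna)
  n <- nchar(s)
  if (n < 147)
    stop("a nucleosomal construct needs at least 147 bp (got ", n, ")")
  shls <- defectShls()
  def <- data.frame(shl = shls, k = rules@baseK, mu_plus = rules@baseMu,
                    mu_minus = rules@baseMu)
  g2 <- 1
  kinds <- vapply(shls, function(i) {
    pos <- seq@dyad + (10 * i - 5):(10 * i + 4)
    pos <- pos[pos >= 1 & pos <= n]
    classifyWindow(substr(s, min(pos), max(pos)))
  }, character(1))
  applyAt <- function(idx, kind) {
    i <- shls[idx]
    if (kind == "ApA") {
      def$mu_plus[idx] <<- def$mu_plus[idx] + rules@dMuPlusApA
    } else if (kind == "TpA") {
      def$k[idx] <<- def$k[idx] * rules@kMultTpA
      if (abs(i) == 2) def$mu_minus[idx] <<- def$mu_minus[idx] + rules@dMuMinusTpA
      if (i == 2) g2 <<- rules@g2TpA
    }
  }
  for (idx in seq_along(shls)) {
    if (kinds[idx] != "baseline") {
      applyAt(idx, kinds[idx])
      if (mirror && shls[idx] != 0) {
        midx <- match(-shls[idx], shls)
        if (kinds[midx] == "baseline") applyAt(midx, kinds[idx])
      }
    }
  }
  con <- data.frame(shl = contactShls(), depth = rules@baseDepth, tilt = 0)
  if (seq@positioning) {
    con$tilt[con$shl %in% c(1.5, 2.5)] <- rules@tilt601 / 2
  }
  new("SequenceProfile", defects = def, contacts = con, g1 = 1, g2 = g2)
}

#' Read / write a single-record FASTA sequence
#'
#' The record description carries \code{dyad=<i> positioning=<0|1>} so that
#' write-then-read round-trips the full \code{\linkS4class{BaseSequence}}.
#' Lowercase input is normalized to uppercase; any non-ACGT character is
#' rejected with its position.
#'
#' @param path file path.
#' @param dyad optional dyad override when the header carries none.
#' @return \code{readFastaSequence}: a \code{\linkS4class{BaseSequence}}.
#' @export
readFastaSequence <- function(path, dyad = NULL) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1)
    stop("expected a single FASTA record, found ", length(set))
  s <- toupper(as.character(set[[1]]))
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0)
    stop("invalid nucleotide '", substr(s, bad, bad), "' at position ", bad)
  nm <- names(set)[1]
  d <- regmatches(nm, regexec("dyad=([0-9]+)", nm))[[1]]
  if (length(d) == 2) dyad <- as.integer(d[2])
  if (is.null(dyad)) dyad <- as.integer(ceiling(nchar(s) / 2))
  p <- regmatches(nm, regexec("positioning=([01])", nm))[[1]]
  positioning <- length(p) == 2 && p[2] == "1"
  new("BaseSequence", dna = Biostrings::DNAString(s), dyad = dyad,
      positioning = positioning)
}

#' @rdname readFastaSequence
#' @param seq a \code{\linkS4class{BaseSequence}} to write.
#' @param name FASTA record name.
#' @export
writeFastaSequence <- function(seq, path, name = "construct") {
  stopifnot(is(seq, "BaseSequence"))
  set <- Biostrings::DNAStringSet(seq@dna)
  names(set) <- sprintf("%s dyad=%d positioning=%d", name, seq@dyad,
                        as.integer(seq@positioning))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
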