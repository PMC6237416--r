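#' Superhelical-location grid of the reduced model
#'
#' The nucleosome wraps ~147 bp in ~1.7 turns; the strong histone-DNA
#' contacts sit where the DNA minor groove faces the octamer, at the 14
#' half-integer superhelical locations (SHLs) -6.5 ... +6.5.  Twist defects
#' live between adjacent contacts, at the 13 integer SHLs -6 ... +6: the
#' defect at SHL i is \code{d_i = x[i + 0.5] - x[i - 0.5]}.
#'
#' @return \code{contactShls()}: the 14 half-integer contact SHLs.
#'   \code{defectShls()}: the 13 integer defect SHLs.
#' @examples
#' contactShls()
#' defectShls()
#' @export
contactShls <- function() seq(-6.5, 6.5, by = 1)

#' @rdname contactShls
#' @export
defectShls <- function() seq(-6, 6, by = 1)

# index of a contact SHL in the 16-coordinate layout (x first, then y1, y2)
contactIndex <- function(shl) {
  i <- match(shl, contactShls())
  if (anyNA(i)) stop("not a contact SHL: ", paste(shl[is.na(i)], collapse = ", "))
  i
}

coordNames <- function() {
  c(paste0("x_", contactShls()), "y1", "y2")
}
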