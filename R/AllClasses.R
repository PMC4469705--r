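#' @import methods
NULL

#' Base-pair table of one sequence/structure
#'
#' A \code{PairTable} records, position by position, how one nucleotide
#' sequence realises its dot-bracket secondary structure: every matched
#' bracket pair becomes a row with status \code{"paired"}, holding the 5' and
#' 3' positions and bases and the helix the pair belongs to; unpaired
#' positions and alignment gap columns get rows of status \code{"unpaired"}
#' and \code{"gap"}.  Rows are ordered along the sequence, and within a helix
#' pairs run from the helix base (the pair with the smallest 5' position)
#' outward, which is the order the barcode extraction quotas count in.
#'
#' @slot strainId single character, the sequence id.
#' @slot pairs data.frame with columns \code{fivePrimePos},
#'   \code{threePrimePos} (integer, \code{NA} when not paired),
#'   \code{fivePrimeBase}, \code{threePrimeBase} (character),
#'   \code{status} (\code{"paired"}, \code{"unpaired"} or \code{"gap"}) and
#'   \code{helix} (\code{"STEM"}, \code{"HI"}, \code{"HII"}, \code{"HIII"},
#'   \code{"HIV"}, \code{"OTHER"} or \code{NA}).
#' @slot seqLength length of the underlying (aligned) sequence.
#'
#' @seealso [buildPairTable()], [consensusPairing()], [extractBarcodePairs()]
#' @export
setClass("PairTable",
  representation(strainId = "character", pairs = "data.frame",
                 seqLength = "integer"))

setValidity("PairTable", function(object) {
  p <- object@pairs
  need <- c("fivePrimePos", "threePrimePos", "fivePrimeBase",
            "threePrimeBase", "status", "helix")
  if (!all(need %in% names(p)))
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  if (length(object@strainId) != 1L || !nzchar(object@strainId))
    return("strainId must be a single non-empty string")
  paired <- p$status == "paired"
  if (any(paired & !(p$fivePrimePos < p$threePrimePos), na.rm = TRUE))
    return("paired rows must satisfy fivePrimePos < threePrimePos")
  pos <- c(p$fivePrimePos[paired], p$threePrimePos[paired])
  if (anyDuplicated(pos))
    return("a position appears in two pairs")
  TRUE
})

#' Number-coded ITS-2 barcodes for a set of strains
#'
#' A \code{BarcodeSet} holds the number-coded barcodes of one or more strains
#' on a shared consensus position axis.  Codes follow the base-pair coding
#' scheme A-U = 1, U-A = 2, G-C = 3, C-G = 4, G:U = 5, U:G = 6, mismatched
#' pairing = 7, deletion/unpaired/single base = 8; positions whose underlying
#' bases carry an IUPAC ambiguity letter are \code{NA} ("unknown", serialised
#' as \code{"?"}).
#'
#' @slot codes integer matrix, strains in rows (unique rownames), barcode
#'   positions in columns; entries in 1..8 or \code{NA}.
#'
#' @seealso [encodeBarcode()], [barcodeSet()], [cbcHcbcMatrix()]
#' @export
setClass("BarcodeSet", representation(codes = "matrix"))

setValidity("BarcodeSet", function(object) {
  m <- object@codes
  if (!is.integer(m))
    return("codes must be an integer matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)) ||
      any(!nzchar(rownames(m))))
    return("codes must have unique non-empty rownames (strain ids)")
  v <- m[!is.na(m)]
  if (length(v) && (any(v < 1L) || any(v > 8L)))
    return("codes must lie in 1..8 or be NA (unknown)")
  TRUE
})

#' Pairwise CBC / hemi-CBC count matrix
#'
#' Square strain-by-strain matrices of compensatory base change (CBC) and
#' hemi-CBC (HCBC) counts between number-coded barcodes.  The conventional
#' single-table layout (CBCs in the upper triangle, HCBCs in the lower) is
#' produced by \code{as.matrix}.
#'
#' @slot cbc,hcbc symmetric integer matrices with zero diagonal and matching
#'   dimnames (strain ids).
#'
#' @seealso [cbcHcbcMatrix()], [delimitSpecies()]
#' @export
setClass("CbcMatrix", representation(cbc = "matrix", hcbc = "matrix"))

setValidity("CbcMatrix", function(object) {
  for (nm in c("cbc", "hcbc")) {
    m <- slot(object, nm)
    if (nrow(m) != ncol(m)) return(sprintf("%s must be square", nm))
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      return(sprintf("%s must have matching row/col names", nm))
    if (any(m < 0)) return(sprintf("%s counts must be >= 0", nm))
    if (!isTRUE(all.equal(m, t(m)))) return(sprintf("%s must be symmetric", nm))
    if (any(diag(m) != 0)) return(sprintf("%s must have a zero diagonal", nm))
  }
  if (!identical(dimnames(object@cbc), dimnames(object@hcbc)))
    return("cbc and hcbc must share dimnames")
  TRUE
})

#' Partition of strains into species blocks
#'
#' Species blocks are the single-linkage connected components of the
#' zero-CBC relation: two strains fall in one block when a chain of pairwise
#' zero-CBC links connects them.  Triples that break transitivity (a-b and
#' b-c linked at zero CBCs while a-c shows at least one CBC) are merged into
#' one block but reported in \code{conflictFlags}.
#'
#' @slot blocks named list of character vectors; the vectors are disjoint and
#'   jointly cover all strains.
#' @slot conflicts data.frame with columns \code{a}, \code{b}, \code{c}
#'   listing non-transitive zero-CBC triples.
#'
#' @seealso [delimitSpecies()], [assignHaplotypes()], [kOverTheta()]
#' @export
setClass("SpeciesPartition",
  representation(blocks = "list", conflicts = "data.frame"))

setValidity("SpeciesPartition", function(object) {
  all_ids <- unlist(object@blocks, use.names = FALSE)
  if (anyDuplicated(all_ids))
    return("blocks must be disjoint")
  if (!all(c("a", "b", "c") %in% names(object@conflicts)))
    return("conflicts must have columns a, b, c")
  TRUE
})
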