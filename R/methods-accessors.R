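#' @rdname PairTable-class
#' @export
setMethod("basePairs", "PairTable", function(x) x@pairs)

#' @rdname PairTable-class
#' @export
setMethod("strainIds", "PairTable", function(x) x@strainId)

setMethod("show", "PairTable", function(object) {
  p <- object@pairs
  cat(sprintf("PairTable for '%s': %d paired, %d unpaired, %d gap (length %d)\n",
              object@strainId, sum(p$status == "paired"),
              sum(p$status == "unpaired"), sum(p$status == "gap"),
              object@seqLength))
  hx <- table(p$helix[p$status == "paired"], useNA = "no")
  if (length(hx))
    cat("  pairs per helix:",
        paste(sprintf("%s=%d", names(hx), as.integer(hx)), collapse = ", "),
        "\n")
})

#' @rdname BarcodeSet-class
#' @export
setMethod("strainIds", "BarcodeSet", function(x) rownames(x@codes))

#' @rdname BarcodeSet-class
#' @export
setMethod("codeMatrix", "BarcodeSet", function(x) x@codes)

#' @rdname BarcodeSet-class
#' @export
setMethod("barcodeLength", "BarcodeSet", function(x) ncol(x@codes))

#' @rdname BarcodeSet-class
#' @param i strain index or id.
#' @export
setMethod("[", "BarcodeSet", function(x, i) {
  new("BarcodeSet", codes = x@codes[i, , drop = FALSE])
})

#' @rdname BarcodeSet-class
#' @export
setMethod("length", "BarcodeSet", function(x) nrow(x@codes))

setMethod("show", "BarcodeSet", function(object) {
  cat(sprintf("BarcodeSet: %d strain(s) x %d position(s)\n",
              nrow(object@codes), ncol(object@codes)))
  n <- min(5L, nrow(object@codes))
  for (k in seq_len(n))
    cat(sprintf("  %-14s %s\n", rownames(object@codes)[k],
                codeString(object@codes[k, ])))
  if (nrow(object@codes) > n)
    cat(sprintf("  ... and %d more\n", nrow(object@codes) - n))
})

#' Serialise a code vector as a digit string
#'
#' Unknown (\code{NA}) codes print as \code{"?"}, mirroring the tabular
#' barcode layout used in ITS-2 barcode figures.
#'
#' @param codes integer vector over 1..8 with \code{NA} for unknown.
#' @return single character string.
#' @export
codeString <- function(codes) {
  s <- as.character(codes)
  s[is.na(s)] <- "?"
  paste(s, collapse = "")
}

#' @rdname CbcMatrix-class
#' @export
setMethod("cbcCounts", "CbcMatrix", function(x) x@cbc)

#' @rdname CbcMatrix-class
#' @export
setMethod("hcbcCounts", "CbcMatrix", function(x) x@hcbc)

#' @rdname CbcMatrix-class
#' @export
setMethod("strainIds", "CbcMatrix", function(x) rownames(x@cbc))

#' Combined upper/lower-triangle layout
#'
#' Returns one square matrix with CBC counts in the upper triangle and HCBC
#' counts in the lower triangle (zero diagonal), the layout customary for
#' published pairwise CBC tables.
#'
#' @param x a [CbcMatrix-class].
#' @param ... ignored.
#' @return integer matrix.
#' @export
setMethod("as.matrix", "CbcMatrix", function(x, ...) {
  m <- x@cbc
  m[lower.tri(m)] <- x@hcbc[lower.tri(m)]
  m
})

setMethod("show", "CbcMatrix", function(object) {
  cat(sprintf("CbcMatrix: %d strains (upper = CBC, lower = HCBC)\n",
              nrow(object@cbc)))
  print(as.matrix(object))
})

#' @rdname SpeciesPartition-class
#' @export
setMethod("speciesBlocks", "SpeciesPartition", function(x) x@blocks)

#' @rdname SpeciesPartition-class
#' @export
setMethod("conflictFlags", "SpeciesPartition", function(x) x@conflicts)

#' @rdname SpeciesPartition-class
#' @export
setMethod("length", "SpeciesPartition", function(x) length(x@blocks))

#' @rdname SpeciesPartition-class
#' @export
setMethod("strainIds", "SpeciesPartition",
          function(x) unlist(x@blocks, use.names = FALSE))

setMethod("show", "SpeciesPartition", function(object) {
  cat(sprintf("SpeciesPartition: %d block(s), %d strain(s), %d conflict(s)\n",
              length(object@blocks),
              length(unlist(object@blocks, use.names = FALSE)),
              nrow(object@conflicts)))
  for (nm in names(object@blocks))
    cat(sprintf("  %s: %s\n", nm, paste(object@blocks[[nm]], collapse = ", ")))
})
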