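#' Build a base-pair table from a sequence, its structure and helix ranges
#'
#' Matched brackets become paired rows; the helix label of a pair is taken
#' from the annotated helix whose 5' interval contains the pair's 5'
#' position, with the pair's 3' position required to fall in the same
#' helix's 3' interval.  Pairs touching no annotated interval are labelled
#' \code{OTHER}.  Rows are ordered along the sequence, so within a nested
#' helix pairs run from the helix base outward.
#'
#' @param sequence a single sequence: a length-1 [Biostrings::RNAStringSet],
#'   or a character string (then give \code{strainId}).
#' @param structure dot-bracket string of the same length.
#' @param annotation helix annotation data.frame
#'   (see [readHelixAnnotation()]); may be \code{NULL} for an unannotated
#'   table.
#' @param strainId id used when \code{sequence} carries no name.
#' @return a [PairTable-class].
#'
#' @section Errors: an annotation interval that splits a pair across helices
#'   signals an \code{annotationError}; an unbalanced structure a
#'   \code{structureError}.
#' @examples
#' buildPairTable("GCAAGC", "((..))", NULL, strainId = "s1")
#' @export
buildPairTable <- function(sequence, structure, annotation = NULL,
                           strainId = NULL) {
  if (methods::is(sequence, "XStringSet")) {
    if (length(sequence) != 1L)
      .err("usageError", "sequence must be a single record")
    if (is.null(strainId)) strainId <- names(sequence)
    sequence <- as.character(sequence)
  }
  if (is.null(strainId)) strainId <- names(sequence)
  if (is.null(strainId) || !nzchar(strainId)) strainId <- "seq"
  sequence <- toupper(chartr("T", "U", unname(sequence)))
  .checkDotBracket(structure, strainId)
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  sq <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(ch) != length(sq))
    .err("structureError", "structure and sequence lengths differ")
  if (!is.null(annotation)) {
    annotation <- validateHelixAnnotation(annotation)
    if (any(annotation$three_end > length(sq)))
      .err("annotationError", "helix annotation exceeds sequence length")
  }
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
    }
  }
  open <- which(!is.na(partner))
  helixOf <- function(i, j) {
    if (is.null(annotation)) return("OTHER")
    in5 <- annotation$helix_name[annotation$five_start <= i &
                                 i <= annotation$five_end]
    in3 <- annotation$helix_name[annotation$three_start <= j &
                                 j <= annotation$three_end]
    if (length(in5) && length(in3) && in5 == in3) return(in5)
    if (length(in5) == 0L && length(in3) == 0L) return("OTHER")
    .err("annotationError",
         sprintf("pair (%d,%d) is split across helix annotation intervals",
                 i, j))
  }
  rows <- data.frame(
    fivePrimePos = seq_len(n),
    threePrimePos = NA_integer_,
    fivePrimeBase = sq,
    threePrimeBase = NA_character_,
    status = ifelse(sq == "-", "gap", "unpaired"),
    helix = NA_character_,
    stringsAsFactors = FALSE)
  if (length(open)) {
    j <- partner[open]
    rows$threePrimePos[open] <- j
    rows$threePrimeBase[open] <- sq[j]
    rows$status[open] <- "paired"
    rows$helix[open] <- vapply(seq_along(open),
                               function(k) helixOf(open[k], j[k]),
                               character(1))
    rows <- rows[-j, , drop = FALSE]   # closing positions live in their pair
  }
  rownames(rows) <- NULL
  new("PairTable", strainId = strainId, pairs = rows,
      seqLength = as.integer(n))
}

#' Regenerate the dot-bracket string of a pair table
#'
#' Inverse of [buildPairTable()]: paired rows emit \code{(}/\code{)},
#' unpaired rows \code{.}, gap rows \code{-}.
#'
#' @param table a [PairTable-class].
#' @return dot-bracket string.
#' @export
pairTableToDotBracket <- function(table) {
  p <- table@pairs
  out <- rep(".", table@seqLength)
  out[p$fivePrimePos[p$status == "gap"]] <- "-"
  paired <- p$status == "paired"
  out[p$fivePrimePos[paired]] <- "("
  out[p$threePrimePos[paired]] <- ")"
  paste(out, collapse = "")
}

#' Majority-rule consensus pairing across strains
#'
#' A pair (i, j) of alignment columns enters the consensus when it occurs
#' (same two columns) in at least \code{threshold} of the input tables; ties
#' at the threshold are retained.  Consensus pairs inherit the majority
#' helix label, and per-position consensus bases are the majority base.
#'
#' @param tables list of [PairTable-class] objects on one alignment axis.
#' @param threshold fraction in (0, 1]; default 0.5 (strict majority with
#'   ties kept).
#' @return a [PairTable-class] with \code{strainId = "consensus"}.
#'
#' @section Errors: tables of different alignment lengths signal a
#'   \code{crossReferenceError}.
#' @export
consensusPairing <- function(tables, threshold = 0.5) {
  .assertNumber(threshold, "threshold", lower = 1e-9, upper = 1)
  if (!length(tables))
    .err("usageError", "need at least one pair table")
  lens <- vapply(tables, function(t) t@seqLength, integer(1))
  if (length(unique(lens)) != 1L)
    .err("crossReferenceError",
         "pair tables lie on different alignment coordinate axes")
  L <- lens[1]
  nT <- length(tables)
  keyCount <- list()
  for (t in tables) {
    p <- t@pairs[t@pairs$status == "paired", , drop = FALSE]
    for (k in seq_len(nrow(p))) {
      key <- sprintf("%d:%d", p$fivePrimePos[k], p$threePrimePos[k])
      ent <- keyCount[[key]]
      if (is.null(ent)) ent <- list(n = 0L, helix = character(0))
      ent$n <- ent$n + 1L
      ent$helix <- c(ent$helix, p$helix[k])
      keyCount[[key]] <- ent
    }
  }
  keep <- names(keyCount)[vapply(keyCount, function(e) e$n / nT,
                                 numeric(1)) >= threshold]
  # majority base per column (ties broken alphabetically, '-' last)
  baseTab <- matrix("-", nrow = nT, ncol = L)
  for (r in seq_len(nT)) {
    p <- tables[[r]]@pairs
    baseTab[r, p$fivePrimePos] <- p$fivePrimeBase
    paired <- p$status == "paired"
    baseTab[r, p$threePrimePos[paired]] <- p$threePrimeBase[paired]
  }
  majBase <- apply(baseTab, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    cand <- names(tb)[tb == tb[1]]
    ord <- c(setdiff(sort(cand), "-"), intersect(cand, "-"))
    ord[1]
  })
  pairedAt <- rep(FALSE, L)
  consRows <- NULL
  if (length(keep)) {
    ij <- do.call(rbind, strsplit(keep, ":", fixed = TRUE))
    i <- as.integer(ij[, 1]); j <- as.integer(ij[, 2])
    hel <- vapply(keep, function(key) {
      h <- keyCount[[key]]$helix
      h[is.na(h)] <- "OTHER"
      tb <- sort(table(factor(h, levels = c(.HELIX_NAMES, "OTHER"))),
                 decreasing = TRUE)
      names(tb)[1]
    }, character(1))
    o <- order(i)
    consRows <- data.frame(
      fivePrimePos = i[o], threePrimePos = j[o],
      fivePrimeBase = majBase[i[o]], threePrimeBase = majBase[j[o]],
      status = "paired", helix = hel[o], stringsAsFactors = FALSE)
    pairedAt[c(i, j)] <- TRUE
  }
  rest <- which(!pairedAt)
  restRows <- data.frame(
    fivePrimePos = rest, threePrimePos = NA_integer_,
    fivePrimeBase = majBase[rest], threePrimeBase = NA_character_,
    status = ifelse(majBase[rest] == "-", "gap", "unpaired"),
    helix = NA_character_, stringsAsFactors = FALSE)
  rows <- rbind(consRows, restRows)
  rows <- rows[order(rows$fivePrimePos), , drop = FALSE]
  rownames(rows) <- NULL
  new("PairTable", strainId = "consensus", pairs = rows,
      seqLength = as.integer(L))
}
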