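.CHANGE_LEVELS <- c("identical", "CBC", "HCBC", "not_comparable")

# 9x9 lookup over code indices 1..8 plus 9 = unknown.
# 0 identical, 1 CBC, 2 HCBC, 3 not comparable.
.classTable <- local({
  decode <- function(k) strsplit(names(.CODE_PAIRS)[k], "")[[1]]
  m <- matrix(3L, 9, 9)
  for (a in 1:6) for (b in 1:6) {
    if (a == b) { m[a, b] <- 0L; next }
    nd <- sum(decode(a) != decode(b))
    m[a, b] <- if (nd == 2L) 1L else 2L
  }
  m[7, 7] <- 0L   # mismatch vs mismatch: identical by convention, not counted
  m[8, 8] <- 0L   # absent vs absent
  m
})

#' Classify a pair of barcode codes as CBC, hemi-CBC or neither
#'
#' Both codes in 1..6 imply concrete ordered nucleotide pairs: if both
#' implied nucleotides differ the change is a compensatory base change
#' (CBC); if exactly one differs it is a hemi-CBC (HCBC); equal codes are
#' identical.  Codes 7 (mismatch), 8 (deletion/unpaired/single base) and
#' unknown (\code{NA}) make the position non-comparable, except that 7-7
#' and 8-8 are identical-by-convention (and never counted as changes).
#'
#' @param a,b codes in 1..8 or \code{NA} (unknown).
#' @return one of \code{"identical"}, \code{"CBC"}, \code{"HCBC"},
#'   \code{"not_comparable"}; vectorised over \code{a}, \code{b}.
#' @examples
#' classifyCodePair(1, 2)  # A-U vs U-A: CBC
#' classifyCodePair(3, 5)  # G-C vs G:U: HCBC
#' @export
classifyCodePair <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  ok <- function(x) is.na(x) | (x >= 1L & x <= 8L)
  if (any(!ok(a)) || any(!ok(b)))
    .err("usageError", "codes must lie in 1..8 or be NA (unknown)")
  ai <- ifelse(is.na(a), 9L, a)
  bi <- ifelse(is.na(b), 9L, b)
  .CHANGE_LEVELS[.classTable[cbind(ai, bi)] + 1L]
}

#' Pairwise CBC and hemi-CBC counts between barcodes
#'
#' Counts, for every strain pair, the barcode positions classified CBC and
#' HCBC by [classifyCodePair()]; non-comparable positions contribute to
#' neither count.
#'
#' @param barcodes a [BarcodeSet-class].
#' @return a [CbcMatrix-class].
#' @export
cbcHcbcMatrix <- function(barcodes) {
  m <- codeMatrix(barcodes)
  idx <- m
  idx[is.na(idx)] <- 9L
  n <- nrow(m)
  cbc <- hcbc <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cls <- .classTable[cbind(idx[i, ], idx[j, ])]
    cbc[i, j] <- cbc[j, i] <- sum(cls == 1L)
    hcbc[i, j] <- hcbc[j, i] <- sum(cls == 2L)
  }
  new("CbcMatrix", cbc = cbc, hcbc = hcbc)
}

#' Delimit species as zero-CBC connected components
#'
#' Two strains belong to one species when a chain of pairwise zero-CBC
#' links connects them (single linkage).  Following the rule that at least
#' one CBC separates species, every off-diagonal CBC count of at least one
#' splits; non-transitive triples — a-b and b-c at zero CBCs but a-c with a
#' CBC — are merged into one block and flagged rather than failing.
#'
#' @param x a [CbcMatrix-class] (or a [BarcodeSet-class], run through
#'   [cbcHcbcMatrix()] first).
#' @return a [SpeciesPartition-class]; blocks are named \code{SP1},
#'   \code{SP2}, ... in first-occurrence order.
#' @export
delimitSpecies <- function(x) {
  if (methods::is(x, "BarcodeSet")) x <- cbcHcbcMatrix(x)
  cbc <- cbcCounts(x)
  ids <- rownames(cbc)
  n <- length(ids)
  adj <- cbc == 0L
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  blocks <- split(ids, comp)
  names(blocks) <- paste0("SP", seq_along(blocks))
  conflicts <- data.frame(a = character(0), b = character(0),
                          c = character(0), stringsAsFactors = FALSE)
  for (blk in blocks) {
    bi <- match(blk, ids)
    for (p in seq_along(bi)) for (q in seq_along(bi)) {
      if (p >= q) next
      a <- bi[p]; cc <- bi[q]
      if (cbc[a, cc] > 0L) {
        bmid <- which(cbc[a, ] == 0L & cbc[cc, ] == 0L)
        bmid <- setdiff(bmid, c(a, cc))
        b <- if (length(bmid)) bmid[1] else NA_integer_
        conflicts <- rbind(conflicts, data.frame(
          a = ids[a], b = if (is.na(b)) NA_character_ else ids[b],
          c = ids[cc], stringsAsFactors = FALSE))
      }
    }
  }
  new("SpeciesPartition", blocks = blocks, conflicts = conflicts)
}

#' Uncorrected p-distance matrix
#'
#' Entry (a, b) is the fraction of differing columns over the columns
#' comparable between the two sequences; columns where either sequence
#' carries a gap or an IUPAC ambiguity letter are excluded from both
#' numerator and denominator.
#'
#' @param sequences aligned [Biostrings::RNAStringSet] (or named character
#'   vector of equal-length strings).
#' @return symmetric numeric matrix with zero diagonal.
#'
#' @section Errors: a pair with zero comparable columns signals an
#'   \code{undefinedDistanceError}; unequal lengths an
#'   \code{alignmentError}.
#' @export
pDistanceMatrix <- function(sequences) {
  nm <- names(sequences)
  s <- toupper(chartr("T", "U", as.character(sequences)))
  names(s) <- nm
  if (length(unique(nchar(s))) != 1L)
    .err("alignmentError", "sequences must be aligned (equal lengths)")
  chm <- do.call(rbind, strsplit(s, "", fixed = TRUE))
  plain <- matrix(chm %in% c("A", "C", "G", "U"), nrow = nrow(chm))
  n <- length(s)
  d <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- plain[i, ] & plain[j, ]
    if (!any(comp))
      .err("undefinedDistanceError",
           sprintf("no comparable columns between '%s' and '%s'",
                   names(s)[i], names(s)[j]))
    d[i, j] <- d[j, i] <- sum(chm[i, comp] != chm[j, comp]) / sum(comp)
  }
  d
}

#' Between- versus within-species divergence (K over theta)
#'
#' For every ordered pair of species blocks, K is the mean between-block
#' p-distance and theta the mean within-block pairwise p-distance of the
#' reference (first) block; their ratio flags candidate species pairs when
#' it reaches the threshold.  Singleton reference blocks, or blocks whose
#' within diversity is zero, yield an undefined (NA) ratio rather than an
#' error.
#'
#' @param partition a [SpeciesPartition-class] (or named list of strain-id
#'   vectors).
#' @param distances symmetric distance matrix over the partitioned strains.
#' @param threshold ratio at which a pair is flagged as candidate distinct
#'   species; default 4.
#' @return data.frame with columns \code{reference}, \code{other},
#'   \code{K}, \code{theta}, \code{ratio}, \code{candidate}.
#' @export
kOverTheta <- function(partition, distances, threshold = 4) {
  .assertNumber(threshold, "threshold", lower = 0)
  blocks <- if (methods::is(partition, "SpeciesPartition"))
    partition@blocks else partition
  ids <- rownames(distances)
  missing <- setdiff(unlist(blocks, use.names = FALSE), ids)
  if (length(missing))
    .err("crossReferenceError",
         sprintf("strain(s) missing from distance matrix: %s",
                 paste(missing, collapse = ", ")))
  nm <- names(blocks)
  out <- NULL
  for (ra in nm) for (rb in nm) {
    if (ra == rb) next
    A <- blocks[[ra]]; B <- blocks[[rb]]
    K <- mean(distances[A, B, drop = FALSE])
    theta <- if (length(A) >= 2L) {
      w <- distances[A, A, drop = FALSE]
      mean(w[upper.tri(w)])
    } else NA_real_
    ratio <- if (!is.na(theta) && theta > 0) K / theta else NA_real_
    out <- rbind(out, data.frame(
      reference = ra, other = rb, K = K, theta = theta, ratio = ratio,
      candidate = !is.na(ratio) && ratio >= threshold,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Export a species partition as TSV
#'
#' @param partition a [SpeciesPartition-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePartitionTsv <- function(partition, path) {
  blocks <- speciesBlocks(partition)
  df <- data.frame(strain_id = unlist(blocks, use.names = FALSE),
                   species_block = rep(names(blocks), lengths(blocks)),
                   stringsAsFactors = FALSE)
  flagged <- unique(unlist(conflictFlags(partition), use.names = FALSE))
  df$conflict <- df$strain_id %in% flagged
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
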