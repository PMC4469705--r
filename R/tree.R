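#' Normalized Hamming distance between number-coded barcodes
#'
#' Positions where either barcode is unknown (\code{NA}) are excluded, as
#' are positions where both barcodes are 8 (neither strain has the pair);
#' an 8 against any other code counts as a difference.  The distance is
#' differing positions over compared positions.
#'
#' @param a,b integer code vectors on one position axis (rows of a
#'   [BarcodeSet-class]).
#' @return list with \code{value} (fraction in `[0, 1]`) and
#'   \code{comparedPositions}.
#'
#' @section Errors: zero compared positions signal an
#'   \code{undefinedDistanceError}; different lengths a
#'   \code{crossReferenceError}.
#' @export
barcodeDistance <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != length(b))
    .err("crossReferenceError", "barcodes must share one position axis")
  keep <- !is.na(a) & !is.na(b) & !(a == 8L & b == 8L)
  if (!any(keep))
    .err("undefinedDistanceError", "no comparable barcode positions")
  list(value = sum(a[keep] != b[keep]) / sum(keep),
       comparedPositions = sum(keep))
}

#' All pairwise barcode distances
#'
#' @param barcodes a [BarcodeSet-class].
#' @return symmetric numeric matrix of [barcodeDistance()] values.
#' @export
barcodeDistanceMatrix <- function(barcodes) {
  m <- codeMatrix(barcodes)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- barcodeDistance(m[i, ], m[j, ])$value
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor-joining agglomeration with two determinism rules: ties
#' in the Q-criterion are broken by lowest (row, column) index, and negative
#' branch lengths are clamped to zero with the total clamped deficit kept in
#' the result's \code{"negativeDeficit"} attribute.
#'
#' @param distances symmetric numeric matrix with zero diagonal, at least
#'   three taxa, dimnames giving taxon labels.
#' @return unrooted [ape::phylo] tree whose leaf set equals the taxon set.
#'
#' @section Errors: fewer than three taxa signal a \code{usageError}.
#' @export
neighborJoining <- function(distances) {
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 3L)
    .err("usageError", "neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0))
    .err("usageError", "distance matrix must be symmetric with zero diagonal")
  labs <- rownames(D)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  frag <- vapply(labs, .quoteNewickLabel, character(1))
  deficit <- 0
  clamp <- function(x) {
    if (x < 0) { deficit <<- deficit - x; 0 } else x
  }
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    # lowest (row, column) among ties, upper triangle
    Q[lower.tri(Q)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newFrag <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], li, frag[j], lj)
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
    rownames(D2) <- colnames(D2) <- seq_len(m - 1L)
    D <- D2
  }
  l1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  l2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  l3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], l1, frag[2], l2, frag[3], l3)
  tree <- ape::read.tree(text = txt)
  attr(tree, "negativeDeficit") <- deficit
  tree
}

#' Distance phylogeny of number-coded barcodes
#'
#' Convenience wrapper: pairwise [barcodeDistanceMatrix()] followed by
#' [neighborJoining()].
#'
#' @param barcodes a [BarcodeSet-class] with at least three strains.
#' @return unrooted [ape::phylo] tree.
#' @export
barcodeTree <- function(barcodes) {
  neighborJoining(barcodeDistanceMatrix(barcodes))
}
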