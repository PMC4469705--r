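# Base-pair number code: A-U = 1, U-A = 2, G-C = 3, C-G = 4,
# G:U = 5, U:G = 6, mismatch = 7, deletion/unpaired/single base = 8.
.CODE_PAIRS <- c(AU = 1L, UA = 2L, GC = 3L, CG = 4L, GU = 5L, UG = 6L)

#' The six canonical/wobble pair codes
#'
#' @return named integer vector mapping ordered base pairs (5' base then
#'   3' base) to codes 1..6.
#' @export
codePairs <- function() .CODE_PAIRS

#' Extract the conserved ITS-2 barcode pairs from a pair table
#'
#' The barcode region concatenates, in order: the first 14 pairs of the
#' 5.8S/LSU stem, the first 5 pairs of Helix I, the first 11 pairs of Helix
#' II (which include its pyrimidine-pyrimidine mismatch), and all pairs of
#' Helix III — each block counted from the helix base outward.  A helix
#' holding fewer pairs than its quota is padded with gap-status placeholder
#' rows (later coded 8), so all barcodes share one position axis.
#'
#' @param table a [PairTable-class] with helix labels.
#' @param hiiiPairs number of Helix III pairs to emit; \code{NULL} (default)
#'   takes every Helix III pair in \code{table}.  Supply the consensus count
#'   when encoding strains whose individual structures gain or lose Helix
#'   III pairs.
#' @param quotas named integer vector with elements \code{STEM}, \code{HI},
#'   \code{HII}; defaults 14, 5 and 11.
#' @return data.frame of base-pair rows (one per barcode position).
#'
#' @section Errors: a table without Helix III pairs signals an
#'   \code{annotationError}.
#' @export
extractBarcodePairs <- function(table, hiiiPairs = NULL,
                                quotas = c(STEM = 14L, HI = 5L, HII = 11L)) {
  p <- table@pairs
  if (!any(p$helix %in% "HIII"))
    .err("annotationError", "pair table has no Helix III (HIII) pairs")
  pick <- function(helix, quota) {
    rows <- p[p$status == "paired" & !is.na(p$helix) & p$helix == helix, ,
              drop = FALSE]
    rows <- rows[order(rows$fivePrimePos), , drop = FALSE]  # base outward
    if (nrow(rows) >= quota) return(rows[seq_len(quota), , drop = FALSE])
    pad <- data.frame(
      fivePrimePos = rep(NA_integer_, quota - nrow(rows)),
      threePrimePos = NA_integer_, fivePrimeBase = "-",
      threePrimeBase = "-", status = "gap", helix = helix,
      stringsAsFactors = FALSE)
    rbind(rows, pad)
  }
  nH3 <- sum(p$status == "paired" & p$helix %in% "HIII")
  if (is.null(hiiiPairs)) hiiiPairs <- nH3
  out <- rbind(pick("STEM", as.integer(quotas[["STEM"]])),
               pick("HI", as.integer(quotas[["HI"]])),
               pick("HII", as.integer(quotas[["HII"]])),
               pick("HIII", as.integer(hiiiPairs)))
  rownames(out) <- NULL
  out
}

#' Translate barcode pairs into the 1-8 number code
#'
#' Each position is coded by its ordered nucleotide pair: the six
#' canonical/wobble pairs map to 1..6, any other paired combination is a
#' mismatch (7), and gap placeholders, unpaired or single bases are 8.  A
#' paired position carrying an IUPAC ambiguity letter is coded unknown
#' (\code{NA}), since an N cannot assert a real pairing.
#'
#' @param pairs data.frame from [extractBarcodePairs()] (or any base-pair
#'   rows with \code{status}, \code{fivePrimeBase}, \code{threePrimeBase}).
#' @return integer vector of codes (NA = unknown), one per row.
#' @examples
#' encodeBarcode(data.frame(status = "paired", fivePrimeBase = "A",
#'                          threePrimeBase = "U"))  # 1
#' @export
encodeBarcode <- function(pairs) {
  n <- nrow(pairs)
  codes <- rep(8L, n)
  paired <- pairs$status == "paired"
  if (any(paired)) {
    b5 <- pairs$fivePrimeBase[paired]
    b3 <- pairs$threePrimeBase[paired]
    plain <- b5 %in% c("A", "C", "G", "U") & b3 %in% c("A", "C", "G", "U")
    gapish <- b5 == "-" | b3 == "-"
    v <- rep(NA_integer_, sum(paired))
    key <- paste0(b5, b3)
    hit <- .CODE_PAIRS[key]
    v[plain] <- ifelse(is.na(hit[plain]), 7L, hit[plain])
    v[gapish] <- 8L
    codes[paired] <- v
  }
  codes
}

#' Assemble a BarcodeSet from per-strain code vectors
#'
#' @param codes named list of equal-length integer code vectors, or an
#'   integer matrix with strain rownames.
#' @return a [BarcodeSet-class].
#' @export
barcodeSet <- function(codes) {
  if (is.list(codes)) {
    lens <- lengths(codes)
    if (length(unique(lens)) != 1L)
      .err("crossReferenceError", "barcodes must share one position axis")
    m <- do.call(rbind, lapply(codes, as.integer))
    rownames(m) <- names(codes)
    codes <- m
  }
  storage.mode(codes) <- "integer"
  new("BarcodeSet", codes = codes)
}

#' Compute number-coded barcodes for a set of strains
#'
#' Runs the full extraction path: per-strain pair tables from the aligned
#' sequences and dot-bracket structures, a majority consensus pairing, and
#' barcode extraction from the consensus.  The consensus barcode pairs
#' define the shared position axis: at each axis position a strain is coded
#' by its own bases when its structure holds that exact column pair, and by
#' 8 (missing base pair) otherwise, so a pair lost in one strain never
#' shifts its downstream codes.
#'
#' @param sequences aligned [Biostrings::RNAStringSet].
#' @param structures named character vector of aligned dot-bracket strings
#'   (see [readStructureFile()]).
#' @param annotation helix annotation data.frame.
#' @param threshold consensus threshold passed to [consensusPairing()].
#' @return a [BarcodeSet-class] with the consensus [PairTable-class]
#'   attached as attribute \code{"consensus"}.
#' @export
computeBarcodes <- function(sequences, structures, annotation,
                            threshold = 0.5) {
  ids <- names(sequences)
  missing <- setdiff(ids, names(structures))
  if (length(missing))
    .err("crossReferenceError",
         sprintf("no structure for sequence(s): %s",
                 paste(missing, collapse = ", ")))
  tables <- lapply(ids, function(id)
    buildPairTable(as.character(sequences[[id]]), structures[[id]],
                   annotation, strainId = id))
  cons <- if (length(tables) >= 2L)
    consensusPairing(tables, threshold = threshold) else tables[[1]]
  axis <- extractBarcodePairs(cons)
  codes <- lapply(tables, function(t) .encodeAtAxis(t, axis))
  names(codes) <- ids
  bs <- barcodeSet(codes)
  attr(bs, "consensus") <- cons
  bs
}

#' @noRd
.encodeAtAxis <- function(table, axis) {
  p <- table@pairs
  paired <- p[p$status == "paired", , drop = FALSE]
  key <- paste(paired$fivePrimePos, paired$threePrimePos)
  rows <- data.frame(
    status = rep("gap", nrow(axis)),
    fivePrimeBase = "-", threePrimeBase = "-",
    stringsAsFactors = FALSE)
  axisKey <- paste(axis$fivePrimePos, axis$threePrimePos)
  hit <- match(axisKey, key)
  hit[is.na(axis$fivePrimePos)] <- NA   # axis pad positions stay code 8
  found <- !is.na(hit)
  rows$status[found] <- "paired"
  rows$fivePrimeBase[found] <- paired$fivePrimeBase[hit[found]]
  rows$threePrimeBase[found] <- paired$threePrimeBase[hit[found]]
  encodeBarcode(rows)
}

#' Assign BC-style haplotype labels
#'
#' Species indices are assigned in first-occurrence order of the species
#' blocks along the input strains; within a species, distinct code series
#' get lowercase letters \code{a}, \code{b}, ... in first-occurrence order.
#' Strains with identical code series share one label, and a species with a
#' single variant carries no letter (e.g. \code{BC-2} but \code{BC-1a},
#' \code{BC-1b}).
#'
#' @param barcodes a [BarcodeSet-class].
#' @param partition a [SpeciesPartition-class], or a named character vector
#'   mapping strain id to species block.
#' @return named character vector, strain id to haplotype label.
#'
#' @section Errors: a strain absent from the partition signals a
#'   \code{crossReferenceError}.
#' @export
assignHaplotypes <- function(barcodes, partition) {
  m <- codeMatrix(barcodes)
  ids <- rownames(m)
  if (methods::is(partition, "SpeciesPartition")) {
    block <- rep(names(partition@blocks), lengths(partition@blocks))
    names(block) <- unlist(partition@blocks, use.names = FALSE)
  } else block <- partition
  missing <- setdiff(ids, names(block))
  if (length(missing))
    .err("crossReferenceError",
         sprintf("strain(s) missing from partition: %s",
                 paste(missing, collapse = ", ")))
  blk <- unname(block[ids])
  spIdx <- match(blk, unique(blk))
  series <- apply(m, 1L, codeString)
  lab <- character(length(ids))
  for (s in unique(spIdx)) {
    sel <- spIdx == s
    variants <- unique(series[sel])
    letter <- if (length(variants) == 1L) "" else letters[match(series[sel],
                                                                variants)]
    lab[sel] <- paste0("BC-", s, letter)
  }
  stats::setNames(lab, ids)
}
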