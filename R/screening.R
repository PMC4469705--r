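#' Default marker region intervals
#'
#' 1-based inclusive alignment columns of the V4 (616-845) and V9
#' (1631-1737) hypervariable regions of the SSU rRNA, as positioned in the
#' reference alignment this workflow was built around.  Note the quoted
#' ranges span 230 and 107 columns; companion prose describing these
#' markers as 229 and 106 bp is off by one, and the ranges are treated as
#' authoritative.
#'
#' @return named list of c(start, end) integer vectors.
#' @export
defaultRegions <- function() {
  list(V4 = c(616L, 845L), V9 = c(1631L, 1737L))
}

#' Slice a marker region out of an alignment
#'
#' @param alignment aligned [Biostrings::RNAStringSet].
#' @param interval c(start, end), 1-based inclusive alignment columns.
#' @return list with \code{aligned} (the column slice, gaps preserved) and
#'   \code{ungapped} (per-record gap-free copies) as
#'   [Biostrings::RNAStringSet]s.
#'
#' @section Errors: an interval outside the alignment signals a
#'   \code{usageError}.
#' @export
extractAlignmentRegion <- function(alignment, interval) {
  w <- unique(Biostrings::width(alignment))
  if (length(w) != 1L)
    .err("alignmentError", "alignment records must have equal length")
  if (length(interval) != 2L || any(is.na(interval)) ||
      interval[1] < 1L || interval[2] > w || interval[1] > interval[2])
    .err("usageError",
         sprintf("interval [%s, %s] outside alignment of width %d",
                 interval[1], interval[2], w))
  sliced <- Biostrings::subseq(alignment, start = interval[1],
                               end = interval[2])
  ung <- Biostrings::RNAStringSet(gsub("-", "", as.character(sliced),
                                       fixed = TRUE))
  names(ung) <- names(alignment)
  list(aligned = sliced, ungapped = ung)
}

#' Global (ends-free) identity and coverage between two sequences
#'
#' Deterministic pairwise alignment standing in for a BLAST-style search
#' against a small local panel.  The alignment is global with free terminal
#' gaps; identity is matching columns over aligned columns (terminal
#' overhangs excluded), and coverage is the fraction of the query inside
#' the aligned region.  IUPAC ambiguity letters count as mismatches.
#'
#' @param query,reference ungapped sequences (character or
#'   [Biostrings::RNAString]).
#' @param match,mismatch,gapOpening,gapExtension alignment scores; defaults
#'   +1, -1, -2, -0.5.
#' @return list with \code{identity} and \code{coverage} (query) and
#'   \code{referenceCoverage}, all percentages, plus \code{partial}
#'   (TRUE when the reference is not fully covered).
#'
#' @section Errors: an empty sequence signals a \code{usageError}.
#' @export
globalIdentity <- function(query, reference, match = 1, mismatch = -1,
                           gapOpening = -2, gapExtension = -0.5) {
  q <- toupper(chartr("U", "T", as.character(query)))
  r <- toupper(chartr("U", "T", as.character(reference)))
  if (!nzchar(q) || !nzchar(r))
    .err("usageError", "sequences must be non-empty")
  if (grepl("-", paste0(q, r), fixed = TRUE))
    .err("usageError", "sequences must be ungapped")
  alph <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")
  mat <- matrix(mismatch, length(alph), length(alph),
                dimnames = list(alph, alph))
  diag(mat)[1:4] <- match   # only unambiguous self-matches score as match
  aln <- Biostrings::pairwiseAlignment(
    pattern = q, subject = r, type = "overlap",
    substitutionMatrix = mat,
    gapOpening = abs(gapOpening), gapExtension = abs(gapExtension))
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  asu <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(ap)
  matches <- sum(ap == asu & ap %in% c("A", "C", "G", "T"))
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  qCov <- (Biostrings::end(pr) - Biostrings::start(pr) + 1L) / nchar(q)
  rCov <- (Biostrings::end(sr) - Biostrings::start(sr) + 1L) / nchar(r)
  list(identity = 100 * matches / cols,
       coverage = 100 * qCov,
       referenceCoverage = 100 * rCov,
       partial = rCov < 1)
}

#' Default screening thresholds
#'
#' @return list: \code{minIdentity} (97), \code{v4Strict} (99).
#' @export
defaultScreeningThresholds <- function() {
  list(minIdentity = 97, v4Strict = 99)
}

.HIT_LEVELS <- c("unassigned", "foreign_taxon", "genus_level_only",
                 "putative_new_lineage", "same_species_candidate",
                 "species_match")

#' Classify a query sequence against a reference panel
#'
#' Implements the screening guideline: a hit at 100\% identity and 100\%
#' coverage identifies the species; below that, structure evidence decides.
#' At or above the minimum identity (default 97\%), a query whose barcode
#' shows zero CBCs against the best-hit species' barcode is a
#' same-species candidate, while one or more CBCs flag a putative new
#' lineage.  V4-only evidence between 97\% and the V4-strict threshold
#' (default 99\%) resolves the genus only, as does high identity without a
#' barcode.  Below the minimum identity the query is unassigned — or a
#' foreign taxon when its barcode carries CBCs at the genus-diagnostic
#' positions.
#'
#' @param query ungapped query sequence (character or
#'   [Biostrings::RNAString]).
#' @param panel list with elements \code{sequences} (named ungapped
#'   [Biostrings::RNAStringSet]), optional \code{barcodes}
#'   ([BarcodeSet-class]) and \code{species} (named vector, strain id to
#'   species label).
#' @param queryBarcode optional integer code vector for the query on the
#'   panel's barcode axis.
#' @param marker \code{"ITS2"}, \code{"V4"} or \code{"V9"}; V4 triggers the
#'   stricter identity rule.
#' @param thresholds list as [defaultScreeningThresholds()].
#' @param diagnosticPositions optional integer positions of the
#'   genus-diagnostic CBC signature on the barcode axis, used for the
#'   foreign-taxon call.
#' @return one-row data.frame: \code{query_id}, \code{reference_id},
#'   \code{identity}, \code{coverage}, \code{cbc_count},
#'   \code{classification}.
#' @export
classifyQuery <- function(query, panel, queryBarcode = NULL,
                          marker = c("ITS2", "V4", "V9"),
                          thresholds = defaultScreeningThresholds(),
                          diagnosticPositions = NULL) {
  marker <- match.arg(marker)
  for (nm in c("minIdentity", "v4Strict"))
    .assertNumber(thresholds[[nm]], nm, lower = 1e-9, upper = 100)
  refs <- panel$sequences
  if (is.null(refs) || length(refs) == 0L)
    .err("usageError", "panel must contain reference sequences")
  hits <- lapply(as.character(refs), function(r)
    globalIdentity(query, r))
  idv <- vapply(hits, `[[`, numeric(1), "identity")
  best <- which.max(idv)
  hit <- hits[[best]]
  refId <- names(refs)[best]
  qid <- if (!is.null(names(query)) && nzchar(names(query)[1]))
    names(query)[1] else "query"

  cbcN <- NA_integer_
  diagCbcN <- NA_integer_
  if (!is.null(queryBarcode) && !is.null(panel$barcodes) &&
      refId %in% strainIds(panel$barcodes)) {
    refCodes <- codeMatrix(panel$barcodes)[refId, ]
    cls <- classifyCodePair(queryBarcode, refCodes)
    cbcN <- sum(cls == "CBC")
    if (!is.null(diagnosticPositions))
      diagCbcN <- sum(cls[diagnosticPositions] == "CBC")
  }

  minId <- thresholds$minIdentity
  cl <- if (hit$identity >= 100 - 1e-9 && hit$coverage >= 100 - 1e-9 &&
            !hit$partial) {
    "species_match"
  } else if (hit$identity >= minId) {
    if (marker == "V4" && hit$identity < thresholds$v4Strict)
      "genus_level_only"
    else if (!is.na(cbcN)) {
      if (cbcN == 0L) "same_species_candidate" else "putative_new_lineage"
    } else "genus_level_only"
  } else {
    if (!is.na(diagCbcN) && diagCbcN > 0L) "foreign_taxon" else "unassigned"
  }
  data.frame(query_id = qid, reference_id = refId,
             identity = hit$identity, coverage = hit$coverage,
             cbc_count = cbcN, classification = cl,
             stringsAsFactors = FALSE)
}

#' Screen a set of queries against a panel
#'
#' @param queries named ungapped [Biostrings::RNAStringSet].
#' @param panel,marker,thresholds,diagnosticPositions as [classifyQuery()].
#' @param queryBarcodes optional [BarcodeSet-class] of query barcodes.
#' @return data.frame of one [classifyQuery()] row per query.
#' @export
screenQueries <- function(queries, panel, queryBarcodes = NULL,
                          marker = c("ITS2", "V4", "V9"),
                          thresholds = defaultScreeningThresholds(),
                          diagnosticPositions = NULL) {
  marker <- match.arg(marker)
  rows <- lapply(names(queries), function(id) {
    qb <- if (!is.null(queryBarcodes) && id %in% strainIds(queryBarcodes))
      codeMatrix(queryBarcodes)[id, ] else NULL
    q <- stats::setNames(as.character(queries[[id]]), id)
    classifyQuery(q, panel, queryBarcode = qb, marker = marker,
                  thresholds = thresholds,
                  diagnosticPositions = diagnosticPositions)
  })
  do.call(rbind, rows)
}
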