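#' Read a (possibly aligned) FASTA file of nucleotide sequences
#'
#' Sequences are held internally over the RNA alphabet: \code{T} is
#' transcribed to \code{U} on input and the original DNA/RNA state of every
#' record is kept in the result's metadata so output can restore it.
#' Alignment gaps (\code{-}) and IUPAC ambiguity letters are preserved.
#'
#' @param path path to a FASTA file.
#' @param aligned logical; when \code{TRUE} (default) all records must have
#'   equal length and the file is treated as an alignment.
#' @return a [Biostrings::RNAStringSet] in file order, with a logical
#'   \code{wasDNA} vector in its metadata.
#'
#' @section Errors: empty file or duplicate ids signal a \code{formatError};
#'   unequal lengths in aligned mode signal an \code{alignmentError}.
#' @export
readFasta <- function(path, aligned = TRUE) {
  .assertFlag(aligned, "aligned")
  if (!file.exists(path))
    .err("formatError", sprintf("file not found: %s", path))
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    .err("formatError", sprintf("not readable as FASTA: %s", path)))
  if (length(raw) == 0L)
    .err("formatError", sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids)))
    .err("formatError", "FASTA record with empty id")
  if (anyDuplicated(ids))
    .err("formatError", sprintf("duplicate FASTA id(s): %s",
         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  s <- toupper(as.character(raw))
  if (any(!nzchar(s)))
    .err("formatError", "FASTA record with empty sequence")
  if (aligned && length(unique(nchar(s))) != 1L)
    .err("alignmentError",
         "aligned FASTA records must all have the same length")
  wasDNA <- grepl("T", s, fixed = TRUE)
  s <- chartr("T", "U", s)
  bad <- grepl("[^ACGURYSWKMBDHVN.-]", s)
  if (any(bad))
    .err("formatError", sprintf("invalid residue letters in record(s): %s",
         paste(ids[bad], collapse = ", ")))
  out <- Biostrings::RNAStringSet(s)
  names(out) <- ids
  S4Vectors::metadata(out) <- list(wasDNA = stats::setNames(wasDNA, ids))
  out
}

#' @rdname readFasta
#' @export
readAlignedFasta <- function(path) readFasta(path, aligned = TRUE)

#' Write sequences to FASTA
#'
#' @param sequences an [Biostrings::RNAStringSet] (or named character vector).
#' @param path output path.
#' @param asDNA write \code{T} instead of \code{U}. Default restores each
#'   record's original alphabet from the \code{wasDNA} metadata when present.
#' @return the path, invisibly.
#' @export
writeFasta <- function(sequences, path, asDNA = NULL) {
  s <- as.character(sequences)
  if (is.null(names(s)) || any(!nzchar(names(s))))
    .err("usageError", "sequences must be named")
  if (is.null(asDNA)) {
    md <- tryCatch(S4Vectors::metadata(sequences)$wasDNA, error = function(e) NULL)
    asDNA <- if (is.null(md)) rep(FALSE, length(s)) else unname(md[names(s)])
    asDNA[is.na(asDNA)] <- FALSE
  } else {
    asDNA <- rep(isTRUE(asDNA), length(s))
  }
  s[asDNA] <- chartr("U", "T", s[asDNA])
  writeLines(paste0(">", names(s), "\n", s), path)
  invisible(path)
}

#' Read a Vienna-style dot-bracket structure file
#'
#' The expected dialect is one \code{>id} header line followed by one
#' dot-bracket line per record.  Only nested round brackets are accepted
#' (\code{(}, \code{)}, \code{.} and, in aligned mode, \code{-} on gap
#' columns); pseudoknot bracket alphabets are rejected.
#'
#' @param path path to the structure file.
#' @param sequences the [Biostrings::RNAStringSet] the structures annotate.
#' @param aligned when \code{TRUE}, each structure must have the aligned
#'   length and carry \code{-} exactly on its sequence's gap columns;
#'   when \code{FALSE} it must match the ungapped length.
#' @return named character vector, id to dot-bracket string.
#'
#' @section Errors: unbalanced or ill-formed structures signal a
#'   \code{structureError}; a structure id absent from \code{sequences}
#'   signals a \code{crossReferenceError}.
#' @export
readStructureFile <- function(path, sequences, aligned = TRUE) {
  .assertFlag(aligned, "aligned")
  if (!file.exists(path))
    .err("formatError", sprintf("file not found: %s", path))
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0L || length(ln) %% 2L != 0L)
    .err("formatError", "structure file must alternate '>id' and structure lines")
  hdr <- ln[seq(1L, length(ln), by = 2L)]
  body <- trimws(ln[seq(2L, length(ln), by = 2L)])
  if (any(!startsWith(hdr, ">")))
    .err("formatError", "structure records must start with '>id'")
  ids <- sub("\\s.*$", "", sub("^>", "", hdr))
  if (anyDuplicated(ids))
    .err("formatError", "duplicate structure id(s)")
  seqs <- as.character(sequences)
  missing <- setdiff(ids, names(seqs))
  if (length(missing))
    .err("crossReferenceError",
         sprintf("structure id(s) without sequence: %s",
                 paste(missing, collapse = ", ")))
  for (k in seq_along(ids)) {
    .checkDotBracket(body[k], ids[k])
    sq <- seqs[[ids[k]]]
    want <- if (aligned) nchar(sq) else
      nchar(gsub("-", "", sq, fixed = TRUE))
    if (nchar(body[k]) != want)
      .err("structureError",
           sprintf("structure length %d for '%s' does not match %s length %d",
                   nchar(body[k]), ids[k],
                   if (aligned) "aligned" else "ungapped", want))
    if (aligned) {
      gapSeq <- gregexpr("-", sq, fixed = TRUE)[[1]]
      gapStr <- gregexpr("-", body[k], fixed = TRUE)[[1]]
      if (!identical(as.integer(gapSeq), as.integer(gapStr)))
        .err("structureError",
             sprintf("gap columns of structure '%s' do not match its sequence",
                     ids[k]))
    }
  }
  stats::setNames(body, ids)
}

#' @noRd
.checkDotBracket <- function(db, id) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  if (any(!ch %in% c("(", ")", ".", "-")))
    .err("structureError",
         sprintf("structure '%s' contains characters outside '().-'", id))
  depth <- cumsum((ch == "(") - (ch == ")"))
  if (any(depth < 0L) || depth[length(depth)] != 0L)
    .err("structureError", sprintf("unbalanced brackets in structure '%s'", id))
  invisible(TRUE)
}

#' Write structures as a Vienna-style dot-bracket file
#'
#' @param structures named character vector of dot-bracket strings.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStructureFile <- function(structures, path) {
  if (is.null(names(structures)))
    .err("usageError", "structures must be named")
  writeLines(paste0(">", names(structures), "\n", structures), path)
  invisible(path)
}

.HELIX_NAMES <- c("STEM", "HI", "HII", "HIII", "HIV")

#' Read a helix-annotation TSV
#'
#' Dot-bracket carries no helix names, so helices are annotated in a sidecar
#' TSV with columns \code{helix_name} (one of STEM, HI, HII, HIII, HIV),
#' \code{five_start}, \code{five_end}, \code{three_start}, \code{three_end}
#' (1-based inclusive alignment columns).  The 5' range of each helix must
#' lie entirely left of its 3' range, and ranges must not overlap across
#' helices.
#'
#' @param path path to the TSV.
#' @return data.frame with the five columns above.
#' @export
readHelixAnnotation <- function(path) {
  if (!file.exists(path))
    .err("formatError", sprintf("file not found: %s", path))
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateHelixAnnotation(a)
}

#' @rdname readHelixAnnotation
#' @param annotation a candidate annotation data.frame, validated and
#'   returned.
#' @export
validateHelixAnnotation <- function(annotation) {
  need <- c("helix_name", "five_start", "five_end", "three_start", "three_end")
  if (!all(need %in% names(annotation)))
    .err("formatError", sprintf("helix annotation needs columns: %s",
                                paste(need, collapse = ", ")))
  a <- annotation[, need]
  if (any(!a$helix_name %in% .HELIX_NAMES))
    .err("formatError", sprintf("helix_name must be one of %s",
                                paste(.HELIX_NAMES, collapse = ", ")))
  if (anyDuplicated(a$helix_name))
    .err("formatError", "duplicate helix_name rows")
  num <- as.matrix(a[, -1])
  if (any(is.na(num)) || any(num < 1) || any(num != round(num)))
    .err("formatError", "helix ranges must be positive integers")
  if (any(a$five_start > a$five_end) || any(a$three_start > a$three_end))
    .err("formatError", "helix range starts must not exceed ends")
  if (any(a$five_end >= a$three_start))
    .err("formatError", "each helix's 5' range must lie left of its 3' range")
  iv <- cbind(c(a$five_start, a$three_start), c(a$five_end, a$three_end))
  o <- order(iv[, 1])
  iv <- iv[o, , drop = FALSE]
  if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
    .err("formatError", "helix ranges overlap")
  a
}

#' @rdname readHelixAnnotation
#' @param path output path.
#' @export
writeHelixAnnotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialise a phylogenetic tree as Newick text
#'
#' Branch lengths are written at full double precision; leaf labels
#' containing Newick metacharacters are single-quoted (internal quotes
#' doubled), so any label survives a round trip through a conforming
#' Newick parser.
#'
#' @param tree an [ape::phylo] tree with at least two leaves and
#'   non-negative branch lengths.
#' @param path optional; when given, the text is also written to this file.
#' @return the Newick string.
#' @export
writeNewick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo"))
    .err("usageError", "tree must be an ape 'phylo' object")
  if (length(tree$tip.label) < 2L)
    .err("usageError", "tree must have at least 2 leaves")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    .err("usageError", "branch lengths must be >= 0")
  e <- tree$edge
  kids <- split(seq_len(nrow(e)), e[, 1])
  ntip <- length(tree$tip.label)
  fmt <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows))
      return(.quoteNewickLabel(tree$tip.label[node]))
    parts <- vapply(rows, function(r) {
      bl <- if (is.null(tree$edge.length)) "" else
        sprintf(":%.15g", tree$edge.length[r])
      paste0(fmt(e[r, 2]), bl)
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(fmt(ntip + 1L), ";")
  if (!is.null(path)) writeLines(txt, path)
  txt
}

#' @noRd
.quoteNewickLabel <- function(label) {
  if (grepl("[]()\\[{}:;,'\" \t]", label))
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  else label
}

#' Write a pairwise CBC/HCBC matrix as CSV
#'
#' One square table with CBC counts in the upper-right triangle and HCBC
#' counts in the lower-left, the customary published layout.
#'
#' @param x a [CbcMatrix-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCbcCsv <- function(x, path) {
  m <- as.matrix(x)
  utils::write.csv(data.frame(strain = rownames(m), m, check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a barcode table as TSV
#'
#' Columns: \code{strain_id}, \code{haplotype}, and the number-code series
#' as one contiguous digit string with \code{?} for unknown positions.
#'
#' @param barcodes a [BarcodeSet-class].
#' @param labels optional named character vector of haplotype labels
#'   (e.g. from [assignHaplotypes()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeBarcodeTable <- function(barcodes, path, labels = NULL) {
  m <- codeMatrix(barcodes)
  lab <- if (is.null(labels)) rep(NA_character_, nrow(m)) else
    unname(labels[rownames(m)])
  df <- data.frame(strain_id = rownames(m), haplotype = lab,
                   codes = apply(m, 1L, codeString),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode table written by [writeBarcodeTable()]
#'
#' @param path path to the TSV.
#' @return a [BarcodeSet-class]; haplotype labels, when present, are
#'   attached as the \code{"labels"} attribute.
#' @export
readBarcodeTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(codes = "character"))
  if (!all(c("strain_id", "codes") %in% names(df)))
    .err("formatError", "barcode table needs columns strain_id, codes")
  if (length(unique(nchar(df$codes))) > 1L)
    .err("formatError", "barcode code strings must share one length")
  m <- t(vapply(strsplit(df$codes, "", fixed = TRUE),
                function(ch) {
                  v <- suppressWarnings(as.integer(ch))
                  v[ch == "?"] <- NA_integer_
                  v
                }, integer(nchar(df$codes[1]))))
  rownames(m) <- df$strain_id
  bs <- new("BarcodeSet", codes = m)
  if ("haplotype" %in% names(df))
    attr(bs, "labels") <- stats::setNames(df$haplotype, df$strain_id)
  bs
}
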