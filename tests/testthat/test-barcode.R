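test_that("barcode extraction follows the 14/5/11/all quotas with padding", {
  panel <- simulateBarcodePanel()
  tables <- lapply(names(panel$structures), function(id)
    buildPairTable(as.character(panel$sequences[[id]]),
                   panel$structures[[id]], panel$annotation, strainId = id))
  cons <- consensusPairing(tables)
  pairs <- extractBarcodePairs(cons)
  expect_equal(nrow(pairs), 73L)
  expect_equal(as.vector(table(factor(pairs$helix,
                                      c("STEM", "HI", "HII", "HIII")))),
               c(14L, 5L, 11L, 43L))

  # short helices pad with gap placeholders that encode as 8
  tiny <- buildPairTable(tinySequence(), tinyStructure(), tinyAnnotation(),
                         strainId = "t")
  tp <- extractBarcodePairs(tiny)
  expect_equal(nrow(tp), 14L + 5L + 11L + 3L)
  hiBlock <- tp[tp$helix == "HI", ]
  expect_equal(hiBlock$status, c(rep("paired", 3), rep("gap", 2)))
  expect_equal(encodeBarcode(hiBlock), c(5L, 3L, 4L, 8L, 8L))

  noH3 <- buildPairTable("GCAAGC", "((..))", NULL, strainId = "s")
  expect_error(extractBarcodePairs(noH3), class = "annotationError")
})

test_that("the number code maps every pair type as published", {
  mk <- function(b5, b3, status = "paired")
    data.frame(status = status, fivePrimeBase = b5, threePrimeBase = b3,
               stringsAsFactors = FALSE)
  expect_equal(encodeBarcode(mk("A", "U")), 1L)
  expect_equal(encodeBarcode(mk("U", "A")), 2L)
  expect_equal(encodeBarcode(mk("G", "C")), 3L)
  expect_equal(encodeBarcode(mk("C", "G")), 4L)
  expect_equal(encodeBarcode(mk("G", "U")), 5L)
  expect_equal(encodeBarcode(mk("U", "G")), 6L)
  expect_equal(encodeBarcode(mk("A", "G")), 7L)   # mismatched pairing
  expect_equal(encodeBarcode(mk("C", "U")), 7L)   # pyrimidine-pyrimidine
  expect_equal(encodeBarcode(mk("A", "A", "unpaired")), 8L)
  expect_equal(encodeBarcode(mk("-", "-", "gap")), 8L)
  expect_true(is.na(encodeBarcode(mk("N", "U"))))  # ambiguity -> unknown
  expect_true(is.na(encodeBarcode(mk("A", "R"))))
})

test_that("codes 1-6 decode bijectively to ordered base pairs", {
  expect_equal(unname(codePairs()), 1:6)
  expect_equal(anyDuplicated(names(codePairs())), 0L)
  for (k in 1:6) {
    nt <- strsplit(names(codePairs())[k], "")[[1]]
    df <- data.frame(status = "paired", fivePrimeBase = nt[1],
                     threePrimeBase = nt[2], stringsAsFactors = FALSE)
    expect_equal(encodeBarcode(df), k)
  }
})

test_that("ambiguity letters in the sequence yield unknown codes end to end", {
  panel <- simulateBarcodePanel(barcodePanelSpec(seed = 3))
  s <- strsplit(as.character(panel$sequences[[1]]), "")[[1]]
  s[panel$layout$five[2]] <- "N"   # second stem pair now carries an N
  seqs <- Biostrings::RNAStringSet(c(panel$sequences,
    Biostrings::RNAStringSet(stats::setNames(paste(s, collapse = ""),
                                             "mutant"))))
  structures <- c(panel$structures,
                  stats::setNames(panel$structures[[1]], "mutant"))
  bs <- computeBarcodes(seqs, structures, panel$annotation)
  expect_true(is.na(codeMatrix(bs)["mutant", 2]))
  expect_false(anyNA(codeMatrix(bs)[names(panel$structures), ]))
})

test_that("haplotype labels follow first-occurrence order and share on identity", {
  bs <- barcodeSet(list(x = c(1L, 2L, 3L), y = c(1L, 2L, 3L)))
  lab <- assignHaplotypes(bs, c(x = "SP1", y = "SP1"))
  expect_equal(unname(lab), c("BC-1", "BC-1"))

  bs2 <- barcodeSet(list(x = c(1L, 2L, 3L), y = c(1L, 2L, 8L),
                         z = c(1L, 2L, 3L)))
  lab2 <- assignHaplotypes(bs2, c(x = "SP1", y = "SP1", z = "SP1"))
  expect_equal(unname(lab2), c("BC-1a", "BC-1b", "BC-1a"))

  bs3 <- barcodeSet(list(a = c(1L, 1L), b = c(2L, 2L), c = c(3L, 3L)))
  lab3 <- assignHaplotypes(bs3, c(a = "S1", b = "S2", c = "S3"))
  expect_equal(unname(lab3), c("BC-1", "BC-2", "BC-3"))

  expect_error(assignHaplotypes(bs, c(x = "SP1")),
               class = "crossReferenceError")
})

test_that("relabeling input order permutes label numbers, never membership", {
  panel <- simulateBarcodePanel(barcodePanelSpec(seed = 9))
  bs <- panel$codes
  part <- delimitSpecies(cbcHcbcMatrix(bs))
  lab <- assignHaplotypes(bs, part)
  perm <- rev(strainIds(bs))
  bsRev <- bs[perm]
  labRev <- assignHaplotypes(bsRev, part)
  # same grouping: two strains share a label before iff they share one after
  for (i in strainIds(bs)) for (j in strainIds(bs))
    expect_equal(lab[[i]] == lab[[j]], labRev[[i]] == labRev[[j]])
})
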