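test_that("region extraction slices inclusive column intervals", {
  aln <- randomAlignedRna(3, 10, seed = 1)
  reg <- extractAlignmentRegion(aln, c(5L, 8L))
  expect_equal(unique(Biostrings::width(reg$aligned)), 4L)

  wide <- randomAlignedRna(2, 1800, seed = 2)
  expect_equal(unique(Biostrings::width(
    extractAlignmentRegion(wide, defaultRegions()$V4)$aligned)), 230L)
  expect_equal(unique(Biostrings::width(
    extractAlignmentRegion(wide, defaultRegions()$V9)$aligned)), 107L)

  expect_error(extractAlignmentRegion(aln, c(8L, 12L)), class = "usageError")
})

test_that("region extraction strips gaps from the ungapped copies", {
  aln <- Biostrings::RNAStringSet(c(a = "AC-GUA", b = "ACGG-A"))
  reg <- extractAlignmentRegion(aln, c(2L, 5L))
  expect_equal(as.character(reg$aligned), c(a = "C-GU", b = "CGG-"))
  expect_equal(as.character(reg$ungapped), c(a = "CGU", b = "CGG"))
})

test_that("global identity and coverage behave like a strict BLAST criterion", {
  set.seed(3)
  r <- paste(sample(c("A", "C", "G", "U"), 100, TRUE), collapse = "")
  self <- globalIdentity(r, r)
  expect_equal(self$identity, 100)
  expect_equal(self$coverage, 100)

  q <- strsplit(r, "")[[1]]
  for (p in c(10, 50, 90)) q[p] <- setdiff(c("A", "C", "G", "U"), q[p])[1]
  three <- globalIdentity(paste(q, collapse = ""), r)
  expect_equal(three$identity, 97)

  prefix <- globalIdentity(substr(r, 1, 50), r)
  expect_equal(prefix$identity, 100)
  expect_equal(prefix$coverage, 100)   # the query itself is fully aligned
  expect_true(prefix$partial)          # but flagged partial vs the reference

  amb <- globalIdentity(paste0("N", substr(r, 2, 100)), r)
  expect_equal(amb$identity, 99)       # ambiguity counts as mismatch

  expect_error(globalIdentity("", r), class = "usageError")
})

test_that("identity with itself is 100 percent for random sequences", {
  set.seed(4)
  for (len in c(20, 57, 200)) {
    s <- paste(sample(c("A", "C", "G", "U"), len, TRUE), collapse = "")
    expect_equal(globalIdentity(s, s)$identity, 100)
  }
})

test_that("query classification follows the guideline rules", {
  panel <- simulateBarcodePanel(barcodePanelSpec(seed = 5))
  refs <- list(sequences = panel$sequences, barcodes = panel$codes)

  # exact copy: species level
  q <- stats::setNames(as.character(panel$sequences[[1]]), "q")
  hit <- classifyQuery(q, refs, queryBarcode = codeMatrix(panel$codes)[1, ])
  expect_equal(hit$classification, "species_match")
  expect_equal(hit$identity, 100)

  # high identity, zero CBCs: same-species candidate
  qs <- simulateQuerySet(panel, identities = 98, seed = 6)
  hit2 <- classifyQuery(
    stats::setNames(as.character(qs$queries[[1]]), "q2"), refs,
    queryBarcode = codeMatrix(qs$queryBarcodes)[1, ])
  expect_equal(hit2$classification, "same_species_candidate")

  # high identity, planted CBC vs every species: putative new lineage
  qc <- simulateQuerySet(panel, identities = 98, plantCbc = TRUE, seed = 7)
  hit3 <- classifyQuery(
    stats::setNames(as.character(qc$queries[[1]]), "q3"), refs,
    queryBarcode = codeMatrix(qc$queryBarcodes)[1, ])
  expect_equal(hit3$classification, "putative_new_lineage")
  expect_gte(hit3$cbc_count, 1L)

  # V4-only evidence below the strict cutoff resolves the genus only
  qv <- simulateQuerySet(panel, identities = 97.5, seed = 8)
  hit4 <- classifyQuery(
    stats::setNames(as.character(qv$queries[[1]]), "q4"), refs,
    queryBarcode = codeMatrix(qv$queryBarcodes)[1, ], marker = "V4")
  expect_equal(hit4$classification, "genus_level_only")

  # far below the identity floor: unassigned
  qu <- simulateQuerySet(panel, identities = 90, seed = 9)
  hit5 <- classifyQuery(
    stats::setNames(as.character(qu$queries[[1]]), "q5"), refs,
    queryBarcode = codeMatrix(qu$queryBarcodes)[1, ])
  expect_equal(hit5$classification, "unassigned")

  expect_error(classifyQuery(q, refs,
                             thresholds = list(minIdentity = 0,
                                               v4Strict = 99)),
               class = "usageError")
})

test_that("classification never demotes as identity rises", {
  rank <- function(cl) match(cl, c("unassigned", "genus_level_only",
                                   "same_species_candidate",
                                   "species_match"))
  panel <- simulateBarcodePanel(barcodePanelSpec(seed = 10))
  refs <- list(sequences = panel$sequences, barcodes = panel$codes)
  targets <- c(90, 95, 97, 98, 99.5, 100)
  qs <- simulateQuerySet(panel, identities = targets, seed = 11)
  cls <- vapply(seq_along(targets), function(k) {
    classifyQuery(stats::setNames(as.character(qs$queries[[k]]), "q"),
                  refs,
                  queryBarcode = codeMatrix(qs$queryBarcodes)[k, ]
                  )$classification
  }, character(1))
  expect_true(all(diff(rank(cls)) >= 0))
})

test_that("simulated query panels match their truth classes exactly", {
  panel <- simulateBarcodePanel(barcodePanelSpec(seed = 12))
  refs <- list(sequences = panel$sequences, barcodes = panel$codes)
  qs <- simulateQuerySet(panel, identities = c(100, 99.5, 98, 97, 90),
                         seed = 13)
  hits <- screenQueries(qs$queries, refs, queryBarcodes = qs$queryBarcodes)
  expect_identical(hits$classification, qs$truth$expected_class)
  expect_equal(hits$identity, qs$truth$achieved_identity, tolerance = 1e-9)
})
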