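test_that("bracket matching yields ordered base pairs with sequence bases", {
  pt <- buildPairTable("GCAAGC", "((..))", NULL, strainId = "s1")
  p <- basePairs(pt)
  paired <- p[p$status == "paired", ]
  expect_equal(paired$fivePrimePos, c(1L, 2L))
  expect_equal(paired$threePrimePos, c(6L, 5L))
  expect_equal(paired$fivePrimeBase, c("G", "C"))
  expect_equal(paired$threePrimeBase, c("C", "G"))

  empty <- buildPairTable("GCAAGC", "......", NULL, strainId = "s1")
  expect_equal(sum(basePairs(empty)$status == "paired"), 0L)
})

test_that("helix labels come from the annotation and split pairs are errors", {
  pt <- buildPairTable(tinySequence(), tinyStructure(), tinyAnnotation(),
                       strainId = "t")
  p <- basePairs(pt)
  expect_equal(sum(p$helix %in% "STEM"), 4L)
  expect_equal(sum(p$helix %in% "HI"), 3L)
  expect_equal(sum(p$helix %in% "HII"), 2L)
  expect_equal(sum(p$helix %in% "HIII"), 3L)

  # a pair whose 5' side is annotated but whose 3' side is not
  ann <- data.frame(helix_name = "HI", five_start = 1L, five_end = 2L,
                    three_start = 4L, three_end = 4L,
                    stringsAsFactors = FALSE)
  expect_error(buildPairTable("GCAAGC", "((..))", ann, strainId = "s"),
               class = "annotationError")
})

test_that("pair tables regenerate their dot-bracket exactly", {
  panel <- simulateBarcodePanel(barcodePanelSpec(seed = 11))
  for (id in names(panel$structures)[c(1, 5, 12)]) {
    pt <- buildPairTable(as.character(panel$sequences[[id]]),
                         panel$structures[[id]], panel$annotation,
                         strainId = id)
    expect_identical(pairTableToDotBracket(pt), unname(panel$structures[[id]]))
  }
})

test_that("consensus pairing applies the threshold with ties retained", {
  mk <- function(db) buildPairTable(tinySequence(), db, tinyAnnotation(),
                                    strainId = "x")
  full <- tinyStructure()
  # drop the innermost HIII pair (cols 23, 26)
  ch <- strsplit(full, "")[[1]]
  ch[c(23, 26)] <- "."
  dropped <- paste(ch, collapse = "")

  t1 <- mk(full); t2 <- mk(full); t3 <- mk(dropped)
  consAll <- consensusPairing(list(t1, t1, t1), threshold = 0.5)
  expect_identical(pairTableToDotBracket(consAll), full)

  cons23 <- consensusPairing(list(t1, t2, t3), threshold = 0.5)
  expect_identical(pairTableToDotBracket(cons23), full)   # 2/3 >= 0.5 kept

  cons13 <- consensusPairing(list(t1, t3, t3), threshold = 0.5)
  expect_identical(pairTableToDotBracket(cons13), dropped) # 1/3 < 0.5 dropped

  # exact tie at the threshold is retained
  consTie <- consensusPairing(list(t1, t3), threshold = 0.5)
  expect_identical(pairTableToDotBracket(consTie), full)
})

test_that("consensus is idempotent and anti-monotone in the threshold", {
  panel <- simulateBarcodePanel(barcodePanelSpec(seed = 7))
  tables <- lapply(names(panel$structures), function(id)
    buildPairTable(as.character(panel$sequences[[id]]),
                   panel$structures[[id]], panel$annotation, strainId = id))
  cons <- consensusPairing(tables, threshold = 0.5)
  again <- consensusPairing(list(cons), threshold = 0.5)
  expect_identical(pairTableToDotBracket(again), pairTableToDotBracket(cons))

  nPairs <- vapply(c(0.1, 0.3, 0.5, 0.8, 1), function(th) {
    p <- basePairs(consensusPairing(tables, threshold = th))
    sum(p$status == "paired")
  }, numeric(1))
  expect_true(all(diff(nPairs) <= 0))
})

test_that("tables on different alignment axes are rejected", {
  t1 <- buildPairTable("GCAAGC", "((..))", NULL, strainId = "a")
  t2 <- buildPairTable("GCAAAGC", "((...))", NULL, strainId = "b")
  expect_error(consensusPairing(list(t1, t2)), class = "crossReferenceError")
})
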