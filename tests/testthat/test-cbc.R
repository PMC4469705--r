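# Independent oracle: expand each code in 1..6 to its ordered nucleotide
# pair and count differing partners.
.oraclePairs <- c(`1` = "AU", `2` = "UA", `3` = "GC", `4` = "CG",
                  `5` = "GU", `6` = "UG")
oracleClassify <- function(a, b) {
  if (identical(a, b)) return("identical")
  pa <- strsplit(.oraclePairs[[as.character(a)]], "")[[1]]
  pb <- strsplit(.oraclePairs[[as.character(b)]], "")[[1]]
  nd <- sum(pa != pb)
  if (nd == 2) "CBC" else "HCBC"
}

test_that("classifier agrees with nucleotide expansion on all 36 code pairs", {
  for (a in 1:6) for (b in 1:6)
    expect_identical(classifyCodePair(a, b), oracleClassify(a, b),
                     label = sprintf("codes (%d,%d)", a, b))
})

test_that("codes 7, 8 and unknown are never CBC or HCBC", {
  expect_identical(classifyCodePair(7, 7), "identical")
  expect_identical(classifyCodePair(8, 8), "identical")
  for (x in c(1:6, 8)) expect_identical(classifyCodePair(7, x)[x != 7],
                                        "not_comparable")
  for (x in c(1:6, 7)) expect_identical(classifyCodePair(8, x)[x != 8],
                                        "not_comparable")
  expect_identical(classifyCodePair(NA, 1), "not_comparable")
  expect_identical(classifyCodePair(NA, NA), "not_comparable")
  expect_error(classifyCodePair(9, 1), class = "usageError")
})

test_that("classification is symmetric in its arguments", {
  codes <- c(1:8, NA)
  for (a in codes) for (b in codes)
    expect_identical(classifyCodePair(a, b), classifyCodePair(b, a))
})

test_that("CBC/HCBC matrices count classified positions and stay symmetric", {
  bs <- barcodeSet(list(a = c(1L, 3L, 8L, 7L, NA),
                        b = c(2L, 5L, 8L, 7L, 4L),
                        c = c(1L, 3L, 8L, 7L, NA)))
  cm <- cbcHcbcMatrix(bs)
  expect_equal(cbcCounts(cm)["a", "b"], 1L)   # 1 vs 2
  expect_equal(hcbcCounts(cm)["a", "b"], 1L)  # 3 vs 5
  expect_equal(cbcCounts(cm)["a", "c"], 0L)
  expect_equal(diag(cbcCounts(cm)), c(a = 0L, b = 0L, c = 0L))
  expect_identical(cbcCounts(cm), t(cbcCounts(cm)))

  # upper = CBC, lower = HCBC in the combined layout
  m <- as.matrix(cm)
  expect_equal(m["a", "b"], 1L)
  expect_equal(m["b", "a"], 1L)

  # reordering strains permutes rows/columns only
  cm2 <- cbcHcbcMatrix(bs[c("c", "a", "b")])
  expect_identical(cbcCounts(cm2)[c("a", "b", "c"), c("a", "b", "c")],
                   cbcCounts(cm))
})

test_that("counts never increase when a barcode position is removed", {
  panel <- simulateBarcodePanel(barcodePanelSpec(seed = 21))
  full <- cbcHcbcMatrix(panel$codes)
  m <- codeMatrix(panel$codes)
  for (drop in c(1L, 20L, 73L)) {
    sub <- cbcHcbcMatrix(barcodeSet(m[, -drop]))
    expect_true(all(cbcCounts(sub) <= cbcCounts(full)))
    expect_true(all(hcbcCounts(sub) <= hcbcCounts(full)))
  }
})

test_that("species delimitation splits on any CBC and merges zero-CBC chains", {
  # all pairs separated
  bsAll <- barcodeSet(list(a = c(1L, 1L), b = c(2L, 1L), c = c(3L, 1L)))
  pAll <- delimitSpecies(bsAll)
  expect_equal(length(pAll), 3L)

  # non-transitive zero-CBC triple: merged and flagged
  mkMat <- function(cbc) {
    dimnames(cbc) <- list(c("a", "b", "c"), c("a", "b", "c"))
    new("CbcMatrix", cbc = cbc, hcbc = matrix(0L, 3, 3, dimnames = dimnames(cbc)))
  }
  cbc <- matrix(0L, 3, 3)
  cbc[1, 3] <- cbc[3, 1] <- 1L
  part <- delimitSpecies(mkMat(cbc))
  expect_equal(length(part), 1L)
  expect_equal(nrow(conflictFlags(part)), 1L)
  expect_setequal(unlist(conflictFlags(part)[1, c("a", "c")]), c("a", "c"))
  expect_equal(conflictFlags(part)$b, "b")
})

test_that("p-distance excludes gap and ambiguity columns pairwise", {
  d <- pDistanceMatrix(c(a = "ACGUACGUAC", b = "ACGUACGUAC"))
  expect_equal(d["a", "b"], 0)
  d2 <- pDistanceMatrix(c(a = "ACGUACGUAC", b = "ACGUACGUAG"))
  expect_equal(d2["a", "b"], 0.1)
  # gap column drops out of numerator and denominator
  d3 <- pDistanceMatrix(c(a = "ACGUACGUA-", b = "ACGUACGUAG"))
  expect_equal(d3["a", "b"], 0)
  d4 <- pDistanceMatrix(c(a = "NCGUACGUAA", b = "ACGUACGUAG"))
  expect_equal(d4["a", "b"], 1 / 9)
  expect_error(pDistanceMatrix(c(a = "----", b = "AAAA")),
               class = "undefinedDistanceError")
})

test_that("p-distance matches ape's raw pairwise-deletion distance", {
  seqs <- randomAlignedRna(6, 200, seed = 5)
  ours <- pDistanceMatrix(seqs)
  dna <- ape::as.DNAbin(lapply(strsplit(chartr("U", "T",
                                               as.character(seqs)), ""),
                               identity))
  theirs <- as.matrix(ape::dist.dna(dna, model = "raw",
                                    pairwise.deletion = TRUE))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("K/theta reports ratios with guards for undefined cases", {
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 0.02
  D["c", "d"] <- D["d", "c"] <- 0.02
  for (i in c("a", "b")) for (j in c("c", "d"))
    D[i, j] <- D[j, i] <- 0.08
  kt <- kOverTheta(list(X = c("a", "b"), Y = c("c", "d")), D)
  row <- kt[kt$reference == "X" & kt$other == "Y", ]
  expect_equal(row$K, 0.08)
  expect_equal(row$theta, 0.02)
  expect_equal(row$ratio, 4)
  expect_true(row$candidate)   # ties at the threshold flag

  # zero within-block diversity -> undefined, not an error
  D0 <- D; D0["a", "b"] <- D0["b", "a"] <- 0
  kt0 <- kOverTheta(list(X = c("a", "b"), Y = c("c", "d")), D0)
  expect_true(is.na(kt0$ratio[kt0$reference == "X" & kt0$other == "Y"]))
  # singleton reference block likewise
  kt1 <- kOverTheta(list(X = "a", Y = c("c", "d")), D)
  expect_true(is.na(kt1$ratio[kt1$reference == "X"][1]))
})

test_that("planted 10x divergence clears the K/theta threshold", {
  seqs <- twoPopulationSeqs(nPer = 4, len = 400, nDiv = 40, nPoly = 4,
                            seed = 2)
  D <- pDistanceMatrix(seqs)
  part <- list(A = paste0("A", 1:4), B = paste0("B", 1:4))
  kt <- kOverTheta(part, D)
  expect_true(all(kt$ratio > 4))
})
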