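# Small fixtures built in code; nothing is read from disk except what a
# test itself writes to tempfiles.

writeTempFasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(records), "\n", records), path)
  path
}

writeTempLines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A minimal annotated molecule: 4-pair stem around a 3-pair Helix I, a
# 2-pair Helix II, a 3-pair Helix III hairpin.  Columns:
#  1-4   stem 5'          29-32 stem 3'
#  5     spacer
#  6-8   HI 5', 9-11 loop, 12-14 HI 3'
#  15-16 HII 5', 17-18 loop, 19-20 HII 3'
#  21-23 HIII 5', 24-25 loop, 26-28 HIII 3'
tinyAnnotation <- function() {
  data.frame(
    helix_name = c("STEM", "HI", "HII", "HIII"),
    five_start = c(1L, 6L, 15L, 21L),
    five_end   = c(4L, 8L, 16L, 23L),
    three_start = c(29L, 12L, 19L, 26L),
    three_end   = c(32L, 14L, 20L, 28L),
    stringsAsFactors = FALSE)
}

tinyStructure <- function() {
  paste0("((((", ".", "(((", "...", ")))", "((", "..", "))",
         "(((", "..", ")))", "))))")
}

tinySequence <- function() {
  # complements chosen so every pair is canonical (codes 1..6)
  s <- rep("A", 32)
  put <- function(i, v) s[i] <<- v
  stem5 <- c("G", "C", "A", "U"); stem3 <- c("A", "U", "G", "C")
  s[1:4] <- stem5; s[29:32] <- stem3
  s[5] <- "A"
  s[6:8] <- c("G", "G", "C"); s[12:14] <- c("G", "C", "U")
  s[9:11] <- c("A", "A", "A")
  s[15:16] <- c("A", "U"); s[19:20] <- c("A", "U")
  s[17:18] <- c("C", "C")
  s[21:23] <- c("G", "U", "C"); s[26:28] <- c("G", "A", "C")
  s[24:25] <- c("A", "A")
  paste(s, collapse = "")
}

# Random gap-free aligned RNA sequences for distance cross-checks
randomAlignedRna <- function(n, len, seed) {
  set.seed(seed)
  s <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = ""),
    character(1))
  names(s) <- paste0("s", seq_len(n))
  Biostrings::RNAStringSet(s)
}

# Two-population aligned sequences: population B differs from A's ancestor
# at `nDiv` fixed columns; within-population noise at `nPoly` private
# columns per sequence.
twoPopulationSeqs <- function(nPer = 4, len = 400, nDiv = 40, nPoly = 4,
                              seed = 1) {
  set.seed(seed)
  alphabet <- c("A", "C", "G", "U")
  anc <- sample(alphabet, len, replace = TRUE)
  ancB <- anc
  divCols <- sample(len, nDiv)
  for (p in divCols) ancB[p] <- sample(setdiff(alphabet, ancB[p]), 1)
  mk <- function(base, label) {
    out <- list()
    for (i in seq_len(nPer)) {
      s <- base
      for (p in sample(setdiff(seq_len(len), divCols), nPoly))
        s[p] <- sample(setdiff(alphabet, s[p]), 1)
      out[[paste0(label, i)]] <- paste(s, collapse = "")
    }
    out
  }
  seqs <- c(mk(anc, "A"), mk(ancB, "B"))
  Biostrings::RNAStringSet(unlist(seqs))
}

# Random additive distance matrix from a random tree with positive branches
randomAdditiveMatrix <- function(ntaxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntaxa, br = function(k) stats::runif(k, 0.05, 1))
  list(tree = ape::unroot(tr), D = stats::cophenetic(tr))
}
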