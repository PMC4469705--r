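#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards, so simulators are pure
#' functions of spec + seed.
#'
#' @param seed integer seed.
#' @param expr expression.
#' @return value of \code{expr}.
#' @keywords internal
#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sample() treats a length-1 vector as a range; this never does
.pick1 <- function(x) x[sample.int(length(x), 1L)]

#' Specification of a synthetic ITS-2 barcode panel
#'
#' Defaults mirror the study-scale panel: seven species whose variant
#' counts (3, 1, 3, 1, 1, 1, 2) give twelve haplotypes, helix geometry
#' 14/5/11/43 (a 73-position barcode), one planted CBC and one planted
#' HCBC position private to each species, and two code-8 edits per extra
#' within-species variant.  Because planted positions are private and
#' disjoint, the truth CBC count between species i and j is simply
#' \code{cbcPerSpecies[i] + cbcPerSpecies[j]} (and likewise for HCBCs),
#' independent of the classifier under test.
#'
#' @param nSpecies number of species.
#' @param variantsPerSpecies integer vector (recycled) of haplotype
#'   variants per species.
#' @param strainsPerVariant strains sampled per haplotype variant.
#' @param cbcPerSpecies,hcbcPerSpecies planted private CBC / HCBC positions
#'   per species (recycled); between-species CBC counts are pairwise sums.
#' @param variantEdits code-8 positions distinguishing each extra variant.
#' @param geometry named integer vector: pairs in the 5.8S/LSU stem and
#'   Helices I-III.
#' @param mismatchPairInHII which Helix II pair carries the
#'   pyrimidine-pyrimidine mismatch (coded 7).
#' @param seed integer seed.
#' @return list of class \code{"panelSpec"}.
#' @export
barcodePanelSpec <- function(nSpecies = 7L,
                             variantsPerSpecies = c(3L, 1L, 3L, 1L, 1L, 1L, 2L),
                             strainsPerVariant = 1L,
                             cbcPerSpecies = 1L,
                             hcbcPerSpecies = 1L,
                             variantEdits = 2L,
                             geometry = c(STEM = 14L, HI = 5L, HII = 11L,
                                          HIII = 43L),
                             mismatchPairInHII = 4L,
                             seed = 1L) {
  spec <- list(
    nSpecies = as.integer(nSpecies),
    variantsPerSpecies = rep_len(as.integer(variantsPerSpecies), nSpecies),
    strainsPerVariant = as.integer(strainsPerVariant),
    cbcPerSpecies = rep_len(as.integer(cbcPerSpecies), nSpecies),
    hcbcPerSpecies = rep_len(as.integer(hcbcPerSpecies), nSpecies),
    variantEdits = as.integer(variantEdits),
    geometry = geometry,
    mismatchPairInHII = as.integer(mismatchPairInHII),
    seed = as.integer(seed))
  class(spec) <- "panelSpec"
  spec
}

# CBC / HCBC partner sets of each canonical code, from the code -> ordered
# nucleotide pair map: a CBC partner differs in both nucleotides, an HCBC
# partner in exactly one, with pairing retained (both codes stay in 1..6).
.partnerSets <- local({
  pairs <- strsplit(names(.CODE_PAIRS), "")
  cbc <- hcbc <- vector("list", 6)
  for (a in 1:6) for (b in 1:6) {
    if (a == b) next
    nd <- sum(pairs[[a]] != pairs[[b]])
    if (nd == 2) cbc[[a]] <- c(cbc[[a]], b) else hcbc[[a]] <- c(hcbc[[a]], b)
  }
  list(cbc = cbc, hcbc = hcbc)
})

#' Simulate a barcode panel with planted CBC structure
#'
#' Generates aligned ITS-2-like sequences (a 14-pair closing stem, Helix I,
#' Helix II carrying a pyrimidine-pyrimidine mismatch, Helix III, random
#' loops and spacers), per-strain dot-bracket structures, the helix
#' annotation, and truth tables (species membership, haplotype labels and
#' pairwise planted CBC/HCBC counts).  Deterministic under
#' \code{spec$seed}.
#'
#' @param spec a [barcodePanelSpec()].
#' @param dir optional directory; when given, FASTA, structure, helix-TSV
#'   and truth TSV files are written there.
#' @return list: \code{sequences} ([Biostrings::RNAStringSet]),
#'   \code{structures}, \code{annotation}, \code{codes} (truth
#'   [BarcodeSet-class]), \code{truth} (list with \code{strains},
#'   \code{speciesCbc}, \code{speciesHcbc}, \code{strainCbc},
#'   \code{strainHcbc}), and \code{layout} (column bookkeeping).
#'
#' @section Errors: more planted positions than available barcode positions
#'   signal a \code{specError}.
#' @export
simulateBarcodePanel <- function(spec = barcodePanelSpec(), dir = NULL) {
  g <- spec$geometry
  L <- sum(g)
  mmPos <- g[["STEM"]] + g[["HI"]] + spec$mismatchPairInHII
  avail <- setdiff(seq_len(L), mmPos)
  needVariant <- sum(pmax(spec$variantsPerSpecies - 1L, 0L)) * spec$variantEdits
  need <- sum(spec$cbcPerSpecies) + sum(spec$hcbcPerSpecies) + needVariant
  if (need > length(avail))
    .err("specError",
         sprintf("spec plants %d positions but only %d are available",
                 need, length(avail)))
  .withSeed(spec$seed, {
    pool <- sample(avail)
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    cbcPos <- lapply(spec$cbcPerSpecies, take)
    hcbcPos <- lapply(spec$hcbcPerSpecies, take)
    editPos <- lapply(seq_len(spec$nSpecies), function(i) {
      extra <- max(spec$variantsPerSpecies[i] - 1L, 0L)
      lapply(seq_len(extra), function(v) take(spec$variantEdits))
    })

    baseCodes <- sample(1:6, L, replace = TRUE)
    baseCodes[mmPos] <- 7L

    speciesCodes <- lapply(seq_len(spec$nSpecies), function(i) {
      cod <- baseCodes
      for (p in cbcPos[[i]])
        cod[p] <- .pick1(.partnerSets$cbc[[cod[p]]])
      for (p in hcbcPos[[i]])
        cod[p] <- .pick1(.partnerSets$hcbc[[cod[p]]])
      cod
    })

    strains <- NULL
    codes <- list()
    for (i in seq_len(spec$nSpecies)) {
      nv <- spec$variantsPerSpecies[i]
      for (v in seq_len(nv)) {
        cod <- speciesCodes[[i]]
        if (v > 1L) cod[editPos[[i]][[v - 1L]]] <- 8L
        letter <- if (nv == 1L) "" else letters[v]
        for (s in seq_len(spec$strainsPerVariant)) {
          id <- sprintf("SP%d%s%s", i, letter,
                        if (spec$strainsPerVariant > 1L)
                          sprintf("_%d", s) else "")
          codes[[id]] <- cod
          strains <- rbind(strains, data.frame(
            strain_id = id, species = i, variant = letter,
            haplotype = paste0("BC-", i, letter), stringsAsFactors = FALSE))
        }
      }
    }

    # -- realize sequences and structures ------------------------------
    layout <- .panelLayout(g)
    spacerBases <- sample(c("A", "C", "G", "U"), layout$total,
                          replace = TRUE)   # backbone for unpaired columns
    mmBases <- sample(list(c("C", "U"), c("U", "C"), c("U", "U"),
                           c("C", "C")), 1L)[[1]]
    pairChars <- strsplit(names(.CODE_PAIRS), "")
    seqs <- chars <- list()
    for (id in names(codes)) {
      sq <- spacerBases
      db <- rep(".", layout$total)
      cod <- codes[[id]]
      for (p in seq_len(L)) {
        c5 <- layout$five[p]; c3 <- layout$three[p]
        if (cod[p] == 8L) {
          # variant edit: keep the species' nucleotides, lose the pairing
          ref <- speciesCodes[[strains$species[strains$strain_id == id][1]]][p]
          nt <- if (ref == 7L) mmBases else pairChars[[ref]]
          sq[c5] <- nt[1]; sq[c3] <- nt[2]
        } else {
          nt <- if (cod[p] == 7L) mmBases else pairChars[[cod[p]]]
          sq[c5] <- nt[1]; sq[c3] <- nt[2]
          db[c5] <- "("; db[c3] <- ")"
        }
      }
      seqs[[id]] <- paste(sq, collapse = "")
      chars[[id]] <- paste(db, collapse = "")
    }
    sequences <- Biostrings::RNAStringSet(unlist(seqs))
    structures <- unlist(chars)

    # -- truth tables ---------------------------------------------------
    nC <- spec$cbcPerSpecies
    nH <- spec$hcbcPerSpecies
    speciesCbc <- outer(nC, nC, "+")
    speciesHcbc <- outer(nH, nH, "+")
    diag(speciesCbc) <- diag(speciesHcbc) <- 0L
    dimnames(speciesCbc) <- dimnames(speciesHcbc) <-
      list(paste0("SP", seq_len(spec$nSpecies)),
           paste0("SP", seq_len(spec$nSpecies)))
    sIdx <- strains$species
    strainCbc <- speciesCbc[sIdx, sIdx]
    strainHcbc <- speciesHcbc[sIdx, sIdx]
    dimnames(strainCbc) <- dimnames(strainHcbc) <-
      list(strains$strain_id, strains$strain_id)

    out <- list(
      sequences = sequences,
      structures = structures,
      annotation = layout$annotation,
      codes = barcodeSet(codes),
      truth = list(strains = strains, speciesCbc = speciesCbc,
                   speciesHcbc = speciesHcbc, strainCbc = strainCbc,
                   strainHcbc = strainHcbc),
      layout = layout,
      spec = spec)
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      writeFasta(sequences, file.path(dir, "panel.fasta"))
      writeStructureFile(structures, file.path(dir, "panel.dbn"))
      writeHelixAnnotation(layout$annotation, file.path(dir, "helices.tsv"))
      utils::write.table(strains, file.path(dir, "truth_strains.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeBarcodeTable(out$codes, file.path(dir, "truth_barcodes.tsv"),
                        labels = stats::setNames(strains$haplotype,
                                                 strains$strain_id))
    }
    out
  })
}

#' @noRd
.panelLayout <- function(g) {
  loop <- 4L; spacer <- 4L
  stem <- g[["STEM"]]; hi <- g[["HI"]]; hii <- g[["HII"]]; hiii <- g[["HIII"]]
  # columns: [stem5][sp][hi5 loop hi3][sp][hii5 loop hii3][sp]
  #          [hiii5 loop hiii3][sp][stem3]
  cur <- 0L
  adv <- function(k) {
    out <- (cur + 1L):(cur + k)
    cur <<- cur + k
    out
  }
  stem5 <- adv(stem); adv(spacer)
  hi5 <- adv(hi); adv(loop); hi3 <- adv(hi); adv(spacer)
  hii5 <- adv(hii); adv(loop); hii3 <- adv(hii); adv(spacer)
  hiii5 <- adv(hiii); adv(loop); hiii3 <- adv(hiii); adv(spacer)
  stem3 <- adv(stem)
  total <- cur
  # barcode position p -> 5'/3' columns, base-outward within each helix
  five <- c(stem5, hi5, hii5, hiii5)
  three <- c(rev(stem3), rev(hi3), rev(hii3), rev(hiii3))
  annotation <- data.frame(
    helix_name = c("STEM", "HI", "HII", "HIII"),
    five_start = c(stem5[1], hi5[1], hii5[1], hiii5[1]),
    five_end = c(stem5[stem], hi5[hi], hii5[hii], hiii5[hiii]),
    three_start = c(stem3[1], hi3[1], hii3[1], hiii3[1]),
    three_end = c(stem3[stem], hi3[hi], hii3[hii], hiii3[hiii]),
    stringsAsFactors = FALSE)
  annotation <- annotation[order(annotation$five_start), ]
  list(five = five, three = three, total = total, annotation = annotation)
}

#' Specification of synthetic growth curves
#'
#' Defaults emulate the growth-experiment design: six salinities (0.2 to
#' 3.3\% NaCl), four replicates, fluorescence read every 24 h for 10 days,
#' multiplicative lognormal noise of 5\%.  The default strain panel plants
#' one highly sensitive reference-like strain, one sensitive, one
#' intermediate and one robust rate profile.
#'
#' @param profiles named list: per-strain vector of per-day growth rates
#'   over the salinity panel.
#' @param noiseSigma lognormal sigma of the multiplicative noise.
#' @param replicates replicate curves per strain and salinity.
#' @param timeGrid_h observation times in hours.
#' @param n0 initial fluorescence (arbitrary units).
#' @param seed integer seed.
#' @return list of class \code{"growthSpec"}.
#' @export
growthCurveSpec <- function(
    profiles = list(
      REFSENS = c(1.20, 1.00, 0.40, 0.10, 0.05, 0.02),
      SENS2   = c(1.10, 0.90, 0.50, 0.25, 0.18, 0.10),
      INT1    = c(1.00, 0.95, 0.80, 0.55, 0.48, 0.42),
      ROB1    = c(0.85, 0.86, 0.84, 0.82, 0.79, 0.76)),
    noiseSigma = 0.05,
    replicates = 4L,
    timeGrid_h = seq(0, 216, by = 24),
    n0 = 100,
    seed = 1L) {
  if (!length(timeGrid_h))
    .err("specError", "time grid must be non-empty")
  if (any(vapply(profiles, length, integer(1)) !=
          length(salinityPanel()$all)))
    .err("specError", "each profile needs one rate per panel salinity")
  if (any(unlist(profiles) < 0))
    .err("specError", "planted rates must be >= 0")
  spec <- list(profiles = profiles, noiseSigma = noiseSigma,
               replicates = as.integer(replicates),
               timeGrid_h = timeGrid_h, n0 = n0, seed = as.integer(seed))
  class(spec) <- "growthSpec"
  spec
}

#' Simulate fluorescence growth curves
#'
#' Trajectories follow N(t) = N0 exp(mu t) with per-observation
#' multiplicative lognormal noise; the truth table carries the planted
#' rates and the planted sensitivity ranking (computed arithmetically from
#' the planted rates with the decline rule, independent of the fitting
#' code).
#'
#' @param spec a [growthCurveSpec()].
#' @param dir optional directory for a long-format CSV plus truth CSV.
#' @return list: \code{data} (long data.frame: strain, salinity, replicate,
#'   time_h, fluorescence), \code{truth} (list with \code{rates},
#'   \code{sensitivity}; the first profile is the reference).
#' @export
simulateGrowthCurves <- function(spec = growthCurveSpec(), dir = NULL) {
  sal <- salinityPanel()$all
  .withSeed(spec$seed, {
    rows <- list()
    k <- 0L
    for (strain in names(spec$profiles)) {
      mu <- spec$profiles[[strain]]
      for (si in seq_along(sal)) for (rep in seq_len(spec$replicates)) {
        noise <- exp(stats::rnorm(length(spec$timeGrid_h), 0,
                                  spec$noiseSigma))
        k <- k + 1L
        rows[[k]] <- data.frame(
          strain = strain, salinity = sal[si], replicate = rep,
          time_h = spec$timeGrid_h,
          fluorescence = spec$n0 * exp(mu[si] * spec$timeGrid_h / 24) * noise,
          stringsAsFactors = FALSE)
      }
    }
    data <- do.call(rbind, rows)
    rates <- do.call(rbind, lapply(names(spec$profiles), function(s)
      data.frame(strain = s, salinity = sal, mu = spec$profiles[[s]],
                 stringsAsFactors = FALSE)))
    reference <- names(spec$profiles)[1]
    # a spec whose reference declines nowhere has no defined sensitivity
    sens <- tryCatch(salinitySensitivity(rates, reference),
                     undefinedSensitivityError = function(e) NULL)
    out <- list(data = data,
                truth = list(rates = rates, sensitivity = sens,
                             reference = reference))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(data, file.path(dir, "growth.csv"), row.names = FALSE)
      if (!is.null(sens))
        utils::write.csv(sens, file.path(dir, "truth_sensitivity.csv"),
                         row.names = FALSE)
    }
    out
  })
}

#' Simulate query sequences at controlled identity levels
#'
#' Each query is a panel sequence mutated by the substitution count that
#' brings its global identity within 0.5 percentage points of the target.
#' For targets at or above the minimum screening identity, substitutions
#' fall on unpaired columns only, so the query's barcode equals its
#' source's (zero CBCs) unless \code{plantCbc} converts one barcode pair to
#' a compensatory partner (two coordinated substitutions).  The truth table
#' carries the expected classification under default thresholds.
#'
#' @param panel output of [simulateBarcodePanel()].
#' @param identities target identity percentages in (0, 100].
#' @param plantCbc logical (recycled): plant one CBC into the
#'   corresponding query.
#' @param seed integer seed.
#' @return list: \code{queries} ([Biostrings::RNAStringSet]),
#'   \code{queryBarcodes} ([BarcodeSet-class]), \code{truth} (data.frame:
#'   query_id, source_id, target, achieved_identity, planted_cbc,
#'   expected_class).
#'
#' @section Errors: a target unreachable at the sequence length signals a
#'   \code{specError}.
#' @export
simulateQuerySet <- function(panel, identities = c(100, 99.5, 98, 97, 90),
                             plantCbc = FALSE, seed = 1L) {
  if (any(identities <= 0 | identities > 100))
    .err("usageError", "identities must lie in (0, 100]")
  plantCbc <- rep_len(plantCbc, length(identities))
  thr <- defaultScreeningThresholds()
  L <- unique(Biostrings::width(panel$sequences))[1]
  layout <- panel$layout
  pairedCols <- c(layout$five, layout$three)
  unpairedCols <- setdiff(seq_len(L), pairedCols)
  srcIds <- rep_len(strainIds(panel$codes), length(identities))
  .withSeed(seed, {
    seqs <- list(); qcodes <- list(); truth <- NULL
    for (k in seq_along(identities)) {
      target <- identities[k]
      src <- srcIds[k]
      s <- strsplit(as.character(panel$sequences[[src]]), "")[[1]]
      cod <- codeMatrix(panel$codes)[src, ]
      nMut <- round((1 - target / 100) * L)
      achieved <- 100 * (L - nMut) / L
      if (abs(achieved - target) > 0.5)
        .err("specError",
             sprintf("target identity %.2f%% unreachable at length %d",
                     target, L))
      mutCols <- integer(0)
      plantedCbc <- FALSE
      if (plantCbc[k]) {
        cand <- which(cod >= 1L & cod <= 6L)
        p <- .pick1(cand)
        newCode <- .pick1(.partnerSets$cbc[[cod[p]]])
        nt <- strsplit(names(.CODE_PAIRS)[newCode], "")[[1]]
        s[layout$five[p]] <- nt[1]
        s[layout$three[p]] <- nt[2]
        cod[p] <- newCode
        mutCols <- c(layout$five[p], layout$three[p])
        plantedCbc <- TRUE
        if (nMut < 2L)
          .err("specError",
               "cannot plant a CBC within the substitution budget")
        nMut <- nMut - 2L
      }
      where <- if (target >= thr$minIdentity) unpairedCols else
        setdiff(seq_len(L), mutCols)
      if (nMut > length(where))
        .err("specError",
             sprintf("target identity %.2f%% needs %d substitutions but only %d columns are mutable",
                     target, nMut, length(where)))
      pos <- if (nMut > 0L) sample(where, nMut) else integer(0)
      for (p in pos)
        s[p] <- .pick1(setdiff(c("A", "C", "G", "U"), s[p]))
      qid <- sprintf("Q%02d_id%g", k, target)
      seqs[[qid]] <- paste(s, collapse = "")
      qcodes[[qid]] <- cod
      expected <- if (achieved >= 100 - 1e-9) "species_match"
        else if (achieved >= thr$minIdentity) {
          if (plantedCbc) "putative_new_lineage" else "same_species_candidate"
        } else "unassigned"
      truth <- rbind(truth, data.frame(
        query_id = qid, source_id = src, target = target,
        achieved_identity = achieved, planted_cbc = plantedCbc,
        expected_class = expected, stringsAsFactors = FALSE))
    }
    list(queries = Biostrings::RNAStringSet(unlist(seqs)),
         queryBarcodes = barcodeSet(qcodes),
         truth = truth)
  })
}
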