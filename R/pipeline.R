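#' Default pipeline configuration
#'
#' Every tunable the pipeline stages rely on, with its default: consensus
#' threshold 0.5, screening identity thresholds 97/99, K over theta
#' threshold 4, sensitivity class cutoffs 33/66, growth-fit R-squared gate
#' 0.95, marker region intervals from [defaultRegions()], seed 1.  File
#' path entries are \code{NULL} until supplied.
#'
#' @return named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    fasta = NULL, structures = NULL, helices = NULL,
    barcodeTable = NULL, growthData = NULL, queries = NULL,
    queryBarcodes = NULL,
    referenceStrain = NULL,
    marker = "ITS2",
    consensusThreshold = 0.5,
    minIdentity = 97, v4Strict = 99,
    kThetaThreshold = 4,
    sensitivityCutoffs = c(33, 66),
    r2Gate = 0.95,
    regions = defaultRegions(),
    seed = 1L)
}

#' Run one pipeline stage
#'
#' Orchestrates the analysis stages as composable subcommands: `simulate`
#' writes a synthetic panel, growth curves and a query set; `barcode` turns
#' sequences + structures + helix annotation into a number-coded barcode
#' table; `delimit` consumes that table and writes the CBC/HCBC matrix,
#' species partition and haplotype labels; `tree` builds the barcode
#' distance phylogeny; `screen` classifies queries against a panel;
#' `growth` fits rates and the sensitivity table.  A JSON manifest
#' (inputs with checksums, full effective configuration, package version)
#' is written next to the outputs of every run.
#'
#' @param subcommand one of \code{"simulate"}, \code{"barcode"},
#'   \code{"delimit"}, \code{"tree"}, \code{"screen"}, \code{"growth"}.
#' @param config named list overriding [defaultPipelineConfig()] entries.
#' @param configFile optional YAML file of overrides (the \code{config}
#'   list takes precedence over the file, the file over defaults).
#' @param outDir output directory (created if needed).
#' @return invisibly, a named list of output file paths.
#'
#' @section Errors: a missing input file signals a \code{configError}
#'   naming the path; an invalid configuration value a \code{configError}
#'   naming the field.
#' @export
runPipeline <- function(subcommand = c("simulate", "barcode", "delimit",
                                       "tree", "screen", "growth"),
                        config = list(), configFile = NULL,
                        outDir = tempfile("its2cbc_")) {
  subcommand <- match.arg(subcommand)
  cfg <- defaultPipelineConfig()
  if (!is.null(configFile)) {
    if (!file.exists(configFile))
      .err("configError", sprintf("config file not found: %s", configFile))
    fileCfg <- yaml::read_yaml(configFile)
    cfg[names(fileCfg)] <- fileCfg
  }
  cfg[names(config)] <- config
  .validateConfig(cfg)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  needFile <- function(field) {
    path <- cfg[[field]]
    if (is.null(path))
      .err("configError", sprintf("config field '%s' (input path) not set",
                                  field))
    if (!file.exists(path))
      .err("configError", sprintf("input file not found: %s", path))
    path
  }
  outputs <- list()
  inputs <- character(0)

  if (subcommand == "simulate") {
    panel <- simulateBarcodePanel(barcodePanelSpec(seed = cfg$seed),
                                  dir = outDir)
    simulateGrowthCurves(growthCurveSpec(seed = cfg$seed), dir = outDir)
    qs <- simulateQuerySet(panel, seed = cfg$seed)
    writeFasta(qs$queries, file.path(outDir, "queries.fasta"))
    utils::write.table(qs$truth, file.path(outDir, "truth_queries.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeBarcodeTable(qs$queryBarcodes,
                      file.path(outDir, "query_barcodes.tsv"))
    outputs <- list(
      fasta = file.path(outDir, "panel.fasta"),
      structures = file.path(outDir, "panel.dbn"),
      helices = file.path(outDir, "helices.tsv"),
      growth = file.path(outDir, "growth.csv"),
      queries = file.path(outDir, "queries.fasta"))
  } else if (subcommand == "barcode") {
    fa <- needFile("fasta"); st <- needFile("structures")
    hx <- needFile("helices")
    inputs <- c(fa, st, hx)
    seqs <- readFasta(fa, aligned = TRUE)
    structs <- readStructureFile(st, seqs, aligned = TRUE)
    ann <- readHelixAnnotation(hx)
    bs <- computeBarcodes(seqs, structs, ann,
                          threshold = cfg$consensusThreshold)
    out <- file.path(outDir, "barcodes.tsv")
    writeBarcodeTable(bs, out)
    cons <- attr(bs, "consensus")
    writeStructureFile(stats::setNames(pairTableToDotBracket(cons),
                                       "consensus"),
                       file.path(outDir, "consensus.dbn"))
    outputs <- list(barcodeTable = out,
                    consensus = file.path(outDir, "consensus.dbn"))
  } else if (subcommand == "delimit") {
    bt <- needFile("barcodeTable")
    inputs <- bt
    bs <- readBarcodeTable(bt)
    cm <- cbcHcbcMatrix(bs)
    part <- delimitSpecies(cm)
    labels <- assignHaplotypes(bs, part)
    writeCbcCsv(cm, file.path(outDir, "cbc_matrix.csv"))
    writePartitionTsv(part, file.path(outDir, "partition.tsv"))
    writeBarcodeTable(bs, file.path(outDir, "haplotypes.tsv"),
                      labels = labels)
    if (!is.null(cfg$fasta)) {
      seqs <- readFasta(needFile("fasta"), aligned = TRUE)
      kt <- kOverTheta(part, pDistanceMatrix(seqs),
                       threshold = cfg$kThetaThreshold)
      utils::write.table(kt, file.path(outDir, "k_theta.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs$kTheta <- file.path(outDir, "k_theta.tsv")
      inputs <- c(inputs, cfg$fasta)
    }
    outputs <- c(outputs, list(
      cbcMatrix = file.path(outDir, "cbc_matrix.csv"),
      partition = file.path(outDir, "partition.tsv"),
      haplotypes = file.path(outDir, "haplotypes.tsv")))
  } else if (subcommand == "tree") {
    bt <- needFile("barcodeTable")
    inputs <- bt
    bs <- readBarcodeTable(bt)
    d <- barcodeDistanceMatrix(bs)
    utils::write.csv(d, file.path(outDir, "barcode_distances.csv"))
    tree <- neighborJoining(d)
    writeNewick(tree, file.path(outDir, "barcode_nj.nwk"))
    outputs <- list(distances = file.path(outDir, "barcode_distances.csv"),
                    tree = file.path(outDir, "barcode_nj.nwk"))
  } else if (subcommand == "screen") {
    fa <- needFile("fasta"); qf <- needFile("queries")
    inputs <- c(fa, qf)
    refs <- readFasta(fa, aligned = FALSE)
    queries <- readFasta(qf, aligned = FALSE)
    panel <- list(sequences = refs)
    qb <- NULL
    if (!is.null(cfg$barcodeTable)) {
      bt <- needFile("barcodeTable")
      inputs <- c(inputs, bt)
      panel$barcodes <- readBarcodeTable(bt)
    }
    if (!is.null(cfg$queryBarcodes)) {
      qbPath <- needFile("queryBarcodes")
      inputs <- c(inputs, qbPath)
      qb <- readBarcodeTable(qbPath)
    }
    hits <- screenQueries(queries, panel, queryBarcodes = qb,
                          marker = cfg$marker,
                          thresholds = list(minIdentity = cfg$minIdentity,
                                            v4Strict = cfg$v4Strict))
    out <- file.path(outDir, "screening.tsv")
    utils::write.table(hits, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- list(screening = out)
  } else if (subcommand == "growth") {
    gf <- needFile("growthData")
    inputs <- gf
    data <- utils::read.csv(gf, stringsAsFactors = FALSE)
    rates <- growthRateTable(data, r2Gate = cfg$r2Gate)
    ref <- cfg$referenceStrain
    if (is.null(ref)) ref <- rates$strain[1]
    sens <- salinitySensitivity(rates, ref)
    sens$class <- classifySalinityResponse(sens$sensitivity,
                                           cfg$sensitivityCutoffs)
    utils::write.csv(rates, file.path(outDir, "growth_rates.csv"),
                     row.names = FALSE)
    utils::write.csv(sens, file.path(outDir, "sensitivity.csv"),
                     row.names = FALSE)
    outputs <- list(rates = file.path(outDir, "growth_rates.csv"),
                    sensitivity = file.path(outDir, "sensitivity.csv"))
  }

  manifest <- list(
    subcommand = subcommand,
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputs)), inputs)),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    package = as.character(utils::packageVersion("its2cbc")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  outputs$manifest <- file.path(outDir, "manifest.json")
  invisible(outputs)
}

#' @noRd
.validateConfig <- function(cfg) {
  chk <- function(field, lower, upper) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < lower) || any(v > upper))
      .err("configError",
           sprintf("config field '%s' outside [%s, %s]", field, lower, upper))
  }
  chk("consensusThreshold", 1e-9, 1)
  chk("minIdentity", 1e-9, 100)
  chk("v4Strict", 1e-9, 100)
  chk("kThetaThreshold", 0, Inf)
  chk("r2Gate", 0, 1)
  if (length(cfg$sensitivityCutoffs) != 2L ||
      diff(cfg$sensitivityCutoffs) <= 0)
    .err("configError",
         "config field 'sensitivityCutoffs' must be two increasing numbers")
  invisible(TRUE)
}
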