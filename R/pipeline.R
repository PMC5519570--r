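# End-to-end orchestration: preprocess -> alpha -> EMS (+compartments)
# -> beta -> report, with file-based inputs, deterministic per-stage child
# seeds, and a one-command synthetic demo reproducing the emulated study
# design (8 rivers in 2 drainages, 43 animal + 8 water samples).

#' Build a pipeline configuration
#'
#' Defaults mirror the standard preprocessing and testing choices: 0.005%
#' total-count OTU filter, rarefaction to 8,800 reads, 80% core prevalence,
#' a 99-permutation r1 null with empty rows/columns allowed, and 10,000
#' Mantel permutations.
#'
#' @param table,tree,metadata,fst input file paths (`tree`/`fst` optional;
#'   stages needing them are skipped or fail as documented in
#'   [runPipeline()])
#' @param outputDir directory for all artifacts
#' @param filterMinFraction OTU filter threshold (fraction of total reads)
#' @param rarefactionDepth reads per sample after rarefaction
#' @param corePrevalence core-microbiome prevalence threshold
#' @param nullPermutations r1 null permutations for the EMS stage
#' @param allowEmpty allow empty rows/columns in null matrices
#' @param clumpingTest boundary-clumping convention for classification
#'   (pipeline default `"chisq"`, the conventional published workflow; see
#'   [emsAnalysis()])
#' @param betaPermutations permutations for ANOSIM/PERMANOVA
#' @param mantelPermutations permutations for Mantel tests
#' @param seed master seed; per-stage child seeds are derived from it
#' @return list of class `PipelineConfig`
#' @export
pipelineConfig <- function(table, metadata, outputDir, tree = NULL, fst = NULL,
                           filterMinFraction = 5e-5, rarefactionDepth = 8800,
                           corePrevalence = 0.80, nullPermutations = 99,
                           allowEmpty = TRUE, clumpingTest = "chisq",
                           betaPermutations = 999,
                           mantelPermutations = 10000, seed = 1L) {
  structure(list(table = table, metadata = metadata, tree = tree, fst = fst,
                 outputDir = outputDir, filterMinFraction = filterMinFraction,
                 rarefactionDepth = rarefactionDepth,
                 corePrevalence = corePrevalence,
                 nullPermutations = nullPermutations, allowEmpty = allowEmpty,
                 clumpingTest = clumpingTest,
                 betaPermutations = betaPermutations,
                 mantelPermutations = mantelPermutations,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()].
#'
#' @param path YAML file
#' @return list of class `PipelineConfig`
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

.log <- function(logFile, fmt, ...) {
  line <- sprintf(fmt, ...)
  message(line)
  if (!is.null(logFile))
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), line, "\n",
        sep = "", file = logFile, append = TRUE)
}

# EMSReport -> plain list for JSON (scores and orderings; the ordered matrix
# itself goes to its own TSV)
.reportToList <- function(rep) {
  if (is.null(rep)) return(NULL)
  ord <- rep@ordination
  list(coherence = rep@coherence, turnover = rep@turnover,
       clumping = rep@clumping[c("index", "chi2", "df", "p", "N")],
       classification = rep@classification, nullSpec = rep@nullSpec,
       siteScores = as.list(ord$siteScores),
       eigenvalue = ord$eigenvalue,
       siteOrder = names(ord$siteScores)[ord$rowOrder])
}

#' Run the full metacommunity analysis pipeline
#'
#' Fixed stage order: read and cross-validate inputs; filter rare OTUs and
#' rarefy (in that order); core microbiome; alpha summaries with
#' animal-water shared proportions; EMS on the animal incidence matrix with
#' covariate correlations and an automatic compartment split; beta
#' diversity (Jaccard, unweighted/weighted UniFrac, PCoA, ANOSIM and
#' PERMANOVA by deme and by population, Mantel of community distance
#' against expanded Fst and of Jaccard against geographic distance). Id
#' mismatches between table, tree and metadata fail fast with a
#' reconciliation message; a missing Fst skips the genetic Mantel stage
#' with a logged warning; a missing tree is a hard error since UniFrac is
#' requested by default. All artifacts are written under
#' `config$outputDir`; the JSON report is timestamp-free and byte-identical
#' under a fixed config and seed.
#'
#' @param config a `PipelineConfig` (or YAML path understood by
#'   [readPipelineConfig()])
#' @return the report, invisibly (a list of class `RunReport`)
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$outputDir, "run.log")
  seed <- config$seed
  .log(logFile, "reading inputs")
  tab <- readOTUTable(config$table)
  md <- readSampleMetadata(config$metadata)

  # --- cross-validation (fail fast with a reconciliation report) ---
  orphan <- setdiff(sampleIDs(tab), md$sample_id)
  if (length(orphan))
    stop("table samples missing from metadata: ", paste(orphan, collapse = ", "))
  tree <- NULL
  if (!is.null(config$tree)) {
    if (!file.exists(config$tree))
      stop("tree file not found: ", config$tree)
    tree <- ape::read.tree(config$tree)
    lost <- setdiff(otuIDs(tab), tree$tip.label)
    if (length(lost))
      stop(sprintf("%d table OTU(s) missing from the tree, e.g. %s",
                   length(lost), paste(utils::head(lost, 5), collapse = ", ")))
  } else {
    stop("a rooted tree is required for the UniFrac stage; none supplied")
  }
  fst <- if (!is.null(config$fst) && file.exists(config$fst))
    readDistanceTSV(config$fst) else NULL

  # --- preprocessing: filter, then rarefy ---
  .log(logFile, "filtering OTUs below %.4g of total reads", config$filterMinFraction)
  tab <- filterRareOTUs(tab, config$filterMinFraction)
  .log(logFile, "rarefying to %d reads per sample", config$rarefactionDepth)
  tab <- withCallingHandlers(
    rarefyTable(tab, config$rarefactionDepth, seed = childSeed(seed, 11)),
    warning = function(w) { .log(logFile, "warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning") })
  md <- md[md$sample_id %in% sampleIDs(tab), ]
  core <- coreMicrobiome(tab, config$corePrevalence)
  .log(logFile, "%d samples, %d OTUs after preprocessing; %d core OTUs",
       nrow(counts(tab)), ncol(counts(tab)), length(core))

  # --- alpha ---
  alpha <- alphaSummaries(tab, md)
  utils::write.table(alpha, file.path(config$outputDir, "alpha_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- EMS on the animal incidence matrix ---
  .log(logFile, "EMS analysis (%d-permutation r1 null)", config$nullPermutations)
  inc <- toIncidence(tab, metadata = md, sampleTypes = "animal")
  ems <- emsAnalysis(inc, nPermutations = config$nullPermutations,
                     seed = childSeed(seed, 21),
                     allowEmpty = config$allowEmpty,
                     clumpingTest = config$clumpingTest)
  covCor <- lapply(stats::setNames(nm = c("latitude", "elevation", "forest_cover")),
                   function(cv) tryCatch(
                     scoreCovariateCorrelation(ems, md, cv),
                     error = function(e) NULL))
  split <- tryCatch(
    splitCompartments(inc, boundary = "auto",
                      nPermutations = config$nullPermutations,
                      seed = childSeed(seed, 22),
                      allowEmpty = config$allowEmpty,
                      clumpingTest = config$clumpingTest),
    error = function(e) { .log(logFile, "compartment split failed: %s",
                               conditionMessage(e)); NULL })
  writeOrderedIncidence(ems, file.path(config$outputDir, "ordered_incidence.tsv"),
                        metadata = md)

  # --- beta diversity ---
  .log(logFile, "beta diversity")
  animals <- md[md$sample_type == "animal", ]
  atab <- tab[sampleIDs(tab) %in% animals$sample_id, ]
  jac <- jaccardMatrix(atab)
  uwUF <- unifracMatrix(atab, tree, weighted = FALSE)
  wUF <- unifracMatrix(atab, tree, weighted = TRUE, normalized = TRUE)
  for (nm in c("jaccard", "unweighted_unifrac", "weighted_unifrac"))
    writeDistanceTSV(as.matrix(switch(nm, jaccard = jac,
                                      unweighted_unifrac = uwUF,
                                      weighted_unifrac = wUF)),
                     file.path(config$outputDir, paste0(nm, ".tsv")))
  pcoa <- pcoaOrdination(uwUF)
  utils::write.table(
    data.frame(sample_id = rownames(pcoa$vectors), pcoa$vectors,
               check.names = FALSE),
    file.path(config$outputDir, "pcoa_unweighted_unifrac.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  grouping <- function(col) {
    g <- animals[[col]][match(labels(uwUF), animals$sample_id)]
    keepLevels <- names(which(table(g) >= 2))
    list(g = g, keep = g %in% keepLevels)
  }
  groupTests <- list()
  k <- 0L
  for (col in c("deme", "population")) for (dnm in c("unweighted", "weighted")) {
    gr <- grouping(col)
    dmat <- as.matrix(if (dnm == "unweighted") uwUF else wUF)
    if (length(unique(gr$g[gr$keep])) < 2L) {
      .log(logFile, "warning: fewer than 2 usable %s groups; test skipped", col)
      next
    }
    dsub <- stats::as.dist(dmat[gr$keep, gr$keep])
    k <- k + 1L
    groupTests[[paste(col, dnm, sep = "_")]] <- list(
      factor = col, distance = paste0(dnm, "_unifrac"),
      permanova = permanovaTest(dsub, gr$g[gr$keep], config$betaPermutations,
                                seed = childSeed(seed, 30 + k)),
      anosim = anosimTest(dsub, gr$g[gr$keep], config$betaPermutations,
                          seed = childSeed(seed, 50 + k)))
  }

  mantels <- list()
  if (!is.null(fst)) {
    fstS <- expandFstToSamples(fst, md)
    fm <- as.matrix(fstS)[labels(uwUF), labels(uwUF)]
    mantels$fst_unweighted_unifrac <-
      mantelTest(fm, uwUF, config$mantelPermutations, seed = childSeed(seed, 61))
    mantels$fst_weighted_unifrac <-
      mantelTest(fm, wUF, config$mantelPermutations, seed = childSeed(seed, 62))
  } else {
    .log(logFile, "warning: no Fst matrix supplied; genetic Mantel stage skipped")
  }
  geo <- geographicDistances(animals)
  gm <- as.matrix(geo)[labels(jac), labels(jac)]
  mantels$geographic_jaccard <-
    mantelTest(gm, jac, config$mantelPermutations, seed = childSeed(seed, 63))

  # --- report ---
  report <- structure(list(
    provenance = list(
      tool = "MicroMetacom",
      version = as.character(utils::packageVersion("MicroMetacom")),
      seed = seed, configHash = configHash(unclass(config)),
      parameters = unclass(config)),
    preprocessing = list(nSamples = nrow(counts(tab)),
                         nOTUs = ncol(counts(tab)),
                         rarefactionDepth = config$rarefactionDepth,
                         coreOTUs = core),
    alpha = alpha,
    ems = .reportToList(ems),
    covariateCorrelations = covCor,
    compartments = if (!is.null(split)) list(
      boundary = split@boundary,
      sizes = vapply(split@children, nrow, integer(1)),
      reports = lapply(split@reports, .reportToList)) else NULL,
    beta = list(groupTests = groupTests, mantel = mantels,
                pcoaRelativeEig = pcoa$relativeEig[seq_len(min(5, length(pcoa$relativeEig)))])),
    class = "RunReport")
  jsonlite::write_json(report[setdiff(names(report), character())],
                       file.path(config$outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE, pretty = TRUE)
  .log(logFile, "done; report written to %s",
       file.path(config$outputDir, "report.json"))
  invisible(report)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("MicroMetacom run report\n")
  cat(sprintf("  %d samples x %d OTUs after preprocessing; %d core OTUs\n",
              x$preprocessing$nSamples, x$preprocessing$nOTUs,
              length(x$preprocessing$coreOTUs)))
  cat(sprintf("  EMS classification: %s\n", x$ems$classification))
  if (!is.null(x$compartments))
    cat(sprintf("  compartments (%d | %d sites): %s\n",
                x$compartments$sizes[1], x$compartments$sizes[2],
                paste(vapply(x$compartments$reports, function(r)
                  if (is.null(r)) "not analysed" else r$classification,
                  character(1)), collapse = " / ")))
  for (nm in names(x$beta$groupTests)) {
    gt <- x$beta$groupTests[[nm]]
    cat(sprintf("  %s (%s): PERMANOVA R2 = %.2f (p = %.3g), ANOSIM R = %.2f (p = %.3g)\n",
                gt$factor, gt$distance, gt$permanova$R2, gt$permanova$p,
                gt$anosim$statistic, gt$anosim$p))
  }
  for (nm in names(x$beta$mantel)) {
    mt <- x$beta$mantel[[nm]]
    cat(sprintf("  Mantel %s: r = %.2f (p = %.3g)\n", nm, mt$r, mt$p))
  }
  invisible(x)
}

#' One-command synthetic demo of the full analysis
#'
#' Simulates the emulated study design (8 populations in 2 demes, 43 animal
#' and 8 water samples, clementsian structure aligned with the demes),
#' writes the dataset under `outputDir/data`, and runs the complete
#' pipeline on those files under `outputDir/analysis`.
#'
#' @param outputDir writable output directory
#' @param seed master seed (default 1)
#' @param ... overrides passed to [simulateDataset()]
#' @return the pipeline report, invisibly
#' @export
runDemo <- function(outputDir, seed = 1L, ...) {
  dataDir <- file.path(outputDir, "data")
  ds <- simulateDataset(seed = seed, ...)
  paths <- writeDataset(ds, dataDir,
                        provenance = sprintf("MicroMetacom demo seed=%d", seed))
  config <- pipelineConfig(table = paths[["table"]],
                           metadata = paths[["metadata"]],
                           tree = paths[["tree"]], fst = paths[["fst"]],
                           outputDir = file.path(outputDir, "analysis"),
                           seed = seed)
  runPipeline(config)
}
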