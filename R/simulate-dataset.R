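#' Overlay read abundances on a binary incidence matrix
#'
#' Species receive global abundance weights from a rank-ordered lognormal
#' (species 1 is always the most abundant, giving a realistic rank-abundance
#' curve with a long rare tail). Each sample's read depth is drawn from a
#' negative binomial, and reads are allocated by multinomial sampling over
#' the species present in that sample, with probabilities proportional to
#' the lognormal weights — rescaled so the top-ranked species, where present,
#' takes `dominantFraction` of the sample in expectation. Absent species
#' never receive reads.
#'
#' @param incidence binary sites x species matrix (e.g. from
#'   [simulateIncidence()])
#' @param lognormalMu,lognormalSigma meanlog/sdlog of the species weights
#' @param dominantFraction expected within-sample relative abundance of the
#'   top-ranked species where it occurs, in `(0, 1)`
#' @param depthMean,depthDispersion negative-binomial mean and size of the
#'   per-sample read depth
#' @param seed integer seed
#' @return an [OTUTable-class] with the same dimnames as `incidence`
#' @export
overlayAbundance <- function(incidence, lognormalMu = 6, lognormalSigma = 2.5,
                             dominantFraction = 0.465, depthMean = 20000,
                             depthDispersion = 20, seed = NULL) {
  if (dominantFraction <= 0 || dominantFraction >= 1)
    stop("dominantFraction must lie in (0, 1)")
  if (depthMean <= 0) stop("depthMean must be positive")
  S <- ncol(incidence)
  withSeed(seed, {
    w <- sort(stats::rlnorm(S, lognormalMu, lognormalSigma), decreasing = TRUE)
    depths <- stats::rnbinom(nrow(incidence), mu = depthMean,
                             size = depthDispersion)
    cts <- matrix(0, nrow(incidence), S, dimnames = dimnames(incidence))
    for (i in seq_len(nrow(incidence))) {
      present <- which(incidence[i, ] > 0)
      if (!length(present) || depths[i] == 0) next
      p <- w[present]
      if (1L %in% present && length(present) > 1L) {
        rest <- p[present != 1L]
        p[present == 1L] <- dominantFraction
        p[present != 1L] <- (1 - dominantFraction) * rest / sum(rest)
      } else {
        p <- p / sum(p)
      }
      cts[i, present] <- stats::rmultinom(1L, depths[i], p)
    }
    OTUTable(cts)
  })
}

#' Simulate a rooted binary phylogeny by random sequential coalescence
#'
#' Lineages (one per OTU id) are merged two at a time uniformly at random
#' until a single root remains; every branch gets an independent Exp(1)
#' length. Any rooted binary tree with positive lengths is adequate for
#' phylogenetic beta-diversity testing, so no further realism is attempted.
#'
#' @param otuIDs character vector of >= 2 unique leaf names
#' @param seed integer seed; the Newick string is byte-identical on repeat
#'   calls with the same seed
#' @return a rooted `phylo` with `length(otuIDs)` tips
#' @export
simulateTree <- function(otuIDs, seed = NULL) {
  otuIDs <- as.character(otuIDs)
  if (length(otuIDs) < 2L) stop("at least 2 OTU ids are required")
  if (anyDuplicated(otuIDs))
    stop("duplicate OTU ids: ", otuIDs[duplicated(otuIDs)][1])
  withSeed(seed, {
    frags <- otuIDs
    while (length(frags) > 1L) {
      pick <- sample.int(length(frags), 2L)
      bl <- stats::rexp(2L)
      merged <- sprintf("(%s:%.8f,%s:%.8f)", frags[pick[1]], bl[1],
                        frags[pick[2]], bl[2])
      frags <- c(frags[-pick], merged)
    }
    ape::read.tree(text = paste0(frags, ";"))
  })
}

#' Simulate sample metadata mirroring a multi-river field design
#'
#' Populations (rivers) are laid out along the latent gradient and split into
#' two demes (major drainages). Each population contributes a number of
#' animal samples and (by default) one water sample. Latitude, elevation and
#' percent forest cover are drawn around population-level means that vary
#' monotonically along the gradient — latitude decreasing, elevation and
#' forest cover increasing — with pseudo-coordinates for distance
#' computations. The default design is 8 populations with animal sample
#' sizes 5,5,8,5,3,5,7,5 (43 animals) plus one water sample each.
#'
#' @param nPopulations number of populations (>= 2)
#' @param animalsPerPopulation integer vector (recycled to `nPopulations`);
#'   the default yields 43 animal samples across 8 rivers
#' @param waterPerPopulation water samples per population
#' @param demeSplit number of populations in the first deme
#' @param seed integer seed
#' @return data.frame with columns sample_id, population, deme, sample_type,
#'   latitude, longitude, elevation, forest_cover
#' @export
simulateMetadata <- function(nPopulations = 8,
                             animalsPerPopulation = c(5, 5, 8, 5, 3, 5, 7, 5),
                             waterPerPopulation = 1, demeSplit = 3,
                             seed = NULL) {
  if (nPopulations < 2L) stop("nPopulations must be >= 2")
  animals <- rep_len(as.integer(animalsPerPopulation), nPopulations)
  waters <- rep_len(as.integer(waterPerPopulation), nPopulations)
  pops <- sprintf("P%d", seq_len(nPopulations))
  demes <- ifelse(seq_len(nPopulations) <= demeSplit, "D1", "D2")
  # population-level means along the gradient
  lat0 <- seq(38.1, 35.5, length.out = nPopulations)
  lon0 <- seq(-86.2, -82.0, length.out = nPopulations)
  elev0 <- seq(390, 600, length.out = nPopulations)
  forest0 <- seq(63, 75, length.out = nPopulations)
  withSeed(seed, {
    rows <- lapply(seq_len(nPopulations), function(k) {
      n <- animals[k] + waters[k]
      data.frame(
        sample_id = c(sprintf("%s_a%02d", pops[k], seq_len(animals[k])),
                      if (waters[k] > 0) sprintf("%s_w%02d", pops[k],
                                                 seq_len(waters[k]))),
        population = pops[k], deme = demes[k],
        sample_type = c(rep("animal", animals[k]), rep("water", waters[k])),
        latitude = round(lat0[k] + stats::rnorm(n, 0, 0.05), 5),
        longitude = round(lon0[k] + stats::rnorm(n, 0, 0.05), 5),
        elevation = round(elev0[k] + stats::rnorm(n, 0, 20), 1),
        forest_cover = round(pmin(100, pmax(0, forest0[k] + stats::rnorm(n, 0, 2))), 2),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a pairwise population Fst matrix with divergence structure
#'
#' Expected Fst is `within` for population pairs in the same compartment
#' (deme) and `between` otherwise, plus Gaussian noise, truncated to
#' `[0, 1]`, symmetric with a zero diagonal.
#'
#' @param populationCompartments named vector (names = population ids) giving
#'   each population's compartment/deme
#' @param within,between expected Fst within / between compartments
#'   (`between >= within >= 0`)
#' @param noise sd of the Gaussian perturbation
#' @param seed integer seed
#' @return symmetric matrix with population dimnames
#' @export
simulateFst <- function(populationCompartments, within = 0.05, between = 0.25,
                        noise = 0.02, seed = NULL) {
  if (within < 0 || between < within)
    stop("need between >= within >= 0")
  pops <- names(populationCompartments)
  if (is.null(pops)) stop("populationCompartments must be named by population")
  k <- length(pops)
  withSeed(seed, {
    m <- matrix(0, k, k, dimnames = list(pops, pops))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      mu <- if (populationCompartments[i] == populationCompartments[j])
        within else between
      v <- min(1, max(0, mu + stats::rnorm(1L, 0, noise)))
      m[i, j] <- m[j, i] <- v
    }
    m
  })
}

#' Add a river-water sample sharing a target proportion of animal OTUs
#'
#' The water community holds an exactly-sized uniform subset of the animal
#' pool — `round(targetShared * pool size)` OTUs drawn from the union of the
#' supplied animal samples' OTUs — so each animal's expected shared
#' proportion (shared / animal richness) equals `targetShared`, plus up to
#' `nExclusive` water-exclusive OTUs taken from table columns absent in all
#' the animal samples. Water read counts are allocated like
#' [overlayAbundance()] does, by lognormal-weighted multinomial draw.
#'
#' @param animalTable [OTUTable-class] of animal samples from one population
#'   (columns may include OTUs absent in all of them, which is where
#'   water-exclusive OTUs come from)
#' @param targetShared target shared proportion in `[0, 1]`
#' @param nExclusive water-exclusive OTUs to include (capped at availability)
#' @param depth water-sample read depth
#' @param waterID sample id for the new row
#' @param seed integer seed
#' @return [OTUTable-class] with the water row appended
#' @export
injectWaterOverlap <- function(animalTable, targetShared, nExclusive = 25,
                               depth = 20000, waterID = "water01",
                               seed = NULL) {
  stopifnot(is(animalTable, "OTUTable"))
  stopIfNot01(targetShared, "targetShared")
  cts <- animalTable@counts
  pool <- colnames(cts)[colSums(cts > 0) > 0]
  absent <- setdiff(colnames(cts), pool)
  withSeed(seed, {
    nShared <- round(targetShared * length(pool))
    shared <- if (nShared > 0) sample(pool, nShared) else character()
    exclusive <- if (nExclusive > 0 && length(absent))
      sample(absent, min(nExclusive, length(absent))) else character()
    water_set <- c(shared, exclusive)
    wrow <- matrix(0, 1L, ncol(cts), dimnames = list(waterID, colnames(cts)))
    if (length(water_set)) {
      if (depth < length(water_set))
        stop("depth too small to detect every water OTU")
      w <- sort(stats::rlnorm(length(water_set), 6, 2.5), decreasing = TRUE)
      # one guaranteed read per member so the water community is fully
      # detectable, remainder multinomial
      wrow[1L, water_set] <- 1 +
        stats::rmultinom(1L, depth - length(water_set), w / sum(w))
    }
    OTUTable(rbind(cts, wrow), taxonomy = animalTable@taxonomy)
  })
}

# Toy lineage strings so taxonomy plumbing is exercised end to end.
.simulateTaxonomy <- function(otuIDs, seed = NULL) {
  phyla <- c("Proteobacteria", "Actinobacteria", "Firmicutes", "Bacteroidetes",
             "Cyanobacteria", "Verrucomicrobia", "Acidobacteria")
  withSeed(seed, {
    p <- sample(phyla, length(otuIDs), replace = TRUE)
    tax <- sprintf("k__Bacteria; p__%s; g__genus%03d", p,
                   sample.int(200L, length(otuIDs), replace = TRUE))
    names(tax) <- otuIDs
    tax
  })
}

#' Simulate a complete study dataset with ground truth
#'
#' Assembles everything the pipeline consumes: a structured animal incidence
#' matrix along a population-ordered gradient, `nCore` always-present core
#' species (so a ubiquitous dominant OTU exists, as in real skin
#' microbiomes), a shared pool of water-exclusive OTUs, abundance overlay,
#' one water sample per population with a target animal-water shared
#' proportion, a random coalescent phylogeny over all OTUs, metadata, and a
#' compartment-structured Fst matrix. Defaults emulate a field design of
#' 8 rivers in 2 drainages with 43 animal and 8 water samples.
#'
#' For the default clementsian structure the incidence is hierarchical, as
#' in real host-associated metacommunities: half the structured species have
#' deme-wide ranges (2 compartments aligned with the demes), half have
#' sub-compartment ranges (4 compartments grouping adjacent populations
#' within each deme), so that splitting at the major boundary leaves
#' clementsian structure inside each compartment.
#'
#' @param structure scenario structure for the animal incidence (default
#'   clementsian with compartments aligned to the demes)
#' @param nSpecies structured species count (default sized so that roughly
#'   the study-scale OTU pool survives the rare-OTU filter)
#' @param nCore core species present at every animal site
#' @param nWaterExclusive water-only OTU pool size
#' @param boundaryNoise scenario cell-flip probability
#' @param metadata optional pre-built metadata (defaults to
#'   [simulateMetadata()])
#' @param targetShared animal-water shared-proportion target
#' @param lognormalMu,lognormalSigma,dominantFraction,depthMean,depthDispersion
#'   see [overlayAbundance()]
#' @param fstWithin,fstBetween see [simulateFst()]
#' @param seed master seed; stage seeds are derived deterministically
#' @return a [SimulatedDataset-class]
#' @export
simulateDataset <- function(structure = "clementsian", nSpecies = 4800,
                            nCore = 9, nWaterExclusive = 47,
                            boundaryNoise = 0.05, metadata = NULL,
                            targetShared = 0.29, lognormalMu = 6,
                            lognormalSigma = 1.8, dominantFraction = 0.465,
                            depthMean = 20000, depthDispersion = 20,
                            fstWithin = 0.05, fstBetween = 0.25, seed = 1L) {
  if (is.null(metadata)) metadata <- simulateMetadata(seed = childSeed(seed, 1))
  animals <- metadata[metadata$sample_type == "animal", ]
  nSites <- nrow(animals)
  # compartments follow the deme blocks (populations are gradient-ordered)
  demeSizes <- as.integer(table(factor(animals$deme, unique(animals$deme))))
  if (structure == "clementsian") {
    # hierarchical layers: deme-wide ranges + population-level ranges
    subSizes <- as.integer(table(factor(animals$population,
                                        unique(animals$population))))
    nDeme <- nSpecies %/% 2L
    scen <- metacomScenario(structure, nSites = nSites, nSpecies = nDeme,
                            nCompartments = length(demeSizes),
                            compartmentSizes = demeSizes,
                            boundaryNoise = boundaryNoise,
                            seed = childSeed(seed, 2))
    scenSub <- metacomScenario(structure, nSites = nSites,
                               nSpecies = nSpecies - nDeme,
                               nCompartments = length(subSizes),
                               compartmentSizes = as.integer(subSizes),
                               boundaryNoise = boundaryNoise,
                               seed = childSeed(seed, 7))
    incDeme <- simulateIncidence(scen, shuffleSites = FALSE,
                                 siteIDs = animals$sample_id)
    incSub <- simulateIncidence(scenSub, shuffleSites = FALSE,
                                siteIDs = animals$sample_id)
    inc0 <- cbind(incDeme, incSub)
    # shuffle species columns so abundance rank (assigned by column order in
    # the overlay) is independent of the structural layer
    inc0 <- inc0[, withSeed(childSeed(seed, 8), sample.int(ncol(inc0))),
                 drop = FALSE]
    colnames(inc0) <- sprintf("sp%04d", seq_len(ncol(inc0)))
    inc <- inc0
    attr(inc, "gradientRank") <- attr(incDeme, "gradientRank")
    attr(inc, "compartment") <- attr(incDeme, "compartment")
  } else {
    scen <- metacomScenario(structure, nSites = nSites, nSpecies = nSpecies,
                            boundaryNoise = boundaryNoise,
                            seed = childSeed(seed, 2))
    inc <- simulateIncidence(scen, shuffleSites = FALSE,
                             siteIDs = animals$sample_id)
  }
  truthRank <- attr(inc, "gradientRank")
  truthComp <- attr(inc, "compartment")
  if (nCore > 0) {
    core <- matrix(1L, nSites, nCore,
                   dimnames = list(rownames(inc), sprintf("core%03d", seq_len(nCore))))
    inc <- cbind(core, inc)  # core species lead, so they top the abundance ranks
  }
  otuIDs <- c(colnames(inc),
              if (nWaterExclusive > 0) sprintf("wat%04d", seq_len(nWaterExclusive)))
  full <- cbind(inc, matrix(0L, nSites, nWaterExclusive,
                            dimnames = list(rownames(inc),
                                            setdiff(otuIDs, colnames(inc)))))
  tab <- overlayAbundance(full, lognormalMu = lognormalMu,
                          lognormalSigma = lognormalSigma,
                          dominantFraction = dominantFraction,
                          depthMean = depthMean,
                          depthDispersion = depthDispersion,
                          seed = childSeed(seed, 3))
  # one water sample per population
  waters <- metadata[metadata$sample_type == "water", ]
  allCts <- tab@counts
  for (k in seq_len(nrow(waters))) {
    pop <- waters$population[k]
    popTab <- tab[rownames(tab@counts) %in%
                    animals$sample_id[animals$population == pop], ]
    wtab <- injectWaterOverlap(popTab, targetShared = targetShared,
                               nExclusive = nWaterExclusive,
                               depth = depthMean, waterID = waters$sample_id[k],
                               seed = childSeed(seed, 100 + k))
    allCts <- rbind(allCts, wtab@counts[waters$sample_id[k], , drop = FALSE])
  }
  tax <- .simulateTaxonomy(colnames(allCts), seed = childSeed(seed, 4))
  abundance <- OTUTable(allCts, taxonomy = tax)
  tree <- simulateTree(colnames(allCts), seed = childSeed(seed, 5))
  comp <- stats::setNames(metadata$deme[!duplicated(metadata$population)],
                          unique(metadata$population))
  fst <- simulateFst(comp, within = fstWithin, between = fstBetween,
                     seed = childSeed(seed, 6))
  truth <- list(scenario = scen,
                sample_id = rownames(inc),
                gradientRank = truthRank,
                compartment = truthComp)
  new("SimulatedDataset", abundance = abundance, tree = tree,
      metadata = metadata, fst = fst, truth = truth)
}

#' @describeIn simulateDataset abundance table accessor
#' @param x a SimulatedDataset
#' @export
setMethod("abundance", "SimulatedDataset", function(x) x@abundance)

#' @describeIn simulateDataset metadata accessor
#' @export
setMethod("sampleMetadata", "SimulatedDataset", function(x) x@metadata)

#' @describeIn simulateDataset phylogeny accessor
#' @export
setMethod("phyloTree", "SimulatedDataset", function(x) x@tree)

#' @describeIn simulateDataset population Fst accessor
#' @export
setMethod("fstMatrix", "SimulatedDataset", function(x) x@fst)

#' @describeIn simulateDataset ground-truth labels accessor
#' @export
setMethod("groundTruth", "SimulatedDataset", function(x) x@truth)

setMethod("show", "SimulatedDataset", function(object) {
  md <- object@metadata
  cat(sprintf("SimulatedDataset: %d samples (%d animal, %d water), %d OTUs\n",
              nrow(md), sum(md$sample_type == "animal"),
              sum(md$sample_type == "water"), ncol(object@abundance@counts)))
  cat(sprintf("  %d populations in %d demes; truth structure: %s\n",
              length(unique(md$population)), length(unique(md$deme)),
              object@truth$scenario@structure))
  invisible(NULL)
})

#' Write a simulated dataset to plain-text files
#'
#' Writes `otu_table.tsv` (and `otu_table.biom`, JSON), `tree.nwk`,
#' `metadata.tsv`, `fst.tsv` and `truth.json` under `dir`.
#'
#' @param dataset a [SimulatedDataset-class]
#' @param dir output directory (created if needed)
#' @param provenance optional provenance string for file headers
#' @return invisibly, the named vector of written paths
#' @export
writeDataset <- function(dataset, dir, provenance = NULL) {
  stopifnot(is(dataset, "SimulatedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(table = file.path(dir, "otu_table.tsv"),
             biom = file.path(dir, "otu_table.biom"),
             tree = file.path(dir, "tree.nwk"),
             metadata = file.path(dir, "metadata.tsv"),
             fst = file.path(dir, "fst.tsv"),
             truth = file.path(dir, "truth.json"))
  writeOTUTable(dataset@abundance, paths["table"], format = "tsv",
                provenance = provenance)
  writeOTUTable(dataset@abundance, paths["biom"], format = "biom")
  ape::write.tree(dataset@tree, paths["tree"])
  utils::write.table(dataset@metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeDistanceTSV(dataset@fst, paths["fst"])
  tr <- dataset@truth
  jsonlite::write_json(list(structure = tr$scenario@structure,
                            nCompartments = tr$scenario@nCompartments,
                            boundaryNoise = tr$scenario@boundaryNoise,
                            sample_id = tr$sample_id,
                            gradientRank = tr$gradientRank,
                            compartment = tr$compartment),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
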