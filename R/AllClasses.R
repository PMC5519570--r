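#' @import methods
NULL

setOldClass("phylo")

#' OTUTable: a samples-by-OTU count matrix with optional taxonomy
#'
#' The central abundance container: non-negative integer read counts with
#' unique sample and OTU identifiers, and an optional per-OTU lineage string.
#' Rows are samples, columns are OTUs (on disk the conventional orientation,
#' OTUs as rows, is used; see [readOTUTable()]).
#'
#' @slot counts numeric matrix, samples x OTUs, non-negative; dimnames required.
#' @slot taxonomy named character vector of lineage strings, names are OTU ids;
#'   may be empty.
#'
#' @seealso [OTUTable()], [readOTUTable()], [filterRareOTUs()], [rarefyTable()]
#' @exportClass OTUTable
setClass("OTUTable", representation(counts = "matrix", taxonomy = "character"))

setValidity("OTUTable", function(object) {
  cts <- object@counts
  msg <- character()
  if ((nrow(cts) > 0 && is.null(rownames(cts))) ||
      (ncol(cts) > 0 && is.null(colnames(cts))))
    msg <- c(msg, "counts must have sample (row) and OTU (column) names")
  else {
    if (anyDuplicated(rownames(cts)))
      msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(cts)))
      msg <- c(msg, "duplicate OTU ids")
  }
  if (!is.numeric(cts))
    msg <- c(msg, "counts must be numeric")
  else {
    if (any(!is.finite(cts)))
      msg <- c(msg, "counts must be finite")
    else if (any(cts < 0))
      msg <- c(msg, "counts must be non-negative")
  }
  tax <- object@taxonomy
  if (length(tax) && !all(names(tax) %in% colnames(cts)))
    msg <- c(msg, "taxonomy names must be OTU ids of the table")
  if (length(msg)) msg else TRUE
})

#' EMSReport: elements-of-metacommunity-structure results
#'
#' Holds the ordination and the three EMS statistics (coherence, turnover,
#' boundary clumping) for one incidence matrix, together with the structure
#' classification derived from their joint sign/significance pattern.
#'
#' @slot ordination list: site/species first-axis scores, orderings, the
#'   ordered matrix, and the leading non-trivial eigenvalue.
#' @slot coherence list: observed embedded absences, null mean/sd, z,
#'   normal-approximation and empirical p-values.
#' @slot turnover list: observed replacements on the range-filled matrix,
#'   null mean/sd, z, p-values.
#' @slot clumping list: Morisita index of range-boundary dispersion, chi-square
#'   statistic, df, p-value.
#' @slot classification character: one of checkerboard, random, nested,
#'   clementsian, gleasonian, evenly_spaced (optionally quasi-prefixed), or
#'   indeterminate.
#' @slot nullSpec list: the null-model settings used (model, permutations,
#'   allowEmpty, reordinateNulls, seed).
#'
#' @seealso [emsAnalysis()], [classifyStructure()]
#' @exportClass EMSReport
setClass("EMSReport", representation(
  ordination = "list", coherence = "list", turnover = "list",
  clumping = "list", classification = "character", nullSpec = "list"))

setValidity("EMSReport", function(object) {
  msg <- character()
  if (length(object@classification) != 1L)
    msg <- c(msg, "classification must be a single label")
  ok <- function(x, f) is.null(x[[f]]) || is.na(x[[f]]) || x[[f]] >= 0
  if (!ok(object@coherence, "observed")) msg <- c(msg, "negative absence count")
  if (!ok(object@turnover, "observed")) msg <- c(msg, "negative replacement count")
  if (!ok(object@clumping, "index")) msg <- c(msg, "negative Morisita index")
  if (length(msg)) msg else TRUE
})

#' CompartmentSplit: a boundary split of an ordinated incidence matrix
#'
#' @slot boundary integer index into the ordered site sequence; child 1 holds
#'   ordered rows before the boundary, child 2 the boundary row onwards.
#' @slot children list of two binary matrices (empty species columns dropped).
#' @slot reports list of two [EMSReport-class] objects (NULL where a child was
#'   too small to analyse).
#'
#' @seealso [splitCompartments()]
#' @exportClass CompartmentSplit
setClass("CompartmentSplit", representation(
  boundary = "integer", children = "list", reports = "list"))

setValidity("CompartmentSplit", function(object) {
  msg <- character()
  if (length(object@children) != 2L) msg <- c(msg, "exactly two children required")
  if (length(object@reports) != 2L) msg <- c(msg, "exactly two report slots required")
  if (length(msg)) msg else TRUE
})

#' MetacomScenario: parameters of a synthetic metacommunity
#'
#' Describes a latent one-dimensional environmental gradient and how species
#' ranges are arranged along it.
#'
#' @slot structure one of clementsian, gleasonian, nested, evenly_spaced,
#'   checkerboard, random.
#' @slot nSites,nSpecies matrix dimensions (sites >= 4, species >= 2).
#' @slot nCompartments number of clementsian compartments (>= 1).
#' @slot compartmentSizes optional integer vector of per-compartment site
#'   counts (must sum to nSites); equal blocks when empty.
#' @slot boundaryNoise probability in [0, 0.5) that a cell is flipped after
#'   structure construction.
#' @slot fill Bernoulli occupancy used by the random structure.
#' @slot gradient per-site positions on the latent axis.
#' @slot seed integer seed (NA for none).
#'
#' @seealso [metacomScenario()], [simulateIncidence()]
#' @exportClass MetacomScenario
setClass("MetacomScenario", representation(
  structure = "character", nSites = "integer", nSpecies = "integer",
  nCompartments = "integer", compartmentSizes = "integer",
  boundaryNoise = "numeric", fill = "numeric", gradient = "numeric",
  seed = "integer"))

.scenarioStructures <- c("clementsian", "gleasonian", "nested",
                         "evenly_spaced", "checkerboard", "random")

setValidity("MetacomScenario", function(object) {
  msg <- character()
  if (!object@structure %in% .scenarioStructures)
    msg <- c(msg, paste("unknown structure:", object@structure))
  if (object@nSites < 4L) msg <- c(msg, "nSites must be >= 4")
  if (object@nSpecies < 2L) msg <- c(msg, "nSpecies must be >= 2")
  if (object@boundaryNoise < 0 || object@boundaryNoise >= 0.5)
    msg <- c(msg, "boundaryNoise must lie in [0, 0.5)")
  if (object@nCompartments < 1L) msg <- c(msg, "nCompartments must be >= 1")
  if (object@structure == "clementsian" &&
      object@nCompartments > object@nSites / 2)
    msg <- c(msg, "degenerate scenario: nCompartments exceeds nSites/2")
  if (length(object@compartmentSizes) &&
      (length(object@compartmentSizes) != object@nCompartments ||
       sum(object@compartmentSizes) != object@nSites))
    msg <- c(msg, "compartmentSizes must have one entry per compartment and sum to nSites")
  if (length(object@gradient) != object@nSites)
    msg <- c(msg, "gradient must have one position per site")
  if (object@fill <= 0 || object@fill >= 1)
    msg <- c(msg, "fill must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' SimulatedDataset: a full synthetic study with ground truth
#'
#' Bundles everything the analysis pipeline consumes — abundance table,
#' phylogeny, sample metadata, pairwise population Fst — together with the
#' generating scenario and per-sample truth labels, so structure recovery can
#' be scored against a known answer.
#'
#' @slot abundance an [OTUTable-class] (animal and water samples).
#' @slot tree rooted `phylo` whose tips are exactly the table's OTUs.
#' @slot metadata data.frame with sample_id, population, deme, sample_type,
#'   latitude, longitude, elevation, forest_cover.
#' @slot fst symmetric zero-diagonal matrix over populations.
#' @slot truth list: the scenario, per-sample gradient ranks and compartment
#'   labels.
#'
#' @seealso [simulateDataset()], [writeDataset()]
#' @exportClass SimulatedDataset
setClass("SimulatedDataset", representation(
  abundance = "OTUTable", tree = "phylo", metadata = "data.frame",
  fst = "matrix", truth = "list"))

setValidity("SimulatedDataset", function(object) {
  msg <- character()
  md <- object@metadata
  if (!all(rownames(object@abundance@counts) %in% md$sample_id))
    msg <- c(msg, "every sample needs a metadata row")
  if (!setequal(colnames(object@abundance@counts), object@tree$tip.label))
    msg <- c(msg, "tree tips must equal table OTUs")
  pops <- unique(md$population)
  if (!setequal(rownames(object@fst), pops))
    msg <- c(msg, "fst dimension must match the populations")
  if (length(msg)) msg else TRUE
})
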