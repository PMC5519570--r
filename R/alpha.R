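#' Per-sample alpha-diversity summaries
#'
#' Observed richness (OTUs with nonzero count), Shannon diversity
#' H = -sum p_i log p_i over within-sample proportions (natural log by
#' default), and — when metadata with water samples is supplied — each animal
#' sample's proportion of OTUs shared with its population's water sample(s).
#' A warning is raised when row sums are unequal, since these summaries are
#' meant for a rarefied table.
#'
#' @param x an [OTUTable-class]
#' @param metadata optional metadata data.frame; enables the shared-OTU
#'   proportion for animal samples
#' @param base logarithm base for Shannon H (default `exp(1)`, nats)
#' @param sharedDenominator denominator convention for the shared proportion:
#'   the animal's richness (`"animal"`, default) or the size of the
#'   animal-water union (`"union"`)
#' @return data.frame with columns sample_id, richness, shannon, and (with
#'   metadata) population, deme, sample_type, shared_proportion (NA for water
#'   samples and for animals without a water sample in their population)
#' @export
alphaSummaries <- function(x, metadata = NULL, base = exp(1),
                           sharedDenominator = c("animal", "union")) {
  stopifnot(is(x, "OTUTable"))
  sharedDenominator <- match.arg(sharedDenominator)
  cts <- x@counts
  totals <- rowSums(cts)
  if (length(unique(totals[totals > 0])) > 1L)
    warning("unequal sample depths; alpha summaries are intended for a rarefied table")
  richness <- rowSums(cts > 0)
  shannon <- vegan::diversity(cts, index = "shannon", base = base)
  shannon[totals == 0] <- 0
  out <- data.frame(sample_id = rownames(cts), richness = as.integer(richness),
                    shannon = as.numeric(shannon), stringsAsFactors = FALSE)
  if (is.null(metadata)) return(out)
  md <- metadata[match(out$sample_id, metadata$sample_id), ]
  out$population <- md$population
  out$deme <- md$deme
  out$sample_type <- md$sample_type
  out$shared_proportion <- NA_real_
  for (pop in unique(md$population)) {
    wat <- out$sample_id[md$population == pop & md$sample_type == "water"]
    ani <- out$sample_id[md$population == pop & md$sample_type == "animal"]
    if (!length(wat) || !length(ani)) next
    water_set <- colnames(cts)[colSums(cts[wat, , drop = FALSE] > 0) > 0]
    for (a in ani) {
      animal_set <- colnames(cts)[cts[a, ] > 0]
      out$shared_proportion[out$sample_id == a] <-
        sharedProportion(animal_set, water_set, denominator = sharedDenominator)
    }
  }
  out
}

#' Proportion of an animal sample's OTUs shared with river water
#'
#' @param animal,water either character vectors of present OTU ids, or named
#'   count vectors (nonzero entries are taken as present)
#' @param denominator `"animal"` (shared / animal richness, default) or
#'   `"union"` (shared / size of union)
#' @return fraction in `[0, 1]`; `NA` when the animal sample has no OTUs
#' @examples
#' sharedProportion(c("A", "B", "C", "D", "E"), c("A", "B", "F"))  # 0.4
#' @export
sharedProportion <- function(animal, water, denominator = c("animal", "union")) {
  denominator <- match.arg(denominator)
  toSet <- function(v) {
    if (is.numeric(v)) {
      if (is.null(names(v))) stop("count vectors must be named by OTU id")
      names(v)[v > 0]
    } else unique(as.character(v))
  }
  a <- toSet(animal); w <- toSet(water)
  if (!length(a)) {
    warning("animal sample has no OTUs; shared proportion undefined")
    return(NA_real_)
  }
  shared <- length(intersect(a, w))
  denom <- if (denominator == "animal") length(a) else length(union(a, w))
  shared / denom
}
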