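#' Remove rare OTUs by a fraction of the total read count
#'
#' Drops every OTU whose summed count across samples falls below
#' `minFraction` of the grand total of the input table (default 0.005%, the
#' usual guard against spurious OTUs from sequencing error). The grand total
#' is computed once on the input; samples are untouched.
#'
#' @param x an [OTUTable-class]
#' @param minFraction fraction of the grand total in `[0, 1)`; an OTU is kept
#'   iff its total count is `>= minFraction * sum(counts(x))`.
#' @return filtered [OTUTable-class]
#' @export
filterRareOTUs <- function(x, minFraction = 5e-5) {
  stopifnot(is(x, "OTUTable"))
  if (!is.numeric(minFraction) || minFraction < 0 || minFraction >= 1)
    stop("minFraction must lie in [0, 1)")
  if (minFraction == 0) return(x)
  threshold <- minFraction * sum(x@counts)
  keep <- colSums(x@counts) >= threshold
  if (!any(keep))
    warning("all OTUs fall below the abundance threshold; empty table returned")
  x[, keep]
}

#' Rarefy samples to a common read depth
#'
#' Subsamples each sample's reads without replacement down to exactly `depth`
#' (via [vegan::rrarefy()]); samples whose total is below `depth` are dropped
#' with a warning naming them. Deterministic under `seed`.
#'
#' @param x an [OTUTable-class]
#' @param depth target reads per sample (default 8,800)
#' @param seed integer seed, or NULL to use the current RNG stream
#' @return rarefied [OTUTable-class] (row sums all equal `depth`)
#' @export
rarefyTable <- function(x, depth = 8800, seed = NULL) {
  stopifnot(is(x, "OTUTable"))
  if (!is.numeric(depth) || length(depth) != 1L || depth < 1)
    stop("depth must be a positive count")
  depth <- as.integer(round(depth))
  totals <- rowSums(x@counts)
  shallow <- totals < depth
  if (any(shallow)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(shallow), depth,
                    paste(rownames(x@counts)[shallow], collapse = ", ")))
    x <- x[!shallow, ]
  }
  if (nrow(x@counts) == 0L) return(x)
  exact <- rowSums(x@counts) == depth
  cts <- x@counts
  if (any(!exact)) {
    # vegan warns heuristically when the smallest count "looks" too large
    # for count data; our inputs are genuine read counts
    sub <- withSeed(seed, withCallingHandlers(
      vegan::rrarefy(round(cts[!exact, , drop = FALSE]), depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w)))
          invokeRestart("muffleWarning")
      }))
    cts[!exact, ] <- sub
  }
  out <- x
  out@counts <- cts
  validObject(out)
  out
}

#' Core microbiome: OTUs above a prevalence threshold
#'
#' An OTU belongs to the core when its prevalence (fraction of samples with a
#' nonzero count) is `>= prevalence`, compared on exact fractions with no
#' rounding, so e.g. 41/51 ~ 0.804 passes a 0.80 threshold and 40/51 ~ 0.784
#' does not.
#'
#' @param x an [OTUTable-class]
#' @param prevalence required fraction of samples in `(0, 1]` (default 0.80)
#' @return character vector of core OTU ids, sorted by decreasing mean
#'   relative abundance
#' @export
coreMicrobiome <- function(x, prevalence = 0.80) {
  stopifnot(is(x, "OTUTable"))
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence > 1)
    stop("prevalence must lie in (0, 1]")
  cts <- x@counts
  prev <- colSums(cts > 0) / nrow(cts)
  core <- colnames(cts)[prev >= prevalence]
  if (!length(core)) return(character())
  rel <- cts / pmax(rowSums(cts), 1)
  meanRel <- colMeans(rel[, core, drop = FALSE])
  core[order(-meanRel, seq_along(core))]
}

#' Binary incidence matrix from an abundance table
#'
#' Converts counts to presence/absence, optionally restricting to a subset of
#' sample types (the metacommunity analysis uses the animal skin samples
#' only), and dropping OTUs absent from every retained sample.
#'
#' @param x an [OTUTable-class]
#' @param metadata optional metadata data.frame (required when
#'   `sampleTypes` is given)
#' @param sampleTypes which `sample_type` values to keep, or NULL for all
#' @return binary matrix, sites (samples) x species (OTUs)
#' @export
toIncidence <- function(x, metadata = NULL, sampleTypes = NULL) {
  stopifnot(is(x, "OTUTable"))
  cts <- x@counts
  if (!is.null(sampleTypes)) {
    if (is.null(metadata))
      stop("metadata is required to restrict sample types")
    keep_ids <- metadata$sample_id[metadata$sample_type %in% sampleTypes]
    cts <- cts[rownames(cts) %in% keep_ids, , drop = FALSE]
  }
  inc <- (cts > 0) * 1
  inc <- inc[, colSums(inc) > 0, drop = FALSE]
  inc
}
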