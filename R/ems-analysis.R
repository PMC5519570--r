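#' Full elements-of-metacommunity-structure analysis
#'
#' Ordinates the incidence matrix by reciprocal averaging, draws one stream
#' of r1 fixed-proportional null matrices, evaluates coherence (embedded
#' absences) and species turnover (replacements) against it, measures
#' boundary clumping with Morisita's index, and classifies the
#' metacommunity structure from the joint sign/significance pattern.
#'
#' @param m binary sites x species incidence matrix (counts are binarized;
#'   empty rows/columns removed with a warning)
#' @param nPermutations number of r1 null matrices (default 99)
#' @param seed integer seed for the null stream
#' @param allowEmpty allow empty columns in null matrices (default TRUE)
#' @param reordinateNulls re-ordinate each null before counting (default TRUE)
#' @param margins embedded-absence convention, `"both"` or `"columns"`
#' @param alpha two-tailed significance level for the classification tree
#' @param quasi label non-significant turnover as `quasi-` variants
#' @param dfConvention Morisita chi-square df convention (see
#'   [boundaryClumping()])
#' @param biasCorrect centre the coherence z-score by a double-permutation
#'   estimate of the null-conditioning bias (default TRUE). r1 nulls
#'   inherit the observed matrix's marginal fluctuations plus fresh
#'   sampling noise, which makes them systematically more compressible
#'   under re-ordination than the data; a few nulls are therefore scored
#'   as pseudo-observations against their own second-level nulls and the
#'   mean pseudo z is subtracted. The uncorrected z is kept as `zRaw`.
#'   Turnover is left uncorrected: its classification role is sign or
#'   extreme significance, where the bias is immaterial.
#' @param biasOuter,biasInner first-level pseudo-observations and
#'   second-level permutations used for the bias estimate
#' @param clumpingTest how boundary-clumping significance enters the
#'   classification: `"bootstrap"` (default) compares the observed Morisita
#'   index with a range-placement null — each species' observed range length
#'   placed uniformly at random and the simulated matrix re-ordinated — which
#'   stays calibrated when ordination noise inflates the index;
#'   `"chisq"` uses the conventional dispersion chi-square against 1
#'   (the field's standard workflow, appropriate when the index is far from
#'   1, but prone to calling any ordinated matrix clumped when species far
#'   outnumber sites)
#' @return an [EMSReport-class]
#' @examples
#' scen <- metacomScenario("nested", nSites = 16, nSpecies = 40, seed = 7)
#' rep <- emsAnalysis(simulateIncidence(scen), nPermutations = 49, seed = 7)
#' classification(rep)
#' @export
emsAnalysis <- function(m, nPermutations = 99, seed = NULL, allowEmpty = TRUE,
                        reordinateNulls = TRUE,
                        margins = c("both", "columns"), alpha = 0.05,
                        quasi = FALSE, dfConvention = c("sites", "ranges"),
                        biasCorrect = TRUE, biasOuter = 12, biasInner = 49,
                        clumpingTest = c("bootstrap", "chisq")) {
  margins <- match.arg(margins)
  dfConvention <- match.arg(dfConvention)
  clumpingTest <- match.arg(clumpingTest)
  ord <- ordinateIncidence(m)
  nulls <- .emsNullStats(ord$matrix, nPermutations, seed, allowEmpty,
                         reordinateNulls, margins, keepSims = biasCorrect)
  coh <- .nullSummary(countEmbeddedAbsences(ord$ordered, margins = margins),
                      nulls$absences)
  turn <- .nullSummary(countReplacements(fillRanges(ord$ordered)),
                       nulls$replacements)
  if (biasCorrect) {
    bias <- .emsBias(nulls$sims, nOuter = biasOuter, nInner = biasInner,
                     seed = seed, allowEmpty = allowEmpty,
                     reordinateNulls = reordinateNulls, margins = margins)
    # coherence only: its classification role includes the near-null
    # checkerboard/random decision where the conditioning bias is decisive;
    # turnover is judged by sign or extreme significance, and the
    # null-of-null estimate is unreliable on strongly nested margins
    coh <- .applyBias(coh, bias$absences)
  }
  clump <- boundaryClumping(ord$ordered, dfConvention = dfConvention)
  # classification assesses clumping against a range-placement bootstrap
  # (observed range lengths, boundaries placed uniformly at random,
  # re-ordinated): CA ordination merges boundary tallies wherever adjacent
  # sites are weakly distinguishable, inflating I_M above 1 even for truly
  # random boundaries, and the bootstrap reproduces exactly that bias. The
  # conventional dispersion chi-square against 1 is kept as pChisq.
  clump$pChisq <- clump$p
  clump$test <- clumpingTest
  if (clumpingTest == "bootstrap") {
    nullIM <- .clumpingNullIM(ord$ordered, n = nPermutations,
                              seed = childSeed(seed, 7919))
    nullIM <- nullIM[is.finite(nullIM)]
    if (length(nullIM) >= 5 && stats::sd(nullIM) > 0) {
      clump$nullMean <- mean(nullIM)
      clump$nullSD <- stats::sd(nullIM)
      clump$z <- (clump$index - clump$nullMean) / clump$nullSD
      clump$p <- 2 * stats::pnorm(-abs(clump$z))
    }
  }
  label <- classifyStructure(coh, turn, clump, alpha = alpha, quasi = quasi)
  new("EMSReport",
      ordination = unclass(ord), coherence = coh, turnover = turn,
      clumping = clump, classification = label,
      nullSpec = list(model = "r1", nPermutations = nPermutations,
                      allowEmpty = allowEmpty,
                      reordinateNulls = reordinateNulls,
                      seed = if (is.null(seed)) NA_integer_ else seed,
                      margins = margins, alpha = alpha,
                      dfConvention = dfConvention))
}

#' Classify metacommunity structure from the three EMS statistics
#'
#' Decision tree: significantly more embedded absences than the null
#' (negative coherence) is a checkerboard; non-significant coherence is
#' random; under positive coherence, significantly negative turnover is
#' nested, significantly positive turnover is Clementsian when boundary
#' clumping is significantly above 1, evenly spaced when significantly below
#' 1, and Gleasonian otherwise. Non-significant turnover is labelled by its
#' sign through the same sub-tree, with a `quasi-` prefix when
#' `quasi = TRUE`. Undefined (degenerate) p-values yield `"indeterminate"`.
#'
#' @param coherence,turnover lists as returned by [emsCoherence()] /
#'   [emsTurnover()] (fields `z`, `p`)
#' @param clumping list as returned by [boundaryClumping()] (fields `index`,
#'   `p`)
#' @param alpha significance level (default 0.05)
#' @param quasi enable quasi-structure labels (default FALSE)
#' @return a structure label string
#' @export
classifyStructure <- function(coherence, turnover, clumping, alpha = 0.05,
                              quasi = FALSE) {
  if (is.na(coherence$p) || is.na(turnover$p) || is.na(clumping$p))
    return("indeterminate")
  if (coherence$p >= alpha) return("random")
  if (coherence$z > 0) return("checkerboard")
  turnSig <- turnover$p < alpha
  prefix <- if (!turnSig && quasi) "quasi-" else ""
  if (turnover$z < 0) return(paste0(prefix, "nested"))
  # clumping direction: relative to its null distribution when available
  # (see emsAnalysis), else relative to 1
  clumped <- if (!is.null(clumping$z)) clumping$z > 0 else clumping$index > 1
  clumpLabel <- if (clumping$p < alpha && clumped) "clementsian"
    else if (clumping$p < alpha && !clumped) "evenly_spaced"
    else "gleasonian"
  paste0(prefix, clumpLabel)
}

#' @describeIn emsAnalysis structure label of a report
#' @param x an EMSReport
#' @export
setMethod("classification", "EMSReport", function(x) x@classification)

#' @describeIn emsAnalysis the three EMS statistic records of a report
#' @export
setMethod("emsStats", "EMSReport", function(x)
  list(coherence = x@coherence, turnover = x@turnover, clumping = x@clumping))

setMethod("show", "EMSReport", function(object) {
  co <- object@coherence; tu <- object@turnover; cl <- object@clumping
  fmt <- function(x) format(round(x, 2), big.mark = ",", trim = TRUE)
  cat("Elements of metacommunity structure\n")
  cat(sprintf("  coherence: absences %s; null %s +/- %s; z = %.2f, p = %.3g\n",
              fmt(co$observed), fmt(co$nullMean), fmt(co$nullSD), co$z, co$p))
  cat(sprintf("  turnover:  replacements %s; null %s +/- %s; z = %.2f, p = %.3g\n",
              fmt(tu$observed), fmt(tu$nullMean), fmt(tu$nullSD), tu$z, tu$p))
  cat(sprintf("  clumping:  Morisita index %.2f (df = %d, p = %.3g)\n",
              cl$index, cl$df, cl$p))
  cat(sprintf("  classification: %s\n", object@classification))
  invisible(NULL)
})

#' Split an ordinated matrix into compartments and re-analyse each
#'
#' Splits the site ordering at a boundary — either supplied, or chosen
#' automatically as the position maximizing the Jaccard dissimilarity
#' between the two adjacent ordered sites that would straddle it (the
#' between-group vs within-group separation of adjacent rows) — into two
#' child matrices whose empty species columns are dropped, then ordinates
#' and fully re-analyses each child. Children with fewer than `minRows`
#' sites are refused with a warning (their report slot is NULL).
#'
#' @param m binary incidence matrix
#' @param boundary `"auto"`, or the number of ordered rows in the first
#'   child (1 <= boundary < number of sites)
#' @param minRows smallest analysable child (default 4 sites)
#' @param ... further arguments passed to [emsAnalysis()] for each child
#'   (nPermutations, seed, ...)
#' @return a [CompartmentSplit-class]
#' @export
splitCompartments <- function(m, boundary = "auto", minRows = 4, ...) {
  ord <- ordinateIncidence(m)
  om <- ord$ordered
  n <- nrow(om)
  if (identical(boundary, "auto")) {
    adj <- vapply(seq_len(n - 1L), function(i) {
      a <- om[i, ] > 0; b <- om[i + 1L, ] > 0
      un <- sum(a | b)
      if (un == 0) 0 else 1 - sum(a & b) / un
    }, numeric(1))
    boundary <- which.max(adj)
  }
  boundary <- as.integer(boundary)
  if (boundary < 1L || boundary >= n)
    stop("boundary must lie strictly inside the ordered site range")
  children <- list(om[seq_len(boundary), , drop = FALSE],
                   om[(boundary + 1L):n, , drop = FALSE])
  children <- lapply(children, function(x)
    x[, colSums(x) > 0, drop = FALSE])
  reports <- lapply(seq_along(children), function(k) {
    child <- children[[k]]
    if (nrow(child) < minRows || ncol(child) < 2L) {
      warning(sprintf("compartment %d has %d site(s); analysis refused (needs >= %d)",
                      k, nrow(child), minRows))
      return(NULL)
    }
    tryCatch(emsAnalysis(child, ...), error = function(e) {
      warning(sprintf("compartment %d not analysable: %s", k,
                      conditionMessage(e)))
      NULL
    })
  })
  new("CompartmentSplit", boundary = boundary, children = children,
      reports = reports)
}

setMethod("show", "CompartmentSplit", function(object) {
  cat(sprintf("CompartmentSplit at ordered row %d: children of %d and %d sites\n",
              object@boundary, nrow(object@children[[1]]),
              nrow(object@children[[2]])))
  for (k in 1:2) {
    if (is.null(object@reports[[k]]))
      cat(sprintf("  compartment %d: not analysed\n", k))
    else
      cat(sprintf("  compartment %d: %s\n", k,
                  object@reports[[k]]@classification))
  }
  invisible(NULL)
})

#' Correlate site ordination scores with a sample covariate
#'
#' Pearson correlation (two-tailed t test) between the first-axis site
#' scores and a numeric metadata covariate such as latitude, elevation or
#' percent forest cover — the standard check of what the latent gradient
#' tracks.
#'
#' @param ordination an [ordinateIncidence()] result or an
#'   [EMSReport-class]
#' @param metadata metadata data.frame with a `sample_id` column
#' @param covariate name of a numeric metadata column
#' @return list: r, p, n (samples used)
#' @export
scoreCovariateCorrelation <- function(ordination, metadata, covariate) {
  if (is(ordination, "EMSReport")) ordination <- ordination@ordination
  scores <- ordination$siteScores
  if (!covariate %in% names(metadata))
    stop("no metadata column named '", covariate, "'")
  v <- metadata[[covariate]][match(names(scores), metadata$sample_id)]
  keep <- is.finite(v) & is.finite(scores)
  v <- v[keep]; s <- scores[keep]
  if (length(s) < 3L) stop("need at least 3 samples with covariate values")
  if (stats::sd(v) == 0) {
    warning("zero-variance covariate '", covariate, "'; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(s)))
  }
  ct <- stats::cor.test(s, v, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(s))
}

#' Export an ordered incidence matrix with covariate side-bars
#'
#' Writes the ordinated matrix as TSV plot data: one row per ordered site
#' with its score and any requested metadata covariates, followed by the
#' 0/1 species columns in ordinated order — the data behind the classic
#' ordered-incidence figure.
#'
#' @param report an [EMSReport-class]
#' @param path output TSV path
#' @param metadata optional metadata data.frame
#' @param covariates metadata columns to include as side-bars
#' @return invisibly, `path`
#' @export
writeOrderedIncidence <- function(report, path, metadata = NULL,
                                  covariates = c("latitude", "elevation",
                                                 "forest_cover")) {
  stopifnot(is(report, "EMSReport"))
  ord <- report@ordination
  om <- ord$ordered
  df <- data.frame(sample_id = rownames(om),
                   score = unname(ord$siteScores[ord$rowOrder]))
  if (!is.null(metadata)) {
    idx <- match(df$sample_id, metadata$sample_id)
    for (cv in intersect(covariates, names(metadata)))
      df[[cv]] <- metadata[[cv]][idx]
  }
  utils::write.table(cbind(df, om), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
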