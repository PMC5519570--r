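# EMS statistics: embedded absences (coherence), range filling and species
# replacements (turnover), Morisita boundary clumping, and the r1
# fixed-proportional null-model stream they are all tested against.

#' Count embedded absences in an ordinated incidence matrix
#'
#' An embedded absence is a 0 lying strictly between the first and last 1 of
#' a species column (a gap inside the species' range). By default the same
#' count over site rows is added (both-margins convention, as in the
#' reference metacommunity implementation); `margins = "columns"` restricts
#' to species ranges only.
#'
#' @param m binary ordered matrix
#' @param margins `"both"` (default) or `"columns"`
#' @return integer count
#' @export
countEmbeddedAbsences <- function(m, margins = c("both", "columns")) {
  margins <- match.arg(margins)
  m <- (m > 0) * 1
  total <- .marginAbsences(m)
  if (margins == "both") total <- total + .marginAbsences(t(m))
  unname(total)
}

# gaps within column ranges (vectorized: first/last 1 per column via
# max.col on the transposed matrix)
.marginAbsences <- function(m) {
  cs <- colSums(m)
  ok <- cs > 1
  if (!any(ok)) return(0)
  tm <- t(m[, ok, drop = FALSE])
  n <- ncol(tm)
  first <- max.col(tm, ties.method = "first")
  last <- n + 1L - max.col(tm[, n:1, drop = FALSE], ties.method = "first")
  sum(last - first + 1 - cs[ok])
}

# first and last occupied site per column (NA for empty columns)
.rangeEnds <- function(m) {
  cs <- colSums(m)
  n <- nrow(m)
  first <- rep(NA_integer_, ncol(m))
  last <- first
  ok <- cs > 0
  if (any(ok)) {
    tm <- t(m[, ok, drop = FALSE])
    first[ok] <- max.col(tm, ties.method = "first")
    last[ok] <- n + 1L - max.col(tm[, n:1, drop = FALSE],
                                 ties.method = "first")
  }
  list(first = first, last = last, count = cs)
}

#' Fill species ranges in an ordered incidence matrix
#'
#' Sets every embedded absence to 1, making each species' range a contiguous
#' block of sites — the substrate on which turnover replacements are counted.
#'
#' @param m binary ordered matrix
#' @return matrix with contiguous column ranges
#' @export
fillRanges <- function(m) {
  m <- (m > 0) * 1
  re <- .rangeEnds(m)
  gaps <- which(!is.na(re$first) & (re$last - re$first + 1) > re$count)
  for (j in gaps) m[re$first[j]:re$last[j], j] <- 1
  m
}

#' Count species replacements (turnover) on a range-filled matrix
#'
#' For every unordered species pair (i, j), the number of replacements is
#' (sites holding i but not j) x (sites holding j but not i); the statistic
#' is the sum over all pairs, computed on the range-filled matrix.
#'
#' @param filled binary matrix with contiguous column ranges (see
#'   [fillRanges()])
#' @return numeric count
#' @export
countReplacements <- function(filled) {
  n <- colSums(filled)
  C <- crossprod(filled)            # co-occurrence counts
  onlyI <- n - C                    # [i, j] = sites with i but not j
  prod <- onlyI * t(onlyI)
  sum(prod[upper.tri(prod)])
}

#' Generate fixed-proportional (r1) null incidence matrices
#'
#' The r1 null model conserves each site's observed richness (row sums are
#' reproduced exactly) while filling species by weighted sampling without
#' replacement with probabilities proportional to the observed species
#' occurrence totals. Columns may come out empty; with
#' `allowEmpty = FALSE` such matrices are redrawn. Generation is delegated
#' to [vegan::nullmodel()] (model `"r1"`) and is reproducible under `seed`.
#'
#' @param m binary sites x species matrix
#' @param n number of null matrices (default 99)
#' @param seed integer seed
#' @param allowEmpty keep null matrices with empty columns (default TRUE)
#' @return 3-d array, sites x species x n
#' @export
r1Null <- function(m, n = 99, seed = NULL, allowEmpty = TRUE) {
  m <- (as.matrix(m) > 0) * 1
  if (n < 1) stop("n must be >= 1")
  nm <- vegan::nullmodel(m, "r1")
  draw <- function(k, s) {
    sims <- if (is.null(s)) stats::simulate(nm, nsim = k)
            else stats::simulate(nm, nsim = k, seed = s)
    sims
  }
  sims <- draw(n, seed)
  if (!allowEmpty) {
    ok <- apply(sims, 3L, function(x) all(colSums(x) > 0))
    tries <- 0L
    while (!all(ok) && tries < 50L) {
      tries <- tries + 1L
      extra <- draw(sum(!ok), if (is.null(seed)) NULL else seed + tries)
      sims[, , !ok] <- extra
      ok <- apply(sims, 3L, function(x) all(colSums(x) > 0))
    }
    if (!all(ok))
      warning("could not avoid empty columns in all null matrices")
  }
  dimnames(sims) <- c(dimnames(m), list(NULL))
  sims
}

# One pass over a shared null stream computing coherence absences, turnover
# replacements and the Morisita boundary-clumping index per null matrix
# (each null re-ordinated first when requested, and range-filled for
# turnover). Returns a list of three numeric vectors.
.emsNullStats <- function(m, nPermutations, seed, allowEmpty, reordinateNulls,
                          margins, keepSims = FALSE, doReplacements = TRUE) {
  sims <- r1Null(m, n = nPermutations, seed = seed, allowEmpty = allowEmpty)
  absences <- numeric(nPermutations)
  replacements <- numeric(nPermutations)
  for (k in seq_len(nPermutations)) {
    nullm <- sims[, , k]
    nullm <- nullm[, colSums(nullm) > 0, drop = FALSE]
    nullm <- nullm[rowSums(nullm) > 0, , drop = FALSE]
    if (reordinateNulls && nrow(nullm) >= 2L && ncol(nullm) >= 2L) {
      ord <- tryCatch(suppressWarnings(ordinateIncidence(nullm)),
                      error = function(e) NULL)
      if (!is.null(ord)) nullm <- ord$ordered
    }
    absences[k] <- countEmbeddedAbsences(nullm, margins = margins)
    if (doReplacements)
      replacements[k] <- countReplacements(fillRanges(nullm))
  }
  list(absences = absences, replacements = replacements,
       sims = if (keepSims) sims)
}

# Double-permutation estimate of the conditioning bias of the z-scores: a
# few first-level null matrices are treated as pseudo-observations, each
# scored against its own second-level r1 null stream. Under the null
# hypothesis the pseudo z-scores should centre on zero; their mean measures
# the bias introduced by conditioning the null on the observed margins
# (r1 nulls are systematically more ordination-compressible than the data
# whose margins they inherit).
.emsBias <- function(sims, nOuter, nInner, seed, allowEmpty,
                     reordinateNulls, margins) {
  L <- min(nOuter, dim(sims)[3])
  zAbs <- rep(NA_real_, L)
  for (k in seq_len(L)) {
    pseudo <- sims[, , k]
    pseudo <- pseudo[, colSums(pseudo) > 0, drop = FALSE]
    pseudo <- pseudo[rowSums(pseudo) > 0, , drop = FALSE]
    if (nrow(pseudo) < 2L || ncol(pseudo) < 2L) next
    ordp <- tryCatch(suppressWarnings(ordinateIncidence(pseudo)),
                     error = function(e) NULL)
    if (is.null(ordp)) next
    xAbs <- countEmbeddedAbsences(ordp$ordered, margins = margins)
    inner <- .emsNullStats(ordp$matrix, nInner, childSeed(seed, 5000 + k),
                           allowEmpty, reordinateNulls, margins,
                           doReplacements = FALSE)
    if (stats::sd(inner$absences) > 0)
      zAbs[k] <- (xAbs - mean(inner$absences)) / stats::sd(inner$absences)
  }
  list(absences = mean(zAbs, na.rm = TRUE))
}

# apply a bias estimate to a .nullSummary record
.applyBias <- function(rec, bias) {
  if (!is.finite(bias) || is.na(rec$z)) return(rec)
  rec$zRaw <- rec$z
  rec$bias <- bias
  rec$z <- rec$z - bias
  rec$p <- 2 * stats::pnorm(-abs(rec$z))
  rec
}

# Range-placement bootstrap for boundary clumping: keep each species'
# observed (filled) range length, place the ranges uniformly at random along
# the sites, re-ordinate, and recompute Morisita's index. This is exactly
# the "randomly distributed boundaries" (Gleasonian) hypothesis conditioned
# on range sizes, and — because every simulated matrix passes through the
# same ordination — it inherits the ordination-induced inflation of I_M
# that a comparison against the fixed value 1 ignores.
.clumpingNullIM <- function(ordered, n = 99, seed = NULL) {
  T <- nrow(ordered)
  lens <- integer(0)
  for (j in seq_len(ncol(ordered))) {
    w <- which(ordered[, j] > 0)
    if (length(w)) lens <- c(lens, w[length(w)] - w[1L] + 1L)
  }
  withSeed(seed, {
    vapply(seq_len(n), function(k) {
      m <- matrix(0L, T, length(lens))
      starts <- vapply(lens, function(L) sample.int(T - L + 1L, 1L), integer(1))
      for (j in seq_along(lens))
        m[starts[j]:(starts[j] + lens[j] - 1L), j] <- 1L
      m <- m[rowSums(m) > 0, , drop = FALSE]
      om <- tryCatch(suppressWarnings(ordinateIncidence(m)$ordered),
                     error = function(e) m)
      tryCatch(boundaryClumping(om)$index, error = function(e) NA_real_)
    }, numeric(1))
  })
}

# observed vs null summary shared by coherence and turnover
.nullSummary <- function(observed, nulls) {
  mu <- mean(nulls)
  sdv <- stats::sd(nulls)
  if (!is.finite(sdv) || sdv == 0) {
    warning("degenerate null distribution (sd = 0); p-values undefined")
    z <- NA_real_; pN <- NA_real_; pE <- NA_real_
  } else {
    z <- (observed - mu) / sdv
    pN <- 2 * stats::pnorm(-abs(z))
    pE <- (1 + sum(abs(nulls - mu) >= abs(observed - mu))) /
      (length(nulls) + 1)
  }
  list(observed = observed, nullMean = mu, nullSD = sdv, z = z,
       p = pN, pEmpirical = pE, nPermutations = length(nulls))
}

#' Coherence: embedded absences against the r1 null
#'
#' Counts embedded absences on the ordinated matrix and compares the count
#' with its distribution over r1 null matrices (each re-ordinated before
#' counting by default). Fewer absences than expected (negative z) is
#' positive coherence — species responding to a shared latent gradient;
#' significantly more absences indicates checkerboard structure.
#'
#' @param m binary incidence matrix (ordinated internally)
#' @param nPermutations,seed,allowEmpty null-model settings (defaults 99,
#'   empty columns allowed)
#' @param reordinateNulls re-ordinate each null matrix before counting
#'   (default TRUE)
#' @param margins absence-counting convention, `"both"` or `"columns"`
#' @param ordination optional precomputed [ordinateIncidence()] result
#' @return list: observed, nullMean, nullSD, z, p (normal approximation),
#'   pEmpirical, nPermutations
#' @export
emsCoherence <- function(m, nPermutations = 99, seed = NULL, allowEmpty = TRUE,
                         reordinateNulls = TRUE,
                         margins = c("both", "columns"), ordination = NULL) {
  margins <- match.arg(margins)
  if (is.null(ordination)) ordination <- ordinateIncidence(m)
  obs <- countEmbeddedAbsences(ordination$ordered, margins = margins)
  nulls <- .emsNullStats(ordination$matrix, nPermutations, seed, allowEmpty,
                         reordinateNulls, margins)$absences
  .nullSummary(obs, nulls)
}

#' Species turnover: replacements against the r1 null
#'
#' Fills species ranges on the ordinated matrix and counts pairwise species
#' replacements, comparing with the same count over (re-ordinated,
#' range-filled) r1 null matrices. More replacements than expected (positive
#' z) points to Gleasonian or Clementsian structure, fewer to nestedness.
#'
#' @inheritParams emsCoherence
#' @return list as in [emsCoherence()]
#' @export
emsTurnover <- function(m, nPermutations = 99, seed = NULL, allowEmpty = TRUE,
                        reordinateNulls = TRUE,
                        margins = c("both", "columns"), ordination = NULL) {
  margins <- match.arg(margins)
  if (is.null(ordination)) ordination <- ordinateIncidence(m)
  if (ncol(ordination$ordered) < 2L) {
    warning("single species: turnover is 0 by definition")
    return(.nullSummary(0, rep(0, nPermutations)))
  }
  obs <- countReplacements(fillRanges(ordination$ordered))
  nulls <- .emsNullStats(ordination$matrix, nPermutations, seed, allowEmpty,
                         reordinateNulls, margins)$replacements
  .nullSummary(obs, nulls)
}

#' Boundary clumping: Morisita's index over range boundaries
#'
#' Each species' two range boundaries (first and last site of its range on
#' the ordinated matrix; a single-site range contributes both at that site)
#' are tallied per site, and Morisita's index of dispersion
#' \eqn{I_M = T \sum n_i (n_i - 1) / (N (N - 1))} is computed over the T
#' sites and N boundaries. \eqn{I_M > 1} means clumped boundaries
#' (Clementsian), \eqn{< 1} hyperdispersed (evenly spaced), \eqn{= 1} random
#' (Gleasonian). Departure from 1 is tested with the dispersion chi-square
#' \eqn{I_M (N - 1) + T - N}; upper tail when clumped, lower when
#' hyperdispersed. The degrees of freedom are `T - 1` under the default
#' `"sites"` convention (the distributional match for the dispersion
#' statistic); `"ranges"` reports `S - 1` over the S species ranges, a
#' convention seen in published EMS tables.
#'
#' @param ordered binary ordered (ordinated) incidence matrix
#' @param dfConvention `"sites"` (default) or `"ranges"`
#' @return list: index, chi2, df, p, boundaries (per-site tallies), N
#' @export
boundaryClumping <- function(ordered, dfConvention = c("sites", "ranges")) {
  dfConvention <- match.arg(dfConvention)
  T <- nrow(ordered)
  ordered <- (ordered > 0) * 1
  re <- .rangeEnds(ordered)
  occupied <- !is.na(re$first)
  nRanges <- sum(occupied)
  tally <- tabulate(c(re$first[occupied], re$last[occupied]), nbins = T)
  N <- sum(tally)
  if (N < 2) stop("fewer than 2 range boundaries; Morisita index undefined")
  IM <- T * sum(tally * (tally - 1)) / (N * (N - 1))
  chi2 <- IM * (N - 1) + T - N
  df <- if (dfConvention == "sites") T - 1L else nRanges - 1L
  p <- if (IM >= 1) stats::pchisq(chi2, df, lower.tail = FALSE)
       else stats::pchisq(chi2, df, lower.tail = TRUE)
  list(index = IM, chi2 = chi2, df = df, p = p, boundaries = tally, N = N)
}
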