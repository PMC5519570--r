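# Ordination and permutation tests on distance matrices. The permutation
# machinery is vegan's; p-values use the (count + 1)/(permutations + 1)
# estimator throughout, and every test is reproducible under a seed.

#' Principal coordinate analysis of a distance matrix
#'
#' Classical metric scaling: the Gower double-centered matrix is
#' eigendecomposed, axes are ordered by eigenvalue, and axes with negative
#' (or numerically zero) eigenvalues are reported but dropped from the
#' returned coordinates.
#'
#' @param dm `dist` or symmetric matrix
#' @return list: `vectors` (samples x positive axes), `eigenvalues` (all,
#'   decreasing, including negatives), `relativeEig` (fractions of the
#'   positive total)
#' @export
pcoaOrdination <- function(dm) {
  d <- stats::as.dist(dm)
  n <- attr(d, "Size")
  if (is.null(n) || n < 3L) stop("PCoA needs at least 3 samples")
  fit <- stats::cmdscale(d, k = n - 1L, eig = TRUE)
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- which(eig > tol)
  vectors <- fit$points[, pos, drop = FALSE]
  colnames(vectors) <- sprintf("Axis%d", seq_along(pos))
  list(vectors = vectors, eigenvalues = eig,
       relativeEig = eig[pos] / sum(eig[pos]))
}

.checkGroups <- function(d, groups) {
  groups <- as.factor(groups)
  if (length(groups) != attr(stats::as.dist(d), "Size"))
    stop("groups must have one label per sample")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("every group needs at least 2 members; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  groups
}

#' ANOSIM: rank-based test of group differences on a distance matrix
#'
#' R = (mean rank of between-group distances - mean rank of within-group
#' distances) / (M / 2) with M the number of pairs; significance by
#' permutation of the group labels (delegated to [vegan::anosim()]).
#'
#' @param dm `dist` or symmetric matrix
#' @param groups group labels, one per sample
#' @param nPermutations label permutations (default 999)
#' @param seed integer seed
#' @return list: statistic (R), p, nPermutations, method
#' @export
anosimTest <- function(dm, groups, nPermutations = 999, seed = NULL) {
  d <- stats::as.dist(dm)
  groups <- .checkGroups(d, groups)
  fit <- withSeed(seed, vegan::anosim(d, groups, permutations = nPermutations))
  list(statistic = unname(fit$statistic), p = fit$signif,
       nPermutations = nPermutations, method = "ANOSIM")
}

#' PERMANOVA (Adonis): distance-based variance partition by one factor
#'
#' Pseudo-F = (SS_between / (k - 1)) / (SS_within / (n - k)) with the sums
#' of squares obtained from squared distances via the Gower-centered
#' partition; R2 = SS_between / SS_total; permutation p as in ANOSIM
#' (delegated to [vegan::adonis2()]).
#'
#' @inheritParams anosimTest
#' @return list: R2, F (pseudo-F), p, nPermutations, method
#' @export
permanovaTest <- function(dm, groups, nPermutations = 999, seed = NULL) {
  d <- stats::as.dist(dm)
  groups <- .checkGroups(d, groups)
  df <- data.frame(groups = groups)
  fit <- withSeed(seed,
    vegan::adonis2(d ~ groups, data = df, permutations = nPermutations))
  list(R2 = fit$R2[1], F = fit$F[1], p = fit$`Pr(>F)`[1],
       nPermutations = nPermutations, method = "PERMANOVA")
}

#' Mantel test: correlation between two distance matrices
#'
#' Pearson correlation over the n(n-1)/2 off-diagonal pairs; significance by
#' jointly permuting rows and columns of one matrix (delegated to
#' [vegan::mantel()]), p = (permuted r >= observed + 1) / (permutations + 1).
#' Matrices with labelled entries must agree on their ids; a zero-variance
#' matrix yields r = NA with a warning.
#'
#' @param dmA,dmB `dist` objects or symmetric matrices over the same samples
#' @param nPermutations permutations (default 10,000)
#' @param seed integer seed
#' @return list: r, p, nPermutations, method
#' @export
mantelTest <- function(dmA, dmB, nPermutations = 10000, seed = NULL) {
  a <- stats::as.dist(dmA); b <- stats::as.dist(dmB)
  if (attr(a, "Size") != attr(b, "Size"))
    stop("distance matrices differ in size")
  if (attr(a, "Size") < 4L) stop("Mantel test needs at least 4 samples")
  la <- attr(a, "Labels"); lb <- attr(b, "Labels")
  if (!is.null(la) && !is.null(lb)) {
    if (!setequal(la, lb))
      stop("distance matrices have mismatching ids")
    if (!identical(la, lb)) {       # align B to A's label order
      mb <- as.matrix(b)[la, la]
      b <- stats::as.dist(mb)
    }
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in a distance matrix; Mantel r undefined")
    return(list(r = NA_real_, p = NA_real_, nPermutations = nPermutations,
                method = "Mantel"))
  }
  fit <- withSeed(seed, vegan::mantel(a, b, method = "pearson",
                                      permutations = nPermutations))
  list(r = unname(fit$statistic), p = fit$signif,
       nPermutations = nPermutations, method = "Mantel")
}
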