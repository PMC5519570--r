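#' Ordinate an incidence matrix by reciprocal averaging
#'
#' Computes the first non-trivial correspondence-analysis axis of a binary
#' sites-by-species matrix and orders rows and columns by their scores, the
#' standard first step of an elements-of-metacommunity-structure analysis.
#' The axis is obtained by singular-value decomposition of the
#' chi-square-standardized matrix \eqn{(P - r c^T) / \sqrt{r c^T}} (row and
#' column standard coordinates \eqn{u_1/\sqrt r}, \eqn{v_1/\sqrt c}), which
#' is the fixed point of reciprocal averaging but deterministic. The axis
#' sign is fixed so the first input row's score is non-negative (if zero,
#' the first nonzero site score is made positive); ties in the ordering are
#' broken by original index.
#'
#' @param m binary sites x species matrix; counts are binarized. Empty rows
#'   and columns are removed with a warning before ordination.
#' @return an object of class `EMSOrdination`: list with elements
#'   `siteScores`, `speciesScores` (named, input order), `rowOrder`,
#'   `colOrder`, `ordered` (the reordered matrix), `eigenvalue` (first
#'   non-trivial inertia), and `matrix` (the cleaned input).
#' @examples
#' m <- rbind(S1 = c(1, 1, 0, 0), S2 = c(1, 1, 1, 0),
#'            S3 = c(0, 1, 1, 1), S4 = c(0, 0, 1, 1))
#' colnames(m) <- paste0("sp", 1:4)
#' ordinateIncidence(m)$rowOrder
#' @export
ordinateIncidence <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- sprintf("S%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sp%d", seq_len(ncol(m)))
  m <- (m > 0) * 1
  emptyR <- rowSums(m) == 0
  emptyC <- colSums(m) == 0
  if (any(emptyR) || any(emptyC)) {
    warning(sprintf("removing %d empty row(s) and %d empty column(s) before ordination",
                    sum(emptyR), sum(emptyC)))
    m <- m[!emptyR, !emptyC, drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("ordination needs at least 2 non-empty rows and columns")
  N <- sum(m)
  P <- m / N
  r <- rowSums(P)
  cc <- colSums(P)
  Sm <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  # leading singular triple via the smaller Gram matrix (much faster than a
  # full SVD when species far outnumber sites, and exactly equivalent)
  if (nrow(Sm) <= ncol(Sm)) {
    ev <- eigen(tcrossprod(Sm), symmetric = TRUE)
    sigma2 <- ev$values[1]
    if (sigma2 < 1e-24)
      stop("degenerate matrix: no non-trivial correspondence axis ",
           "(all rows/columns proportional)")
    u1 <- ev$vectors[, 1]
    v1 <- crossprod(Sm, u1) / sqrt(sigma2)
  } else {
    ev <- eigen(crossprod(Sm), symmetric = TRUE)
    sigma2 <- ev$values[1]
    if (sigma2 < 1e-24)
      stop("degenerate matrix: no non-trivial correspondence axis ",
           "(all rows/columns proportional)")
    v1 <- ev$vectors[, 1]
    u1 <- Sm %*% v1 / sqrt(sigma2)
  }
  site <- as.numeric(u1) / sqrt(r)
  species <- as.numeric(v1) / sqrt(cc)
  # deterministic orientation: first (nonzero) site score positive
  nz <- which(abs(site) > 1e-12)
  if (length(nz) && site[nz[1]] < 0) {
    site <- -site
    species <- -species
  }
  names(site) <- rownames(m)
  names(species) <- colnames(m)
  rowOrder <- order(site, seq_along(site))
  colOrder <- order(species, seq_along(species))
  structure(list(siteScores = site, speciesScores = species,
                 rowOrder = rowOrder, colOrder = colOrder,
                 ordered = m[rowOrder, colOrder, drop = FALSE],
                 eigenvalue = sigma2, matrix = m),
            class = "EMSOrdination")
}

#' @export
print.EMSOrdination <- function(x, ...) {
  cat(sprintf("Reciprocal-averaging ordination: %d sites x %d species\n",
              nrow(x$ordered), ncol(x$ordered)))
  cat(sprintf("  first non-trivial inertia: %.4f\n", x$eigenvalue))
  cat("  site order: ", paste(utils::head(names(x$siteScores)[x$rowOrder], 8),
                              collapse = " "),
      if (nrow(x$ordered) > 8) "..." else "", "\n")
  invisible(x)
}
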