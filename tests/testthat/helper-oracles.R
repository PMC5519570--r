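# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check: plain loops, explicit enumeration.

# embedded absences, both margins, by explicit cell scan
oracleAbsences <- function(m) {
  gaps <- function(v) {
    w <- which(v > 0)
    if (length(w) < 2) return(0L)
    sum(v[w[1]:w[length(w)]] == 0)
  }
  tot <- 0L
  for (j in seq_len(ncol(m))) tot <- tot + gaps(m[, j])
  for (i in seq_len(nrow(m))) tot <- tot + gaps(m[i, ])
  tot
}

# turnover replacements by explicit pair/site enumeration on the filled matrix
oracleReplacements <- function(m) {
  f <- m
  for (j in seq_len(ncol(f))) {
    w <- which(f[, j] > 0)
    if (length(w) > 1) f[w[1]:w[length(w)], j] <- 1
  }
  tot <- 0
  S <- ncol(f)
  if (S < 2) return(0)
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    a <- 0; b <- 0
    for (s in seq_len(nrow(f))) {
      if (f[s, i] > 0 && f[s, j] == 0) a <- a + 1
      if (f[s, j] > 0 && f[s, i] == 0) b <- b + 1
    }
    tot <- tot + a * b
  }
  tot
}

# Morisita index by direct re-implementation of the formula
oracleMorisita <- function(m) {
  T <- nrow(m)
  tally <- numeric(T)
  for (j in seq_len(ncol(m))) {
    w <- which(m[, j] > 0)
    if (!length(w)) next
    tally[min(w)] <- tally[min(w)] + 1
    tally[max(w)] <- tally[max(w)] + 1
  }
  N <- sum(tally)
  T * sum(tally * (tally - 1)) / (N * (N - 1))
}

# first non-trivial CA axis by dense eigendecomposition (not SVD) of the
# chi-square standardized cross-product
oracleCAScores <- function(m) {
  N <- sum(m)
  P <- m / N
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  ev <- eigen(t(S) %*% S, symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  species <- v1 / sqrt(cc)
  u1 <- S %*% v1
  u1 <- u1 / sqrt(sum(u1^2))
  site <- as.numeric(u1) / sqrt(r)
  list(site = unname(site), species = unname(species),
       eigenvalue = ev$values[1])
}

# UniFrac by explicit per-branch loop; clade membership from phangorn
oracleUniFrac <- function(counts, tree, weighted = FALSE, normalized = TRUE) {
  n <- nrow(counts)
  tree <- ape::reorder.phylo(tree, "cladewise")
  desc <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  tipIdx <- match(tree$tip.label, colnames(counts))
  dm <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  prop <- counts / pmax(rowSums(counts), 1)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    num <- 0; den <- 0
    for (e in seq_along(desc)) {
      tips <- tipIdx[desc[[e]]]
      l <- tree$edge.length[e]
      if (weighted) {
        pa <- sum(prop[a, tree$tip.label[desc[[e]]]])
        pb <- sum(prop[b, tree$tip.label[desc[[e]]]])
        num <- num + l * abs(pa - pb)
        den <- den + l * (pa + pb)
      } else {
        ina <- any(counts[a, tree$tip.label[desc[[e]]]] > 0)
        inb <- any(counts[b, tree$tip.label[desc[[e]]]] > 0)
        if (xor(ina, inb)) num <- num + l
        if (ina || inb) den <- den + l
      }
    }
    dm[a, b] <- dm[b, a] <-
      if (weighted && !normalized) num else if (den == 0) 0 else num / den
  }
  dm
}

# random binary matrix guaranteed free of empty rows/columns
randomIncidence <- function(nr, nc, fill = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- matrix(rbinom(nr * nc, 1, fill), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      dimnames(m) <- list(sprintf("S%d", seq_len(nr)),
                          sprintf("sp%d", seq_len(nc)))
      return(m)
    }
  }
}
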