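# Between-sample dissimilarities: Jaccard, unweighted/weighted UniFrac,
# geographic great-circle distance, and expansion of population-level Fst to
# the sample level. All return base `dist` objects carrying a "kind"
# attribute.

#' Jaccard dissimilarity between samples
#'
#' Binary Jaccard, d = 1 - |A intersect B| / |A union B| over OTU presence
#' sets (counts are binarized). A pair of empty samples is defined as
#' distance 0 with a warning.
#'
#' @param x an [OTUTable-class] or a samples x OTUs matrix
#' @return `dist` with attribute `kind = "jaccard"`
#' @export
jaccardMatrix <- function(x) {
  m <- if (is(x, "OTUTable")) x@counts else as.matrix(x)
  b <- (m > 0) * 1
  empty <- rowSums(b) == 0
  d <- suppressWarnings(vegan::vegdist(b, method = "jaccard", binary = TRUE))
  if (any(empty)) {
    warning("empty sample(s) present; pairwise distances involving them set to 1, 0 between two empty samples")
    dm <- as.matrix(d)
    dm[empty, ] <- 1; dm[, empty] <- 1
    dm[empty, empty] <- 0
    diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  attr(d, "kind") <- "jaccard"
  d
}

#' UniFrac phylogenetic dissimilarity between samples
#'
#' Unweighted UniFrac is the branch length unique to either sample's leaf
#' set divided by the branch length spanned by their union. Weighted UniFrac
#' is \eqn{\sum_b l_b |p_{bA} - p_{bB}|} over branches, with \eqn{p_{bX}}
#' the proportion of sample X's reads descending from branch b; when
#' `normalized`, it is divided by \eqn{\sum_b l_b (p_{bA} + p_{bB})}
#' (equivalently the abundance-weighted root-to-tip depth), bounding it to
#' `[0, 1]`. Computed by a single post-order accumulation of per-branch
#' presence/mass.
#'
#' @param x an [OTUTable-class] or samples x OTUs matrix
#' @param tree rooted `phylo`; every table OTU must be a tip (extra tips are
#'   pruned)
#' @param weighted abundance-weighted variant (default FALSE)
#' @param normalized normalize weighted UniFrac to `[0, 1]` (default TRUE;
#'   ignored for unweighted)
#' @return `dist` with attribute `kind` = `"unweighted_unifrac"` or
#'   `"weighted_unifrac"`
#' @export
unifracMatrix <- function(x, tree, weighted = FALSE, normalized = TRUE) {
  m <- if (is(x, "OTUTable")) x@counts else as.matrix(x)
  missing <- setdiff(colnames(m), tree$tip.label)
  if (length(missing))
    stop("OTUs missing from the tree: ", paste(missing, collapse = ", "))
  if (!ape::is.rooted(tree))
    stop("UniFrac requires a rooted tree")
  extra <- setdiff(tree$tip.label, colnames(m))
  if (length(extra)) tree <- ape::drop.tip(tree, extra)
  tree <- stats::reorder(tree, "postorder")
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  nS <- nrow(m)
  # per-sample tip mass (proportions for weighted, presence for unweighted)
  tipMass <- t(m[, tree$tip.label, drop = FALSE])
  if (weighted) {
    tot <- colSums(tipMass)
    tot[tot == 0] <- 1
    tipMass <- sweep(tipMass, 2L, tot, "/")
  } else {
    tipMass <- (tipMass > 0) * 1
  }
  nodeMass <- matrix(0, nNode, nS)
  nodeMass[seq_len(nTip), ] <- tipMass
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  for (e in seq_along(parent))      # postorder: children before parents
    nodeMass[parent[e], ] <- nodeMass[parent[e], ] + nodeMass[child[e], ]
  branch <- nodeMass[child, , drop = FALSE]  # per-branch mass, edges x samples
  len <- tree$edge.length
  dm <- matrix(0, nS, nS, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(nS - 1L)) for (j in (i + 1L):nS) {
    a <- branch[, i]; b <- branch[, j]
    if (weighted) {
      num <- sum(len * abs(a - b))
      if (normalized) {
        den <- sum(len * (a + b))
        dm[i, j] <- if (den == 0) 0 else num / den
      } else dm[i, j] <- num
    } else {
      pa <- a > 0; pb <- b > 0
      den <- sum(len[pa | pb])
      dm[i, j] <- if (den == 0) 0 else sum(len[xor(pa, pb)]) / den
    }
    dm[j, i] <- dm[i, j]
  }
  asKindDist(dm, if (weighted) "weighted_unifrac" else "unweighted_unifrac")
}

#' Great-circle geographic distances between samples
#'
#' Haversine distance in kilometres (Earth radius 6,371 km) between the
#' sample pseudo-coordinates in the metadata.
#'
#' @param metadata data.frame with sample_id, latitude, longitude
#' @return `dist` (km) with attribute `kind = "geographic"`
#' @export
geographicDistances <- function(metadata) {
  bad <- !is.finite(metadata$latitude) | !is.finite(metadata$longitude)
  if (any(bad))
    stop("samples with missing coordinates: ",
         paste(metadata$sample_id[bad], collapse = ", "))
  pts <- cbind(metadata$longitude, metadata$latitude)
  dm <- geosphere::distm(pts, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
  dimnames(dm) <- list(metadata$sample_id, metadata$sample_id)
  asKindDist(dm, "geographic")
}

#' Expand a population-level Fst matrix to the sample level
#'
#' Builds a sample-by-sample matrix where d(i, j) is the Fst between the
#' samples' populations (0 within a population), so population-level genetic
#' differentiation can enter a Mantel test against sample-level community
#' distances.
#'
#' @param fst square symmetric matrix with population dimnames
#' @param metadata metadata data.frame
#' @param sampleTypes which sample types to include (default `"animal"`)
#' @return `dist` with attribute `kind = "fst"`
#' @export
expandFstToSamples <- function(fst, metadata, sampleTypes = "animal") {
  md <- metadata[metadata$sample_type %in% sampleTypes, ]
  unknown <- setdiff(unique(md$population), rownames(fst))
  if (length(unknown))
    stop("populations missing from the Fst matrix: ",
         paste(unknown, collapse = ", "))
  idx <- match(md$population, rownames(fst))
  dm <- fst[idx, idx]
  dimnames(dm) <- list(md$sample_id, md$sample_id)
  diag(dm) <- 0
  asKindDist(dm, "fst")
}
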