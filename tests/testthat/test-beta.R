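# Beta diversity: Jaccard, UniFrac, PCoA, ANOSIM, PERMANOVA, Mantel,
# geographic and Fst expansion.

test_that("Jaccard dissimilarities follow set arithmetic", {
  cts <- rbind(x = c(1, 1, 1, 0), y = c(0, 1, 1, 1), z = c(1, 1, 1, 0),
               q = c(0, 0, 0, 2))
  colnames(cts) <- c("A", "B", "C", "D")
  d <- as.matrix(jaccardMatrix(OTUTable(cts)))
  expect_equal(d["x", "y"], 0.5)        # {A,B,C} vs {B,C,D}
  expect_equal(d["x", "z"], 0)
  expect_equal(d["x", "q"], 1)          # disjoint
  empty <- rbind(e1 = c(0, 0), e2 = c(0, 0), s = c(1, 1))
  colnames(empty) <- c("A", "B")
  expect_warning(de <- as.matrix(jaccardMatrix(empty)), "empty")
  expect_equal(de["e1", "e2"], 0)
  expect_equal(de["e1", "s"], 1)
})

test_that("UniFrac matches the per-branch brute-force oracle", {
  for (r in 1:6) {
    set.seed(400 + r)
    tree <- simulateTree(sprintf("o%d", 1:16), seed = 400 + r)
    cts <- matrix(rpois(5 * 16, 3) * rbinom(5 * 16, 1, 0.6), 5, 16,
                  dimnames = list(sprintf("s%d", 1:5), sprintf("o%d", 1:16)))
    cts[rowSums(cts) == 0, 1] <- 1
    for (w in c(FALSE, TRUE)) {
      mine <- as.matrix(unifracMatrix(cts, tree, weighted = w))
      orc <- oracleUniFrac(cts, tree, weighted = w)
      expect_equal(mine, orc, tolerance = 1e-10)
    }
    raw <- as.matrix(unifracMatrix(cts, tree, weighted = TRUE,
                                   normalized = FALSE))
    expect_equal(raw, oracleUniFrac(cts, tree, weighted = TRUE,
                                    normalized = FALSE), tolerance = 1e-10)
  }
})

test_that("UniFrac edge cases: identical, disjoint subtrees, missing OTUs", {
  tree <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  cts <- rbind(s1 = c(A = 3, B = 1, C = 0, D = 0),
               s2 = c(A = 0, B = 0, C = 2, D = 5),
               s3 = c(A = 3, B = 1, C = 0, D = 0))
  du <- as.matrix(unifracMatrix(cts, tree, weighted = FALSE))
  dw <- as.matrix(unifracMatrix(cts, tree, weighted = TRUE))
  expect_equal(du["s1", "s3"], 0)
  expect_equal(dw["s1", "s3"], 0)
  expect_equal(du["s1", "s2"], 1)       # disjoint subtrees spanning the union
  expect_equal(dw["s1", "s2"], 1)       # weighted normalized also maximal here
  bad <- cbind(cts, E = c(1, 0, 0))
  expect_error(unifracMatrix(bad, tree), "E")
})

test_that("UniFrac agrees with phyloseq on unweighted distances", {
  set.seed(410)
  tree <- simulateTree(sprintf("o%d", 1:24), seed = 410)
  cts <- matrix(rpois(6 * 24, 2) * rbinom(6 * 24, 1, 0.5), 6, 24,
                dimnames = list(sprintf("s%d", 1:6), sprintf("o%d", 1:24)))
  cts[rowSums(cts) == 0, 1] <- 1
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(t(cts), taxa_are_rows = TRUE),
    phyloseq::phy_tree(tree))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
  mine <- as.matrix(unifracMatrix(cts, tree, weighted = FALSE))
  expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-10)
})

test_that("unweighted UniFrac is a metric on random instances", {
  set.seed(420)
  tree <- simulateTree(sprintf("o%d", 1:12), seed = 420)
  cts <- matrix(rbinom(8 * 12, 1, 0.5), 8, 12,
                dimnames = list(sprintf("s%d", 1:8), sprintf("o%d", 1:12)))
  cts[rowSums(cts) == 0, 1] <- 1
  d <- as.matrix(unifracMatrix(cts, tree))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
})

test_that("PCoA recovers Euclidean configurations and flags degeneracy", {
  pts <- cbind(c(0, 3, 0, 4, 1), c(0, 0, 4, 3, 1))
  rownames(pts) <- sprintf("s%d", 1:5)
  d <- as.matrix(dist(pts))
  fit <- pcoaOrdination(d)
  rec <- as.matrix(dist(fit$vectors))
  expect_equal(rec, d, tolerance = 1e-8)
  # equilateral triangle: two equal eigenvalues, third ~ 0
  eq <- matrix(1, 3, 3) - diag(3)
  dimnames(eq) <- list(letters[1:3], letters[1:3])
  f2 <- pcoaOrdination(eq)
  expect_equal(f2$eigenvalues[1], f2$eigenvalues[2], tolerance = 1e-10)
  expect_lt(abs(f2$eigenvalues[3]), 1e-10)
  expect_error(pcoaOrdination(matrix(0, 2, 2)), "at least 3")
})

test_that("ANOSIM and PERMANOVA behave at the separation extremes", {
  # two tight clusters far apart
  pts <- rbind(matrix(rnorm(10, 0, .01), 5), matrix(rnorm(10, 50, .01), 5))
  rownames(pts) <- sprintf("s%d", 1:10)
  g <- rep(c("a", "b"), each = 5)
  d <- dist(pts)
  an <- anosimTest(d, g, nPermutations = 199, seed = 1)
  expect_equal(an$statistic, 1)
  pm <- permanovaTest(d, g, nPermutations = 199, seed = 1)
  expect_gt(pm$R2, 0.999)
  expect_lt(pm$p, 0.05)
  # labels unrelated to structure: R near 0
  set.seed(77)
  pts2 <- matrix(rnorm(24), 12)
  rownames(pts2) <- sprintf("s%d", 1:12)
  an0 <- anosimTest(dist(pts2), rep(c("a", "b"), 6),
                    nPermutations = 199, seed = 2)
  expect_lt(abs(an0$statistic), 0.3)
  expect_gt(an0$p, 0.05)
  expect_error(anosimTest(d, c(rep("a", 9), "b")), "at least 2 members")
  expect_error(permanovaTest(d, rep("a", 10)), "at least 2 groups")
})

test_that("PERMANOVA matches a direct centroid partition on Euclidean data", {
  set.seed(430)
  pts <- rbind(matrix(rnorm(16, 0), 8), matrix(rnorm(16, 1.5), 8))
  rownames(pts) <- sprintf("s%d", 1:16)
  g <- factor(rep(c("a", "b"), each = 8))
  pm <- permanovaTest(dist(pts), g, nPermutations = 99, seed = 3)
  # direct sums of squares from coordinates
  grand <- colMeans(pts)
  sst <- sum(sweep(pts, 2, grand)^2)
  ssw <- sum(unlist(lapply(split(as.data.frame(pts), g), function(x)
    sum(sweep(as.matrix(x), 2, colMeans(as.matrix(x)))^2))))
  ssb <- sst - ssw
  expect_equal(pm$R2, ssb / sst, tolerance = 1e-8)
  expect_equal(pm$F, (ssb / 1) / (ssw / 14), tolerance = 1e-8)
})

test_that("Mantel statistics and edge cases are sound", {
  set.seed(440)
  pts <- matrix(rnorm(24), 12)
  rownames(pts) <- sprintf("s%d", 1:12)
  d <- dist(pts)
  mt <- mantelTest(d, d, nPermutations = 199, seed = 4)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_lt(mt$p, 0.05)
  const <- matrix(1, 12, 12) - diag(12)
  dimnames(const) <- list(rownames(pts), rownames(pts))
  expect_warning(m0 <- mantelTest(d, const, nPermutations = 99, seed = 5),
                 "zero variance")
  expect_true(is.na(m0$r))
  # label alignment: permuting one matrix's order must not change r
  m2 <- as.matrix(d)
  perm <- sample(rownames(m2))
  mtp <- mantelTest(d, m2[perm, perm], nPermutations = 199, seed = 4)
  expect_equal(mtp$r, 1, tolerance = 1e-12)
  rownames(m2)[1] <- colnames(m2)[1] <- "other"
  expect_error(mantelTest(d, m2), "mismatch")
})

test_that("permutation tests are seed-reproducible", {
  set.seed(450)
  pts <- matrix(rnorm(20), 10)
  rownames(pts) <- sprintf("s%d", 1:10)
  d <- dist(pts)
  g <- rep(c("a", "b"), 5)
  expect_identical(anosimTest(d, g, 99, seed = 6), anosimTest(d, g, 99, seed = 6))
  expect_identical(permanovaTest(d, g, 99, seed = 6),
                   permanovaTest(d, g, 99, seed = 6))
  expect_identical(mantelTest(d, d + 0, 99, seed = 6),
                   mantelTest(d, d + 0, 99, seed = 6))
})

test_that("geographic distances are great-circle kilometres", {
  md <- data.frame(sample_id = c("a", "b", "c"),
                   latitude = c(0, 0, 0), longitude = c(0, 180, 0))
  d <- as.matrix(geographicDistances(md))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], pi * 6371, tolerance = 1e-6)
  bad <- md; bad$latitude[2] <- NA
  expect_error(geographicDistances(bad), "b")
  # symmetry and triangle inequality on random points
  set.seed(460)
  md2 <- data.frame(sample_id = sprintf("s%d", 1:30),
                    latitude = runif(30, -80, 80),
                    longitude = runif(30, -180, 180))
  g <- as.matrix(geographicDistances(md2))
  expect_equal(g, t(g))
  for (i in 1:10) {
    idx <- sample(30, 3)
    expect_lte(g[idx[1], idx[2]],
               g[idx[1], idx[3]] + g[idx[3], idx[2]] + 1e-6)
  }
})

test_that("Fst expansion maps population distances onto samples", {
  fst <- matrix(c(0, .1, .1, 0), 2, dimnames = list(c("P1", "P2"),
                                                    c("P1", "P2")))
  md <- data.frame(sample_id = c("a1", "a2", "b1", "w1"),
                   population = c("P1", "P1", "P2", "P1"),
                   sample_type = c("animal", "animal", "animal", "water"))
  d <- as.matrix(expandFstToSamples(fst, md))
  expect_equal(dim(d), c(3, 3))               # animals only
  expect_equal(d["a1", "a2"], 0)
  expect_equal(d["a1", "b1"], 0.1)
  expect_true(all(d %in% c(0, fst)))
  md$population[1] <- "P9"
  expect_error(expandFstToSamples(fst, md), "P9")
})
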