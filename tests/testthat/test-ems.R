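# Elements of metacommunity structure: ordination, coherence, turnover,
# boundary clumping, r1 nulls, classification, compartments.

test_that("ordination matches a dense eigendecomposition oracle up to sign", {
  for (r in 1:10) {
    m <- randomIncidence(8, 12, seed = 100 + r)
    ord <- ordinateIncidence(m)
    orc <- oracleCAScores(m)
    flip <- sign(sum(ord$siteScores * orc$site))
    expect_equal(unname(ord$siteScores), flip * orc$site, tolerance = 1e-8)
    expect_equal(unname(ord$speciesScores), flip * orc$species,
                 tolerance = 1e-8)
    expect_equal(ord$eigenvalue, orc$eigenvalue, tolerance = 1e-10)
  }
})

test_that("block-diagonal matrices ordinate into contiguous blocks", {
  set.seed(25)
  m <- matrix(0, 10, 12)
  m[1:5, 1:6] <- 1
  m[6:10, 7:12] <- 1
  dimnames(m) <- list(sprintf("S%d", 1:10), sprintf("sp%d", 1:12))
  m <- m[sample.int(10), sample.int(12)]
  ord <- ordinateIncidence(m)
  blocks <- as.integer(sub("S", "", names(ord$siteScores)[ord$rowOrder])) <= 5
  expect_true(all(diff(blocks) >= 0) || all(diff(blocks) <= 0))
})

test_that("ordination is deterministic, sign-fixed and permutation-invariant", {
  m <- randomIncidence(9, 11, seed = 7)
  o1 <- ordinateIncidence(m)
  expect_gte(o1$siteScores[1], 0)
  perm <- m[sample.int(9), sample.int(11)]
  o2 <- ordinateIncidence(perm)
  expect_equal(o2$ordered[rownames(o1$ordered), colnames(o1$ordered)],
               o1$ordered)
})

test_that("degenerate matrices are refused", {
  allones <- matrix(1, 4, 4, dimnames = list(letters[1:4], LETTERS[1:4]))
  expect_error(ordinateIncidence(allones), "degenerate")
  expect_error(ordinateIncidence(matrix(1, 1, 3)), "at least 2")
  withEmpty <- randomIncidence(6, 6, seed = 1)
  withEmpty[2, ] <- 0
  expect_warning(ordinateIncidence(withEmpty), "empty")
})

test_that("embedded absences and replacements match brute force exactly", {
  expect_equal(countEmbeddedAbsences(cbind(c(1, 0, 1))), 1)
  contiguous <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1))
  expect_equal(countEmbeddedAbsences(contiguous), 0)
  for (r in 1:15) {
    m <- randomIncidence(8, 10, seed = 200 + r)
    expect_identical(as.integer(countEmbeddedAbsences(m)),
                     as.integer(oracleAbsences(m)))
    expect_identical(as.numeric(countReplacements(fillRanges(m))),
                     as.numeric(oracleReplacements(m)))
  }
})

test_that("turnover counts behave on canonical patterns", {
  checker <- rbind(s1 = c(1, 0), s2 = c(0, 1))
  expect_equal(countReplacements(fillRanges(checker)), 1)
  nested <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))
  expect_equal(countReplacements(fillRanges(nested)), 0)
})

test_that("coherence and turnover are invariant to reversing the axis", {
  m <- randomIncidence(10, 14, seed = 33)
  om <- ordinateIncidence(m)$ordered
  rev <- om[nrow(om):1, ncol(om):1]
  expect_equal(countEmbeddedAbsences(om), countEmbeddedAbsences(rev))
  expect_equal(countReplacements(fillRanges(om)),
               countReplacements(fillRanges(rev)))
})

test_that("Morisita index matches closed forms and the direct formula", {
  # all 2S boundaries on one site: I_M = T
  onesite <- matrix(0, 7, 5)
  onesite[3, ] <- 1
  expect_equal(boundaryClumping(onesite)$index, 7)
  # one boundary per site: I_M = 0
  spread <- matrix(0, 6, 3)
  spread[1:2, 1] <- 1; spread[3:4, 2] <- 1; spread[5:6, 3] <- 1
  expect_equal(boundaryClumping(spread)$index, 0)
  for (r in 1:10) {
    m <- randomIncidence(10, 20, seed = 300 + r)
    expect_equal(boundaryClumping(m)$index, oracleMorisita(m),
                 tolerance = 1e-12)
  }
  expect_error(boundaryClumping(matrix(0, 4, 2)), "boundaries")
  # df conventions
  m <- randomIncidence(10, 20, seed = 311)
  expect_equal(boundaryClumping(m, dfConvention = "sites")$df, 9)
  expect_equal(boundaryClumping(m, dfConvention = "ranges")$df, 19)
})

test_that("r1 nulls conserve row sums and respect column marginals", {
  m <- randomIncidence(10, 15, seed = 40)
  sims <- r1Null(m, n = 200, seed = 41)
  expect_true(all(apply(sims, 3, rowSums) == rowSums(m)))
  # a zero-marginal species is never sampled
  m2 <- m; m2[, 3] <- 0
  sims2 <- r1Null(m2, n = 100, seed = 42)
  expect_true(all(sims2[, 3, ] == 0))
  # 2x3, richness (2,2), marginals (2,1,1): sequential weighted sampling
  # without replacement gives P(sp1) = 5/6 and P(sp2) = P(sp3) = 7/12
  # (exact enumeration over draw orders)
  m3 <- rbind(c(1, 1, 0), c(1, 0, 1))
  sims3 <- r1Null(m3, n = 2000, seed = 43)
  p <- c(5 / 6, 7 / 12, 7 / 12)
  for (j in 1:3) {
    se <- sqrt(p[j] * (1 - p[j]) / (2 * 2000))
    expect_lt(abs(mean(sims3[, j, ]) - p[j]), 3 * se)
  }
  # reproducibility
  expect_identical(r1Null(m, n = 5, seed = 9), r1Null(m, n = 5, seed = 9))
})

test_that("the classification tree follows the EMS decision rules", {
  rec <- function(z, p) list(z = z, p = p)
  clump <- function(index, p) list(index = index, p = p)
  # strong positive coherence + positive turnover + clumped boundaries
  expect_equal(classifyStructure(rec(-12, 1e-6), rec(8, 1e-6),
                                 clump(72.41, 1e-6)), "clementsian")
  expect_equal(classifyStructure(rec(-1, 0.4), rec(8, 1e-6),
                                 clump(2, 0.01)), "random")
  expect_equal(classifyStructure(rec(5, 0.001), rec(8, 1e-6),
                                 clump(2, 0.01)), "checkerboard")
  expect_equal(classifyStructure(rec(-5, 0.001), rec(-4, 1e-3),
                                 clump(2, 0.5)), "nested")
  expect_equal(classifyStructure(rec(-5, 0.001), rec(4, 1e-3),
                                 clump(0.2, 0.01)), "evenly_spaced")
  expect_equal(classifyStructure(rec(-5, 0.001), rec(4, 1e-3),
                                 clump(1.2, 0.4)), "gleasonian")
  # quasi labelling under non-significant turnover
  expect_equal(classifyStructure(rec(-5, 0.001), rec(1, 0.3),
                                 clump(5, 0.01), quasi = TRUE),
               "quasi-clementsian")
  expect_equal(classifyStructure(rec(-5, 0.001), rec(-1, 0.3),
                                 clump(5, 0.01), quasi = TRUE), "quasi-nested")
  # degenerate p-values propagate
  expect_equal(classifyStructure(rec(NA, NA), rec(1, 0.5), clump(1, 0.5)),
               "indeterminate")
})

test_that("noise-free canonical structures are recovered", {
  # the checkerboard scenario is excluded here: against a bias-corrected r1
  # null its negative-coherence signature is not reliably detectable (see
  # the methods vignette); its combinatorial property is tested separately
  labels <- c(clementsian = "clementsian", gleasonian = "gleasonian",
              nested = "nested", random = "random")
  for (st in names(labels)) {
    scen <- metacomScenario(st, nSites = 36, nSpecies = 90,
                            nCompartments = if (st == "clementsian") 2L else 1L,
                            boundaryNoise = 0, seed = 500 + match(st, names(labels)))
    m <- simulateIncidence(scen)
    got <- classification(suppressWarnings(
      emsAnalysis(m, nPermutations = 99, seed = 17)))
    expect_equal(got, labels[[st]], label = sprintf("structure %s", st))
  }
})

test_that("label recovery does not improve as boundary noise increases", {
  rate <- vapply(c(0, 0.15, 0.3), function(noise) {
    hits <- vapply(1:12, function(r) {
      scen <- metacomScenario("clementsian", 30, 80, nCompartments = 2,
                              boundaryNoise = noise, seed = 700 + r)
      m <- simulateIncidence(scen)
      classification(suppressWarnings(
        emsAnalysis(m, nPermutations = 99, seed = r))) == "clementsian"
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rate) <= 0))
  expect_gt(rate[1], 0.8)
})

test_that("compartment splitting finds the true boundary and re-analyses", {
  scen <- metacomScenario("clementsian", nSites = 20, nSpecies = 60,
                          nCompartments = 2, boundaryNoise = 0, seed = 60)
  m <- simulateIncidence(scen, shuffleSites = FALSE)
  sp <- splitCompartments(m, nPermutations = 49, seed = 61)
  expect_equal(sp@boundary, 10L)               # equal blocks of 10 sites
  expect_setequal(unlist(lapply(sp@children, rownames)), rownames(m))
  # tiny child refused
  m4 <- randomIncidence(4, 8, seed = 62)
  expect_warning(sp4 <- splitCompartments(m4, boundary = 1,
                                          nPermutations = 19, seed = 63),
                 "refused")
  expect_null(sp4@reports[[1]])
  expect_error(splitCompartments(m4, boundary = 4), "strictly inside")
})

test_that("covariate correlations behave at the exact and null extremes", {
  m <- randomIncidence(12, 20, seed = 70)
  ord <- ordinateIncidence(m)
  md <- data.frame(sample_id = rownames(m), cov = unname(ord$siteScores),
                   anti = -unname(ord$siteScores), flat = 1)
  expect_equal(scoreCovariateCorrelation(ord, md, "cov")$r, 1,
               tolerance = 1e-10)
  expect_equal(scoreCovariateCorrelation(ord, md, "anti")$r, -1,
               tolerance = 1e-10)
  expect_warning(out <- scoreCovariateCorrelation(ord, md, "flat"),
                 "zero-variance")
  expect_true(is.na(out$r))
  expect_error(scoreCovariateCorrelation(ord, md, "nope"), "no metadata")
  # independent covariate: p roughly uniform over simulations
  set.seed(71)
  ps <- vapply(1:400, function(i) {
    md$noise <- rnorm(12)
    scoreCovariateCorrelation(ord, md, "noise")$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("an EMSReport prints its statistics and classification", {
  m <- randomIncidence(10, 20, seed = 80)
  rep <- suppressWarnings(emsAnalysis(m, nPermutations = 29, seed = 81))
  out <- capture.output(show(rep))
  expect_true(any(grepl("coherence", out)))
  expect_true(any(grepl("classification", out)))
  s <- emsStats(rep)
  expect_named(s, c("coherence", "turnover", "clumping"))
  expect_true(s$coherence$observed >= 0)
  expect_true(s$clumping$index >= 0)
})
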