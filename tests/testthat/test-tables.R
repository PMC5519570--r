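# OTU-table I/O, preprocessing, and alpha-level summaries.

mkTable <- function(cts, tax = character()) OTUTable(cts, taxonomy = tax)

test_that("TSV and BIOM round-trips preserve the table", {
  cts <- matrix(c(5, 0, 3, 2, 8, 1), nrow = 2,
                dimnames = list(c("s1", "s2"), c("otuA", "otuB", "otuC")))
  tax <- c(otuA = "k__Bacteria; p__Proteobacteria",
           otuB = "k__Bacteria; p__Firmicutes",
           otuC = "k__Bacteria; p__Actinobacteria")
  tab <- mkTable(cts, tax)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeOTUTable(tab, tsv, provenance = "test seed=1")
  back <- readOTUTable(tsv)
  expect_equal(counts(back), counts(tab))
  expect_equal(taxonomy(back)[otuIDs(tab)], taxonomy(tab)[otuIDs(tab)])
  biom <- withr::local_tempfile(fileext = ".biom")
  writeOTUTable(tab, biom)
  back2 <- readOTUTable(biom)
  expect_equal(counts(back2)[rownames(cts), colnames(cts)], counts(tab))
})

test_that("malformed tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1\ts2", "otuA\t5\t-2"), f)
  expect_error(readOTUTable(f), "negative")
  writeLines(c("#OTU ID\ts1\ts2", "otuA\t5"), f)
  expect_error(readOTUTable(f), "ragged")
  writeLines(c("#OTU ID\ts1\ts2", "otuA\t1\t2", "otuA\t3\t4"), f)
  expect_error(readOTUTable(f), "duplicate")
  expect_error(OTUTable(matrix(-1, 1, 1, dimnames = list("s", "o"))),
               "non-negative")
})

test_that("rare-OTU filter removes exactly the OTUs below the threshold", {
  # grand total 10,000; at minFraction 0.005 the threshold is 50 reads
  cts <- cbind(a = c(30, 19), b = c(25, 25), c = c(10, 39), d = c(9852, 0))
  rownames(cts) <- c("s1", "s2")
  tab <- mkTable(cts)
  kept <- otuIDs(filterRareOTUs(tab, 0.005))
  expect_setequal(kept, c("b", "d"))      # a = 49 < 50, c = 49 < 50, b = 50
  expect_equal(counts(filterRareOTUs(tab, 0)), counts(tab))
  allRare <- mkTable(matrix(c(1, 0, 0, 1), 2,
                            dimnames = list(c("s1", "s2"), c("x", "y"))))
  expect_warning(out <- filterRareOTUs(allRare, 0.9), "below")
  expect_equal(ncol(counts(out)), 0)
})

test_that("rarefaction yields exact depths and drops shallow samples", {
  set.seed(1)
  cts <- rbind(deep = rmultinom(1, 10000, rep(1, 50))[, 1],
               exact = rmultinom(1, 8800, rep(1, 50))[, 1],
               shallow = rmultinom(1, 5000, rep(1, 50))[, 1])
  colnames(cts) <- sprintf("o%d", 1:50)
  tab <- mkTable(cts)
  expect_warning(r <- rarefyTable(tab, 8800, seed = 2), "shallow")
  expect_setequal(sampleIDs(r), c("deep", "exact"))
  expect_true(all(rowSums(counts(r)) == 8800))
  expect_equal(counts(r)["exact", ], cts["exact", ])  # already at depth
  expect_true(all(counts(r) <= counts(tab)[c("deep", "exact"), ]))
  expect_warning(r2 <- rarefyTable(tab, 8800, seed = 2))
  expect_identical(counts(r), counts(r2))             # deterministic
  expect_error(rarefyTable(tab, 0), "positive")
})

test_that("rarefaction preserves expected relative abundances", {
  set.seed(3)
  v <- c(5000, 3000, 1500, 400, 100)
  cts <- matrix(v, 1, dimnames = list("s", sprintf("o%d", 1:5)))
  tab <- mkTable(cts)
  reps <- t(vapply(1:1000, function(i)
    suppressWarnings(counts(rarefyTable(tab, 2000, seed = i))[1, ] / 2000),
    numeric(5)))
  p <- v / sum(v)
  se <- sqrt(p * (1 - p) / 2000) / sqrt(1000)
  expect_true(all(abs(colMeans(reps) - p) < 3 * se + 1e-12))
})

test_that("core membership uses >= on exact prevalence fractions", {
  cts <- matrix(0, 51, 3, dimnames = list(sprintf("s%d", 1:51),
                                          c("in41", "out40", "everywhere")))
  cts[1:41, "in41"] <- 1
  cts[1:40, "out40"] <- 1
  cts[, "everywhere"] <- 2
  tab <- mkTable(cts)
  core <- coreMicrobiome(tab, 0.80)
  expect_true("in41" %in% core)        # 41/51 = 0.804 >= 0.80
  expect_false("out40" %in% core)      # 40/51 = 0.784 < 0.80
  expect_equal(coreMicrobiome(tab, 1.0), "everywhere")
  expect_equal(core[1], "everywhere")  # sorted by mean relative abundance
})

test_that("alpha summaries match closed-form Shannon and richness", {
  cts <- rbind(even = c(50, 50, 0), single = c(100, 0, 0),
               mix = c(70, 20, 10))
  colnames(cts) <- c("a", "b", "c")
  al <- suppressWarnings(alphaSummaries(mkTable(cts)))
  expect_equal(al$richness, c(2L, 1L, 3L))
  expect_equal(al$shannon[1], log(2), tolerance = 1e-12)
  expect_equal(al$shannon[2], 0)
  expect_equal(al$shannon[3],
               -(0.7 * log(0.7) + 0.2 * log(0.2) + 0.1 * log(0.1)),
               tolerance = 1e-12)
  # base-2 option
  al2 <- suppressWarnings(alphaSummaries(mkTable(cts), base = 2))
  expect_equal(al2$shannon[1], 1, tolerance = 1e-12)
  # invariance under OTU relabeling; maximal for uniform counts
  perm <- cts[, c(3, 1, 2)]
  expect_equal(suppressWarnings(alphaSummaries(mkTable(perm)))$shannon,
               al$shannon)
  expect_equal(al$shannon[1], log(al$richness[1]))
})

test_that("shared proportion follows the stated denominator conventions", {
  expect_equal(sharedProportion(c("A", "B", "C", "D", "E"), c("A", "B", "F")),
               0.4)
  expect_equal(sharedProportion(c("A", "B"), c("C", "D")), 0)
  expect_equal(sharedProportion(c("A", "B"), c("A", "B", "C")), 1)
  expect_equal(sharedProportion(c("A", "B", "C", "D", "E"), c("A", "B", "F"),
                                denominator = "union"), 2 / 6)
  expect_warning(p <- sharedProportion(character(), c("A")), "no OTUs")
  expect_true(is.na(p))
  # count-vector form
  expect_equal(sharedProportion(c(A = 5, B = 0, C = 2), c(A = 1, B = 3)), 0.5)
})

test_that("alpha summaries attach per-animal water-shared proportions", {
  cts <- rbind(a1 = c(5, 5, 5, 0), a2 = c(5, 0, 5, 5), w1 = c(9, 0, 0, 3))
  colnames(cts) <- c("o1", "o2", "o3", "o4")
  md <- data.frame(sample_id = c("a1", "a2", "w1"), population = "P1",
                   deme = "D1", sample_type = c("animal", "animal", "water"))
  al <- suppressWarnings(alphaSummaries(mkTable(cts), md))
  expect_equal(al$shared_proportion[al$sample_id == "a1"], 1 / 3)
  expect_equal(al$shared_proportion[al$sample_id == "a2"], 2 / 3)
  expect_true(is.na(al$shared_proportion[al$sample_id == "w1"]))
})

test_that("incidence conversion binarizes, filters types, drops empty OTUs", {
  cts <- rbind(a1 = c(3, 0, 1), a2 = c(1, 0, 0), w1 = c(0, 7, 1))
  colnames(cts) <- c("o1", "o2", "o3")
  md <- data.frame(sample_id = rownames(cts), population = "P1", deme = "D1",
                   sample_type = c("animal", "animal", "water"))
  inc <- toIncidence(mkTable(cts), md, sampleTypes = "animal")
  expect_equal(rownames(inc), c("a1", "a2"))
  expect_setequal(colnames(inc), c("o1", "o3"))   # o2 only in water
  expect_true(all(inc %in% c(0, 1)))
  expect_equal(inc["a1", "o1"], 1)
})

test_that("distance-matrix TSV round-trips", {
  m <- matrix(c(0, .2, .2, 0), 2, dimnames = list(c("P1", "P2"), c("P1", "P2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceTSV(m, f)
  expect_equal(readDistanceTSV(f), m)
})
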