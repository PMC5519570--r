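#' Define a synthetic metacommunity scenario
#'
#' A scenario places `nSites` sites on a one-dimensional latent environmental
#' gradient and arranges `nSpecies` species ranges along it according to one
#' of the canonical metacommunity structures:
#' \describe{
#'   \item{clementsian}{species ranges are contiguous site intervals whose
#'     boundaries coincide within each of `nCompartments` compartments, with
#'     no overlap between compartments.}
#'   \item{gleasonian}{contiguous intervals with independently uniform
#'     endpoints.}
#'   \item{nested}{each species occupies all sites whose gradient position
#'     lies below a species-specific threshold.}
#'   \item{evenly_spaced}{contiguous equal-length ranges with maximally
#'     staggered boundaries.}
#'   \item{checkerboard}{species assembled in mutually exclusive
#'     complementary pairs; the underlying balanced site partitions are
#'     near-orthogonal (truncated Walsh designs), the idealized
#'     competition mosaic with no latent gradient at all.}
#'   \item{random}{independent Bernoulli occupancy at probability `fill`.}
#' }
#' After construction each cell is flipped independently with probability
#' `boundaryNoise`.
#'
#' @param structure structure label (see above)
#' @param nSites,nSpecies matrix dimensions (nSites >= 4, nSpecies >= 2)
#' @param nCompartments number of clementsian compartments; rejected when it
#'   exceeds `nSites / 2` (compartments would be degenerate)
#' @param compartmentSizes optional per-compartment site counts summing to
#'   `nSites`; near-equal blocks when NULL
#' @param boundaryNoise cell-flip probability in `[0, 0.5)`
#' @param fill occupancy probability for the random structure
#' @param gradient per-site latent positions; evenly spaced on `[0, 1]` when
#'   NULL
#' @param seed integer seed (NA/NULL for the current RNG stream)
#' @return a [MetacomScenario-class]
#' @export
metacomScenario <- function(structure, nSites, nSpecies, nCompartments = 1L,
                            compartmentSizes = NULL, boundaryNoise = 0,
                            fill = 0.25, gradient = NULL, seed = NULL) {
  if (is.null(gradient)) gradient <- seq(0, 1, length.out = nSites)
  new("MetacomScenario",
      structure = as.character(structure), nSites = as.integer(nSites),
      nSpecies = as.integer(nSpecies), nCompartments = as.integer(nCompartments),
      compartmentSizes = as.integer(compartmentSizes %||% integer()),
      boundaryNoise = as.numeric(boundaryNoise), fill = as.numeric(fill),
      gradient = as.numeric(gradient),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "MetacomScenario", function(object) {
  cat(sprintf("MetacomScenario: %s, %d sites x %d species", object@structure,
              object@nSites, object@nSpecies))
  if (object@structure == "clementsian")
    cat(sprintf(", %d compartments", object@nCompartments))
  cat(sprintf(", boundary noise %.3g\n", object@boundaryNoise))
  invisible(NULL)
})

# Near-equal contiguous blocks of n sites into k compartments.
.blockSizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Generate a binary incidence matrix with known structure
#'
#' Sites are constructed in gradient order and then (by default) shuffled;
#' the true gradient rank and, for clementsian scenarios, the compartment of
#' each site are stored as attributes `gradientRank` and `compartment` so
#' that ordination recovery and compartment detection can be scored against
#' ground truth. Attribute `scenario` keeps the generating scenario.
#'
#' @param scenario a [MetacomScenario-class]
#' @param shuffleSites permute the site rows after construction (default TRUE)
#' @param siteIDs,speciesIDs optional id vectors; defaults `S01...`/`sp001...`
#' @return binary matrix (sites x species) with truth attributes
#' @export
simulateIncidence <- function(scenario, shuffleSites = TRUE,
                              siteIDs = NULL, speciesIDs = NULL) {
  stopifnot(is(scenario, "MetacomScenario"))
  validObject(scenario)
  n <- scenario@nSites; S <- scenario@nSpecies
  seed <- if (is.na(scenario@seed)) NULL else scenario@seed
  withSeed(seed, {
    m <- matrix(0L, n, S)
    compartment <- rep(NA_integer_, n)
    switch(scenario@structure,
      clementsian = {
        sizes <- if (length(scenario@compartmentSizes))
          scenario@compartmentSizes else .blockSizes(n, scenario@nCompartments)
        ends <- cumsum(sizes)
        starts <- c(1L, head(ends, -1L) + 1L)
        comp_of_species <- rep(seq_along(sizes), length.out = S)
        for (j in seq_len(S)) {
          k <- comp_of_species[j]
          m[starts[k]:ends[k], j] <- 1L
        }
        compartment <- rep(seq_along(sizes), sizes)
      },
      gleasonian = {
        for (j in seq_len(S)) {
          e <- sample.int(n, 2L, replace = TRUE)
          m[min(e):max(e), j] <- 1L
        }
      },
      nested = {
        thr <- sample.int(n, S, replace = TRUE)
        for (j in seq_len(S)) m[seq_len(thr[j]), j] <- 1L
      },
      evenly_spaced = {
        L <- max(2L, n %/% 2L)
        starts <- round(seq(1L, n - L + 1L, length.out = S))
        for (j in seq_len(S)) m[starts[j]:(starts[j] + L - 1L), j] <- 1L
      },
      checkerboard = {
        # complementary pairs over near-orthogonal balanced partitions
        # (truncated Walsh designs): balanced splits whose pairwise
        # correlations are essentially zero, so no site ordering can
        # compress more than a fraction of the species ranges
        p <- 2L^ceiling(log2(n))
        H <- matrix(1, 1, 1)
        while (ncol(H) < p) H <- rbind(cbind(H, H), cbind(H, -H))
        cols <- sample(2:p)
        for (j in seq_len(S %/% 2L)) {
          base <- (H[seq_len(n), cols[1L + (j - 1L) %% (p - 1L)]] + 1) / 2
          if (j > p - 1L) base <- base[sample.int(n)]
          m[, 2L * j - 1L] <- base
          m[, 2L * j] <- 1 - base
        }
        if (S %% 2L == 1L) m[, S] <- stats::rbinom(n, 1L, 0.5)
      },
      random = {
        m[] <- stats::rbinom(n * S, 1L, scenario@fill)
      },
      stop("unknown structure: ", scenario@structure))
    if (scenario@boundaryNoise > 0) {
      flips <- stats::rbinom(n * S, 1L, scenario@boundaryNoise)
      m <- abs(m - matrix(flips, n, S))
    }
    perm <- if (shuffleSites) sample.int(n) else seq_len(n)
    m <- m[perm, , drop = FALSE]
    rownames(m) <- siteIDs %||% sprintf("S%0*d", nchar(n), seq_len(n))
    colnames(m) <- speciesIDs %||% sprintf("sp%0*d", max(3L, nchar(S)), seq_len(S))
    attr(m, "gradientRank") <- perm           # true gradient rank of each row
    attr(m, "gradient") <- scenario@gradient[perm]
    attr(m, "compartment") <- compartment[perm]
    attr(m, "scenario") <- scenario
    m
  })
}
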