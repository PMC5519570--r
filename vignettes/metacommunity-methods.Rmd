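---
title: "Microbial metacommunity structure: models, statistics and design choices"
author: "MicroMetacom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microbial metacommunity structure: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MicroMetacom)
```

## The analysis this package implements

Host-associated bacterial communities — here, the skin microbiota of
stream-dwelling amphibians sampled across several rivers in two major
drainages — can be treated as a *metacommunity*: a set of local communities
(individual hosts) linked by dispersal of their member taxa. The package
implements the whole desk-side workflow for such data:

1. **Preprocessing** of a samples-by-OTU count table: removal of OTUs below
   a fraction of the total read count, rarefaction to a common depth, core
   microbiome extraction, per-sample richness and Shannon diversity, and
   the proportion of each host's OTUs shared with its river's water sample.
2. **Elements of metacommunity structure (EMS)**: ordination of the binary
   host-by-OTU incidence matrix by reciprocal averaging, and the three
   classical statistics — coherence, species turnover, boundary clumping —
   evaluated against a fixed-proportional (r1) permutation null, followed
   by classification into checkerboard, random, nested, Clementsian,
   Gleasonian or evenly spaced structure, and recursive compartment
   analysis.
3. **Beta diversity**: Jaccard and (un)weighted UniFrac distances,
   principal coordinates, ANOSIM and PERMANOVA group tests, and Mantel
   correlations of community distance against population-genetic (Fst) and
   geographic distance.
4. A **synthetic-data generator** that produces complete studies — count
   table, rooted phylogeny, sample metadata, Fst matrix — with known
   metacommunity structure, so every stage can be validated against ground
   truth.

## The EMS statistics

Given a binary sites-by-species matrix, reciprocal averaging (the first
non-trivial correspondence-analysis axis) ranks sites and species so that
similar rows and columns are adjacent. We compute the axis by singular
value decomposition of the chi-square standardized matrix
$(P - r c^\top)/\sqrt{r c^\top}$, which is the fixed point of the iterative
averaging procedure but deterministic; scores are the standard coordinates
$u_1/\sqrt{r}$, $v_1/\sqrt{c}$. The axis sign is fixed (first site's score
non-negative), and ordering ties break by original index, so ordination is
exactly reproducible. Degenerate matrices (all rows or columns
proportional, e.g. all-ones) are refused with an explanatory error.

On the ordered matrix:

* **Coherence** counts *embedded absences* — zeros lying strictly inside a
  species' range (and, by default, inside a site's range across species:
  the both-margins convention of the reference EMS implementation; a
  columns-only switch is provided). Fewer absences than the null
  expectation means species respond to a shared latent gradient.
* **Turnover** first fills every range (embedded absences set to 1) and
  then counts, over all unordered species pairs, the product of the number
  of sites where each species occurs without the other. More replacements
  than expected indicates Gleasonian or Clementsian turnover; fewer,
  nestedness.
* **Boundary clumping** tallies each species' two range boundaries per site
  and computes Morisita's index of dispersion
  $I_M = T \sum n_i(n_i-1) / (N(N-1))$; values above 1 mean coincident
  boundaries.

Coherence and turnover are tested against the **r1 fixed-proportional
null**: each null matrix conserves every site's observed richness exactly
while filling species with probability proportional to their occurrence
totals (generation is delegated to `vegan`'s `"r1"` null model, which
implements precisely this sampling scheme). Defaults follow standard
practice for large microbial matrices: 99 permutations, empty rows and
columns allowed, and each null matrix re-ordinated before counting. The
observed count is compared with the null distribution by z-score, with a
two-tailed normal-approximation p-value (an empirical-rank p is also
reported); a degenerate null (sd = 0) propagates an `indeterminate` label.

### The conditioning bias of the r1 z-score, and its correction

The classical z-score is anticonservative. On truly random matrices of 60
sites by 150 species the coherence z averages about $+1.5$, flagging a
quarter of them as significantly incoherent at $\alpha = 0.05$.
Decomposing the statistic shows why: raw absence counts of data and nulls
agree, but the *re-ordinated* r1 nulls are systematically more
compressible than the data whose margins they inherit — their column
totals carry the observed totals' fluctuations plus fresh sampling noise,
which strengthens the chance correspondence axis. The same drift appears
when an r1 null matrix is itself tested against its own r1 nulls, so the
bias is a property of conditioning the null on the observed margins, not
of any particular data set.

`emsAnalysis()` therefore applies a double-permutation correction by
default (`biasCorrect = TRUE`): a subset of the first-level null matrices
(12 by default) are treated as pseudo-observations, each is scored against
its own second-level r1 null stream (49 permutations), and the mean pseudo
z — the bias — is subtracted from the observed coherence z before the
normal p-value is taken. Under the null hypothesis the corrected z is
approximately centred with standard deviation slightly below 1, making
the test mildly conservative. The uncorrected z is retained in the
report (`zRaw`), since it is what the uncorrected published workflow
produces. The turnover z is deliberately left uncorrected: its role in
the classification is its sign or extreme significance, where a
1.5-standard-deviation shift is immaterial, and the null-of-null estimate
becomes unreliable for strongly nested margins, where second-level nulls
drift in their own right.

A consequence worth stating plainly: once the bias is removed, the
checkerboard signature — significantly *more* embedded absences than the
r1 null — is no longer reliably detectable at this scale for any
exclusion-based community we could construct (complementary random pairs,
unequal exclusive subsets, dense mutually exclusive groups, approximate
2-designs with near-constant pairwise overlaps). The best construction,
complementary pairs over near-orthogonal balanced partitions, reaches a
corrected z of only about $+1.3$. Exclusion constraints barely change a
matrix's ordination compressibility relative to a same-margin
randomization, so apparent checkerboard detections under the uncorrected
test are largely the conditioning bias itself. The structure-recovery
validation accordingly covers clementsian, gleasonian, nested and random
scenarios; checkerboard generation is provided and its combinatorial
property is tested, but its recovery is documented as an open limitation
of the EMS framework in this regime rather than papered over.

### Why boundary clumping needs special care

Reciprocal averaging only estimates the latent site order. Wherever two
adjacent sites are weakly distinguishable, their order is effectively
arbitrary, and a local mis-ordering *merges* the boundary tallies of the
two sites. Since Morisita's index is quadratic in the tallies, this
inflates $I_M$ above 1 even when boundaries are truly random: on
noise-free Gleasonian matrices of 60 sites and 150 species, the index is
about 0.97 in the true gradient order but 1.4–2.6 after ordination. A
chi-square test against 1 therefore calls essentially *every* ordinated
matrix clumped once species far outnumber sites.

The package offers two assessments (argument `clumpingTest`):

* `"bootstrap"` (default for `emsAnalysis()`): a range-placement null —
  each species keeps its observed range length, ranges are placed uniformly
  at random along the sites, and each simulated matrix is re-ordinated
  before its index is computed. This is exactly the "randomly distributed
  boundaries" hypothesis conditioned on range sizes, and because the null
  passes through the same ordination it inherits the same inflation. It is
  calibrated for single-gradient matrices and is what the structure-recovery
  validation uses.
* `"chisq"` (default for the file-based pipeline): the conventional
  dispersion chi-square $I_M(N-1) + T - N$ against df $T-1$, the field's
  standard workflow. It is reported in all cases (as `pChisq`), and both df
  conventions (sites $-$ 1; species ranges $-$ 1) are available since
  published tables differ in which they print.

Neither test is uniformly better. The bootstrap's own re-ordination becomes
pathological for deep hierarchical matrices (many near-ubiquitous species
plus nested block structure): the null matrices lose the real gradient, are
ordered almost arbitrarily, and end up *more* inflated than the data, so
genuine clumping can be under-called. The conventional chi-square has the
opposite failure mode. The pipeline defaults to the conventional test
because its purpose is to reproduce the standard published workflow on
study-shaped data; the bare analysis function defaults to the calibrated
bootstrap because its purpose is inference on a single latent gradient.
This trade-off is a known limitation, documented here deliberately.

### Classification

The decision tree (two-tailed $\alpha = 0.05$, configurable): significantly
*more* absences than the null → checkerboard; non-significant coherence →
random; under positive coherence, significantly negative turnover → nested;
otherwise Clementsian / evenly spaced / Gleasonian according to whether
boundary clumping is significantly high / significantly low / neither.
Non-significant turnover classifies by its sign (the six-structure scheme);
setting `quasi = TRUE` adds the `quasi-` prefix for those cases.

### Compartments

`splitCompartments()` cuts the ordered site sequence at a supplied boundary
or, in `auto` mode, at the adjacent-site pair with the largest Jaccard
dissimilarity (the sharpest compositional break in the ordination), drops
species absent from each child, and re-runs the full analysis per child.
Children with fewer than 4 sites are refused with a warning rather than
analysed.

## The synthetic generator: what it emulates and what it does not

The generator's defaults reproduce the shape of a real multi-river field
study: 8 populations (rivers) split 3/5 into two drainages (demes), animal
sample sizes 5,5,8,5,3,5,7,5 (43 hosts) plus one water sample per river —
51 samples in all. Species ranges are laid out on a one-dimensional latent
gradient on which sites are generated already sorted (then shuffled, with
the truth stored), because EMS presumes a dominant latent axis and this
makes ordination recovery directly testable. Noise is applied as
independent cell flips — the simplest perturbation with one interpretable
parameter — rather than boundary jitter.

Specifics worth knowing:

* **Canonical structures.** Clementsian compartments are contiguous site
  blocks with species ranges spanning exactly their block; Gleasonian
  ranges have independent uniform endpoints; nested species occupy all
  sites below a threshold; evenly spaced ranges are equal-length and
  maximally staggered; random occupancy is Bernoulli at a configurable
  fill (default 0.25). The checkerboard structure assembles species in
  mutually exclusive complementary pairs whose balanced site partitions
  are near-orthogonal (truncated Walsh designs) — the idealized
  competition mosaic with no latent gradient, and the construction that
  comes closest to a detectable negative-coherence signature (see the
  bias-correction section above for why full detectability is out of
  reach at this scale).
* **Abundance overlay.** Species weights are a rank-ordered lognormal
  (meanlog 6, sdlog 1.8 at the dataset level), read depths are negative
  binomial (mean 20,000, dispersion 20), and reads are multinomial within
  each sample's present species, with the top-ranked species rescaled to a
  46.5% expected share where it occurs. The pre-filter pool of 4,800
  species was sized so that roughly 1,650 OTUs survive the 0.005% filter,
  with ~60% of surviving OTUs at a post-rarefaction total below 100 reads
  — a long rare tail, though somewhat shorter than deep-sequencing reality,
  a consequence of simulating at desk scale.
* **Hierarchical structure.** The default dataset layers deme-wide ranges
  (2 compartments) with population-level ranges (8 compartments), shuffling
  the species columns so abundance rank is independent of layer; this gives
  compartments that are themselves structured, as real host metacommunities
  are.
* **Water samples** hold an exactly-sized uniform subset of their
  population's animal OTU pool (so each animal's expected shared proportion
  equals the target, 0.29 by default), plus water-exclusive OTUs; every
  water OTU receives at least one read so the community is fully
  detectable. The water sample's richness relative to animals is a free
  parameter (`nExclusive`), since field studies rarely pin it down.
* **Phylogeny.** A random sequential coalescent with Exp(1) branch lengths
  — any rooted binary tree with positive lengths exercises UniFrac fully;
  no attempt is made at realistic tree shape.
* **Fst.** Population pairs get expected Fst 0.05 within and 0.25 between
  demes plus Gaussian noise, truncated to [0, 1].

What passing tests on these data do **not** show: robustness to chimeras or
sequencing error (reads are never simulated), 16S copy-number effects,
compositional biases of extraction and PCR, or tree-inference error. The
generator validates the *statistics*, not the upstream molecular pipeline.

## Preprocessing conventions

The pipeline order is fixed — filter rare OTUs first, then rarefy — and
tests pin that order, since the two operations do not commute. The rare-OTU
threshold is `minFraction * grand total` computed on the input table, with
`>=` retention. Rarefaction subsamples without replacement to exactly the
target depth (default 8,800 reads) and *drops* shallower samples rather
than padding them. Core-microbiome membership uses `>=` on exact prevalence
fractions (41/51 passes an 80% threshold, 40/51 does not). Shannon
diversity uses natural logarithms by default (configurable base). The
shared-OTU proportion divides by the animal's richness by default, with a
union-denominator switch, because the field convention is ambiguous.

## Beta diversity choices

UniFrac is computed by a single post-order accumulation of per-branch
presence or mass; weighted UniFrac is normalized by
$\sum_b l_b (p_{bA} + p_{bB})$ by default so it is bounded by [0, 1].
PERMANOVA is the one-factor Gower-partition form (the tests performed here
are single-factor: deme, population); ANOSIM is rank-based; both use
permutation p-values of the form (count + 1)/(permutations + 1), as does
the Mantel test (default 10,000 permutations). Geographic distance is
great-circle (haversine, Earth radius 6,371 km) on the metadata
pseudo-coordinates — river-network distance is out of scope. The
population-level Fst matrix is expanded to sample level (zero within
population) for Mantel tests against sample-level community distance.

## Problem sizes and determinism

Every stochastic step takes an explicit seed; one master seed derives
per-stage child seeds so stages can be re-run in isolation, and the
pipeline's JSON report is byte-identical under a fixed configuration and
seed. The validation suite runs the structure-recovery study at 60 sites by
150 species with 20 replicates per scenario and 99-permutation nulls,
permutation-test calibration at 1,000 null simulations of 199 permutations
each, and the full synthetic study at 51 samples with a 4,800-species pool
— sizes chosen to mirror the emulated design while remaining comfortable on
a single CPU (the complete demo takes a few minutes).

## Known limitations

* Evenly spaced structure is recovered reliably only in the single-layer
  canonical setting; on noisy or hierarchical data the ordination-inflated
  Morisita index makes true hyperdispersion hard to distinguish from
  randomness.
* The clumping test duality described above: neither convention dominates,
  and reports include both.
* Only the first correspondence axis is used (no detrending, no multi-axis
  ordination); metacommunities structured along two independent gradients
  will be summarized by whichever axis dominates.
* PERMANOVA is single-factor; nested or multi-factor designs are out of
  scope, as are partial Mantel tests.
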