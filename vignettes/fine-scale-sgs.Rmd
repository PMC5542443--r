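---
title: "Methods: fine-scale spatial genetic structure with finekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale spatial genetic structure with finekin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finekin)
```

`finekin` analyses within-population spatial genetic structure (SGS) from
georeferenced diploid microsatellite genotypes and maternally inherited
plastid haplotypes, and ships a forward-in-time simulator that produces
data with exactly the drift–dispersal structure the analyses assume. This
vignette documents the statistical model behind each module, the
numerical choices, and the known limitations.

## Data model

A `genotype_matrix` stores codominant diploid genotypes as two allele
columns per locus, with `NA` for missing copies; alleles are arbitrary
labels (repeat numbers for SSRs). A `spatial_frame` holds per-individual
coordinates in metres, either planar or projected from longitude/latitude
with a local equirectangular approximation (1 degree of latitude =
111,195 m; longitude scaled by `cos(latitude)`). A `haplotype_set` holds
one plastid haplotype label per individual; `call_haplotypes()` derives
labels from an alignment by scoring substitution columns, coding each
distinct gap run (indel extent) as a single presence/absence character so
a multi-base indel counts once, and scoring declared inversion regions by
orientation (forward / reverse-complement) rather than per-site.

## Kinship correlograms and the Sp statistic

Pairwise kinship uses the Loiselle et al. (1995) estimator. For allele
*a* at locus *l* with sample frequency *p* over *n_l* genotyped
individuals, the pair term is
`(x_ia - p)(x_ja - p) + p(1 - p)/(n_l - 1)`, where `x` is the individual
allele dosage (0, 1/2, 1 for diploids; 0/1 for haploid plastid data). The
multilocus coefficient is a ratio of sums: numerators summed over all
alleles and loci, divided by the summed denominators `p(1 - p)`. This
weighting keeps rare alleles from dominating and makes the estimator
usable with missing data (pairs simply drop loci where either member is
untyped).

The correlogram averages kinship within distance classes with
approximately equal pair counts (ties at a class boundary are kept
together, so exactly equal splits are not always attainable). Pairs at
zero distance contribute to class means but are excluded from the
log-distance regression. The regression slope *b* of kinship on
`ln(distance)` is tested one-sided (*b* < 0) by permuting individuals
across spatial positions; reported P values are
`(extreme + 1)/(n_perm + 1)`. Slope standard errors come from a
delete-one-locus jackknife, flagged when fewer than 4 loci are available.
The summary statistic is `Sp = -b / (1 - F1)` with `F1` the mean kinship
of the first distance class; under isolation by distance in two
dimensions Sp estimates `1 / (4 pi D sigma_g^2)` with *D* the effective
density and `sigma_g^2 = sigma_seed^2 + sigma_pollen^2 / 2`.

Limitation: for haploid single-locus data, same-haplotype pairs have
kinship slightly above 1 (the finite-sample correction adds
`p(1-p)/(n-1)`), so a first distance class made up entirely of
same-haplotype pairs gives `F1 > 1` and a sign-flipped Sp. `plastid_fsgs()`
therefore reports *b*, its permutation P and F1 alongside Sp; with
monomorphic haplotype data it declines (returns `NULL` with a message).

## Spatially weighted PCA

`spca_analysis()` diagonalises `(1/2n) X' (W + W') X`, where *X* holds
centred allele dosages and *W* is a row-standardised spatial connection
network (k-nearest-neighbour, distance threshold, or Gabriel graph).
Positive eigenvalues capture global (cline-like, positive
autocorrelation) structure, negative eigenvalues local (checkerboard)
structure. `g_l_tests()` tests the total positive mass (G) and absolute
negative mass (L) against row-permutation nulls. Leading score signs are
fixed by correlation with the x coordinate so replicate runs are
comparable. A disconnected network triggers a warning, not an error.

## Bayesian admixture

`run_admixture()` is a Gibbs sampler for the no-admixture-prior mixture
model with admixture proportions: cluster allele frequencies get a
`Dirichlet(lambda = 1)` prior, individual ancestry vectors a
`Dirichlet(alpha)` prior with a common alpha updated by a Metropolis step
(normal proposal, SD 0.025, uniform prior on (0, 10]). Model selection
reports `L(K) = mean(D) - var(D)/2` from the posterior deviance, and the
Evanno Delta-K over replicate runs. Replicate Q matrices are aligned by
greedy matching on column correlations. `assign_gene_pools()` thresholds
ancestry at 0.5 or 0.875. The sampler's conditional updates are verified
by a Geweke "getting it right" test: successive-conditional simulation
(resampling data given the latent state) is compared against marginal
prior-forward simulation with batch-mean z-scores.

Expect upward bias of a few units in `L(K)` on tiny problems (the
variance-penalty estimator of the marginal likelihood is not exact);
model-selection tests compare across K rather than to absolute values.

## Diversity, inbreeding, null alleles, clones

Allelic richness is rarefied to a standard sample size by the exact
hypergeometric formula; expected heterozygosity uses the unbiased
`n/(n-1)` correction; `F_IS` is tested by permuting gene copies within
loci. Null alleles are handled with an EM maximum-likelihood fit in which
blanks are null homozygotes, yielding a per-locus null frequency and a
corrected `F_IS*`. Caveat: with no observed blanks the EM cannot separate
a Wahlund effect from nulls and will absorb substructure into the null
frequency; `F_IS*` should be read jointly with the raw `F_IS` and its
permutation test. Clonality uses `P_gen`, the probability of a multilocus
genotype under HWE, and `psex = P(X >= k - 1)` with
`X ~ Binomial(N - 1, P_gen)` — note psex *increases* with sample size.

## Heterogeneity and cyto-nuclear tests

Weir–Cockerham theta is computed as a ratio of summed variance
components and tested by permuting group labels. Categorical
associations use Fisher's exact test (2x2) or Monte-Carlo sampling of
tables with fixed margins (r x c). The partial Mantel statistic is the
matrix correlation of residuals controlling a third matrix, permuting
rows/columns of the first matrix; it matches `vegan::mantel.partial` to
numerical precision. Continental contrasts use a pooled-variance
one-tailed t-test; rank associations use Spearman's rho with an exact P
by full permutation enumeration for n <= 10.

## The forward simulator

`simulate_population()` evolves one diploid individual per node of a
toroidal lattice (density `D = 1/spacing^2`). Each generation every node
is replaced by an offspring whose mother is drawn by a Gaussian seed
kernel (`sigma_seed`) and father by a Gaussian pollen kernel
(`sigma_pollen`) around the mother, with optional selfing and clonal
reproduction. Nuclear SSRs mutate stepwise within 40 states; the plastid
haplotype follows the maternal line. Null alleles are masked i.i.d. per
gene copy at configurable per-locus rates (both copies masked = missing;
one masked = apparent homozygote), with the truth retained for
verification. Scenarios: `panmixia`, `ibd`, `two_deme_contact` (divergent
demes meeting at a contact zone with assortative mating), and
`altitudinal_barrier`. The default number of generations scales as
`10 * extent / sigma_g` so SGS is near drift–dispersal equilibrium.
Torus wrap-around flattens kinship–distance regressions at the habitat
scale, so calibration experiments sample a central window.

## Numerical conventions

All permutation P values are `(extreme + 1)/(n_perm + 1)`; every
stochastic routine requires an explicit seed and is bitwise reproducible;
multilocus statistics are ratios of sums, never means of ratios;
rarefaction and small-sample Spearman/Fisher P values are exact where
enumeration is feasible. Reference values for *Symphonia globulifera*
populations are provided as data (`symphonia_fsgs()`, `symphonia_sites()`)
for cross-checking the Sp identity and the continental contrasts.
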