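---
title: "Methods: population structure, matrilineal culture and historical abundance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure, matrilineal culture and historical abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matrikin)
```

# The scientific problem

Baleen whales such as the southern right whale learn their migratory
destinations from their mothers.  If calves inherit both their mother's
mitochondrial DNA and her feeding- and calving-ground preferences, then
maternally directed fidelity ("migratory culture") leaves two signatures in
biopsy data:

1. **Structure at the wintering end**: calving grounds differ in mtDNA
   haplotype frequencies (and, if males also show fidelity, in nuclear
   allele frequencies).
2. **Structure at the feeding end**: whales sharing a mtDNA haplotype
   (a *matriline*) feed in similar places, so their skin carries similar
   stable-isotope values — particularly carbon (delta-13C), which tracks
   feeding latitude, whereas nitrogen (delta-15N) mostly tracks trophic
   level and need not differ between matrilines.

`matrikin` implements the full analysis battery for both signatures from a
single sample table (one biopsy per row: stratum labels, sex, mtDNA
haplotype, up to 17 microsatellite loci, optional delta-13C/delta-15N), plus
a Monte-Carlo conversion of coalescent genetic diversity into historical
census abundance.  A synthetic-data generator produces data with exactly the
statistical structure the analyses assume, with full ground truth, so every
stage is testable with no external data.

# Data model and quality control

Genotypes are unordered pairs of integer fragment sizes per locus; a locus
is either fully typed or fully missing.  Missing-data codes (classically
`"0"`) are configurable on input and normalised to one internal state.
Strata are assigned at three levels — sampling location, habitat class
(calving vs migratory) and management unit — through a location mapping
(e.g. VIC/TAS/NSW/QLD pooling to a southeast unit, SA/WA to a southwest
unit).

QC follows standard long-term biopsy-programme practice:

* **Per-allele error rate** from re-amplified internal controls (plain
  proportion of single-allele discrepancies).
* **Probability of identity** `P_ID = prod_l (sum p_i^4 + sum (2 p_i p_j)^2)`
  for unrelated individuals; the sibling-adjusted variant is not
  implemented because published applications of this pipeline report only
  the unrelated form.
* **Duplicate detection** over all pairs with at least `min_shared_loci = 8`
  comparable loci and at most `max_mismatch = 1` mismatches.  The defaults
  are deliberately permissive: a resampled individual with one allele
  miscalled (the error mode the error rate quantifies) still matches at 1
  mismatch.  Flagged pairs with mismatches are reported for review, never
  auto-merged.  `dedupe()` retains one copy of each genotype *per sampling
  location* (most-typed member, ties by ID), so the same whale sampled in
  two locations stays in both location-level analyses — matching the field
  convention for migratory species.
* **Hardy-Weinberg exact test** by Monte Carlo: the observed allele
  multiset is repeatedly shuffled into random diploid pairings, which
  samples the exact conditional-on-allele-counts null; the p-value is the
  probability of genotype tables no more likely than the observed one.
  Default 100,000 shuffles with an explicit seed; the suite cross-checks
  tiny tables against full enumeration and large samples against the
  chi-square approximation.

# Differentiation statistics

* **Haplotype and nucleotide diversity**: unbiased estimators
  `h = n(1 - sum p^2)/(n - 1)` and mean pairwise per-site difference over
  sampled sequence pairs.
* **AMOVA / Phi_ST**: two-level Excoffier-style decomposition from pairwise
  haplotype differences treated as squared distances.  With the identity
  distance the statistic collapses exactly to haplotype-frequency F_ST (the
  suite verifies this against an independent indicator-variable ANOVA);
  with raw sequence differences it is Phi_ST.  Raw difference counts are
  the simplest distance model consistent with "haplotype distances"; no
  substitution-model correction is applied.
* **Weir-Cockerham F_ST** (1984 theta) for microsatellites, summing
  per-allele variance components within and across loci; missing genotypes
  are dropped locus by locus.
* **Jost's D**: per-locus `D_est` from unbiased `H_S`/`H_T` with
  harmonic-mean sample-size correction, combined across loci by arithmetic
  mean (the GENODIVE-style dialect; other programs use ratios of averaged
  heterozygosities).  Negative estimates from the unbiased estimators are
  reported as computed, never truncated — near-zero comparisons between
  weakly differentiated strata depend on this.
* **Significance**: stratum labels of *individuals* are permuted
  (10,000 permutations by default) with the add-one rule
  `p = (#{perm >= obs} + 1)/(n_perm + 1)`.  The exact test of
  differentiation runs a Metropolis chain over contingency tables with
  fixed margins (elementary 2x2 corner moves, hypergeometric acceptance
  ratio) and reports a batch-means Monte-Carlo standard error; the suite
  checks it against Fisher's exact test.  Desk-scale defaults are 100,000
  steps / 10,000 dememorization; published-scale settings (10^6/10^6) are
  reachable through the arguments.

# Factorial correspondence analysis

Genotypes are encoded as allele-dosage counts (0/1/2 per allele, the
Genetix convention); a missing locus contributes zeros and is absorbed by
the row mass rather than imputed — a documented limitation that slightly
shrinks incompletely typed individuals toward the origin.  The
correspondence analysis itself is the chi-square-metric SVD of the
standardized row-profile residuals; axis signs are fixed by forcing the
largest-magnitude coordinate positive so plots are reproducible.  The suite
verifies the total-inertia identity (chi-square statistic / grand total)
and agreement of singular values with an independent implementation.

# The isotope-genetics association battery

All four published lines of evidence are implemented:

1. **Kruskal-Wallis** rank test of delta-13C (and delta-15N) across mtDNA
   haplotypes (tie-corrected, chi-square p).
2. **AIC model weighting**: Gaussian linear models over every subset of
   {haplotype, sex, state}, optionally with all two-way interactions among
   included mains; Akaike weights; and the summed weight of models
   containing each factor.  AIC (not AICc) is the default to match common
   practice in this literature; AICc is a switch.
3. **Matriline randomization test**: observed F-ratio (between/within
   mean squares) of delta-13C over matrilines, compared with 10,000 random
   relabelings; the p-value is the *plain proportion* of randomized F
   at least as extreme — deliberately different from the add-one rule of
   the generic permutation engine, following the original procedure.
   A matriline is haplotype x management unit: where one haplotype spans
   demographically distinct units it likely represents several matrilineal
   groups.
4. **Relatedness vs isotope distance**: Ritland and Lynch-Ritland pairwise
   relatedness (reference frequencies from the full analysed sample,
   pair included — the COANCESTRY default; leave-pair-out is available by
   passing frequencies), converted to a dissimilarity by the monotone
   transform `max(r) - r`, and Mantel-tested against Euclidean isotope
   distances with one-sided alternative "higher relatedness, smaller
   isotopic distance".  The transform is a package choice (any monotone
   decreasing map gives the same permutation test up to sign) and is
   configurable by transforming the matrix yourself.

# From coalescent theta to census abundance

For a maternally inherited locus, `theta = 2 N_e(f) mu_gen` with `mu_gen`
the per-generation substitution rate.  The Monte Carlo draws, per theta
draw: generation span `G ~ Uniform(18.1, 28.8)` years;
`mu_gen = mu_site_year * G` with `mu_site_year = 2.0e-8` (bowhead-derived
control-region rate); `N_e(f) = theta / (2 mu_gen)`; mature females
`N_T(f) = 2 N_e(f)`; and census size `N_C = c N_T(f)` with
`c ~ Uniform(2.5, 4.71)` (mature-female fraction from equilibrium to
maximal-growth conditions) drawn independently.  Means and percentile 95%
limits are reported over 2,000 draws.  Theta is interpreted per site —
the only reading that puts control-region theta and plausible N_e(f) on
the same scale.

When the sampler's posterior draws are unavailable, a log-normal stand-in
is fitted to the 95% HPD interval by least squares on the log bounds
(`meanlog` the log-interval midpoint, `sdlog` its half-width over 1.96),
which reproduces both bounds exactly.  Coalescent posteriors are strongly
right-skewed, so the reported point estimate generally sits off this
stand-in's median and the stand-in's mean is *not* the published posterior
mean; the stand-in is a dialect for propagating interval uncertainty, not
a reconstruction of the posterior.  Because the whole chain is exactly
scale-equivariant in theta (doubling every draw doubles every abundance
mean), results can be anchored to a known mean `N_e(f)` by rescaling the
draws — the acceptance script uses this to reproduce published mean census
sizes from published mean effective sizes via the independence identity
`E[N_C] = 2 E[c] E[N_e(f)] = 7.21 E[N_e(f)]`.

```{r}
est <- theta_estimate("WA", 4.72e-3, 8.31e-5, 0.0115)
theta_to_abundance(est, n_draws = 2000, seed = 1)
```

# The synthetic-data generator

The generator emulates, with known truth, every structure the analyses
assume:

* **Island-model genotypes**: ancestral allele frequencies from a flat
  Dirichlet; regional frequencies from a Balding-Nichols-style Dirichlet
  with concentration `(1 - F_ST)/F_ST`, which makes the differentiation
  parameter directly targetable; genotypes by within-region random mating.
  mtDNA haplotype frequencies are perturbed the same way.
* **Haplotype sequences**: independent Poisson(`divergence/2`)
  substitutions per haplotype on a random ancestral sequence, so expected
  pairwise differences match `divergence` up to a small same-site
  collision deficit.
* **Matriline isotopes**: each haplotype x management-unit matriline gets
  a delta-13C niche mean `Normal(base, matriline_effect_sd)`; individuals
  add `Normal(0, isotope_noise_sd)`; delta-15N comes from one common
  distribution for everyone, mirroring the expected negative finding.
  Field data do not pin down the within-matriline spread, so the defaults
  (1.2 permil between, 0.5 permil within) are a plausible-magnitude choice
  for Southern Ocean feeding-latitude spread, documented here and *not*
  presented as estimates of the real system.
* **Pedigree pairs** by Mendelian transmission from founders (parent-
  offspring and full-sib r = 0.5, half-sib 0.25, unrelated 0), for
  calibrating the relatedness estimators.
* **Artifacts**: duplicate profiles (optionally with loci dropped) and
  allele miscalls at a configured per-allele rate, injected as an exact
  count (`round(rate * calls)`) so the registry-measured rate equals the
  configured one; every change is registered, enabling closed-loop QC
  tests.

Every stochastic entry point requires a seed, and identical seeds give
identical output.  What passing tests on these simulations do *not* show:
real microsatellites have size homoplasy, null alleles and allele-specific
error; real isotope values drift with age, sex, reproductive state and
tissue turnover; and real haplotype frequencies reflect coalescent history
rather than a one-parameter perturbation.  The generator validates the
estimators' arithmetic and calibration, not the biology.

# Numerical and design choices

* Negative differentiation and relatedness estimates are reported as
  computed (unbiased-estimator convention).
* The generic permutation p uses add-one smoothing; the matriline
  randomization test uses the plain proportion.  Both are documented where
  they appear; the difference matters only at p near 0.
* Zero within-group variance makes the F-ratio infinite; randomized
  infinities count as "as extreme" so the p-value stays valid.
* Monomorphic loci: HWE p = 1 with a warning; Jost's D contributes 0;
  Weir-Cockerham drops the locus (all-monomorphic data are flagged
  undefined rather than reported as 0).
* The Lynch-Ritland reference-ordering weights can vanish (e.g. an
  equifrequent heterozygote); such orderings contribute nothing rather
  than NaN, and the two orderings of each pair are averaged.
* Pairs sharing fewer than `min_shared_loci = 2` typed loci get `NA`
  relatedness.
* Default problem sizes in the test-suite and acceptance script
  (100-locus/50-per-deme recovery runs, 40 single-locus mtDNA replicates,
  500 pedigree pairs per class, 500-replicate calibration sweeps at 99-400
  Monte-Carlo steps) were chosen so each sweep gives standard errors well
  inside the assertion bands while the whole battery runs on a laptop in
  about two minutes; published-scale permutation and chain counts are all
  reachable through function arguments.
* The model-weighting power check runs on a single simulated wintering
  region, where matriline coincides with haplotype: with several regions
  the haplotype x unit niche structure splits support between `haplotype`
  and `state` terms (that split is why the randomization test groups by
  haplotype x unit in the first place), so the single-region setting is
  the faithful mirror of "haplotype drives the isotope signal".

# Known limitations

* No null-allele or allele-binning model; QC assumes called genotypes.
* Two-level AMOVA only (among/within strata); no migration-rate or
  coalescent estimation — theta is consumed as input, not estimated.
* The exact-test chain can mix slowly on very sparse tables; the reported
  batch-means standard error is the diagnostic to watch.
* P_ID as published elsewhere cannot be reproduced without the original
  allele frequencies; the implementation is validated on closed-form
  fixtures instead.
* The delta-15N channel is analysed but expected to carry no matriline
  signal; it is reported as secondary output.
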