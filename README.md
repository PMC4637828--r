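# matrikin

Population structure, matrilineal culture and historical abundance from
DNA profiles and stable isotopes.

## What this is for

Long-lived migratory marine mammals — the motivating case is the southern
right whale around Australia and New Zealand — learn their migratory
destinations from their mothers.  That "migratory culture" predicts two
measurable signatures in skin-biopsy data:

* **calving grounds differ genetically** (mtDNA haplotype frequencies for
  maternal fidelity; microsatellite allele frequencies if males follow
  too), and
* **whales of the same matriline feed in similar places**, so mtDNA
  haplotype and microsatellite relatedness predict similarity in skin
  stable-isotope values (delta-13C tracks feeding latitude; delta-15N,
  tracking trophic level, should show no such signal).

`matrikin` is an R toolkit for the whole analysis chain on a single sample
table (one biopsy per row: location/habitat/management-unit labels, sex,
mtDNA haplotype, up to 17 microsatellite loci, optional delta-13C and
delta-15N), plus an mtDNA haplotype FASTA:

* **QC**: per-allele error rate, probability of identity
  (`P_ID = prod_l [sum p_i^4 + sum_{i<j} (2 p_i p_j)^2]`), duplicate
  detection and per-location dedupe, Monte-Carlo Hardy-Weinberg exact
  tests.
* **Diversity and differentiation**: haplotype/nucleotide diversity,
  two-level AMOVA giving frequency F_ST (identity distances) and Phi_ST
  (sequence distances), Weir-Cockerham theta for microsatellites, Jost's
  D_est, individual-label permutation tests, and a Markov-chain exact test
  of differentiation.
* **Factorial correspondence analysis** of allele-dosage-encoded
  genotypes.
* **Isotope-genetics battery**: Kruskal-Wallis by haplotype, AIC/Akaike
  model weighting over {haplotype, sex, state} with interactions, the
  matriline randomization F-ratio test (10,000 relabelings, plain
  proportion p), Ritland and Lynch-Ritland pairwise relatedness, and
  Mantel tests of relatedness-derived distance vs Euclidean isotope
  distance.
* **Historical abundance**: Monte-Carlo propagation of coalescent theta
  (per site) through `theta = 2 N_e(f) mu_gen`, with generation span
  `G ~ U(18.1, 28.8)` yr, `mu = 2.0e-8` subs/site/yr, mature females
  `N_T(f) = 2 N_e(f)` and census `N_C = c N_T(f)`, `c ~ U(2.5, 4.71)`.
* **Synthetic data**: a Balding-Nichols island-model generator with
  matriline-structured isotopes, pedigree pairs of known relatedness and
  registered QC artifacts, so the whole pipeline runs and is tested with
  no external data.

See `vignettes/methods.Rmd` for models, assumptions, defaults and
limitations.

## Worked example

```r
library(matrikin)

cfg <- sim_config(n_regions = 3, n_per_region = 30, n_loci = 17,
                  target_fst = 0.05, matriline_effect_sd = 1.2,
                  isotope_noise_sd = 0.5, seed = 2015)
sim <- simulate_island_model(cfg)
profiles <- simulate_matriline_isotopes(sim$profiles, cfg)$profiles
profiles
#> DNA profiles: 90 individuals, 17 loci (L01, L02, L03, L04, L05)
#>   haplotyped: 90; with isotope values: 90

mu <- assign_strata(profiles, "management_unit")
weir_cockerham_fst(profiles, mu)
#> Weir-Cockerham F_ST: theta = 0.04710 over 17 loci
josts_d(profiles, mu)
#> Jost's D = 0.17238 (mean over 17 loci)
amova(profiles$haplotype, mu)
#> AMOVA (identity distances): 90 individuals, 3 strata
#>   among-strata  df=2 SS=1.3222  sigma2=0.00990
#>   within-strata df=87 SS=31.6667  sigma2=0.36398
#>   Phi_ST = 0.02649
```

The microsatellite theta (0.047) recovers the generator's target F_ST of
0.05; Jost's D is larger because it measures allelic turnover rather than
heterozygosity-scaled variance; the single-locus mtDNA Phi_ST (0.026) is
noisier, as expected for one locus.

```r
grp <- matriline_grouping(profiles)          # haplotype x management unit
vals <- setNames(profiles$d13C, profiles$sample_id)[names(grp)]
rt <- matriline_randomization_test(vals, grp, n_rand = 10000, seed = 1)
sprintf("F-ratio = %.2f, p = %.4f", rt$F_ratio, rt$p_value)
#> "F-ratio = 29.05, p = 0.0000"
```

Same-matriline whales are far more isotopically similar than
different-matriline whales (none of 10,000 relabelings reached the
observed F-ratio).

```r
est <- theta_estimate("WA", 4.72e-3, 8.31e-5, 0.0115)  # theta + 95% HPD
theta_to_abundance(est, n_draws = 2000, seed = 1)
#> Historical abundance (WA): 2000 Monte-Carlo draws
#>   Nef  mean       2431  (95% CL       76 -    12875)
#>   NTf  mean       4862  (95% CL      152 -    25751)
#>   NC   mean      17610  (95% CL      525 -    95712)
```

Here the theta draws come from the log-normal interval stand-in (see the
vignette); mean census size is `2 * E[c] = 7.21` times mean female
effective size, and the chain is exactly scale-equivariant in theta, so
draws can be anchored to an externally known mean `N_e(f)`.

`run_pipeline(config, outdir)` wires all stages (simulate/read -> qc ->
diversity -> structure -> fca -> culture -> abundance) into one seeded,
byte-reproducible run writing TSV/JSON reports.

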