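test_that("the island-model generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_regions = 2, n_per_region = 10, n_loci = 5, seed = 11)
  s1 <- simulate_island_model(cfg)
  s2 <- simulate_island_model(cfg)
  expect_identical(as.data.frame(s1$profiles), as.data.frame(s2$profiles))
  expect_identical(s1$truth$allele_freqs, s2$truth$allele_freqs)
  s3 <- simulate_island_model(sim_config(n_regions = 2, n_per_region = 10,
                                         n_loci = 5, seed = 12))
  expect_false(identical(as.data.frame(s1$profiles),
                         as.data.frame(s3$profiles)))
  expect_error(simulate_island_model(sim_config(n_regions = 2, seed = NULL)),
               "seed")
  expect_error(sim_config(alleles_per_locus = 1), "alleles_per_locus")
})

test_that("undifferentiated regions give F_ST near zero over replicates", {
  thetas <- vapply(1:8, function(r) {
    sim <- simulate_island_model(sim_config(n_regions = 2, n_per_region = 30,
                                            n_loci = 30, target_fst = 0,
                                            seed = 100 + r))
    weir_cockerham_fst(sim$profiles,
                       assign_strata(sim$profiles, "management_unit"))$theta
  }, numeric(1))
  se <- sd(thetas) / sqrt(length(thetas))
  expect_lt(abs(mean(thetas)), 3 * se + 1e-3)
})

test_that("a target F_ST of 0.10 is recovered by the estimator", {
  sim <- simulate_island_model(sim_config(n_regions = 2, n_per_region = 50,
                                          n_loci = 100, target_fst = 0.10,
                                          seed = 21))
  wc <- weir_cockerham_fst(sim$profiles,
                           assign_strata(sim$profiles, "management_unit"))
  expect_lt(abs(wc$theta - 0.10), 0.03)
})

test_that("haplotype sequences match the configured divergence", {
  cfg1 <- sim_config(n_haplotypes = 1, seed = 31)
  hs1 <- simulate_haplotype_sequences(cfg1)
  expect_equal(length(hs1), 1L)

  means <- vapply(1:10, function(r) {
    hs <- simulate_haplotype_sequences(
      sim_config(n_haplotypes = 12, divergence = 5, seq_length = 500,
                 seed = 300 + r))
    d <- sequence_distance_matrix(hs)
    mean(d[upper.tri(d)])
  }, numeric(1))
  # expected pairwise difference ~ divergence, minus a tiny collision term
  expect_lt(abs(mean(means) - 5), 3 * sd(means) / sqrt(10) + 0.15)

  hs <- simulate_haplotype_sequences(sim_config(n_haplotypes = 6, seed = 41))
  hs2 <- simulate_haplotype_sequences(sim_config(n_haplotypes = 6, seed = 41))
  expect_identical(names(hs), unique(names(hs)))
  expect_identical(unclass(hs), unclass(hs2))
  expect_error(sim_config(divergence = 600, seq_length = 500))
})

test_that("matriline isotope structure behaves as configured", {
  base <- simulate_island_model(sim_config(n_regions = 2, n_per_region = 40,
                                           n_loci = 2, n_haplotypes = 6,
                                           seed = 51))
  # null: no matriline effect => F-ratio near 1 on average
  f_null <- vapply(1:10, function(r) {
    iso <- simulate_matriline_isotopes(
      base$profiles, sim_config(matriline_effect_sd = 0,
                                isotope_noise_sd = 0.5, seed = 500 + r))
    grp <- matriline_grouping(iso$profiles)
    vals <- setNames(iso$profiles$d13C, iso$profiles$sample_id)[names(grp)]
    matrikin:::f_ratio(vals, grp)
  }, numeric(1))
  expect_lt(abs(mean(f_null) - 1), 0.5)

  # strong effect: F-ratio far above 1, but d15N stays unstructured
  iso <- simulate_matriline_isotopes(
    base$profiles, sim_config(matriline_effect_sd = 3,
                              isotope_noise_sd = 0.3, seed = 61))
  grp <- matriline_grouping(iso$profiles)
  vals <- setNames(iso$profiles$d13C, iso$profiles$sample_id)[names(grp)]
  expect_gt(matrikin:::f_ratio(vals, grp), 5)
  kw_n <- kruskal_wallis(iso$profiles$d15N, grp[iso$profiles$sample_id])
  expect_gt(kw_n$p_value, 0.01)
  expect_identical(attr(iso$truth$matriline_niche_d13C, "names"),
                   unique(paste(base$profiles$haplotype,
                                base$profiles$management_unit, sep = "|")))
})

test_that("parent-offspring pairs always share an allele at every locus", {
  ped <- simulate_pedigree_pairs(
    sim_config(n_loci = 10, alleles_per_locus = 8,
               pedigree = c(parent_offspring = 50, full_sib = 0,
                            half_sib = 0, unrelated = 0), seed = 71))
  g <- genotype_matrix(ped$profiles)
  for (k in seq_len(nrow(ped$pairs))) {
    g1 <- g[ped$pairs$id1[k], ]; g2 <- g[ped$pairs$id2[k], ]
    for (l in seq_len(10)) {
      shared <- intersect(g1[c(2 * l - 1, 2 * l)], g2[c(2 * l - 1, 2 * l)])
      expect_gte(length(shared), 1)
    }
  }
})

test_that("artifact injection is fully registered and closed-loop", {
  sim <- simulate_island_model(sim_config(n_regions = 2, n_per_region = 20,
                                          n_loci = 10, seed = 81))
  cfg <- sim_config(duplicate_count = 3, duplicate_drop_loci = 2,
                    error_rate = 0.01, seed = 81)
  art <- inject_qc_artifacts(sim$profiles, cfg)
  expect_equal(nrow(art$registry$duplicates), 3L)
  expect_equal(nrow(art$registry$allele_errors),
               round(0.01 * art$registry$n_allele_calls))
  expect_true(all(art$registry$allele_errors$old !=
                    art$registry$allele_errors$new))

  # rate 0, no duplicates: identity
  clean <- inject_qc_artifacts(sim$profiles,
                               sim_config(duplicate_count = 0,
                                          error_rate = 0, seed = 82))
  expect_identical(as.data.frame(clean$profiles),
                   as.data.frame(sim$profiles))
})

test_that("the injected error count reproduces a 0.61% measured rate", {
  # 68 individuals x 17 loci = 2312 calls; drop 14 genotypes -> 2284 calls
  set.seed(91)
  n <- 68; n_loci <- 17
  g <- matrix(sample(100:130, n * 2 * n_loci, replace = TRUE), nrow = n)
  drop <- sample(n * n_loci, 14)
  for (d in drop) {
    i <- (d - 1) %% n + 1; l <- (d - 1) %/% n + 1
    g[i, c(2 * l - 1, 2 * l)] <- NA
  }
  loci_names <- sprintf("L%02d", seq_len(n_loci))
  gd <- as.data.frame(g)
  names(gd) <- as.vector(rbind(paste0(loci_names, "_1"),
                               paste0(loci_names, "_2")))
  p <- dna_profiles(cbind(data.frame(sample_id = sprintf("i%02d", 1:n),
                                     location = "WA"), gd))
  art <- inject_qc_artifacts(p, sim_config(duplicate_count = 0,
                                           error_rate = 14 / 2284, seed = 92))
  expect_equal(art$registry$n_allele_calls, 2284L)
  rate <- per_allele_error_rate(art$registry$n_allele_calls,
                                nrow(art$registry$allele_errors))
  expect_equal(round(rate$percent, 2), 0.61)
})
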