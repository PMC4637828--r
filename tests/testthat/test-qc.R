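test_that("per-allele error rate is the plain proportion of miscalls", {
  r <- per_allele_error_rate(2284, 14)
  expect_equal(r$rate, 14 / 2284)
  expect_equal(round(r$percent, 2), 0.61)
  expect_equal(per_allele_error_rate(100, 0)$rate, 0)
  expect_equal(per_allele_error_rate(10, 10)$rate, 1)
  expect_error(per_allele_error_rate(0, 0), "positive")
  expect_error(per_allele_error_rate(10, 11))
})

test_that("probability of identity follows the unrelated-pair formula", {
  expect_equal(probability_of_identity(list(L1 = c(0.5, 0.5)))$overall, 0.375)
  expect_equal(probability_of_identity(list(L1 = c(0.5, 0.5),
                                            L2 = c(0.5, 0.5)))$overall,
               0.140625)
  expect_equal(probability_of_identity(list(L1 = 1))$overall, 1)
  expect_error(probability_of_identity(list()), "empty")
  expect_error(probability_of_identity(list(L1 = c(0.5, 0.4))), "sum to 1")

  # adding loci can only decrease the multi-locus P_ID
  set.seed(5)
  freqs <- lapply(1:6, function(i) {
    p <- runif(4); p / sum(p)
  })
  names(freqs) <- paste0("L", 1:6)
  pids <- vapply(1:6, function(k)
    probability_of_identity(freqs[seq_len(k)])$overall, numeric(1))
  expect_true(all(diff(pids) <= 0))
  expect_lte(probability_of_identity(freqs)$overall,
             min(probability_of_identity(freqs)$per_locus))
})

test_that("duplicate genotypes are found with their match statistics", {
  p <- profiles_with_pair(n = 8, n_loci = 17)
  rep <- find_duplicates(p, min_shared_loci = 8, max_mismatch = 1)
  exact <- rep[rep$mismatches == 0, ]
  expect_true(nrow(exact) >= 1)
  hit <- exact[exact$id1 == "ind01" & exact$id2 == "ind02", ]
  expect_equal(hit$loci_compared, 17L)
  expect_equal(hit$loci_matching, 17L)
  expect_lt(hit$p_id, 1e-6)
})

test_that("profiles differing everywhere are never reported", {
  df <- data.frame(sample_id = c("x", "y"), location = "WA",
                   stringsAsFactors = FALSE)
  g1 <- seq(100, 132, by = 2)[1:10]
  gd <- as.data.frame(rbind(rep(g1, each = 2), rep(g1 + 40, each = 2)))
  names(gd) <- as.vector(rbind(sprintf("L%02d_1", 1:10),
                               sprintf("L%02d_2", 1:10)))
  p <- dna_profiles(cbind(df, gd))
  expect_equal(nrow(find_duplicates(p, min_shared_loci = 8,
                                    max_mismatch = 1)), 0L)
})

test_that("injected duplicates are recovered exactly (closed loop)", {
  sim <- simulate_island_model(sim_config(n_regions = 2, n_per_region = 25,
                                          n_loci = 17, seed = 13))
  art <- inject_qc_artifacts(sim$profiles,
                             sim_config(duplicate_count = 3,
                                        duplicate_drop_loci = 2,
                                        error_rate = 0, seed = 13))
  rep <- find_duplicates(art$profiles, min_shared_loci = 8, max_mismatch = 0)
  truth <- art$registry$duplicates
  truth_pairs <- paste(pmin(truth$original, truth$duplicate),
                       pmax(truth$original, truth$duplicate))
  found_pairs <- paste(rep$id1, rep$id2)
  expect_true(all(truth_pairs %in% found_pairs))
})

test_that("dedupe keeps one copy per stratum and is idempotent", {
  p <- profiles_with_pair(n = 6, n_loci = 12)
  rep <- find_duplicates(p, min_shared_loci = 8, max_mismatch = 0)
  d1 <- dedupe(p, rep, scope = "location")
  expect_equal(nrow(d1), nrow(p) - 1L)
  expect_true("ind01" %in% d1$sample_id)   # lexicographic tie-break
  expect_false("ind02" %in% d1$sample_id)
  rep2 <- find_duplicates(d1, min_shared_loci = 8, max_mismatch = 0)
  d2 <- dedupe(d1, rep2, scope = "location")
  expect_equal(as.data.frame(d2), as.data.frame(d1), ignore_attr = TRUE)

  # same genotype in two different locations: both retained at location scope
  df <- as.data.frame(p)[1:2, ]
  df$location <- c("WA", "VIC")
  p2 <- dna_profiles(df, loci = loci(p))
  rep3 <- find_duplicates(p2, min_shared_loci = 8, max_mismatch = 0)
  expect_equal(nrow(rep3), 1L)  # still reported ...
  d3 <- dedupe(p2, rep3, scope = "location")
  expect_equal(nrow(d3), 2L)    # ... but both copies kept

  # no duplicates: identity
  empty_rep <- find_duplicates(p2[0, ], min_shared_loci = 8)
  expect_identical(nrow(dedupe(p2, rep3[0, ], scope = "location")), 2L)
})

test_that("dedupe retains the most completely typed member", {
  p <- profiles_with_pair(n = 4, n_loci = 10)
  df <- as.data.frame(p)
  df[1, c("L01_1", "L01_2", "L02_1", "L02_2")] <- NA  # ind01 less typed
  p <- dna_profiles(df, loci = loci(p))
  rep <- find_duplicates(p, min_shared_loci = 6, max_mismatch = 0)
  d <- dedupe(p, rep, scope = "location")
  expect_true("ind02" %in% d$sample_id)
  expect_false("ind01" %in% d$sample_id)
})

test_that("HWE Monte-Carlo p matches full enumeration on a tiny table", {
  # 4 heterozygotes Aa: allele counts 4/4; attainable het counts {0, 2, 4}
  g <- cbind(rep(1L, 4), rep(2L, 4))
  p_exact <- hwe_enum_oracle(0, 4, 0)
  expect_equal(p_exact, 22 / 70)
  mc <- hwe_exact_test(g, n_steps = 20000, seed = 2)
  expect_lt(abs(mc$p_value - p_exact), 0.015)
})

test_that("HWE Monte-Carlo agrees with chi-square asymptotics at large n", {
  set.seed(9)
  n <- 400
  a1 <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
  a2 <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
  # perturb towards heterozygote excess so p is in a mid range
  swap <- which(a1 == a2)[1:30]
  a2[swap] <- 3 - a2[swap]
  counts <- c(AA = sum(a1 == 1 & a2 == 1), Aa = sum(a1 != a2),
              aa = sum(a1 == 2 & a2 == 2))
  nA <- 2 * counts[1] + counts[2]
  pA <- nA / (2 * n)
  expd <- n * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
  chi_p <- stats::pchisq(sum((counts - expd)^2 / expd), df = 1,
                         lower.tail = FALSE)
  mc <- hwe_exact_test(cbind(a1, a2), n_steps = 20000, seed = 3)
  expect_lt(abs(mc$p_value - chi_p), 0.02)
})

test_that("HWE p-value is invariant under allele relabeling", {
  set.seed(10)
  a1 <- sample(c(10L, 20L, 30L), 40, replace = TRUE)
  a2 <- sample(c(10L, 20L, 30L), 40, replace = TRUE)
  p1 <- hwe_exact_test(cbind(a1, a2), n_steps = 5000, seed = 4)$p_value
  relab <- c(`10` = 30L, `20` = 10L, `30` = 20L)
  p2 <- hwe_exact_test(cbind(relab[as.character(a1)],
                             relab[as.character(a2)]),
                       n_steps = 5000, seed = 4)$p_value
  expect_equal(p1, p2)
})

test_that("monomorphic loci yield p = 1 with a warning", {
  expect_warning(res <- hwe_exact_test(cbind(c(1L, 1L), c(1L, 1L))),
                 "monomorphic")
  expect_equal(res$p_value, 1)
})
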