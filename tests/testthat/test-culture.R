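test_that("Kruskal-Wallis H matches hand rank computation", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4)
  expect_equal(kruskal_wallis(c(5, 5, 5, 5), rep(c("a", "b"), 2))$H, 0)

  # tie-corrected oracle computed from first principles
  set.seed(63)
  v <- round(rnorm(30), 1)  # rounding induces ties
  g <- sample(c("x", "y", "z"), 30, replace = TRUE)
  rk <- rank(v)
  n <- length(v)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(rk, g, sum)^2 / tabulate(factor(g))) - 3 * (n + 1)
  ties <- table(v)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(kruskal_wallis(v, g)$H, h, tolerance = 1e-10)
})

test_that("AIC weights sum to one and a lone candidate gets weight 1", {
  set.seed(65)
  d <- data.frame(d13C = rnorm(40), hap = sample(c("H1", "H2"), 40, TRUE),
                  sex = sample(c("F", "M"), 40, TRUE))
  mw <- glm_aic_weights(d, "d13C", c("hap", "sex"))
  expect_equal(sum(mw$table$weight), 1)
  expect_equal(min(mw$table$dAIC), 0)
  expect_true(all(mw$table$dAIC >= 0))
  lone <- glm_aic_weights(d, "d13C", character(0))
  expect_equal(nrow(lone$table), 1L)
  expect_equal(lone$table$weight, 1)
})

test_that("factor support reflects a strong simulated matriline effect", {
  set.seed(67)
  n <- 60
  hap <- sample(paste0("H", 1:5), n, replace = TRUE)
  niche <- setNames(rnorm(5, -18, 3), paste0("H", 1:5))
  d <- data.frame(d13C = niche[hap] + rnorm(n, 0, 0.3),
                  haplotype = hap,
                  sex = sample(c("F", "M"), n, TRUE),
                  state = sample(c("WA", "SA", "VIC"), n, TRUE))
  mw <- glm_aic_weights(d, "d13C", c("haplotype", "sex", "state"))
  expect_gt(mw$factor_support[["haplotype"]], 0.95)
})

test_that("pure-noise responses do not concentrate factor support", {
  hits <- 0L
  for (r in 1:20) {
    set.seed(800 + r)
    d <- data.frame(d13C = rnorm(60),
                    haplotype = sample(paste0("H", 1:4), 60, TRUE),
                    sex = sample(c("F", "M"), 60, TRUE))
    mw <- glm_aic_weights(d, "d13C", c("haplotype", "sex"),
                          include_interactions = FALSE)
    if (max(mw$factor_support) > 0.9) hits <- hits + 1L
  }
  expect_lte(hits, 2L)  # <= 10% of null replicates
})

test_that("the randomization F-ratio matches the hand ANOVA example", {
  res <- matriline_randomization_test(c(1, 2, 3, 4), c("a", "a", "b", "b"),
                                      n_rand = 100, seed = 71)
  expect_equal(res$F_ratio, 8)  # MSB = 4, MSW = 0.5
  expect_equal(unname(res$df), c(1, 2))
})

test_that("zero within-group variance yields an infinite F handled sanely", {
  res <- matriline_randomization_test(c(1, 1, 5, 5), c("a", "a", "b", "b"),
                                      n_rand = 200, seed = 73)
  expect_true(is.infinite(res$F_ratio))
  expect_true(res$p_value >= 0 && res$p_value <= 1)
})

test_that("isotope distances are Euclidean and metric", {
  df <- data.frame(sample_id = c("u", "v", "w"), location = "WA",
                   d13C = c(-18, -20, -18), d15N = c(8, 8, 11),
                   L1_1 = 100L, L1_2 = 100L, stringsAsFactors = FALSE)
  p <- dna_profiles(df)
  d1 <- isotope_distance_matrix(p, channels = "d13C")
  expect_equal(d1["u", "v"], 2)
  expect_equal(d1["u", "w"], 0)
  d2 <- isotope_distance_matrix(p)
  expect_equal(d2["u", "w"], 3)
  expect_equal(d2["v", "w"], sqrt(4 + 9))
  set.seed(75)
  dfr <- data.frame(sample_id = sprintf("s%02d", 1:12), location = "WA",
                    d13C = rnorm(12), d15N = rnorm(12),
                    L1_1 = 100L, L1_2 = 100L, stringsAsFactors = FALSE)
  dd <- isotope_distance_matrix(dna_profiles(dfr))
  for (i in 1:12) for (j in 1:12) for (k in 1:12)
    expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
  dfr$d15N[3] <- NA
  expect_warning(dm <- isotope_distance_matrix(dna_profiles(dfr)), "excluded")
  expect_equal(nrow(dm), 11)
})

test_that("Mantel recovers perfect association and flags degeneracy", {
  set.seed(77)
  x <- matrix(rnorm(100), 10); a <- as.matrix(dist(x))
  b <- 3 * a + 2; diag(b) <- 0
  res <- mantel_test(a, b, n_perm = 500, seed = 79)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 501)
  expect_warning(res2 <- mantel_test(matrix(1, 5, 5), a[1:5, 1:5],
                                     n_perm = 10), "constant")
  expect_true(is.na(res2$r))
})

test_that("the Mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(81)
  a <- as.matrix(dist(matrix(rnorm(60), 12)))
  b <- as.matrix(dist(matrix(rnorm(60), 12)))
  mine <- mantel_test(a, b, n_perm = 99, seed = 83)
  veg <- vegan::mantel(a, b, permutations = 0)
  expect_equal(mine$r, unname(veg$statistic), tolerance = 1e-12)
})

test_that("matriline grouping demands haplotype, unit and isotope value", {
  df <- data.frame(sample_id = c("a", "b", "c"), location = "WA",
                   management_unit = c("SWA", "SWA", NA),
                   haplotype = c("H1", NA, "H1"),
                   d13C = c(-18, -19, -20),
                   L1_1 = 100L, L1_2 = 100L, stringsAsFactors = FALSE)
  grp <- matriline_grouping(dna_profiles(df))
  expect_equal(names(grp), "a")
  expect_equal(as.character(grp), "H1|SWA")
})
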