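test_that("complete differentiation gives Phi_ST = 1", {
  p <- fixed_demes(10)
  st <- assign_strata(p, "management_unit")
  expect_equal(amova(p$haplotype, st)$phi_st, 1)
  d <- matrix(c(0, 7, 7, 0), 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  expect_equal(amova(p$haplotype, st, d)$phi_st, 1)
})

test_that("identically distributed strata give Phi_ST near zero", {
  set.seed(17)
  hap <- sample(paste0("H", 1:5), 400, replace = TRUE)
  st <- rep(c("A", "B"), 200)
  expect_lt(abs(amova(hap, st)$phi_st), 0.02)
})

test_that("sums of squares decompose exactly on random fixtures", {
  set.seed(19)
  for (rep in 1:5) {
    hap <- sample(paste0("H", 1:6), 60, replace = TRUE)
    st <- sample(c("A", "B", "C"), 60, replace = TRUE)
    hs <- simulate_haplotype_sequences(sim_config(n_haplotypes = 6,
                                                  seed = 400 + rep))
    names(hs) <- paste0("H", 1:6)
    d <- sequence_distance_matrix(hs)
    am <- amova(hap, st, d)
    expect_equal(am$ss[["among"]] + am$ss[["within"]], am$ss[["total"]])
    expect_equal(sum(am$df), length(hap) - 1)
  }
})

test_that("the variance decomposition matches an independent SS oracle", {
  skip_if_not_installed("vegan")
  set.seed(23)
  hap <- sample(paste0("H", 1:5), 45, replace = TRUE)
  st <- factor(sample(c("A", "B", "C"), 45, replace = TRUE))
  hs <- simulate_haplotype_sequences(sim_config(n_haplotypes = 5, seed = 29))
  names(hs) <- paste0("H", 1:5)
  dmat <- sequence_distance_matrix(hs)
  am <- amova(hap, st, dmat)
  # vegan::adonis2 squares its input distances; feed sqrt so SS match
  d_ind <- stats::as.dist(sqrt(dmat[hap, hap]))
  ad <- vegan::adonis2(d_ind ~ st, permutations = 0)
  expect_equal(am$ss[["among"]], ad$SumOfSqs[1], tolerance = 1e-10)
  expect_equal(am$ss[["within"]], ad$SumOfSqs[2], tolerance = 1e-10)
})

test_that("identity-distance AMOVA equals haplotype-frequency F_ST", {
  # oracle: haploid variance-component F_ST from frequencies (direct ANOVA)
  set.seed(31)
  hap <- sample(paste0("H", 1:4), 80, replace = TRUE,
                prob = c(0.5, 0.3, 0.15, 0.05))
  st <- factor(rep(c("A", "B"), each = 40))
  hap[st == "B"] <- sample(paste0("H", 1:4), 40, replace = TRUE,
                           prob = c(0.1, 0.2, 0.3, 0.4))
  am <- amova(hap, st)
  # indicator-variable one-way ANOVA per haplotype, pooled components
  n_i <- as.numeric(table(st)); N <- sum(n_i); r <- 2
  n_c <- (N - sum(n_i^2) / N) / (r - 1)
  a_sum <- w_sum <- 0
  for (h in unique(hap)) {
    y <- as.numeric(hap == h)
    m_i <- tapply(y, st, mean); m <- mean(y)
    ssa <- sum(n_i * (m_i - m)^2); ssw <- sum((y - m_i[st])^2)
    msa <- ssa / (r - 1); msw <- ssw / (N - r)
    a_sum <- a_sum + (msa - msw) / n_c
    w_sum <- w_sum + msw
  }
  expect_equal(am$phi_st, a_sum / (a_sum + w_sum), tolerance = 1e-12)
})

test_that("AMOVA validates its inputs", {
  expect_error(amova(c("H1", "H2"), c("A", "A")), "2 strata")
  expect_error(amova(c("H1", "H3"), c("A", "B"),
                     matrix(0, 2, 2, dimnames = list(c("H1", "H2"),
                                                     c("H1", "H2")))),
               "absent")
})

test_that("pairwise mtDNA differentiation behaves at the two extremes", {
  p <- fixed_demes(8)
  st <- assign_strata(p, "management_unit")
  d <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  attr(d, "L") <- 500
  res <- pairwise_fst_mtdna(p$haplotype, st, distances = d, n_perm = 200,
                            seed = 5)
  expect_equal(res$estimate[res$statistic == "F_ST"], 1)
  expect_equal(res$estimate[res$statistic == "Phi_ST"], 1)
  expect_lt(max(res$p_value), 0.02)

  set.seed(37)
  hap <- sample(c("H1", "H2"), 60, replace = TRUE)
  st2 <- factor(rep(c("A", "B"), 30))
  res2 <- pairwise_fst_mtdna(hap, st2, n_perm = 200, seed = 7)
  expect_lt(abs(res2$estimate[1]), 0.08)
  expect_gt(res2$p_value[1], 0.1)
})

test_that("differentiation statistics ignore stratum and label order", {
  set.seed(41)
  hap <- sample(paste0("H", 1:4), 50, replace = TRUE)
  st <- sample(c("A", "B"), 50, replace = TRUE)
  a1 <- amova(hap, st)$phi_st
  relab <- c(H1 = "H4", H2 = "H3", H3 = "H2", H4 = "H1")
  a2 <- amova(relab[hap], st)$phi_st
  a3 <- amova(hap, c(A = "B", B = "A")[st])$phi_st
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})
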