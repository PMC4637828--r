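# Shared fixture builders (everything generated in code; no stored data).

# Minimal two-individual, two-locus profile table.
toy_profiles <- function() {
  dna_profiles(data.frame(
    sample_id = c("a", "b"), location = c("WA", "VIC"),
    habitat = c("calving", "calving"), management_unit = c("SWA", "SEA"),
    sex = c("F", "M"), haplotype = c("H1", "H2"),
    d13C = c(-18.5, -19.25), d15N = c(8.1, NA),
    L1_1 = c(100L, 102L), L1_2 = c(104L, 102L),
    L2_1 = c(200L, NA), L2_2 = c(202L, NA),
    stringsAsFactors = FALSE))
}

# Profiles with n_loci loci where two named individuals carry identical
# genotypes and everyone else is random.
profiles_with_pair <- function(n = 10, n_loci = 17, seed = 42) {
  set.seed(seed)
  g <- matrix(sample(100:120, n * 2 * n_loci, replace = TRUE), nrow = n)
  g[2, ] <- g[1, ]  # duplicate pair
  df <- data.frame(sample_id = sprintf("ind%02d", seq_len(n)),
                   location = "WA", habitat = "calving",
                   management_unit = "SWA", sex = "F",
                   haplotype = "H1", stringsAsFactors = FALSE)
  loci_names <- sprintf("L%02d", seq_len(n_loci))
  g <- as.data.frame(g)
  names(g) <- as.vector(rbind(paste0(loci_names, "_1"),
                              paste0(loci_names, "_2")))
  dna_profiles(cbind(df, g), loci = loci_names)
}

# Two demes fixed for different alleles / haplotypes.
fixed_demes <- function(n_per = 10) {
  df <- data.frame(
    sample_id = sprintf("f%02d", seq_len(2 * n_per)),
    location = rep(c("A", "B"), each = n_per),
    habitat = "calving",
    management_unit = rep(c("A", "B"), each = n_per),
    sex = "F",
    haplotype = rep(c("H1", "H2"), each = n_per),
    L1_1 = rep(c(100L, 120L), each = n_per),
    L1_2 = rep(c(100L, 120L), each = n_per),
    L2_1 = rep(c(150L, 160L), each = n_per),
    L2_2 = rep(c(150L, 160L), each = n_per),
    stringsAsFactors = FALSE)
  dna_profiles(df, loci = c("L1", "L2"))
}

# Independent brute-force Weir-Cockerham components via the indicator-variable
# ANOVA route (mean squares MSP/MSI/MSG), used as an oracle.
wc_anova_oracle <- function(profiles, strata) {
  g <- genotype_matrix(profiles)
  ln <- loci(profiles)
  strata <- factor(strata)
  A <- B <- C <- 0
  for (l in seq_along(ln)) {
    a1 <- g[, 2 * l - 1]; a2 <- g[, 2 * l]
    typed <- which(!is.na(a1))
    sub <- droplevels(factor(strata[typed]))
    if (nlevels(sub) < 2 || any(table(sub) < 2)) next
    alleles <- unique(c(a1[typed], a2[typed]))
    if (length(alleles) < 2) next
    n_i <- as.numeric(table(sub))
    r <- length(n_i); N <- sum(n_i)
    n_c <- (N - sum(n_i^2) / N) / (r - 1)
    for (al in alleles) {
      # y[ind, copy] indicator of allele al
      y <- cbind(a1[typed] == al, a2[typed] == al) * 1
      ybar_i <- tapply(rowSums(y) / 2, sub, mean)   # pop means (per copy)
      ybar <- sum(tapply(rowSums(y), sub, sum)) / (2 * N)
      ssp <- sum(2 * n_i * (ybar_i - ybar)^2)
      ind_mean <- rowSums(y) / 2
      ssi <- sum(2 * (ind_mean - ybar_i[sub])^2)
      ssg <- sum((y - ind_mean)^2)
      msp <- ssp / (r - 1)
      msi <- ssi / (N - r)
      msg <- ssg / N
      C <- C + msg
      B <- B + (msi - msg) / 2
      A <- A + (msp - msi) / (2 * n_c)
    }
  }
  list(a = A, b = B, c = C, theta = A / (A + B + C))
}

# Exhaustive-enumeration HWE exact p for a biallelic sample: enumerates all
# heterozygote counts compatible with the allele counts.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  logw <- vapply(hets, function(h) {
    aa1 <- (nA - h) / 2; aa2 <- n - aa1 - h
    lfactorial(n) - lfactorial(aa1) - lfactorial(h) - lfactorial(aa2) +
      h * log(2)
  }, numeric(1))
  w <- exp(logw - max(logw)); w <- w / sum(w)
  obs <- w[match(n_Aa, hets)]
  sum(w[w <= obs + 1e-12])
}
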