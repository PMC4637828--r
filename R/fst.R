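# Microsatellite differentiation statistics: Weir-Cockerham theta and
# Jost's D_est.  Both operate per locus on genotype counts by stratum and
# combine across loci; missing genotypes are excluded locus by locus.

# Per-stratum allele frequencies and heterozygote frequencies at one locus.
locus_by_stratum <- function(a1, a2, strata) {
  typed <- !is.na(a1)
  strata <- droplevels(factor(strata[typed]))
  a1 <- a1[typed]; a2 <- a2[typed]
  lev <- levels(strata)
  alleles <- sort(unique(c(a1, a2)))
  n_i <- as.numeric(table(strata))
  p <- matrix(0, length(lev), length(alleles), dimnames = list(lev, alleles))
  h <- matrix(0, length(lev), length(alleles), dimnames = list(lev, alleles))
  for (g in seq_along(lev)) {
    in_g <- strata == lev[g]
    cnt <- table(factor(c(a1[in_g], a2[in_g]), levels = alleles))
    p[g, ] <- as.numeric(cnt) / (2 * n_i[g])
    for (a in seq_along(alleles)) {
      het <- (a1[in_g] == alleles[a]) != (a2[in_g] == alleles[a])
      h[g, a] <- mean(het)
    }
  }
  list(n = n_i, p = p, h = h, alleles = alleles)
}

# Weir & Cockerham (1984) variance components a, b, c for one allele.
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Weir-Cockerham F_ST for microsatellite genotypes
#'
#' The 1984 theta estimator: per-allele variance components a (among
#' strata), b (among individuals within strata) and c (within individuals)
#' are summed over alleles within a locus and over loci; the multi-locus
#' estimate is the ratio of summed components.  Negative estimates are
#' reported as computed.
#'
#' @param profiles a [dna_profiles].
#' @param strata stratum factor, one label per individual.
#' @return a `wc_fst` object: `theta` (multi-locus), `per_locus` data
#'   frame, summed `components`, and `n_loci_used`.
#' @export
weir_cockerham_fst <- function(profiles, strata) {
  g <- genotype_matrix(profiles)
  ln <- loci(profiles)
  strata <- factor(strata)
  if (nlevels(droplevels(strata)) < 2) stop("need >= 2 strata")
  tot <- c(a = 0, b = 0, c = 0)
  per_locus <- list()
  for (l in seq_along(ln)) {
    a1 <- g[, 2 * l - 1]; a2 <- g[, 2 * l]
    typed <- !is.na(a1)
    sub <- droplevels(factor(strata[typed]))
    if (nlevels(sub) < 2 || any(table(sub) < 2)) next
    ls <- locus_by_stratum(a1, a2, strata)
    if (length(ls$alleles) < 2) {
      per_locus[[ln[l]]] <- c(a = 0, b = 0, c = 0, theta = NA_real_)
      next
    }
    comp <- rowSums(vapply(seq_along(ls$alleles), function(k)
      wc_components(ls$n, ls$p[, k], ls$h[, k]), numeric(3)))
    tot <- tot + comp
    per_locus[[ln[l]]] <- c(comp, theta = unname(comp["a"] / sum(comp)))
  }
  if (!length(per_locus) || sum(tot) == 0)
    return(structure(list(theta = NA_real_, per_locus = NULL,
                          components = tot, n_loci_used = 0L,
                          note = "all usable loci monomorphic"),
                     class = "wc_fst"))
  pl <- as.data.frame(do.call(rbind, per_locus))
  pl$locus <- rownames(pl); rownames(pl) <- NULL
  structure(list(theta = unname(tot["a"] / sum(tot)),
                 per_locus = pl[, c("locus", "a", "b", "c", "theta")],
                 components = tot,
                 n_loci_used = sum(!is.na(pl$theta))),
            class = "wc_fst")
}

#' @export
print.wc_fst <- function(x, ...) {
  cat(sprintf("Weir-Cockerham F_ST: theta = %.5f over %d loci\n",
              x$theta, x$n_loci_used))
  invisible(x)
}

#' Jost's D for microsatellite genotypes
#'
#' Per-locus `D_est` from unbiased within- and total-heterozygosity
#' estimators with harmonic-mean sample-size correction:
#' `Hs_est = 2*ñ/(2*ñ-1) * Hs`, `Ht_est = Ht + Hs_est/(2*ñ*k)`,
#' `D_est = (Ht_est - Hs_est)/(1 - Hs_est) * k/(k-1)`.
#' The multi-locus value is the arithmetic mean of per-locus `D_est`
#' (loci monomorphic over the compared strata contribute 0).  Small
#' negative estimates can occur and are reported as computed.
#'
#' @inheritParams weir_cockerham_fst
#' @return a `josts_d` object: `D` (multi-locus mean), `per_locus`.
#' @export
josts_d <- function(profiles, strata) {
  g <- genotype_matrix(profiles)
  ln <- loci(profiles)
  strata <- factor(strata)
  if (nlevels(droplevels(strata)) < 2) stop("need >= 2 strata")
  d_l <- numeric(0)
  for (l in seq_along(ln)) {
    a1 <- g[, 2 * l - 1]; a2 <- g[, 2 * l]
    typed <- !is.na(a1)
    sub <- droplevels(factor(strata[typed]))
    if (nlevels(sub) < 2) next
    ls <- locus_by_stratum(a1, a2, strata)
    k <- length(ls$n)
    if (length(ls$alleles) < 2) { d_l[ln[l]] <- 0; next }
    n_harm <- k / sum(1 / ls$n)
    hs <- 1 - mean(rowSums(ls$p^2))
    pbar <- colMeans(ls$p)  # unweighted mean frequencies across strata
    ht <- 1 - sum(pbar^2)
    hs_est <- (2 * n_harm / (2 * n_harm - 1)) * hs
    ht_est <- ht + hs_est / (2 * n_harm * k)
    d_l[ln[l]] <- if (hs_est >= 1) NA_real_
                  else ((ht_est - hs_est) / (1 - hs_est)) * (k / (k - 1))
  }
  if (!length(d_l)) stop("no locus typed in >= 2 strata")
  structure(list(D = mean(d_l, na.rm = TRUE),
                 per_locus = data.frame(locus = names(d_l), D_est = unname(d_l),
                                        stringsAsFactors = FALSE)),
            class = "josts_d")
}

#' @export
print.josts_d <- function(x, ...) {
  cat(sprintf("Jost's D = %.5f (mean over %d loci)\n",
              x$D, nrow(x$per_locus)))
  invisible(x)
}
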