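#' Analysis of molecular variance (two-level)
#'
#' Decomposes molecular variance among and within strata from pairwise
#' (squared) distances between individuals' haplotypes, in the Excoffier
#' sum-of-squares framework.  With the identity distance (0 for the same
#' haplotype, 1 otherwise) the resulting Phi_ST equals conventional
#' haplotype-frequency F_ST; with sequence-difference distances it is the
#' distance-weighted Phi_ST.
#'
#' @param haplotypes character vector, one haplotype label per individual.
#' @param strata factor of stratum labels, same length.
#' @param distances optional matrix of pairwise haplotype differences
#'   (treated as squared distances, the convention for difference counts);
#'   `NULL` selects the identity distance.
#' @return an `amova_result`: degrees of freedom, sums of squares, variance
#'   components (`sigma2_among`, `sigma2_within`), and `phi_st`.
#' @export
amova <- function(haplotypes, strata, distances = NULL) {
  strata <- factor(strata)
  keep <- !is.na(haplotypes) & !is.na(strata)
  haplotypes <- haplotypes[keep]; strata <- droplevels(strata[keep])
  n_g <- table(strata)
  if (length(n_g) < 2) stop("need at least 2 strata")
  if (any(n_g == 0)) stop("empty stratum")
  N <- length(haplotypes)
  if (N < 2) stop("need at least 2 individuals in total")
  hl <- unique(haplotypes)
  if (is.null(distances)) {
    d2 <- 1 - diag(length(hl)); dimnames(d2) <- list(hl, hl)
  } else {
    miss <- setdiff(hl, rownames(distances))
    if (length(miss))
      stop("haplotype(s) absent from distance matrix: ",
           paste(miss, collapse = ", "))
    d2 <- distances[hl, hl, drop = FALSE]
  }
  idx <- match(haplotypes, hl)
  D2 <- d2[idx, idx, drop = FALSE]
  ss_total <- sum(D2[upper.tri(D2)]) / N
  ss_within <- 0
  for (g in levels(strata)) {
    in_g <- which(strata == g)
    if (length(in_g) >= 2) {
      Dg <- D2[in_g, in_g, drop = FALSE]
      ss_within <- ss_within + sum(Dg[upper.tri(Dg)]) / length(in_g)
    }
  }
  ss_among <- ss_total - ss_within
  df_among <- length(n_g) - 1
  df_within <- N - length(n_g)
  sigma2_w <- if (df_within > 0) ss_within / df_within else 0
  n_prime <- (N - sum(n_g^2) / N) / df_among
  sigma2_a <- (ss_among / df_among - sigma2_w) / n_prime
  phi <- if (sigma2_a + sigma2_w == 0) NA_real_
         else sigma2_a / (sigma2_a + sigma2_w)
  structure(list(df = c(among = df_among, within = df_within),
                 ss = c(among = ss_among, within = ss_within,
                        total = ss_total),
                 sigma2_among = sigma2_a, sigma2_within = sigma2_w,
                 phi_st = phi, n = N, n_strata = length(n_g),
                 distance = if (is.null(distances)) "identity" else "sequence"),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("AMOVA (%s distances): %d individuals, %d strata\n",
              x$distance, x$n, x$n_strata))
  cat(sprintf("  among-strata  df=%d SS=%.4f  sigma2=%.5f\n",
              x$df["among"], x$ss["among"], x$sigma2_among))
  cat(sprintf("  within-strata df=%d SS=%.4f  sigma2=%.5f\n",
              x$df["within"], x$ss["within"], x$sigma2_within))
  cat(sprintf("  Phi_ST = %.5f\n", x$phi_st))
  invisible(x)
}

#' Pairwise mtDNA differentiation between two strata
#'
#' Runs the two-stratum molecular-variance decomposition twice — with the
#' identity distance (frequency-based F_ST) and with sequence differences
#' (Phi_ST) — and attaches permutation p-values obtained by shuffling
#' individuals between the strata.
#'
#' @param haplotypes haplotype label per individual.
#' @param strata two-level factor.
#' @param distances sequence-difference matrix (for the Phi_ST half); when
#'   `NULL` only the frequency-based statistic is computed.
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @return data frame (class `differentiation_result`) with one row per
#'   statistic: `statistic`, `estimate`, `p_value`, `n_perm`.
#' @export
pairwise_fst_mtdna <- function(haplotypes, strata, distances = NULL,
                               n_perm = 10000, seed = NULL) {
  strata <- droplevels(factor(strata))
  if (nlevels(strata) != 2) stop("exactly two strata required")
  run <- function(d, name) {
    stat_fn <- function(lab) amova(haplotypes, lab, distances = d)$phi_st
    perm <- permutation_pvalue(stat_fn, strata, n_perm = n_perm, seed = seed)
    data.frame(statistic = name, estimate = perm$observed,
               p_value = perm$p_value, n_perm = n_perm,
               stringsAsFactors = FALSE)
  }
  out <- run(NULL, "F_ST")
  if (!is.null(distances)) out <- rbind(out, run(distances, "Phi_ST"))
  class(out) <- c("differentiation_result", "data.frame")
  out
}
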