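#' Pairwise relatedness from multi-locus microsatellite genotypes
#'
#' Method-of-moments estimators suited to loosely related groups:
#'
#' * `"ritland"` — per locus
#'   `r_l = 2/(K-1) * sum_i (x_i - p_i)(y_i - p_i)/p_i`, where `x_i`, `y_i`
#'   are half the allele-i dosages of the two individuals and `p_i` the
#'   reference frequencies; loci are combined weighted by `K_l - 1`.
#' * `"lynch_ritland"` — the regression estimator; with reference alleles
#'   `(a, b)` and proxy dosages `n_a`, `n_b`:
#'   `r = (p_a n_b + p_b n_a - 4 p_a p_b) / ((1 + d_ab)(p_a + p_b) - 4 p_a p_b)`,
#'   loci combined with the reference-specific information weights
#'   `((1 + d_ab)(p_a + p_b) - 4 p_a p_b) / (2 p_a p_b)`, and the two
#'   reference orderings of each pair averaged.
#'
#' Both estimators are unbiased around pedigree relatedness (0 unrelated,
#' 0.25 half-sib, 0.5 parent-offspring / full-sib) and can return negative
#' values for unrelated pairs.
#'
#' @param profiles a [dna_profiles].
#' @param estimator `"ritland"` or `"lynch_ritland"`.
#' @param allele_freqs reference allele frequencies (list per locus of
#'   named vectors); defaults to frequencies observed in `profiles`
#'   (each pair included — the conventional default).
#' @param min_shared_loci pairs typed in common at fewer loci are `NA`.
#' @return a `relatedness_matrix`: symmetric matrix with `NA` diagonal,
#'   attributes `estimator` and `n_shared_loci` (pairwise count matrix).
#' @export
relatedness_estimates <- function(profiles,
                                  estimator = c("ritland", "lynch_ritland"),
                                  allele_freqs = NULL, min_shared_loci = 2) {
  estimator <- match.arg(estimator)
  if (is.null(allele_freqs)) allele_freqs <- observed_allele_freqs(profiles)
  g <- genotype_matrix(profiles)
  ln <- loci(profiles)
  n <- nrow(g)
  if (n < 2) stop("need >= 2 individuals")
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  shared <- matrix(0L, n, n)
  for (l in seq_along(ln)) {
    p <- allele_freqs[[ln[l]]]
    if (is.null(p)) stop("no reference frequencies for locus ", ln[l])
    a1 <- g[, 2 * l - 1]; a2 <- g[, 2 * l]
    typed <- !is.na(a1)
    if (!any(typed)) next
    seen <- unique(c(a1[typed], a2[typed]))
    absent <- setdiff(as.character(seen), names(p))
    if (length(absent))
      stop("allele(s) ", paste(absent, collapse = ", "),
           " at locus ", ln[l], " absent from reference frequencies")
    K <- length(p)
    if (K < 2) next  # monomorphic reference: no information
    # dosage count matrix (0/1/2), zero rows for untyped individuals
    cnt <- matrix(0, n, K, dimnames = list(NULL, names(p)))
    cnt[cbind(which(typed), match(as.character(a1[typed]), names(p)))] <-
      cnt[cbind(which(typed), match(as.character(a1[typed]), names(p)))] + 1
    cnt[cbind(which(typed), match(as.character(a2[typed]), names(p)))] <-
      cnt[cbind(which(typed), match(as.character(a2[typed]), names(p)))] + 1
    mask <- outer(typed, typed, "&")
    shared <- shared + mask
    if (estimator == "ritland") {
      x <- cnt / 2
      z <- sweep(sweep(x, 2, p, "-"), 2, sqrt(p), "/")
      r_l <- (2 / (K - 1)) * tcrossprod(z)
      num <- num + ifelse(mask, (K - 1) * r_l, 0)
      den <- den + (K - 1) * mask
    } else {
      ai <- match(as.character(a1), names(p))
      bi <- match(as.character(a2), names(p))
      pa <- p[ai]; pb <- p[bi]
      d_ab <- as.numeric(a1 == a2)
      denom_x <- (1 + d_ab) * (pa + pb) - 4 * pa * pb
      w_x <- denom_x / (2 * pa * pb)
      usable <- typed & denom_x > 1e-12
      # NUM[x, y] = pa[x]*cnt[y, b[x]] + pb[x]*cnt[y, a[x]] - 4 pa[x] pb[x]
      Cb <- t(cnt[, ifelse(is.na(bi), 1L, bi), drop = FALSE])
      Ca <- t(cnt[, ifelse(is.na(ai), 1L, ai), drop = FALSE])
      NUM <- pa * Cb + pb * Ca - 4 * pa * pb
      r_xy <- NUM / denom_x
      ok <- mask & matrix(usable, n, n)  # rows = reference x
      num <- num + ifelse(ok, w_x * r_xy, 0)
      den <- den + ifelse(ok, w_x, 0)
    }
  }
  r <- num / den
  if (estimator == "lynch_ritland") r <- (r + t(r)) / 2
  r[shared < min_shared_loci] <- NA_real_
  diag(r) <- NA_real_
  dimnames(r) <- list(profiles$sample_id, profiles$sample_id)
  structure(r, estimator = estimator, n_shared_loci = shared,
            class = c("relatedness_matrix", "matrix"))
}

#' Mean relatedness of designated pairs
#'
#' Convenience for pedigree-calibration workflows: looks up the estimates
#' for a set of (id1, id2) pairs in a relatedness matrix.
#'
#' @param r_mat a `relatedness_matrix`.
#' @param pairs data frame with `id1`, `id2` (e.g. from
#'   [simulate_pedigree_pairs()]).
#' @return numeric vector of pairwise estimates, one per row of `pairs`.
#' @export
pair_relatedness <- function(r_mat, pairs) {
  r_mat[cbind(match(pairs$id1, rownames(r_mat)),
              match(pairs$id2, colnames(r_mat)))]
}
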