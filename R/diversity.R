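#' Pairwise sequence-difference matrix for a haplotype set
#'
#' Counts differing sites between every pair of aligned haplotypes; sites
#' with `N` in either sequence are skipped.  In the molecular-variance
#' framework these difference counts play the role of squared distances.
#'
#' @param hapset a [haplotype_set].
#' @return symmetric integer matrix with zero diagonal and an `L`
#'   attribute (alignment length).
#' @export
sequence_distance_matrix <- function(hapset) {
  stopifnot(inherits(hapset, "haplotype_set"))
  L <- attr(hapset, "L")
  chars <- do.call(rbind, strsplit(unclass(hapset), ""))
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(names(hapset), names(hapset)))
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- chars[i, ] != "N" & chars[j, ] != "N"
    d[i, j] <- d[j, i] <- sum(chars[i, ok] != chars[j, ok])
  }
  attr(d, "L") <- L
  d
}

#' Haplotype and nucleotide diversity
#'
#' Unbiased haplotype diversity `h = n (1 - sum p^2) / (n - 1)` and
#' nucleotide diversity `pi` = mean pairwise per-site difference over all
#' sampled sequence pairs (unbiased: pairs of distinct individuals).
#'
#' @param hap_counts named vector of haplotype counts in one stratum
#'   (n = sum >= 2).
#' @param distances pairwise difference matrix from
#'   [sequence_distance_matrix()]; needed for `pi` (its `L` attribute gives
#'   the per-site scaling).  Omit to get `pi = NA`.
#' @return list with `h`, `pi`, `n`.
#' @export
haplotype_and_nucleotide_diversity <- function(hap_counts, distances = NULL) {
  hap_counts <- hap_counts[hap_counts > 0]
  n <- sum(hap_counts)
  if (n < 2) stop("need at least 2 sampled sequences")
  p <- hap_counts / n
  h <- n * (1 - sum(p^2)) / (n - 1)
  pi <- NA_real_
  if (!is.null(distances)) {
    miss <- setdiff(names(hap_counts), rownames(distances))
    if (length(miss))
      stop("haplotype(s) absent from distance matrix: ",
           paste(miss, collapse = ", "))
    L <- attr(distances, "L")
    if (is.null(L)) stop("distance matrix lacks an L attribute")
    d <- distances[names(hap_counts), names(hap_counts), drop = FALSE]
    nn <- outer(as.numeric(hap_counts), as.numeric(hap_counts))
    total <- sum(nn[upper.tri(nn)] * d[upper.tri(d)])  # cross-haplotype pairs
    pi <- total / (n * (n - 1) / 2) / L
  }
  list(h = unname(h), pi = unname(pi), n = n)
}

#' Per-locus diversity summary
#'
#' Observed allele counts, observed heterozygosity and unbiased expected
#' heterozygosity (`He = 2n/(2n-1) * (1 - sum p^2)`) per microsatellite
#' locus, with means over loci.
#'
#' @param profiles a [dna_profiles].
#' @return list with `per_locus` data frame (`locus`, `n_typed`,
#'   `n_alleles`, `Ho`, `He`) and `means`.
#' @export
locus_summary <- function(profiles) {
  g <- genotype_matrix(profiles)
  ln <- loci(profiles)
  rows <- lapply(seq_along(ln), function(l) {
    a1 <- g[, 2 * l - 1]; a2 <- g[, 2 * l]
    typed <- !is.na(a1)
    n <- sum(typed)
    if (n == 0)
      return(data.frame(locus = ln[l], n_typed = 0L, n_alleles = 0L,
                        Ho = NA_real_, He = NA_real_))
    p <- table(c(a1[typed], a2[typed])) / (2 * n)
    ho <- mean(a1[typed] != a2[typed])
    he <- if (length(p) == 1) 0
          else (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    data.frame(locus = ln[l], n_typed = n, n_alleles = length(p),
               Ho = ho, He = he, stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  list(per_locus = per_locus,
       means = c(n_alleles = mean(per_locus$n_alleles),
                 Ho = mean(per_locus$Ho, na.rm = TRUE),
                 He = mean(per_locus$He, na.rm = TRUE)))
}
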