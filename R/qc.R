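#' Per-allele genotyping error rate
#'
#' Rate of single-allele discrepancies among re-amplified internal
#' controls: `n_errors / n_allele_calls`.
#'
#' @param n_allele_calls number of allele amplifications compared (> 0).
#' @param n_errors number of single-allele errors detected.
#' @return list with `rate` (proportion) and `percent`.
#' @examples
#' per_allele_error_rate(2284, 14)  # 0.61%
#' @export
per_allele_error_rate <- function(n_allele_calls, n_errors) {
  if (n_allele_calls <= 0) stop("n_allele_calls must be positive")
  if (n_errors > n_allele_calls || n_errors < 0)
    stop("n_errors must lie in [0, n_allele_calls]")
  rate <- n_errors / n_allele_calls
  list(rate = rate, percent = 100 * rate)
}

#' Probability of identity for unrelated individuals
#'
#' Per-locus `P_ID = sum_i p_i^4 + sum_{i<j} (2 p_i p_j)^2`; the multi-locus
#' value is the product over loci (independence assumption).  This is the
#' probability that two unrelated individuals share an identical multi-locus
#' genotype by chance.
#'
#' @param allele_freqs list of per-locus allele-frequency vectors, each
#'   summing to 1.
#' @param loci_subset optional names/indices restricting the loci used.
#' @return list with `per_locus` vector and `overall` product.
#' @export
probability_of_identity <- function(allele_freqs, loci_subset = NULL) {
  if (!is.null(loci_subset)) allele_freqs <- allele_freqs[loci_subset]
  if (!length(allele_freqs)) stop("empty locus set")
  per_locus <- vapply(allele_freqs, function(p) {
    if (abs(sum(p) - 1) > 1e-9)
      stop("allele frequencies must sum to 1")
    hom <- sum(p^4)
    pp <- outer(p, p)
    het <- sum((2 * pp[upper.tri(pp)])^2)
    hom + het
  }, numeric(1))
  list(per_locus = per_locus, overall = prod(per_locus))
}

# Allele frequencies tabulated from a profile set, per locus.
observed_allele_freqs <- function(profiles) {
  g <- genotype_matrix(profiles)
  ln <- loci(profiles)
  out <- lapply(seq_along(ln), function(l) {
    a <- c(g[, 2 * l - 1], g[, 2 * l])
    tab <- table(a[!is.na(a)])
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  })
  names(out) <- ln
  out
}

#' Find putative duplicate samples by multi-locus genotype matching
#'
#' Compares every pair of profiles at the loci typed in both; pairs with at
#' least `min_shared_loci` comparable loci and at most `max_mismatch`
#' mismatching loci are reported, together with the probability of identity
#' of the matching loci (sample allele frequencies).  Genotypes are
#' compared as unordered allele pairs.
#'
#' @param profiles a [dna_profiles].
#' @param min_shared_loci minimum loci typed in both members (default 8).
#' @param max_mismatch maximum mismatching loci tolerated (default 1;
#'   pairs with > 0 mismatches are reported for review, not auto-merged).
#' @return data frame (class `duplicate_report`) with columns `id1`, `id2`
#'   (sorted so `id1 < id2`, rows ordered by `(id1, id2)`), `loci_compared`,
#'   `loci_matching`, `mismatches`, `p_id`.
#' @export
find_duplicates <- function(profiles, min_shared_loci = 8, max_mismatch = 1) {
  if (min_shared_loci < 1) stop("min_shared_loci must be >= 1")
  g <- genotype_matrix(profiles)
  ln <- loci(profiles)
  freqs <- observed_allele_freqs(profiles)
  n <- nrow(g)
  # canonical sorted genotype per locus for unordered comparison
  lo <- pmin(g[, 2 * seq_along(ln) - 1, drop = FALSE],
             g[, 2 * seq_along(ln), drop = FALSE])
  hi <- pmax(g[, 2 * seq_along(ln) - 1, drop = FALSE],
             g[, 2 * seq_along(ln), drop = FALSE])
  out <- list()
  if (n >= 2) for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- !is.na(lo[i, ]) & !is.na(lo[j, ])
    nc <- sum(both)
    if (nc < min_shared_loci) next
    match_l <- both & lo[i, ] == lo[j, ] & hi[i, ] == hi[j, ]
    nm <- sum(match_l)
    if (nc - nm > max_mismatch) next
    pid <- probability_of_identity(freqs[ln[match_l]])$overall
    ids <- sort(c(rownames(g)[i], rownames(g)[j]))
    out[[length(out) + 1L]] <- data.frame(
      id1 = ids[1], id2 = ids[2], loci_compared = nc, loci_matching = nm,
      mismatches = nc - nm, p_id = pid, stringsAsFactors = FALSE)
  }
  rep <- if (length(out)) do.call(rbind, out)
         else data.frame(id1 = character(), id2 = character(),
                         loci_compared = integer(), loci_matching = integer(),
                         mismatches = integer(), p_id = numeric(),
                         stringsAsFactors = FALSE)
  rep <- rep[order(rep$id1, rep$id2), ]
  rownames(rep) <- NULL
  class(rep) <- c("duplicate_report", "data.frame")
  rep
}

#' Remove duplicate genotypes within strata
#'
#' Retains one copy of each unique genotype per scope stratum (classically
#' per sampling location): within every stratum, duplicate clusters (the
#' connected components of the reported pairs) keep their most completely
#' typed member, ties broken by lexicographic sample ID.  The same genotype
#' appearing in two different strata is retained in both.  Idempotent.
#'
#' @param profiles a [dna_profiles].
#' @param reports a `duplicate_report` from [find_duplicates()] computed on
#'   the same profile set.
#' @param scope stratum level within which duplicates are collapsed.
#' @return the deduplicated [dna_profiles], with removed IDs in the
#'   `removed` attribute.
#' @export
dedupe <- function(profiles, reports,
                   scope = c("location", "habitat", "management_unit")) {
  scope <- match.arg(scope)
  strat <- as.character(assign_strata(profiles, level = scope))
  names(strat) <- profiles$sample_id
  keep_pair <- strat[reports$id1] == strat[reports$id2]
  edges <- reports[keep_pair, c("id1", "id2")]
  # union-find over same-stratum duplicate pairs
  parent <- stats::setNames(profiles$sample_id, profiles$sample_id)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(edges)))
    parent[[find(edges$id1[k])]] <- find(edges$id2[k])
  cluster <- vapply(profiles$sample_id, find, character(1))
  n_typed <- rowSums(!is.na(genotype_matrix(profiles))) / 2
  ord <- order(cluster, -n_typed, profiles$sample_id)
  first <- !duplicated(cluster[ord])
  keep_ids <- profiles$sample_id[ord][first]
  removed <- setdiff(profiles$sample_id, keep_ids)
  out <- profiles[profiles$sample_id %in% keep_ids, , drop = FALSE]
  out <- dna_profiles(as.data.frame(out), loci = loci(profiles))
  attr(out, "removed") <- removed
  out
}

#' Monte-Carlo exact test of Hardy-Weinberg equilibrium at one locus
#'
#' Tests the observed genotype table against the exact conditional
#' distribution given the allele counts, by repeatedly shuffling the
#' observed allele multiset into random diploid pairings (each shuffle is a
#' draw from the exact null).  The p-value is the probability of genotype
#' tables as likely or less likely than the one observed.
#'
#' @param genotypes two-column integer matrix of allele pairs (one row per
#'   individual), or a `dna_profiles` plus `locus` name.
#' @param locus locus name when `genotypes` is a `dna_profiles`.
#' @param n_steps Monte-Carlo shuffles (default 1e5).
#' @param seed RNG seed.
#' @return list with `p_value`, `se` (binomial Monte-Carlo standard
#'   error), `n_steps`.
#' @export
hwe_exact_test <- function(genotypes, locus = NULL, n_steps = 1e5,
                           seed = NULL) {
  if (inherits(genotypes, "dna_profiles")) {
    if (is.null(locus)) stop("supply a locus name")
    g <- genotype_matrix(genotypes)[, paste0(locus, c("_1", "_2"))]
  } else g <- as.matrix(genotypes)
  g <- g[stats::complete.cases(g), , drop = FALSE]
  if (nrow(g) < 1) stop("no typed genotypes")
  alleles <- c(g[, 1], g[, 2])
  if (length(unique(alleles)) == 1L) {
    warning("monomorphic locus: HWE test undefined, p = 1")
    return(list(p_value = 1, se = 0, n_steps = 0L))
  }
  obs_ll <- hwe_table_loglik(g[, 1], g[, 2])
  with_seed(seed, {
    hits <- 0L
    n <- nrow(g)
    for (s in seq_len(n_steps)) {
      perm <- sample(alleles)
      ll <- hwe_table_loglik(perm[seq_len(n)], perm[n + seq_len(n)])
      if (ll <= obs_ll + 1e-9) hits <- hits + 1L
    }
    p <- hits / n_steps
    list(p_value = p, se = sqrt(p * (1 - p) / n_steps), n_steps = n_steps)
  })
}

# Log of the part of the conditional table probability that varies given
# fixed allele counts: h*log(2) - sum(log n_gg!).
hwe_table_loglik <- function(a1, a2) {
  het <- sum(a1 != a2)
  key <- pmin(a1, a2) * 1048576 + pmax(a1, a2)
  het * log(2) - sum(lfactorial(rle(sort.int(key))$lengths))
}
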