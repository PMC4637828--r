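#' Permutation p-value for a stratum-label statistic
#'
#' Shuffles individuals' stratum labels and recomputes the statistic; the
#' p-value uses the add-one rule `p = (#(perm >= obs) + 1) / (n_perm + 1)`,
#' which counts the observed arrangement among the permutations.
#'
#' @param stat_fn function of a label vector returning a scalar statistic
#'   (larger = more differentiated).
#' @param labels stratum labels (factor or vector).
#' @param n_perm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return list with `observed`, `p_value`, `n_perm`, `perm_stats`.
#' @export
permutation_pvalue <- function(stat_fn, labels, n_perm = 10000, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- stat_fn(labels)
  with_seed(seed, {
    perm_stats <- vapply(seq_len(n_perm),
                         function(i) stat_fn(sample(labels)), numeric(1))
    if (all(is.na(perm_stats)) || isTRUE(all(perm_stats == obs)))
      return(list(observed = obs, p_value = 1, n_perm = n_perm,
                  perm_stats = perm_stats))
    p <- (sum(perm_stats >= obs - 1e-12, na.rm = TRUE) + 1) / (n_perm + 1)
    list(observed = obs, p_value = p, n_perm = n_perm,
         perm_stats = perm_stats)
  })
}

#' Markov-chain exact test of population differentiation
#'
#' Raymond-Rousset-style exact test on an alleles-or-haplotypes x strata
#' contingency table.  A Metropolis chain walks the space of tables with
#' the observed margins (elementary 2x2 corner moves, acceptance by the
#' hypergeometric probability ratio); after dememorization, the p-value is
#' the fraction of visited tables whose conditional probability is no
#' larger than the observed table's.
#'
#' @param counts contingency table (matrix) of nonnegative integer counts.
#' @param n_steps chain steps counted toward the p-value (default 1e5).
#' @param n_dememorization burn-in steps (default 1e4).
#' @param seed RNG seed.
#' @return list with `p_value`, `se` (batch-means Monte-Carlo standard
#'   error), `n_steps`.
#' @export
exact_g_test_mcmc <- function(counts, n_steps = 1e5, n_dememorization = 1e4,
                              seed = NULL) {
  x <- as.matrix(counts)
  if (any(x < 0) || any(x != round(x))) stop("counts must be nonnegative integers")
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) {
    warning("degenerate margins: p = 1")
    return(list(p_value = 1, se = 0, n_steps = 0L))
  }
  obs_ll <- -sum(lfactorial(x))
  with_seed(seed, {
    cur <- x
    cur_ll <- obs_ll
    nr <- nrow(x); nc <- ncol(x)
    step <- function() {
      i <- sample.int(nr, 2); j <- sample.int(nc, 2)
      a <- cur[i[1], j[1]]; b <- cur[i[2], j[2]]
      if (a == 0 || b == 0) return(FALSE)
      c_ <- cur[i[1], j[2]]; d <- cur[i[2], j[1]]
      ratio <- (a * b) / ((c_ + 1) * (d + 1))
      if (ratio >= 1 || stats::runif(1) < ratio) {
        cur[i[1], j[1]] <<- a - 1L; cur[i[2], j[2]] <<- b - 1L
        cur[i[1], j[2]] <<- c_ + 1L; cur[i[2], j[1]] <<- d + 1L
        cur_ll <<- cur_ll + log(ratio)
        return(TRUE)
      }
      FALSE
    }
    for (s in seq_len(n_dememorization)) step()
    hits <- logical(n_steps)
    for (s in seq_len(n_steps)) {
      step()
      hits[s] <- cur_ll <= obs_ll + 1e-9
    }
    p <- mean(hits)
    n_batch <- 20L
    bm <- colMeans(matrix(hits[seq_len(n_steps %/% n_batch * n_batch)],
                          ncol = n_batch))
    se <- stats::sd(bm) / sqrt(n_batch)
    list(p_value = p, se = se, n_steps = n_steps)
  })
}
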