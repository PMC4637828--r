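# Isotope-genetics association battery: group tests, AIC model weighting,
# the matriline randomization F-ratio test, isotope distances and the
# Mantel test.

#' Kruskal-Wallis rank test of isotope values across groups
#'
#' Thin wrapper around [stats::kruskal.test()] (tie-corrected H, chi-square
#' p) returning the pieces the reporting layer needs.
#'
#' @param values numeric vector (e.g. delta-13C, permil).
#' @param groups group labels (e.g. mtDNA haplotype).
#' @return list with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1, p_value = 1,
                n = length(values)))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, n = length(values))
}

# All candidate factor sets: subsets of mains, optionally extended by every
# combination of two-way interactions among the included mains.
candidate_formulas <- function(factors, include_interactions) {
  cands <- list(character(0))
  subsets <- unlist(lapply(seq_along(factors), function(k)
    utils::combn(factors, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    cands[[length(cands) + 1L]] <- s
    if (include_interactions && length(s) >= 2) {
      ints <- utils::combn(s, 2, FUN = paste, collapse = ":")
      for (k in seq_along(ints)) {
        int_sets <- utils::combn(ints, k, simplify = FALSE)
        for (is_ in int_sets)
          cands[[length(cands) + 1L]] <- c(s, is_)
      }
    }
  }
  cands
}

#' AIC weighting of linear models for an isotope response
#'
#' Fits Gaussian linear models for every subset of the candidate main
#' effects (plus, optionally, every combination of two-way interactions
#' among the included mains, and the intercept-only model), ranks them by
#' AIC, and converts AIC differences into Akaike weights.  The summed
#' weight of all models containing a factor measures that factor's
#' support — the quantity used to ask whether matriline (mtDNA haplotype)
#' drives the carbon-isotope signal.
#'
#' @param data data frame holding the response and factor columns.
#' @param response response column name (e.g. `"d13C"`).
#' @param factors character vector of categorical predictor column names
#'   (classically haplotype, sex, state).
#' @param include_interactions also consider two-way interactions.
#' @param use_aicc small-sample AICc instead of AIC.
#' @return a `model_weight_table`: `table` (model, k, AIC, dAIC, weight,
#'   ordered by AIC) and `factor_support` (summed weight per factor).
#' @export
glm_aic_weights <- function(data, response, factors,
                            include_interactions = TRUE, use_aicc = FALSE) {
  keep <- stats::complete.cases(data[, c(response, factors), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  for (f in factors) data[[f]] <- droplevels(factor(data[[f]]))
  cands <- candidate_formulas(factors, include_interactions)
  rows <- list()
  for (terms in cands) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fml <- stats::as.formula(paste(response, "~", rhs))
    fit <- try(stats::lm(fml, data = data), silent = TRUE)
    if (inherits(fit, "try-error")) next
    k <- length(stats::coef(fit)) + 1  # + residual variance
    if (nrow(data) <= k) { warning("model '", rhs, "' dropped: n <= k"); next }
    if (any(is.na(stats::coef(fit)))) {
      warning("model '", rhs, "' dropped: aliased (singular) design")
      next
    }
    aic <- stats::AIC(fit)
    if (use_aicc) aic <- aic + 2 * k * (k + 1) / (nrow(data) - k - 1)
    rows[[length(rows) + 1L]] <- data.frame(
      model = rhs, k = k, AIC = aic, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab$weight <- exp(-tab$dAIC / 2) / sum(exp(-tab$dAIC / 2))
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  support <- vapply(factors, function(f)
    sum(tab$weight[grepl(paste0("(^| )", f, "($| |:)"),
                         gsub("\\+", " ", tab$model)) |
                   grepl(paste0(":", f, "($| )"),
                         gsub("\\+", " ", tab$model))]),
    numeric(1))
  structure(list(table = tab, factor_support = support,
                 n = nrow(data), response = response),
            class = "model_weight_table")
}

#' @export
print.model_weight_table <- function(x, n = 6, ...) {
  cat(sprintf("Model weighting for %s (n = %d, %d candidate models)\n",
              x$response, x$n, nrow(x$table)))
  print(utils::head(x$table, n), digits = 4)
  cat("Summed Akaike weight per factor:\n")
  print(round(x$factor_support, 4))
  invisible(x)
}

#' Matriline grouping of profiles
#'
#' Builds the group label used by the matriline randomization test:
#' mtDNA haplotype crossed with management unit, restricted to individuals
#' carrying both a haplotype and the requested isotope value.
#'
#' @param profiles a [dna_profiles].
#' @param channel isotope channel that must be present.
#' @return factor of matriline labels, named by sample ID.
#' @export
matriline_grouping <- function(profiles, channel = "d13C") {
  keep <- !is.na(profiles$haplotype) & !is.na(profiles[[channel]]) &
    !is.na(profiles$management_unit)
  p <- profiles[keep, , drop = FALSE]
  stats::setNames(factor(paste(p$haplotype, p$management_unit, sep = "|")),
                  p$sample_id)
}

#' Matriline randomization test (F-ratio)
#'
#' Tests whether individuals of the same matriline have more similar
#' isotope values than individuals of different matrilines.  The observed
#' F-ratio (between- to within-group mean squares) is compared with its
#' distribution over `n_rand` random relabelings; the p-value is the plain
#' proportion of randomized F-values at least as extreme as the observed
#' one (no add-one smoothing, following the original procedure).
#'
#' @param values numeric isotope values.
#' @param grouping group labels (e.g. from [matriline_grouping()]).
#' @param n_rand randomizations (default 10000).
#' @param seed RNG seed.
#' @return list with `F_ratio`, `p_value`, `n_rand`, `df`.
#' @export
matriline_randomization_test <- function(values, grouping, n_rand = 10000,
                                         seed = NULL) {
  keep <- !is.na(values) & !is.na(grouping)
  values <- values[keep]; grouping <- droplevels(factor(grouping[keep]))
  if (nlevels(grouping) < 2) stop("need >= 2 groups")
  if (length(values) < 3) stop("need >= 3 values")
  if (n_rand < 1) stop("n_rand must be >= 1")
  f_obs <- f_ratio(values, grouping)
  with_seed(seed, {
    f_rand <- vapply(seq_len(n_rand),
                     function(i) f_ratio(values, sample(grouping)),
                     numeric(1))
    p <- mean(f_rand >= f_obs - 1e-12)
    list(F_ratio = f_obs, p_value = p, n_rand = n_rand,
         df = c(between = nlevels(grouping) - 1,
                within = length(values) - nlevels(grouping)))
  })
}

# Between- to within-group mean-square ratio; Inf when groups are internally
# constant but differ (Inf >= Inf counts in the randomization comparison).
f_ratio <- function(values, grouping) {
  gm <- mean(values)
  means <- tapply(values, grouping, mean)
  n_g <- tabulate(grouping)
  ssb <- sum(n_g * (means - gm)^2)
  ssw <- sum((values - means[grouping])^2)
  df_b <- nlevels(grouping) - 1
  df_w <- length(values) - nlevels(grouping)
  msb <- ssb / df_b
  msw <- if (df_w > 0) ssw / df_w else 0
  if (msw == 0) return(if (msb == 0) 0 else Inf)
  msb / msw
}

#' Pairwise Euclidean isotope distances
#'
#' @param profiles a [dna_profiles] (or any data frame with the channels).
#' @param channels isotope columns to use; a single channel gives absolute
#'   differences.
#' @return symmetric distance matrix, rows/cols named by sample ID;
#'   individuals missing any requested channel are excluded with a warning.
#' @export
isotope_distance_matrix <- function(profiles, channels = c("d13C", "d15N")) {
  v <- as.data.frame(profiles)[, channels, drop = FALSE]
  keep <- stats::complete.cases(v)
  if (!all(keep))
    warning(sum(!keep), " individual(s) excluded for missing isotope values")
  m <- as.matrix(v[keep, , drop = FALSE])
  rownames(m) <- profiles$sample_id[keep]
  as.matrix(stats::dist(m))
}

#' Convert a relatedness matrix to a dissimilarity
#'
#' Monotone decreasing transform `max(r) - r`, so that higher relatedness
#' maps to smaller distance (for Mantel comparison with isotope distances).
#'
#' @param r_mat symmetric relatedness matrix.
#' @return distance-like matrix with zero diagonal.
#' @export
relatedness_to_distance <- function(r_mat) {
  d <- max(r_mat, na.rm = TRUE) - r_mat
  diag(d) <- 0
  d
}

#' Mantel test of two distance matrices
#'
#' Pearson correlation of the off-diagonal entries, with significance from
#' simultaneous row/column permutation of the second matrix.  The default
#' alternative `"greater"` tests for positive association — with
#' relatedness first passed through [relatedness_to_distance()], this is
#' the one-sided direction "higher relatedness, smaller isotopic distance".
#'
#' @param a,b symmetric matrices over the same individuals (matching
#'   dimnames are aligned; otherwise order is taken as-is).
#' @param n_perm permutations (default 10000).
#' @param seed RNG seed.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return list with `r`, `p_value`, `n_perm`, `n`.
#' @export
mantel_test <- function(a, b, n_perm = 10000, seed = NULL,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.null(rownames(a)) && !is.null(rownames(b))) {
    common <- intersect(rownames(a), rownames(b))
    if (length(common) < 3) stop("fewer than 3 shared individuals")
    a <- a[common, common]; b <- b[common, common]
  }
  if (!all(dim(a) == dim(b))) stop("matrices must have matching dimensions")
  n <- nrow(a)
  lt <- lower.tri(a)
  if (stats::sd(a[lt]) == 0 || stats::sd(b[lt]) == 0) {
    warning("constant matrix: Mantel r undefined")
    return(list(r = NA_real_, p_value = NA_real_, n_perm = 0L, n = n))
  }
  r_obs <- stats::cor(a[lt], b[lt])
  with_seed(seed, {
    r_perm <- vapply(seq_len(n_perm), function(i) {
      o <- sample.int(n)
      stats::cor(a[lt], b[o, o][lt])
    }, numeric(1))
    p <- switch(alternative,
      greater = (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1),
      less = (sum(r_perm <= r_obs + 1e-12) + 1) / (n_perm + 1),
      two.sided = (sum(abs(r_perm) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1))
    list(r = r_obs, p_value = p, n_perm = n_perm, n = n)
  })
}
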