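#' Allele-count indicator matrix for correspondence analysis
#'
#' Encodes each individual as the number of copies (0/1/2) of every allele
#' observed in the sample, concatenated over loci — the classical encoding
#' for factorial correspondence analysis of multi-locus genotypes.  Missing
#' loci contribute zero counts (the row mass absorbs the difference).
#'
#' @param profiles a [dna_profiles].
#' @return numeric matrix, individuals x alleles; column names are
#'   `<locus>.<allele>`.
#' @export
allele_indicator_matrix <- function(profiles) {
  if (!nrow(profiles)) stop("empty profile set")
  g <- genotype_matrix(profiles)
  ln <- loci(profiles)
  blocks <- lapply(seq_along(ln), function(l) {
    a1 <- g[, 2 * l - 1]; a2 <- g[, 2 * l]
    alleles <- sort(unique(c(a1[!is.na(a1)], a2[!is.na(a2)])))
    if (!length(alleles)) return(NULL)
    m <- sapply(alleles, function(a)
      ifelse(is.na(a1), 0, (a1 == a) + (a2 == a)))
    m <- matrix(m, nrow = nrow(g))
    colnames(m) <- paste0(ln[l], ".", alleles)
    m
  })
  out <- do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
  rownames(out) <- profiles$sample_id
  out
}

#' Factorial correspondence analysis of a nonnegative count matrix
#'
#' Chi-square-metric decomposition of the row-profile matrix (classical
#' correspondence analysis): individuals receive principal coordinates on
#' the leading axes, each axis carrying an inertia (eigenvalue) and a
#' percent of total inertia.  Axis signs are fixed by forcing the
#' largest-magnitude row coordinate positive, so results are reproducible.
#'
#' @param m nonnegative matrix with positive grand total (e.g. from
#'   [allele_indicator_matrix()]).
#' @param n_axes number of leading axes to return (truncated to the rank).
#' @return an `fca_result`: `coords` (rows x axes, principal coordinates),
#'   `inertia` (all positive eigenvalues), `percent_inertia`.
#' @export
fca_coordinates <- function(m, n_axes = 2) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("matrix must be nonnegative")
  tot <- sum(m)
  if (tot <= 0) stop("matrix has zero total")
  keep_col <- colSums(m) > 0
  keep_row <- rowSums(m) > 0
  if (!all(keep_row))
    stop("row(s) with zero mass: ",
         paste(rownames(m)[!keep_row], collapse = ", "))
  m <- m[, keep_col, drop = FALSE]
  P <- m / tot
  r <- rowSums(P); c_ <- colSums(P)
  S <- (P - outer(r, c_)) / outer(sqrt(r), sqrt(c_))
  sv <- svd(S)
  pos <- sv$d > max(sv$d, 1e-300) * 1e-10 & sv$d > 1e-12
  d <- sv$d[pos]
  if (!length(d)) {
    warning("table is rank 1: no non-trivial axes")
    return(structure(list(coords = matrix(numeric(0), nrow(m), 0,
                                          dimnames = list(rownames(m), NULL)),
                          inertia = numeric(0),
                          percent_inertia = numeric(0), n_axes = 0L),
                     class = "fca_result"))
  }
  U <- sv$u[, pos, drop = FALSE]
  n_axes <- min(n_axes, length(d))
  coords <- (U * (1 / sqrt(r)))[, seq_len(n_axes), drop = FALSE] *
    rep(d[seq_len(n_axes)], each = nrow(m))
  # deterministic axis orientation
  for (k in seq_len(ncol(coords))) {
    top <- which.max(abs(coords[, k]))
    if (coords[top, k] < 0) coords[, k] <- -coords[, k]
  }
  dimnames(coords) <- list(rownames(m), paste0("Axis", seq_len(n_axes)))
  structure(list(coords = coords, inertia = d^2,
                 percent_inertia = 100 * d^2 / sum(d^2),
                 n_axes = n_axes),
            class = "fca_result")
}

#' @export
print.fca_result <- function(x, ...) {
  cat(sprintf("FCA: %d individuals on %d axes\n", nrow(x$coords), x$n_axes))
  cat("  inertia (%): ",
      paste(sprintf("%.1f", x$percent_inertia[seq_len(x$n_axes)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fca_result <- function(x, groups = NULL, axes = c(1, 2), ...) {
  stopifnot(max(axes) <= ncol(x$coords))
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  plot(x$coords[, axes[1]], x$coords[, axes[2]], col = col, pch = 19,
       xlab = sprintf("Axis %d (%.1f%%)", axes[1], x$percent_inertia[axes[1]]),
       ylab = sprintf("Axis %d (%.1f%%)", axes[2], x$percent_inertia[axes[2]]),
       ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_len(nlevels(factor(groups))), pch = 19)
  invisible(x)
}
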