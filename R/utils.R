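# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  seed = NULL uses (and advances) the global stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Symmetric-capable Dirichlet sampler via gamma draws.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- 1 / k  # numerical underflow guard
  g / rowSums(g)
}

# Column pairs (<locus>_1, <locus>_2) for a set of loci.
locus_cols <- function(loci) as.vector(rbind(paste0(loci, "_1"),
                                             paste0(loci, "_2")))
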