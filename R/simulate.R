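#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulator: an island model of microsatellite
#' and mtDNA differentiation among wintering regions, matriline-structured
#' carbon isotope values, pedigree pairs of known relatedness, and injected
#' genotyping artifacts.  Defaults describe a moderately differentiated
#' three-region system typed at 17 microsatellite loci, with per-allele
#' error and duplicate-sample rates of the magnitude seen in long-term
#' biopsy programmes.
#'
#' @param n_regions number of wintering regions (demes).
#' @param n_per_region individuals sampled per region.
#' @param n_loci number of microsatellite loci.
#' @param alleles_per_locus alleles segregating per locus (>= 2).
#' @param target_fst differentiation parameter of the island model, in
#'   `[0, 1)`; the Balding-Nichols draw makes multi-locus F_ST center here.
#' @param n_haplotypes number of mtDNA control-region haplotypes.
#' @param seq_length control-region alignment length L (bp).
#' @param divergence expected pairwise sequence difference between
#'   haplotypes (substitutions).
#' @param d13C_base baseline delta-13C (permil).
#' @param matriline_effect_sd between-matriline spread of delta-13C niche
#'   means (permil).
#' @param isotope_noise_sd within-matriline delta-13C spread (permil).
#' @param d15N_mean,d15N_sd single common delta-15N distribution for all
#'   individuals (no matriline structure, by construction).
#' @param pedigree named counts of simulated pairs:
#'   `parent_offspring`, `full_sib`, `half_sib`, `unrelated`.
#' @param duplicate_count number of resampled (duplicate) profiles to inject.
#' @param duplicate_drop_loci loci dropped (set missing) in each duplicate.
#' @param error_rate per-allele miscall rate for artifact injection.
#' @param seed integer seed; mandatory for any stochastic run.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_regions = 3, n_per_region = 30, n_loci = 17,
                       alleles_per_locus = 10, target_fst = 0.05,
                       n_haplotypes = 10, seq_length = 500, divergence = 5,
                       d13C_base = -18, matriline_effect_sd = 1.2,
                       isotope_noise_sd = 0.5,
                       d15N_mean = 8, d15N_sd = 0.8,
                       pedigree = c(parent_offspring = 100, full_sib = 100,
                                    half_sib = 100, unrelated = 100),
                       duplicate_count = 3, duplicate_drop_loci = 2,
                       error_rate = 14 / 2284, seed = NULL) {
  stopifnot(target_fst >= 0, target_fst < 1,
            error_rate >= 0, error_rate <= 1,
            matriline_effect_sd >= 0, isotope_noise_sd >= 0,
            divergence <= seq_length)
  if (alleles_per_locus < 2) stop("alleles_per_locus must be >= 2")
  cfg <- list(n_regions = n_regions, n_per_region = n_per_region,
              n_loci = n_loci, alleles_per_locus = alleles_per_locus,
              target_fst = target_fst, n_haplotypes = n_haplotypes,
              seq_length = seq_length, divergence = divergence,
              d13C_base = d13C_base,
              matriline_effect_sd = matriline_effect_sd,
              isotope_noise_sd = isotope_noise_sd,
              d15N_mean = d15N_mean, d15N_sd = d15N_sd,
              pedigree = pedigree, duplicate_count = duplicate_count,
              duplicate_drop_loci = duplicate_drop_loci,
              error_rate = error_rate, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

require_seed <- function(cfg) {
  if (is.null(cfg$seed))
    stop("sim_config$seed must be set for stochastic simulation")
  as.integer(cfg$seed)
}

# Balding-Nichols-style regional frequencies: Dirichlet around ancestral p
# with concentration (1 - F)/F, so E[p_r] = p and Var gives F_ST = F.
bn_region_freqs <- function(p, fst, n_regions) {
  if (fst == 0) return(matrix(p, n_regions, length(p), byrow = TRUE))
  rdirichlet(n_regions, p * (1 - fst) / fst)
}

#' Simulate microsatellite + mtDNA profiles under an island model
#'
#' Ancestral allele frequencies per locus are drawn from a flat Dirichlet;
#' each region's frequencies are a Balding-Nichols perturbation with
#' differentiation parameter `target_fst`; genotypes are drawn by
#' within-region random mating.  Regional mtDNA haplotype frequencies use
#' the same Dirichlet perturbation.  Sex is assigned 50/50.
#'
#' @param cfg a [sim_config()] (seed required).
#' @return list with `profiles` (a [dna_profiles]) and `truth` (ancestral
#'   and regional allele/haplotype frequencies, the target F_ST, and an
#'   empty artifact registry).
#' @export
simulate_island_model <- function(cfg) {
  seed <- require_seed(cfg)
  with_seed(seed, {
    k <- cfg$n_regions; n <- cfg$n_per_region
    regions <- paste0("R", seq_len(k))
    loci_names <- sprintf("L%02d", seq_len(cfg$n_loci))
    allele_sizes <- 100L + 2L * (seq_len(cfg$alleles_per_locus) - 1L)
    n_tot <- k * n
    region_of <- rep(regions, each = n)

    geno <- matrix(NA_integer_, n_tot, 2 * cfg$n_loci)
    colnames(geno) <- locus_cols(loci_names)
    allele_freqs <- vector("list", cfg$n_loci); names(allele_freqs) <- loci_names
    ancestral <- vector("list", cfg$n_loci); names(ancestral) <- loci_names
    for (l in seq_len(cfg$n_loci)) {
      p <- drop(rdirichlet(1, rep(1, cfg$alleles_per_locus)))
      pr <- bn_region_freqs(p, cfg$target_fst, k)
      dimnames(pr) <- list(regions, allele_sizes)
      ancestral[[l]] <- stats::setNames(p, allele_sizes)
      allele_freqs[[l]] <- pr
      for (r in seq_len(k)) {
        idx <- which(region_of == regions[r])
        draws <- sample(allele_sizes, 2 * length(idx), replace = TRUE,
                        prob = pr[r, ])
        geno[idx, 2 * l - 1] <- draws[seq_along(idx)]
        geno[idx, 2 * l] <- draws[length(idx) + seq_along(idx)]
      }
    }

    hap_names <- sprintf("H%02d", seq_len(cfg$n_haplotypes))
    hp <- drop(rdirichlet(1, rep(1, cfg$n_haplotypes)))
    hap_freqs <- bn_region_freqs(hp, cfg$target_fst, k)
    dimnames(hap_freqs) <- list(regions, hap_names)
    hap <- character(n_tot)
    for (r in seq_len(k)) {
      idx <- which(region_of == regions[r])
      hap[idx] <- sample(hap_names, length(idx), replace = TRUE,
                         prob = hap_freqs[r, ])
    }

    df <- data.frame(sample_id = sprintf("S%04d", seq_len(n_tot)),
                     location = region_of, habitat = "calving",
                     management_unit = region_of,
                     sex = sample(c("F", "M"), n_tot, replace = TRUE),
                     haplotype = hap, stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(geno))
    profiles <- dna_profiles(df, loci = loci_names)
    truth <- structure(list(target_fst = cfg$target_fst,
                            ancestral_freqs = ancestral,
                            allele_freqs = allele_freqs,
                            hap_freqs = hap_freqs,
                            ancestral_hap_freqs = stats::setNames(hp, hap_names),
                            artifacts = NULL, seed = seed),
                       class = "sim_truth")
    list(profiles = profiles, truth = truth)
  })
}

#' Simulate aligned control-region haplotype sequences
#'
#' Each haplotype receives an independent Poisson number of substitutions
#' (mean `divergence / 2`) sprinkled on a common random ancestral sequence,
#' so the expected pairwise difference between haplotypes is close to
#' `divergence` (slightly below it when two lineages hit the same site).
#'
#' @param cfg a [sim_config()] (seed required).
#' @return a [haplotype_set] of `n_haplotypes` sequences of length
#'   `seq_length`.
#' @export
simulate_haplotype_sequences <- function(cfg) {
  seed <- require_seed(cfg)
  if (cfg$n_haplotypes < 1) stop("n_haplotypes must be >= 1")
  with_seed(seed + 1L, {
    bases <- c("A", "C", "G", "T")
    L <- cfg$seq_length
    anc <- sample(bases, L, replace = TRUE)
    seqs <- character(cfg$n_haplotypes)
    for (i in seq_len(cfg$n_haplotypes)) {
      s <- anc
      n_mut <- stats::rpois(1, cfg$divergence / 2)
      n_mut <- min(n_mut, L)
      if (n_mut > 0) {
        sites <- sample.int(L, n_mut)
        for (j in sites) s[j] <- sample(setdiff(bases, s[j]), 1)
      }
      seqs[i] <- paste(s, collapse = "")
    }
    haplotype_set(stats::setNames(seqs, sprintf("H%02d", seq_len(cfg$n_haplotypes))))
  })
}

#' Simulate matriline-structured stable-isotope profiles
#'
#' Operationalises a matriline as (mtDNA haplotype x management unit).  Each
#' matriline receives a delta-13C niche mean drawn from
#' `Normal(d13C_base, matriline_effect_sd)`; individual delta-13C values add
#' `Normal(0, isotope_noise_sd)` noise.  delta-15N is drawn from one common
#' distribution for every individual, so it carries no matriline signal.
#'
#' @param profiles a [dna_profiles] with haplotypes assigned.
#' @param cfg a [sim_config()] (seed required).
#' @param truth optional `sim_truth` to extend.
#' @return list with `profiles` (isotope columns filled) and `truth`
#'   (matriline niche means added).
#' @export
simulate_matriline_isotopes <- function(profiles, cfg, truth = NULL) {
  seed <- require_seed(cfg)
  if (anyNA(profiles$haplotype)) stop("all profiles must carry a haplotype")
  with_seed(seed + 2L, {
    matriline <- paste(profiles$haplotype, profiles$management_unit, sep = "|")
    groups <- unique(matriline)
    niche <- stats::setNames(
      stats::rnorm(length(groups), cfg$d13C_base, cfg$matriline_effect_sd),
      groups)
    profiles$d13C <- niche[matriline] +
      stats::rnorm(nrow(profiles), 0, cfg$isotope_noise_sd)
    profiles$d15N <- stats::rnorm(nrow(profiles), cfg$d15N_mean, cfg$d15N_sd)
    if (is.null(truth))
      truth <- structure(list(artifacts = NULL, seed = seed),
                         class = "sim_truth")
    truth$matriline_niche_d13C <- niche
    list(profiles = profiles, truth = truth)
  })
}

# Draw one diploid genotype (2-col matrix row per locus) from allele freqs.
draw_founder <- function(freqs) {
  vapply(freqs, function(p)
    sample(as.integer(names(p)), 2, replace = TRUE, prob = p), integer(2))
}

mendel_child <- function(g1, g2) {
  rbind(g1[cbind(sample(1:2, ncol(g1), replace = TRUE), seq_len(ncol(g1)))],
        g2[cbind(sample(1:2, ncol(g2), replace = TRUE), seq_len(ncol(g2)))])
}

#' Simulate genotype pairs of known pedigree relatedness
#'
#' Builds parent-offspring (r = 0.5), full-sib (r = 0.5), half-sib
#' (r = 0.25) and unrelated (r = 0) pairs by Mendelian transmission from
#' founders drawn at the configured allele frequencies.
#'
#' @param cfg a [sim_config()] (seed required); `pedigree` gives pair counts.
#' @param allele_freqs optional list (per locus) of named founder allele
#'   frequency vectors; defaults to flat-Dirichlet draws as in
#'   [simulate_island_model()] without differentiation.
#' @return list with `profiles` (both members of every pair), `pairs`
#'   (data frame: `id1`, `id2`, `relationship`, `r_true`) and
#'   `allele_freqs` (the founder frequencies used).
#' @export
simulate_pedigree_pairs <- function(cfg, allele_freqs = NULL) {
  seed <- require_seed(cfg)
  with_seed(seed + 3L, {
    loci_names <- sprintf("L%02d", seq_len(cfg$n_loci))
    allele_sizes <- 100L + 2L * (seq_len(cfg$alleles_per_locus) - 1L)
    if (is.null(allele_freqs)) {
      allele_freqs <- lapply(seq_len(cfg$n_loci), function(l)
        stats::setNames(drop(rdirichlet(1, rep(1, cfg$alleles_per_locus))),
                        allele_sizes))
      names(allele_freqs) <- loci_names
    }
    r_of <- c(parent_offspring = 0.5, full_sib = 0.5,
              half_sib = 0.25, unrelated = 0)
    rows <- list(); pairs <- list(); counter <- 0L
    for (rel in names(r_of)) {
      n_pairs <- cfg$pedigree[[rel]]
      if (is.null(n_pairs) || n_pairs == 0) next
      for (i in seq_len(n_pairs)) {
        counter <- counter + 1L
        f1 <- draw_founder(allele_freqs)
        f2 <- draw_founder(allele_freqs)
        pair <- switch(rel,
          parent_offspring = list(f1, mendel_child(f1, f2)),
          full_sib = list(mendel_child(f1, f2), mendel_child(f1, f2)),
          half_sib = {
            f3 <- draw_founder(allele_freqs)
            list(mendel_child(f1, f2), mendel_child(f1, f3))
          },
          unrelated = list(f1, f2))
        ids <- sprintf("P%04d%s", counter, c("a", "b"))
        for (m in 1:2) {
          g <- pair[[m]]
          row <- c(list(sample_id = ids[m], location = "SIM",
                        habitat = "calving", management_unit = "SIM",
                        sex = "unknown", haplotype = NA_character_),
                   stats::setNames(as.list(as.integer(rbind(g[1, ], g[2, ]))),
                                   locus_cols(loci_names)))
          rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                     stringsAsFactors = FALSE)
        }
        pairs[[length(pairs) + 1L]] <- data.frame(
          id1 = ids[1], id2 = ids[2], relationship = rel,
          r_true = unname(r_of[rel]), stringsAsFactors = FALSE)
      }
    }
    list(profiles = dna_profiles(do.call(rbind, rows), loci = loci_names),
         pairs = do.call(rbind, pairs), allele_freqs = allele_freqs)
  })
}

#' Inject genotyping artifacts: duplicate samples and allele miscalls
#'
#' Duplicates are re-sampled copies of existing individuals (optionally
#' with a few loci dropped to mimic partial amplification).  Allele errors
#' replace exactly `round(error_rate * n_calls)` of the non-missing allele
#' calls (sampled without replacement) with a different allele from the
#' same locus's observed allele set, so the realised error rate matches the
#' configured one.  Every change is recorded in a registry.
#'
#' @param profiles a [dna_profiles].
#' @param cfg a [sim_config()] (seed required).
#' @return list with `profiles` (corrupted, duplicates appended) and
#'   `registry` (list: `duplicates` data frame mapping original to
#'   duplicate IDs; `allele_errors` data frame of every miscall;
#'   `n_allele_calls` the number of calls the rate was applied to).
#' @export
inject_qc_artifacts <- function(profiles, cfg) {
  seed <- require_seed(cfg)
  with_seed(seed + 4L, {
    ln <- loci(profiles)
    dup_reg <- NULL
    if (cfg$duplicate_count > 0) {
      take <- sample(nrow(profiles), cfg$duplicate_count)
      dup <- as.data.frame(profiles)[take, , drop = FALSE]
      dup$sample_id <- paste0(dup$sample_id, "_dup")
      for (i in seq_len(nrow(dup))) {
        drop_n <- min(cfg$duplicate_drop_loci, length(ln))
        if (drop_n > 0) {
          dl <- sample(ln, drop_n)
          dup[i, locus_cols(dl)] <- NA_integer_
        }
      }
      dup_reg <- data.frame(original = profiles$sample_id[take],
                            duplicate = dup$sample_id,
                            stringsAsFactors = FALSE)
      profiles <- dna_profiles(rbind(as.data.frame(profiles), dup), loci = ln)
    }
    g <- genotype_matrix(profiles)
    called <- which(!is.na(g))
    n_calls <- length(called)
    n_err <- round(cfg$error_rate * n_calls)
    err_reg <- NULL
    if (n_err > 0) {
      hit <- sample(called, n_err)
      err_reg <- data.frame(sample_id = rownames(g)[(hit - 1) %% nrow(g) + 1],
                            column = colnames(g)[(hit - 1) %/% nrow(g) + 1],
                            old = g[hit], new = NA_integer_,
                            stringsAsFactors = FALSE)
      for (j in seq_along(hit)) {
        col <- (hit[j] - 1) %/% nrow(g) + 1
        l_idx <- (col + 1) %/% 2
        pool <- unique(stats::na.omit(c(g[, 2 * l_idx - 1], g[, 2 * l_idx])))
        alt <- setdiff(pool, g[hit[j]])
        g[hit[j]] <- if (length(alt)) sample(rep(alt, 2), 1)
                     else g[hit[j]] + 2L  # monomorphic locus: shift size
        err_reg$new[j] <- g[hit[j]]
      }
      df <- as.data.frame(profiles)
      df[, colnames(g)] <- g
      profiles <- dna_profiles(df, loci = ln)
    }
    list(profiles = profiles,
         registry = list(duplicates = dup_reg, allele_errors = err_reg,
                         n_allele_calls = n_calls))
  })
}
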