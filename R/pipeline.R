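#' Run the full analysis pipeline
#'
#' Wires the stages — synthetic-data generation (or reading supplied
#' inputs), genotype QC, diversity, differentiation structure, factorial
#' correspondence analysis, the isotope-genetics association battery and
#' the theta-to-abundance Monte Carlo — into one reproducible run that
#' writes machine-readable TSV/JSON reports plus an echo of the effective
#' configuration.  Identical config + seed gives identical outputs.
#'
#' @param config a nested list, or the path of a YAML file with the same
#'   structure.  Recognised entries: `seed` (mandatory), `stages`
#'   (character vector; default all), `simulate` (overrides for
#'   [sim_config()]), `inputs` (`sample_table`, `haplotype_fasta` paths —
#'   used instead of simulation), `qc`, `structure`, `culture`,
#'   `abundance` (stage options; see the pipeline vignette).
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of the files written per stage.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory")
  seed <- as.integer(config$seed)
  stages_all <- c("simulate", "qc", "diversity", "structure", "fca",
                  "culture", "abundance")
  stages <- if (is.null(config$stages)) stages_all
            else match.arg(unlist(config$stages), stages_all, several.ok = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  wpath <- function(f) file.path(outdir, f)
  wtsv <- function(d, f) {
    utils::write.table(d, wpath(f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    wpath(f)
  }
  yaml::write_yaml(config, wpath("config_echo.yaml"))

  # --- inputs: simulate or read -------------------------------------------
  hapset <- NULL; truth <- NULL
  if (!is.null(config$inputs)) {
    profiles <- read_sample_table(config$inputs$sample_table)
    if (!is.null(config$inputs$haplotype_fasta))
      hapset <- read_haplotype_fasta(config$inputs$haplotype_fasta)
  } else {
    cfg <- do.call(sim_config, c(config$simulate, list(seed = seed)))
    sim <- simulate_island_model(cfg)
    hapset <- simulate_haplotype_sequences(cfg)
    iso <- simulate_matriline_isotopes(sim$profiles, cfg, sim$truth)
    profiles <- iso$profiles; truth <- iso$truth
    if ("simulate" %in% stages) {
      out$simulate <- c(
        write_sample_table(profiles, wpath("sample_table.csv")),
        write_haplotype_fasta(hapset, wpath("haplotypes.fasta")))
      jsonlite::write_json(
        list(target_fst = truth$target_fst,
             matriline_niche_d13C = as.list(truth$matriline_niche_d13C),
             seed = seed),
        wpath("sim_truth.json"), auto_unbox = TRUE, digits = NA)
      out$simulate <- c(out$simulate, wpath("sim_truth.json"))
    }
  }
  strata <- assign_strata(profiles, level = "management_unit")

  # --- qc ------------------------------------------------------------------
  if ("qc" %in% stages) {
    qc_opt <- config$qc
    dup <- find_duplicates(profiles,
                           min_shared_loci = qc_opt$min_shared_loci %||% 8,
                           max_mismatch = qc_opt$max_mismatch %||% 1)
    out$qc <- wtsv(as.data.frame(dup), "qc_duplicates.tsv")
    profiles <- dedupe(profiles, dup, scope = "location")
    strata <- assign_strata(profiles, level = "management_unit")
    hwe <- do.call(rbind, lapply(loci(profiles), function(l) {
      res <- suppressWarnings(
        hwe_exact_test(profiles, locus = l,
                       n_steps = qc_opt$hwe_steps %||% 20000,
                       seed = seed + 11L))
      data.frame(locus = l, p_value = res$p_value, se = res$se)
    }))
    out$qc <- c(out$qc, wtsv(hwe, "qc_hwe.tsv"))
  }

  # --- diversity -----------------------------------------------------------
  if ("diversity" %in% stages) {
    dmat <- if (!is.null(hapset)) sequence_distance_matrix(hapset) else NULL
    div <- do.call(rbind, lapply(levels(strata), function(s) {
      hc <- table(profiles$haplotype[strata == s])
      ls <- locus_summary(profiles[strata == s, , drop = FALSE])
      hp <- if (sum(hc) >= 2)
        haplotype_and_nucleotide_diversity(hc, dmat)
      else list(h = NA, pi = NA, n = sum(hc))
      data.frame(stratum = s, n = sum(strata == s), h = hp$h, pi = hp$pi,
                 mean_alleles = ls$means["n_alleles"],
                 Ho = ls$means["Ho"], He = ls$means["He"])
    }))
    out$diversity <- wtsv(div, "diversity.tsv")
  }

  # --- structure -----------------------------------------------------------
  if ("structure" %in% stages) {
    st_opt <- config$structure
    n_perm <- st_opt$n_perm %||% 1000
    lev <- levels(strata)
    dmat <- if (!is.null(hapset)) sequence_distance_matrix(hapset) else NULL
    nstr <- length(lev)
    mt <- matrix(NA_real_, nstr, nstr, dimnames = list(lev, lev))
    ms <- mt
    rows <- list()
    for (i in seq_len(nstr - 1)) for (j in (i + 1):nstr) {
      sel <- strata %in% lev[c(i, j)]
      sub <- droplevels(strata[sel])
      pf <- pairwise_fst_mtdna(profiles$haplotype[sel], sub,
                               distances = dmat, n_perm = n_perm,
                               seed = seed + 13L)
      wc <- weir_cockerham_fst(profiles[sel, , drop = FALSE], sub)
      jd <- josts_d(profiles[sel, , drop = FALSE], sub)
      mt[j, i] <- pf$estimate[pf$statistic == "F_ST"]
      if ("Phi_ST" %in% pf$statistic)
        mt[i, j] <- pf$estimate[pf$statistic == "Phi_ST"]
      ms[j, i] <- wc$theta; ms[i, j] <- jd$D
      rows[[length(rows) + 1L]] <- data.frame(
        stratum1 = lev[i], stratum2 = lev[j],
        mtDNA_FST = mt[j, i], mtDNA_PhiST = mt[i, j],
        usat_WC_FST = wc$theta, usat_JostD = jd$D,
        mtDNA_FST_p = pf$p_value[pf$statistic == "F_ST"])
    }
    out$structure <- c(
      wtsv(cbind(stratum = lev, as.data.frame(ms)),
           "structure_microsat_matrix.tsv"),
      wtsv(cbind(stratum = lev, as.data.frame(mt)),
           "structure_mtdna_matrix.tsv"),
      wtsv(do.call(rbind, rows), "structure_pairwise.tsv"))
  }

  # --- fca -----------------------------------------------------------------
  if ("fca" %in% stages) {
    fc <- fca_coordinates(allele_indicator_matrix(profiles), n_axes = 2)
    out$fca <- wtsv(data.frame(sample_id = rownames(fc$coords), fc$coords,
                               stratum = as.character(strata)),
                    "fca_coordinates.tsv")
  }

  # --- culture -------------------------------------------------------------
  if ("culture" %in% stages) {
    cu_opt <- config$culture
    grp <- matriline_grouping(profiles)
    vals <- stats::setNames(profiles$d13C, profiles$sample_id)[names(grp)]
    kw <- kruskal_wallis(profiles$d13C, profiles$haplotype)
    rand <- matriline_randomization_test(vals, grp,
                                         n_rand = cu_opt$n_rand %||% 1000,
                                         seed = seed + 17L)
    mw <- glm_aic_weights(
      data.frame(d13C = profiles$d13C, haplotype = profiles$haplotype,
                 sex = profiles$sex, state = profiles$location),
      "d13C", c("haplotype", "sex", "state"))
    rmat <- relatedness_estimates(profiles, "ritland")
    iso_d <- isotope_distance_matrix(profiles, channels = "d13C")
    man <- mantel_test(relatedness_to_distance(rmat), iso_d,
                       n_perm = cu_opt$n_perm %||% 1000, seed = seed + 19L)
    jsonlite::write_json(
      list(kruskal_wallis = kw,
           randomization = rand[c("F_ratio", "p_value", "n_rand")],
           mantel_ritland_d13C = man[c("r", "p_value", "n_perm", "n")],
           factor_support = as.list(mw$factor_support)),
      wpath("culture_results.json"), auto_unbox = TRUE, digits = NA)
    out$culture <- c(wpath("culture_results.json"),
                     wtsv(mw$table, "culture_model_weights.tsv"))
  }

  # --- abundance -----------------------------------------------------------
  if ("abundance" %in% stages && !is.null(config$abundance)) {
    ab_opt <- config$abundance
    rows <- lapply(ab_opt$populations, function(p) {
      est <- theta_estimate(p$label, p$theta, p$hpd_low, p$hpd_high,
                            L = p$L %||% 500,
                            mu_site_year = p$mu %||% 2.0e-8)
      res <- theta_to_abundance(est, n_draws = ab_opt$n_draws %||% 2000,
                                seed = seed + 23L)
      data.frame(population = p$label, t(c(
        Nef_mean = res$summary["Nef", "mean"],
        Nef_lo = res$summary["Nef", "lo95"],
        Nef_hi = res$summary["Nef", "hi95"],
        NC_mean = res$summary["NC", "mean"],
        NC_lo = res$summary["NC", "lo95"],
        NC_hi = res$summary["NC", "hi95"])))
    })
    out$abundance <- wtsv(do.call(rbind, rows), "abundance.tsv")
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
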