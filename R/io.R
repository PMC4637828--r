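#' Read a delimited sample table of DNA + isotope profiles
#'
#' The expected layout is a header row with columns `sample_id`, `location`,
#' `habitat`, `management_unit`, `sex`, `haplotype`, `d13C`, `d15N`, followed
#' by paired integer allele columns `<locus>_1`, `<locus>_2`.  Configurable
#' missing-data codes (classically `"0"` for microsatellite alleles) are
#' normalised to a single internal missing state.
#'
#' @param path CSV (or TSV, by extension) file.
#' @param missing_codes character vector of values to treat as missing in
#'   allele, haplotype and isotope columns; `""` and `"NA"` are always
#'   treated as missing.
#' @param sep field separator; guessed from the file extension by default.
#' @return a [dna_profiles] object.
#' @export
read_sample_table <- function(path, missing_codes = c("", "NA"),
                              sep = if (grepl("\\.tsv$", path)) "\t" else ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!nrow(raw)) stop("empty sample table: ", path)
  missing_codes <- union(missing_codes, c("", "NA"))
  loci <- detect_loci(names(raw))
  allele_cols <- as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2")))
  for (col in intersect(c("haplotype", "d13C", "d15N", allele_cols), names(raw)))
    raw[[col]][raw[[col]] %in% missing_codes] <- NA
  for (col in c("d13C", "d15N")) if (col %in% names(raw))
    raw[[col]] <- as.numeric(raw[[col]])
  for (col in allele_cols) {
    val <- suppressWarnings(as.integer(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(val)
    if (any(bad))
      stop("non-integer allele value(s) in column ", col, " (rows ",
           paste(which(bad), collapse = ", "), ")")
    raw[[col]] <- val
  }
  dna_profiles(raw, loci = loci)
}

#' Write a sample table
#'
#' Inverse of [read_sample_table()]: writes the canonical column layout so
#' that `read_sample_table(write_sample_table(x))` round-trips.
#'
#' @param x a `dna_profiles` object.
#' @param path output file; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(x, path) {
  stopifnot(inherits(x, "dna_profiles"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read aligned haplotype sequences from FASTA
#'
#' @param path FASTA file of aligned control-region haplotypes; all records
#'   must have equal length.
#' @return a [haplotype_set].
#' @export
read_haplotype_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("no FASTA records in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L)
    stop("FASTA records differ in length: ",
         paste(sprintf("%s (%d bp)", names(dna)[lens != max(lens)],
                       lens[lens != max(lens)]), collapse = ", "))
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  seqs <- gsub("[^ACGT]", "N", seqs)
  haplotype_set(seqs)
}

#' Write haplotype sequences to FASTA
#'
#' @param hapset a [haplotype_set].
#' @param path output FASTA file.
#' @return `path`, invisibly.
#' @export
write_haplotype_fasta <- function(hapset, path) {
  stopifnot(inherits(hapset, "haplotype_set"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(">", names(hapset), "\n", unclass(hapset)), con, sep = "\n")
  invisible(path)
}

#' Read a stratification scheme from YAML or JSON
#'
#' Expected structure: a top-level `locations` mapping, each entry
#' `location: {habitat: ..., management_unit: ...}`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [strat_scheme].
#' @export
read_strat_scheme <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  if (is.null(cfg$locations)) stop("scheme file lacks a 'locations' mapping")
  locs <- names(cfg$locations)
  strat_scheme(
    location = locs,
    habitat = vapply(cfg$locations, function(e) as.character(e$habitat),
                     character(1)),
    management_unit = vapply(cfg$locations,
                             function(e) as.character(e$management_unit),
                             character(1)))
}
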