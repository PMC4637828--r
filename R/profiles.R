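#' DNA + isotope profile tables
#'
#' A `dna_profiles` object is a data frame with one row per biopsy sample,
#' carrying identity columns (`sample_id`, `location`, `habitat`,
#' `management_unit`, `sex`, `haplotype`), optional stable-isotope columns
#' (`d13C`, `d15N`, in permil) and a pair of integer allele columns
#' `<locus>_1`, `<locus>_2` per microsatellite locus (fragment sizes;
#' unordered within a locus).  A locus is either fully typed (both alleles
#' present) or fully missing (`NA`, `NA`) for a given individual.
#'
#' @param x data frame with the columns described above.
#' @param loci character vector of locus names; defaults to every column
#'   pair `<name>_1`/`<name>_2` found in `x`.
#' @return `x` with class `dna_profiles` and a `loci` attribute.
#' @examples
#' df <- data.frame(sample_id = c("a", "b"), location = "WA",
#'                  habitat = "calving", management_unit = "SWA",
#'                  sex = c("F", "M"), haplotype = c("H1", "H2"),
#'                  d13C = c(-18.2, -19.1), d15N = c(8.1, 7.9),
#'                  L1_1 = c(100L, 102L), L1_2 = c(104L, 102L))
#' p <- dna_profiles(df)
#' loci(p)
#' @export
dna_profiles <- function(x, loci = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (is.null(loci)) loci <- detect_loci(names(x))
  id_cols <- c("sample_id", "location", "habitat", "management_unit",
               "sex", "haplotype")
  missing_cols <- setdiff(c("sample_id", "location"), names(x))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (col in setdiff(id_cols, names(x))) x[[col]] <- NA_character_
  for (col in c("d13C", "d15N")) if (!col %in% names(x)) x[[col]] <- NA_real_
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  bad_hab <- !is.na(x$habitat) & !x$habitat %in% c("calving", "migratory")
  if (any(bad_hab))
    stop("habitat must be 'calving' or 'migratory' (or NA); got: ",
         paste(unique(x$habitat[bad_hab]), collapse = ", "))
  x$sex <- ifelse(is.na(x$sex) | x$sex == "", "unknown", as.character(x$sex))
  bad_sex <- !x$sex %in% c("F", "M", "unknown")
  if (any(bad_sex))
    stop("sex must be 'F', 'M' or 'unknown'; got: ",
         paste(unique(x$sex[bad_sex]), collapse = ", "))
  for (loc in loci) {
    c1 <- paste0(loc, "_1"); c2 <- paste0(loc, "_2")
    if (!all(c(c1, c2) %in% names(x)))
      stop("locus ", loc, " lacks a complete allele column pair")
    x[[c1]] <- as.integer(x[[c1]]); x[[c2]] <- as.integer(x[[c2]])
    half <- xor(is.na(x[[c1]]), is.na(x[[c2]]))
    if (any(half))
      stop("half-typed genotype at locus ", loc, " (rows ",
           paste(which(half), collapse = ", "),
           "): a locus carries exactly 2 alleles or is missing")
  }
  x <- x[, c(id_cols, "d13C", "d15N",
             as.vector(rbind(paste0(loci, "_1"), paste0(loci, "_2"))))]
  structure(x, loci = loci, class = c("dna_profiles", "data.frame"))
}

detect_loci <- function(cols) {
  a1 <- sub("_1$", "", grep("_1$", cols, value = TRUE))
  a2 <- sub("_2$", "", grep("_2$", cols, value = TRUE))
  odd <- c(setdiff(a1, a2), setdiff(a2, a1))
  if (length(odd))
    stop("unpaired allele column(s) for locus/loci: ",
         paste(odd, collapse = ", "))
  a1[a1 %in% a2]
}

#' @rdname dna_profiles
#' @export
loci <- function(x) attr(x, "loci")

#' Extract the genotype matrix
#'
#' @param x a `dna_profiles` object.
#' @return integer matrix, one row per individual, two columns per locus
#'   (`<locus>_1`, `<locus>_2`), rownames = sample IDs.
#' @export
genotype_matrix <- function(x) {
  stopifnot(inherits(x, "dna_profiles"))
  cols <- as.vector(rbind(paste0(loci(x), "_1"), paste0(loci(x), "_2")))
  m <- as.matrix(as.data.frame(x)[, cols, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$sample_id
  m
}

#' Extract isotope profiles
#'
#' @param x a `dna_profiles` object.
#' @param drop_missing drop rows with neither isotope measured.
#' @return data frame with `sample_id`, `d13C`, `d15N`.
#' @export
isotope_profiles <- function(x, drop_missing = TRUE) {
  out <- data.frame(sample_id = x$sample_id, d13C = x$d13C, d15N = x$d15N,
                    stringsAsFactors = FALSE)
  if (drop_missing) out <- out[!(is.na(out$d13C) & is.na(out$d15N)), ]
  rownames(out) <- NULL
  out
}

#' @export
`[.dna_profiles` <- function(x, i, j, ..., drop = FALSE) {
  ln <- attr(x, "loci")
  out <- NextMethod()
  if (is.data.frame(out) && all(locus_cols(ln) %in% names(out))) {
    attr(out, "loci") <- ln
    class(out) <- c("dna_profiles", "data.frame")
  }
  out
}

#' @export
print.dna_profiles <- function(x, ...) {
  cat(sprintf("DNA profiles: %d individuals, %d loci (%s)\n",
              nrow(x), length(loci(x)),
              paste(utils::head(loci(x), 5), collapse = ", ")))
  n_iso <- sum(!is.na(x$d13C) | !is.na(x$d15N))
  cat(sprintf("  haplotyped: %d; with isotope values: %d\n",
              sum(!is.na(x$haplotype)), n_iso))
  invisible(x)
}

#' Aligned mtDNA control-region haplotypes
#'
#' @param sequences named character vector of equal-length, gap-free
#'   A/C/G/T/N sequences (one per haplotype).
#' @return a `haplotype_set`: the sequence vector with an `L` attribute
#'   (alignment length in bp).
#' @examples
#' hs <- haplotype_set(c(H1 = "ACGTA", H2 = "ACGTT"))
#' attr(hs, "L")
#' @export
haplotype_set <- function(sequences) {
  if (!length(sequences)) stop("empty haplotype set")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all haplotypes must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate haplotype names: ",
         paste(unique(names(sequences)[duplicated(names(sequences))]),
               collapse = ", "))
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("haplotype sequences differ in length: ",
         paste(sprintf("%s=%d", names(sequences), lens)[lens != lens[1]],
               collapse = ", "), " vs ", names(sequences)[1], "=", lens[1])
  if (any(grepl("[^ACGTN]", sequences)))
    stop("sequences may contain only A/C/G/T/N")
  structure(sequences, L = unname(lens[1]), class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("Haplotype set: %d haplotypes, alignment length %d bp\n",
              length(x), attr(x, "L")))
  invisible(x)
}

#' Stratification scheme: location -> (habitat, management unit)
#'
#' Encodes how sampling locations pool into habitat classes and management
#' units, e.g. VIC/TAS/NSW/QLD -> SEA and SA/WA -> SWA.
#'
#' @param location,habitat,management_unit parallel character vectors, one
#'   entry per sampling location.
#' @return a `strat_scheme` data frame.
#' @export
strat_scheme <- function(location, habitat, management_unit) {
  if (anyDuplicated(location))
    stop("each location may be mapped once; duplicated: ",
         paste(unique(location[duplicated(location)]), collapse = ", "))
  bad <- !habitat %in% c("calving", "migratory")
  if (any(bad)) stop("habitat must be 'calving' or 'migratory'")
  structure(data.frame(location = as.character(location),
                       habitat = as.character(habitat),
                       management_unit = as.character(management_unit),
                       stringsAsFactors = FALSE),
            class = c("strat_scheme", "data.frame"))
}

#' Partition profiles into strata
#'
#' Groups individuals by sampling location, habitat class or management
#' unit.  The groups are disjoint and cover every profile; sizes are
#' attached as an attribute.
#'
#' @param profiles a `dna_profiles` object.
#' @param level one of `"location"`, `"habitat"`, `"management_unit"`.
#' @param scheme optional `strat_scheme`; when supplied, habitat and
#'   management unit are looked up from the scheme by location (every
#'   location must be mapped), otherwise the profile columns are used.
#' @return factor of stratum labels (one per profile) with a `sizes`
#'   attribute.
#' @export
assign_strata <- function(profiles,
                          level = c("location", "habitat", "management_unit"),
                          scheme = NULL) {
  level <- match.arg(level)
  loc <- profiles$location
  if (!is.null(scheme)) {
    stopifnot(inherits(scheme, "strat_scheme"))
    unmapped <- setdiff(unique(loc), scheme$location)
    if (length(unmapped))
      stop("unmapped location(s): ", paste(unmapped, collapse = ", "))
    idx <- match(loc, scheme$location)
    lab <- switch(level, location = loc,
                  habitat = scheme$habitat[idx],
                  management_unit = scheme$management_unit[idx])
  } else {
    lab <- switch(level, location = loc,
                  habitat = profiles$habitat,
                  management_unit = profiles$management_unit)
    if (anyNA(lab))
      stop("profiles lack ", level, " labels and no scheme was supplied")
  }
  f <- factor(lab)
  attr(f, "sizes") <- table(f)
  f
}
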