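#' Build and validate a tidy genotype table
#'
#' Genotypes are carried in long ("tidy") form: one row per individual x
#' locus with a diploid call code.  The five call codes are `hom1`, `het`,
#' `hom2` (called genotypes), `missing` (insufficient reads) and `nocall`
#' (allele ratio in a dead zone of the calling rule).  `missing` and `nocall`
#' both count as "not called" in every downstream computation.
#'
#' @param x A data frame with columns `individual`, `locus_id`, `call` and
#'   optionally `population` and `sample_type` (`hair`, `swab` or `tissue`).
#' @return A tibble with the validated columns; `population` defaults to
#'   `"pop1"` and `sample_type` to `"tissue"` when absent.
#' @export
#' @examples
#' genotype_tbl(data.frame(
#'   individual = c("i1", "i1"), locus_id = c("L1", "L2"),
#'   call = c("het", "hom1")
#' ))
genotype_tbl <- function(x) {
  x <- as_tibble(x)
  need <- c("individual", "locus_id", "call")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("genotype table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"population" %in% names(x)) x$population <- "pop1"
  if (!"sample_type" %in% names(x)) x$sample_type <- "tissue"
  bad <- setdiff(unique(x$call), GENO_CODES)
  if (length(bad)) {
    abort(paste0("unknown genotype call code(s): ", paste(bad, collapse = ", ")))
  }
  if (any(is.na(x$population) | x$population == "")) {
    abort("population ids must be non-empty")
  }
  if (anyDuplicated(x[, c("individual", "locus_id")])) {
    abort("duplicated individual x locus rows in genotype table")
  }
  x[, c("individual", "population", "sample_type", "locus_id", "call")]
}

#' Convert genotype calls to allele-2 dosage codes
#'
#' `hom1` -> 0, `het` -> 1, `hom2` -> 2; `missing`/`nocall` -> `NA`.
#' This is the numeric dialect used by the CSV export and by variance
#' component computations.
#'
#' @param call Character vector of call codes.
#' @return Integer vector of allele-2 copy numbers.
#' @export
geno_as_dosage <- function(call) {
  unname(c(hom1 = 0L, het = 1L, hom2 = 2L, missing = NA_integer_,
           nocall = NA_integer_)[call])
}

#' @rdname geno_as_dosage
#' @param dosage Integer vector in 0/1/2/NA.
#' @export
dosage_as_geno <- function(dosage) {
  out <- rep("missing", length(dosage))
  out[!is.na(dosage) & dosage == 0] <- "hom1"
  out[!is.na(dosage) & dosage == 1] <- "het"
  out[!is.na(dosage) & dosage == 2] <- "hom2"
  out
}

#' Build and validate a locus definition table
#'
#' One row per biallelic SNP: identifier, scaffold and 1-based position,
#' the two alleles, the allele-specific in-silico probe sequences used for
#' read counting, and (optionally) flanking/amplicon sequence.
#'
#' @param x Data frame with columns `locus_id`, `allele1`, `allele2`,
#'   `probe1`, `probe2`; optional `scaffold`, `position`, `flank`,
#'   `class_label` (`neutral`/`adaptive`).
#' @return Validated tibble.
#' @export
locus_tbl <- function(x) {
  x <- as_tibble(x)
  need <- c("locus_id", "allele1", "allele2", "probe1", "probe2")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("locus table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(x$locus_id)) abort("duplicated locus_id in locus table")
  if (any(x$allele1 == x$allele2)) abort("allele1 and allele2 must differ")
  check_dna(x$probe1, "probe1")
  check_dna(x$probe2, "probe2")
  if ("position" %in% names(x) && any(x$position < 1)) {
    abort("positions are 1-based and must be >= 1")
  }
  x
}
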