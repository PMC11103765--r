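#' Read a genotype matrix from CSV
#'
#' The wide dialect: a header row of locus ids, one row per individual with
#' an `individual` column, calls coded as allele-2 dosage 0/1/2 with `NA`
#' for missing.  Lines starting with `#` are treated as comments.
#'
#' @param path CSV path.
#' @param meta Optional data frame (`individual`, `population`,
#'   `sample_type`) joined onto the result.
#' @return A [genotype_tbl()].
#' @export
read_genotypes_csv <- function(path, meta = NULL) {
  wide <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stopifnot("individual" %in% names(wide))
  long <- wide %>%
    tidyr::pivot_longer(-"individual", names_to = "locus_id",
                        values_to = "dosage") %>%
    mutate(call = dosage_as_geno(.data$dosage)) %>%
    select(-"dosage")
  if (!is.null(meta)) long <- left_join(long, as_tibble(meta), by = "individual")
  genotype_tbl(long)
}

#' Write a genotype table as CSV
#'
#' @param geno Genotype table.
#' @param path Output path.
#' @param codes `"numeric"` writes the wide 0/1/2/NA dosage dialect;
#'   `"symbolic"` writes wide hom1/het/hom2/NA/NC codes.
#' @param header Optional character vector written as `#` comment lines
#'   (parameters, seed, tool version) ahead of the table.
#' @return The path, invisibly.
#' @export
write_genotypes_csv <- function(geno, path, codes = c("numeric", "symbolic"),
                                header = NULL) {
  codes <- match.arg(codes)
  geno <- genotype_tbl(geno)
  wide <- geno %>%
    mutate(value = if (codes == "numeric") {
      as.character(geno_as_dosage(.data$call))
    } else {
      c(hom1 = "hom1", het = "het", hom2 = "hom2", missing = "NA",
        nocall = "NC")[.data$call]
    }) %>%
    select("individual", "locus_id", "value") %>%
    tidyr::pivot_wider(names_from = "locus_id", values_from = "value")
  if (!is.null(header)) {
    writeLines(paste0("# ", header), path)
    readr::write_csv(wide, path, append = TRUE, col_names = TRUE, na = "NA")
  } else {
    readr::write_csv(wide, path, na = "NA")
  }
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Biallelic SNP records only; the GT field is mapped onto call codes with
#' the REF allele as allele 1 (`0/0` -> `hom1`, `0/1` -> `het`,
#' `1/1` -> `hom2`, `./.` -> `missing`).  Positions follow the VCF 1-based
#' convention.
#'
#' @param path VCF path (plain or gzipped).
#' @param meta Optional per-individual metadata joined on.
#' @return List with `genotypes` (a [genotype_tbl()]) and `loci` (tibble
#'   `locus_id`, `scaffold`, `position`, `allele1`, `allele2`).
#' @export
read_genotypes_vcf <- function(path, meta = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    !grepl(",", fix$ALT, fixed = TRUE)
  if (!all(keep)) {
    inform(sprintf("dropping %d non-biallelic-SNP record(s)", sum(!keep)))
  }
  loci <- tibble(
    locus_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                      paste0(fix$CHROM, "_", fix$POS), fix$ID),
    scaffold = fix$CHROM,
    position = as.integer(fix$POS),
    allele1 = fix$REF, allele2 = fix$ALT
  )[keep, ]
  gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  rownames(gt) <- loci$locus_id
  long <- as_tibble(gt, rownames = "locus_id") %>%
    tidyr::pivot_longer(-"locus_id", names_to = "individual",
                        values_to = "gt") %>%
    mutate(gt = gsub("|", "/", .data$gt, fixed = TRUE),
           call = dplyr::case_when(
             is.na(.data$gt) | .data$gt == "./." ~ "missing",
             .data$gt == "0/0" ~ "hom1",
             .data$gt %in% c("0/1", "1/0") ~ "het",
             .data$gt == "1/1" ~ "hom2",
             TRUE ~ "missing"
           )) %>%
    select("individual", "locus_id", "call")
  if (!is.null(meta)) long <- left_join(long, as_tibble(meta), by = "individual")
  list(genotypes = genotype_tbl(long), loci = loci)
}

#' Read a locus/probe table from CSV
#'
#' Columns `locus_id`, `allele1`, `allele2`, `probe1`, `probe2` and any
#' extras (`scaffold`, `position`, `flank`, ...).
#'
#' @param path CSV path.
#' @return A [locus_tbl()].
#' @export
read_loci_csv <- function(path) {
  locus_tbl(readr::read_csv(path, comment = "#", show_col_types = FALSE))
}

#' Read a population map
#'
#' CSV with columns `individual`, `population` and optionally
#' `sample_type`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_popmap_csv <- function(path) {
  pm <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("individual", "population") %in% names(pm)))
  pm
}

#' Write amplicon sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  check_dna(unname(seqs))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
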