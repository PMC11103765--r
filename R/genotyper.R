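#' Allele-ratio calling thresholds
#'
#' The published allele-ratio rule: loci with fewer than 10 reads are not
#' genotyped; otherwise the ratio `r = n1/n2` calls `hom1` when `r > 10`,
#' `hom2` when `r < 0.1`, and `het` when `0.2 <= r <= 5`.  Ratios in the
#' dead zones `(0.1, 0.2)` and `(5, 10]` become `nocall`, a code distinct
#' from depth-based `missing`.
#'
#' @param min_reads Minimum total reads (`n1 + n2`) to attempt a call.
#' @param hom1_ratio Ratios strictly above this call `hom1`.
#' @param hom2_ratio Ratios strictly below this call `hom2`.
#' @param het_lo,het_hi Inclusive heterozygote ratio band.
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(min_reads = 10, hom1_ratio = 10, hom2_ratio = 0.1,
                            het_lo = 0.2, het_hi = 5) {
  if (!(hom2_ratio < het_lo && het_lo <= het_hi && het_hi < hom1_ratio)) {
    abort("thresholds must satisfy hom2_ratio < het_lo <= het_hi < hom1_ratio")
  }
  structure(list(min_reads = min_reads, hom1_ratio = hom1_ratio,
                 hom2_ratio = hom2_ratio, het_lo = het_lo, het_hi = het_hi),
            class = "call_thresholds")
}

#' Call a genotype from per-allele read counts
#'
#' Vectorized allele-ratio caller.  `n2 = 0` gives an infinite ratio and
#' hence `hom1` when depth allows (and symmetrically `n1 = 0` gives `hom2`).
#'
#' @param n1,n2 Non-negative integer vectors of allele-1 / allele-2 probe
#'   counts.
#' @param th A [call_thresholds()].
#' @return Character vector of call codes.
#' @export
#' @examples
#' call_genotype(c(95, 30, 4), c(5, 10, 4))
call_genotype <- function(n1, n2, th = call_thresholds()) {
  if (any(n1 < 0) || any(n2 < 0)) abort("read counts must be non-negative")
  r <- ifelse(n2 == 0, Inf, n1 / n2)
  out <- rep("nocall", length(n1))
  out[r > th$hom1_ratio] <- "hom1"
  out[r < th$hom2_ratio] <- "hom2"
  out[r >= th$het_lo & r <= th$het_hi] <- "het"
  out[n1 + n2 < th$min_reads] <- "missing"
  out
}

read_fastq_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Count allele-specific probe occurrences in reads
#'
#' For each locus, counts reads containing the allele-1 or allele-2 in-silico
#' probe as an exact forward-strand substring.  A read increments at most one
#' locus-allele counter: loci are scanned in sorted `locus_id` order, probe 1
#' before probe 2, and the first match wins; reads matching probes of more
#' than one locus are reported via a message, since they indicate a panel
#' defect.
#'
#' @param reads Character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTQ file (quality
#'   strings are read but ignored).
#' @param loci Locus table (see [locus_tbl()]) with unique probes.
#' @param individual Optional individual id stamped on the output.
#' @return Tibble with one row per locus: `individual`, `locus_id`, `n1`,
#'   `n2`, `on_target_reads`, `total_reads` (the last two are per-individual
#'   tallies repeated on each row).
#' @export
count_alleles <- function(reads, loci, individual = NA_character_) {
  loci <- locus_tbl(loci)
  loci <- arrange(loci, .data$locus_id)
  probes <- c(rbind(loci$probe1, loci$probe2)) # interleaved: L1.p1, L1.p2, ...
  if (anyDuplicated(probes)) {
    abort("probes are not unique across loci and alleles")
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastq_seqs(reads)
  }
  reads <- as.character(reads)
  total <- length(reads)
  n_probe <- length(probes)
  hit_first <- rep(NA_integer_, total)   # first matching probe per read
  n_loci_hit <- rep(0L, total)
  if (total > 0) {
    rs <- Biostrings::DNAStringSet(reads)
    ## group probes by width: Aho-Corasick dictionaries need constant width
    for (w in unique(nchar(probes))) {
      idx <- which(nchar(probes) == w)
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(probes[idx]))
      mt <- Biostrings::vwhichPDict(pd, rs)
      lens <- lengths(mt)
      if (sum(lens) == 0) next
      read_of <- rep.int(seq_along(mt), lens)
      probe_of <- idx[unlist(mt, use.names = FALSE)]
      ## lowest probe index per read, within this width group
      o <- order(read_of, probe_of)
      first <- o[!duplicated(read_of[o])]
      r1 <- read_of[first]; p1 <- probe_of[first]
      upd <- is.na(hit_first[r1]) | p1 < hit_first[r1]
      hit_first[r1[upd]] <- p1[upd]
      ## distinct loci hit per read (panel-defect diagnostics)
      lp <- unique(cbind(read_of, (probe_of + 1L) %/% 2L))
      n_loci_hit <- n_loci_hit + tabulate(lp[, 1], nbins = total)
    }
  }
  multi <- sum(n_loci_hit > 1)
  if (multi > 0) {
    inform(sprintf(
      "%d read(s) matched probes of more than one locus; assigned to the first locus in sorted order",
      multi))
  }
  counts <- tabulate(hit_first[!is.na(hit_first)], nbins = n_probe)
  on_target <- sum(!is.na(hit_first))
  tibble(
    individual = individual,
    locus_id = loci$locus_id,
    n1 = counts[seq(1, n_probe, by = 2)],
    n2 = counts[seq(2, n_probe, by = 2)],
    on_target_reads = on_target,
    total_reads = total
  )
}

#' Genotype per-individual FASTQ files with the allele-ratio pipeline
#'
#' Convenience wrapper: [count_alleles()] on each FASTQ, then
#' [call_genotype()] on the counts.
#'
#' @param fastq_files Named character vector of FASTQ paths; names are
#'   individual ids.
#' @param loci Locus table.
#' @param th A [call_thresholds()].
#' @param meta Optional data frame with `individual`, `population`,
#'   `sample_type` joined onto the output.
#' @return List with `counts` (per individual x locus) and `genotypes`
#'   (a [genotype_tbl()]).
#' @export
genotype_fastq <- function(fastq_files, loci, th = call_thresholds(),
                           meta = NULL) {
  stopifnot(!is.null(names(fastq_files)))
  counts <- purrr::map_dfr(names(fastq_files), function(id) {
    count_alleles(fastq_files[[id]], loci, individual = id)
  })
  geno <- counts %>%
    mutate(call = call_genotype(.data$n1, .data$n2, th)) %>%
    select("individual", "locus_id", "call")
  if (!is.null(meta)) {
    geno <- left_join(geno, as_tibble(meta), by = "individual")
  }
  list(counts = counts, genotypes = genotype_tbl(geno))
}

#' Filter a genotype table on missingness
#'
#' Loci with no data for `max_locus_missing` (50% by default) or more of the
#' individuals are removed first; individuals missing `max_ind_missing` or
#' more of the surviving loci are removed second.  Both bounds are
#' inclusive, matching the "50% or more" filtering wording.
#'
#' @param geno Genotype table.
#' @param max_locus_missing,max_ind_missing Inclusive missingness bounds.
#' @return Filtered genotype tibble with attributes `"removed_loci"` and
#'   `"removed_individuals"`.
#' @export
filter_matrix <- function(geno, max_locus_missing = 0.5,
                          max_ind_missing = 0.5) {
  geno <- genotype_tbl(geno)
  if (nrow(geno) == 0) abort("empty genotype table")
  loc_miss <- geno %>%
    group_by(.data$locus_id) %>%
    summarise(miss = mean(!is_called(.data$call)), .groups = "drop")
  bad_loci <- loc_miss$locus_id[loc_miss$miss >= max_locus_missing]
  out <- filter(geno, !.data$locus_id %in% bad_loci)
  ind_miss <- out %>%
    group_by(.data$individual) %>%
    summarise(miss = mean(!is_called(.data$call)), .groups = "drop")
  bad_inds <- ind_miss$individual[ind_miss$miss >= max_ind_missing]
  out <- filter(out, !.data$individual %in% bad_inds)
  if (nrow(out) == 0) warn("all loci or individuals removed by missingness filter")
  attr(out, "removed_loci") <- bad_loci
  attr(out, "removed_individuals") <- bad_inds
  out
}

#' Per-individual genotyping success
#'
#' Percentage of loci genotyped (`hom1`/`het`/`hom2`) per individual.
#'
#' @param geno Genotype table with `sample_type` metadata.
#' @return Tibble `individual`, `population`, `sample_type`, `n_loci`,
#'   `pct_genotyped` (0-100).
#' @export
genotyping_success <- function(geno) {
  geno <- genotype_tbl(geno)
  geno %>%
    group_by(.data$individual, .data$population, .data$sample_type) %>%
    summarise(n_loci = n(),
              pct_genotyped = 100 * mean(is_called(.data$call)),
              .groups = "drop")
}

#' Summarise genotyping success by sample type
#'
#' @param success Output of [genotyping_success()].
#' @return Tibble per sample type: `n_individuals`, `mean`, `min`, `max`,
#'   `median` of the per-individual genotyping percentage.
#' @export
success_by_sample_type <- function(success) {
  success %>%
    group_by(.data$sample_type) %>%
    summarise(n_individuals = n(),
              mean = mean(.data$pct_genotyped),
              min = min(.data$pct_genotyped),
              max = max(.data$pct_genotyped),
              median = median(.data$pct_genotyped),
              .groups = "drop")
}
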