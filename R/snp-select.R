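#' Expected heterozygosity of a biallelic locus
#'
#' Gene diversity `2p(1-p)` for a biallelic SNP with allele-1 frequency `p`.
#'
#' @param p Numeric vector of allele frequencies in \[0, 1\].
#' @return Expected heterozygosity in \[0, 0.5\].
#' @export
#' @examples
#' expected_heterozygosity(0.5)
expected_heterozygosity <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1]")
  }
  2 * p * (1 - p)
}

#' Per-locus missingness and allele-frequency summaries
#'
#' For each locus, the fraction of individuals whose call is `missing` or
#' `nocall`, the allele-1 frequency among called genotypes, the resulting
#' expected heterozygosity and the minor allele frequency.
#'
#' @param geno Genotype table (see [genotype_tbl()]).
#' @param loci Optional character vector restricting (and checking) the loci.
#' @return Tibble with columns `locus_id`, `n`, `n_called`, `missingness`,
#'   `p1`, `he`, `maf`.
#' @export
locus_missingness <- function(geno, loci = NULL) {
  geno <- genotype_tbl(geno)
  if (!is.null(loci)) {
    unknown <- setdiff(loci, unique(geno$locus_id))
    if (length(unknown)) {
      abort(paste0("locus id(s) not in genotype table: ",
                   paste(unknown, collapse = ", ")))
    }
    geno <- filter(geno, .data$locus_id %in% loci)
  }
  geno %>%
    group_by(.data$locus_id) %>%
    summarise(
      n = n(),
      n_called = sum(is_called(.data$call)),
      missingness = mean(!is_called(.data$call)),
      p1 = if (n_called[1] > 0) {
        (2 * sum(.data$call == "hom1") + sum(.data$call == "het")) /
          (2 * n_called[1])
      } else NA_real_,
      .groups = "drop"
    ) %>%
    mutate(
      he = ifelse(is.na(.data$p1), NA_real_, 2 * .data$p1 * (1 - .data$p1)),
      maf = pmin(.data$p1, 1 - .data$p1)
    )
}

#' Candidate SNP filter configuration
#'
#' Defaults follow the neutral-candidate selection used for panel design:
#' missingness below 0.4, expected heterozygosity above 0.1, one SNP per
#' scaffold.  The extra knobs (`min_maf`, `min_spacing_bp`, `biallelic_only`)
#' cover the reduced-representation pipeline's filter set (biallelic SNPs,
#' >2% minor allele frequency, >10 kb apart).  All thresholds are strict
#' inequalities.
#'
#' @param max_missing Loci must have missingness strictly below this.
#' @param min_he Loci must have expected heterozygosity strictly above this.
#' @param one_per_scaffold Keep at most one SNP per scaffold (highest He,
#'   ties broken by smallest position).
#' @param min_maf Minor allele frequency must be strictly above this.
#' @param min_spacing_bp A locus fails when any other candidate on the same
#'   scaffold lies within this many base pairs (strictly greater distance
#'   required); 0 disables the rule.
#' @param biallelic_only Drop loci whose definition is not a biallelic SNP.
#' @param min_reads Genotypes backed by this many reads or fewer are treated
#'   as missing before the missingness rule; applied only when a per-genotype
#'   depth table is supplied to [filter_candidates()] (otherwise skipped with
#'   a notice).  0 disables the rule.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_missing = 0.4, min_he = 0.1,
                          one_per_scaffold = TRUE, min_maf = 0,
                          min_spacing_bp = 0, biallelic_only = TRUE,
                          min_reads = 0) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_he >= 0, min_he <= 1,
            min_maf >= 0, min_maf <= 1, min_spacing_bp >= 0, min_reads >= 0)
  structure(list(max_missing = max_missing, min_he = min_he,
                 one_per_scaffold = one_per_scaffold, min_maf = min_maf,
                 min_spacing_bp = min_spacing_bp,
                 biallelic_only = biallelic_only, min_reads = min_reads),
            class = "filter_config")
}

#' Filter candidate SNPs for a panel
#'
#' Applies, in order: missingness, expected heterozygosity, minor allele
#' frequency, within-scaffold spacing, and the one-SNP-per-scaffold rule.
#' Every rejected locus is annotated with the first rule it failed; survivors
#' are returned in deterministic (scaffold, position) order.
#'
#' @param geno Genotype table covering the candidate loci.
#' @param loci Data frame with `locus_id`, `scaffold`, `position` (and
#'   optionally `allele1`/`allele2` for the biallelic check).
#' @param cfg A [filter_config()].
#' @param depth Optional per-genotype read-depth table (`individual`,
#'   `locus_id`, `depth`) enabling the minimum-read-depth rule.
#' @return Tibble with one row per candidate: `locus_id`, `scaffold`,
#'   `position`, `missingness`, `he`, `maf`, `pass`, `reason` (NA when
#'   passing).  Attribute `"survivors"` holds the ordered surviving ids.
#' @export
filter_candidates <- function(geno, loci, cfg = filter_config(),
                              depth = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  if (cfg$min_reads > 0) {
    if (is.null(depth)) {
      inform("min_reads filter skipped: no per-genotype depth table supplied")
    } else {
      geno <- genotype_tbl(geno) %>%
        left_join(as_tibble(depth)[, c("individual", "locus_id", "depth")],
                  by = c("individual", "locus_id")) %>%
        mutate(call = ifelse(!is.na(.data$depth) &
                               .data$depth <= cfg$min_reads,
                             "missing", .data$call)) %>%
        select(-"depth")
    }
  }
  loci <- as_tibble(loci)
  if (!all(c("locus_id", "scaffold", "position") %in% names(loci))) {
    abort("`loci` needs columns locus_id, scaffold, position")
  }
  if (nrow(geno) == 0) {
    warn("empty genotype table: no candidates to filter")
    out <- loci[0, c("locus_id", "scaffold", "position")]
    out$pass <- logical(0); out$reason <- character(0)
    attr(out, "survivors") <- character(0)
    return(out)
  }
  stats <- locus_missingness(geno, loci = loci$locus_id)
  res <- loci %>%
    select("locus_id", "scaffold", "position", any_of(c("allele1", "allele2"))) %>%
    left_join(stats, by = "locus_id") %>%
    arrange(.data$scaffold, .data$position)

  reason <- rep(NA_character_, nrow(res))
  if (cfg$biallelic_only && all(c("allele1", "allele2") %in% names(res))) {
    mono <- res$allele1 == res$allele2 |
      !res$allele1 %in% c("A", "C", "G", "T") |
      !res$allele2 %in% c("A", "C", "G", "T")
    reason[is.na(reason) & mono] <- "NOT_BIALLELIC"
  }
  reason[is.na(reason) & !(res$missingness < cfg$max_missing)] <- "MISSINGNESS"
  reason[is.na(reason) & !(res$he > cfg$min_he)] <- "LOW_HE"
  if (cfg$min_maf > 0) {
    reason[is.na(reason) & !(res$maf > cfg$min_maf)] <- "LOW_MAF"
  }
  if (cfg$min_spacing_bp > 0) {
    ## spacing is judged against every other candidate on the scaffold, so
    ## the rule is independent of the other thresholds (both members of a
    ## too-close pair fail)
    too_close <- res %>%
      group_by(.data$scaffold) %>%
      mutate(.close = vapply(seq_len(n()), function(i) {
        d <- abs(.data$position[-i] - .data$position[i])
        length(d) > 0 && any(d <= cfg$min_spacing_bp)
      }, logical(1))) %>%
      ungroup() %>%
      pull(".close")
    reason[is.na(reason) & too_close] <- "SPACING"
  }
  if (cfg$one_per_scaffold) {
    surv <- which(is.na(reason))
    if (length(surv)) {
      keep <- res[surv, ] %>%
        mutate(.row = surv) %>%
        group_by(.data$scaffold) %>%
        arrange(desc(.data$he), .data$position, .by_group = TRUE) %>%
        slice(1) %>%
        pull(".row")
      reason[setdiff(surv, keep)] <- "SCAFFOLD_DUP"
    }
  }
  res$pass <- is.na(reason)
  res$reason <- reason
  out <- select(res, "locus_id", "scaffold", "position", "missingness",
                "he", "maf", "pass", "reason")
  attr(out, "survivors") <- out$locus_id[out$pass]
  out
}
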