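DISC_CATEGORIES <- c("a_hom_b_het", "a_het_b_hom", "a_hom_b_hom_diff")

classify_mismatch <- function(a, b) {
  dplyr::case_when(
    a == b ~ NA_character_,
    a %in% c("hom1", "hom2") & b == "het" ~ "a_hom_b_het",
    a == "het" & b %in% c("hom1", "hom2") ~ "a_het_b_hom",
    TRUE ~ "a_hom_b_hom_diff"
  )
}

#' Compare two genotype tables cell by cell
#'
#' Restricts both tables to their shared individuals and loci, counts the
#' cells called by both methods, and classifies every discordant cell into
#' one of three categories: method A homozygous / method B heterozygous,
#' A heterozygous / B homozygous, or both homozygous for different alleles.
#' `missing` and `nocall` cells never count as discordant.  For biallelic
#' loci a het/het mismatch is structurally impossible (there is only one
#' heterozygous genotype), which the report asserts.
#'
#' @param a,b Genotype tables sharing allele labelling by locus definition
#'   (allele 1 / allele 2); `a` is conventionally the reference method.
#' @return A `discordance_report` object: list with `per_individual`
#'   (tibble of per-individual counts), `summary` (means across individuals
#'   and the discordance rate), `n_individuals`, `n_loci_compared`.
#' @export
compare_matrices <- function(a, b) {
  a <- genotype_tbl(a); b <- genotype_tbl(b)
  inds <- intersect(unique(a$individual), unique(b$individual))
  loci <- intersect(unique(a$locus_id), unique(b$locus_id))
  if (length(inds) == 0 || length(loci) == 0) {
    abort(paste0(
      "no shared individuals or loci between the two tables\n",
      "  individuals a: ", paste(head(unique(a$individual), 5), collapse = ","),
      " ...  b: ", paste(head(unique(b$individual), 5), collapse = ","), "\n",
      "  loci a: ", paste(head(unique(a$locus_id), 5), collapse = ","),
      " ...  b: ", paste(head(unique(b$locus_id), 5), collapse = ",")))
  }
  cells <- inner_join(
    a %>% filter(.data$individual %in% inds, .data$locus_id %in% loci) %>%
      select("individual", "locus_id", call_a = "call"),
    b %>% filter(.data$individual %in% inds, .data$locus_id %in% loci) %>%
      select("individual", "locus_id", call_b = "call"),
    by = c("individual", "locus_id")
  ) %>%
    mutate(both_called = is_called(.data$call_a) & is_called(.data$call_b),
           category = ifelse(.data$both_called,
                             classify_mismatch(.data$call_a, .data$call_b),
                             NA_character_))
  per_ind <- cells %>%
    group_by(.data$individual) %>%
    summarise(
      n_both = sum(.data$both_called),
      n_discordant = sum(!is.na(.data$category)),
      a_hom_b_het = sum(.data$category == "a_hom_b_het", na.rm = TRUE),
      a_het_b_hom = sum(.data$category == "a_het_b_hom", na.rm = TRUE),
      a_hom_b_hom_diff = sum(.data$category == "a_hom_b_hom_diff",
                             na.rm = TRUE),
      .groups = "drop"
    )
  stopifnot(all(per_ind$n_discordant ==
                  per_ind$a_hom_b_het + per_ind$a_het_b_hom +
                  per_ind$a_hom_b_hom_diff))
  summary <- tibble(
    n_individuals = length(inds),
    n_loci_compared = length(loci),
    mean_both_called = mean(per_ind$n_both),
    mean_discordant = mean(per_ind$n_discordant),
    mean_a_hom_b_het = mean(per_ind$a_hom_b_het),
    mean_a_het_b_hom = mean(per_ind$a_het_b_hom),
    mean_a_hom_b_hom_diff = mean(per_ind$a_hom_b_hom_diff)
  )
  summary$discordance_rate <- if (summary$mean_both_called > 0) {
    summary$mean_discordant / summary$mean_both_called
  } else NA_real_
  structure(list(per_individual = per_ind, summary = summary,
                 n_individuals = length(inds),
                 n_loci_compared = length(loci)),
            class = "discordance_report")
}

#' @export
print.discordance_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Genotype discordance: %d individuals, %d loci\n  mean loci called by both: %.2f\n  mean discordant: %.2f  (rate %.3f)\n",
    s$n_individuals, s$n_loci_compared, s$mean_both_called,
    s$mean_discordant, s$discordance_rate))
  cat(sprintf("  a hom / b het: %.2f   a het / b hom: %.2f   hom / other hom: %.2f\n",
              s$mean_a_hom_b_het, s$mean_a_het_b_hom, s$mean_a_hom_b_hom_diff))
  invisible(x)
}

#' Discordance rate of a comparison
#'
#' The headline rate is the ratio of means: mean discordant loci per
#' individual divided by mean loci called by both methods.  A
#' mean-of-ratios variant (per-individual rates averaged) is available
#' because published per-study rates are not always reproducible from the
#' printed means, suggesting the other aggregation.
#'
#' @param report A `discordance_report` from [compare_matrices()].
#' @param mode `"ratio-of-means"` (default) or `"mean-of-ratios"`.
#' @return Discordance rate as a fraction.
#' @export
discordance_rate <- function(report, mode = c("ratio-of-means",
                                              "mean-of-ratios")) {
  stopifnot(inherits(report, "discordance_report"))
  mode <- match.arg(mode)
  pi <- report$per_individual
  if (mode == "ratio-of-means") {
    if (mean(pi$n_both) == 0) {
      warn("no cells called by both methods; rate undefined")
      return(NA_real_)
    }
    mean(pi$n_discordant) / mean(pi$n_both)
  } else {
    ok <- pi$n_both > 0
    if (!any(ok)) {
      warn("no cells called by both methods; rate undefined")
      return(NA_real_)
    }
    mean(pi$n_discordant[ok] / pi$n_both[ok])
  }
}

#' Discordance rate with mismatch categories excluded
#'
#' Recomputes the rate treating cells of the excluded categories as
#' concordant -- e.g. dropping the hom-vs-het mismatches attributable to
#' allelic dropout in a low-coverage comparison method.
#'
#' @param report A `discordance_report`.
#' @param exclude Character vector of categories among `"a_hom_b_het"`,
#'   `"a_het_b_hom"`, `"a_hom_b_hom_diff"`.
#' @inheritParams discordance_rate
#' @return Recomputed discordance rate (never larger than the original).
#' @export
recompute_excluding <- function(report, exclude,
                                mode = c("ratio-of-means",
                                         "mean-of-ratios")) {
  stopifnot(inherits(report, "discordance_report"))
  mode <- match.arg(mode)
  bad <- setdiff(exclude, DISC_CATEGORIES)
  if (length(bad)) {
    abort(paste0("unknown mismatch category: ", paste(bad, collapse = ", "),
                 "; expected one of ", paste(DISC_CATEGORIES, collapse = ", ")))
  }
  pi <- report$per_individual
  kept <- pi$n_discordant -
    rowSums(as.matrix(pi[, exclude, drop = FALSE]))
  if (mode == "ratio-of-means") {
    mean(kept) / mean(pi$n_both)
  } else {
    ok <- pi$n_both > 0
    mean(kept[ok] / pi$n_both[ok])
  }
}
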