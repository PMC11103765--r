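per_locus_pop_stats <- function(geno) {
  geno %>%
    filter(is_called(.data$call)) %>%
    group_by(.data$population, .data$locus_id) %>%
    summarise(
      n_typed = n(),
      ho = mean(.data$call == "het"),
      p1 = (2 * sum(.data$call == "hom1") + sum(.data$call == "het")) /
        (2 * n()),
      .groups = "drop"
    ) %>%
    mutate(
      ## Nei (1987) sample-size-corrected within-population gene diversity
      hs = ifelse(.data$n_typed > 1,
                  (.data$n_typed / (.data$n_typed - 1)) *
                    (1 - .data$p1^2 - (1 - .data$p1)^2 -
                       .data$ho / (2 * .data$n_typed)),
                  NA_real_)
    )
}

#' Per-population diversity statistics
#'
#' Observed heterozygosity, sample-size-corrected expected heterozygosity
#' (gene diversity, Nei 1987) and the inbreeding coefficient Fis per
#' population.  Populations with fewer than `min_individuals` individuals
#' are excluded, mirroring the >=8-individuals rule used for
#' site-level analyses.  Fis is the ratio-of-sums `1 - sum(Ho)/sum(Hs)` over
#' polymorphic loci (monomorphic loci have `Hs = 0` and drop out of the
#' ratio); `he` in the output is the corrected `Hs`.
#'
#' @param geno Genotype table with population assignments.
#' @param min_individuals Minimum individuals for a population to be
#'   reported (default 8).
#' @param by_locus Return the per-locus table instead of per-population
#'   means.
#' @return Tibble per population: `population`, `n`, `n_loci`, `ho`, `he`,
#'   `fis`; or per population x locus when `by_locus = TRUE`.
#' @export
basic_stats <- function(geno, min_individuals = 8, by_locus = FALSE) {
  geno <- genotype_tbl(geno)
  sizes <- geno %>%
    distinct(.data$individual, .data$population) %>%
    count(.data$population)
  keep <- sizes$population[sizes$n >= min_individuals]
  if (length(keep) == 0) {
    warn(sprintf("no population has >= %d individuals", min_individuals))
    return(tibble(population = character(0), n = integer(0),
                  n_loci = integer(0), ho = numeric(0), he = numeric(0),
                  fis = numeric(0)))
  }
  dropped <- setdiff(sizes$population, keep)
  if (length(dropped)) {
    inform(paste0("excluding population(s) below the individual threshold: ",
                  paste(dropped, collapse = ", ")))
  }
  per_locus <- per_locus_pop_stats(filter(geno, .data$population %in% keep))
  if (by_locus) return(per_locus)
  per_locus %>%
    group_by(.data$population) %>%
    summarise(
      n_loci = n(),
      fis = 1 - sum(.data$ho[.data$hs > 0]) /
        sum(.data$hs[.data$hs > 0]),
      ho = mean(.data$ho),
      he = mean(.data$hs, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    left_join(sizes, by = "population") %>%
    select("population", "n", "n_loci", "ho", "he", "fis")
}

## Weir & Cockerham (1984) variance components per locus for r populations,
## from genotype calls (no inbreeding information, observed het version).
wc_components <- function(geno) {
  dat <- geno %>%
    filter(is_called(.data$call)) %>%
    group_by(.data$locus_id, .data$population) %>%
    summarise(n = n(),
              p = (2 * sum(.data$call == "hom1") + sum(.data$call == "het")) /
                (2 * n()),
              h = mean(.data$call == "het"),
              .groups = "drop")
  dat %>%
    group_by(.data$locus_id) %>%
    filter(n() >= 2, all(.data$n >= 1)) %>%
    summarise(a = {
      r <- n()
      nbar <- mean(.data$n)
      nc <- (r * nbar - sum(.data$n^2) / (r * nbar)) / (r - 1)
      pbar <- sum(.data$n * .data$p) / (r * nbar)
      s2 <- sum(.data$n * (.data$p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(.data$n * .data$h) / (r * nbar)
      (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                       (nbar - 1))
    }, b = {
      r <- n()
      nbar <- mean(.data$n)
      pbar <- sum(.data$n * .data$p) / (r * nbar)
      s2 <- sum(.data$n * (.data$p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(.data$n * .data$h) / (r * nbar)
      (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                               (2 * nbar - 1) / (4 * nbar) * hbar)
    }, cc = {
      r <- n()
      nbar <- mean(.data$n)
      hbar <- sum(.data$n * .data$h) / (r * nbar)
      hbar / 2
    }, .groups = "drop")
}

#' Pairwise Weir-Cockerham Fst
#'
#' Multilocus theta for one or all pairs of populations: variance
#' components are summed over loci before the ratio `a / (a + b + c)`
#' (the recommended multilocus estimator).  Negative estimates are
#' retained; loci with zero total variance are skipped.
#'
#' @param geno Genotype table with population assignments.
#' @param pop_a,pop_b Population ids; when `NULL`, all pairs are computed.
#' @return Tibble `pop_a`, `pop_b`, `n_loci`, `theta`.
#' @export
pairwise_fst <- function(geno, pop_a = NULL, pop_b = NULL) {
  geno <- genotype_tbl(geno)
  pops <- sort(unique(geno$population))
  pairs <- if (is.null(pop_a)) {
    if (length(pops) < 2) abort("need at least two populations")
    utils::combn(pops, 2, simplify = FALSE)
  } else {
    stopifnot(all(c(pop_a, pop_b) %in% pops))
    list(c(pop_a, pop_b))
  }
  purrr::map_dfr(pairs, function(pr) {
    comp <- wc_components(filter(geno, .data$population %in% pr))
    comp <- filter(comp, .data$a + .data$b + .data$cc != 0)
    if (nrow(comp) == 0) {
      warn(sprintf("no usable locus for pair %s-%s; theta undefined",
                   pr[1], pr[2]))
      return(tibble(pop_a = pr[1], pop_b = pr[2], n_loci = 0L,
                    theta = NA_real_))
    }
    tibble(pop_a = pr[1], pop_b = pr[2], n_loci = nrow(comp),
           theta = sum(comp$a) / sum(comp$a + comp$b + comp$cc))
  })
}

#' Bootstrap confidence interval for pairwise Fst
#'
#' Resamples loci with replacement, recomputes the multilocus theta for
#' each replicate, and reports empirical percentiles (2.5% and 97.5% at the
#' default `alpha`), mirroring locus-bootstrap practice for pairwise Fst.
#'
#' @inheritParams pairwise_fst
#' @param n_boot Number of bootstrap replicates (default 999).
#' @param alpha Two-sided confidence level complement (default 0.05).
#' @param seed Optional integer seed for reproducibility.
#' @return A `pairwise_fst_ci` tibble row: `pop_a`, `pop_b`, `n_loci`,
#'   `theta`, `ci_low`, `ci_high`, `n_boot`; attribute `"boot_thetas"`
#'   carries the replicate values.
#' @export
fst_bootstrap_ci <- function(geno, pop_a, pop_b, n_boot = 999, alpha = 0.05,
                             seed = NULL) {
  geno <- genotype_tbl(geno)
  stopifnot(n_boot >= 1)
  comp <- wc_components(filter(geno, .data$population %in% c(pop_a, pop_b)))
  comp <- filter(comp, .data$a + .data$b + .data$cc != 0)
  if (nrow(comp) == 0) abort("no usable locus; theta undefined")
  theta <- sum(comp$a) / sum(comp$a + comp$b + comp$cc)
  if (nrow(comp) < 2) {
    warn("a single usable locus: bootstrap CI undefined")
    out <- tibble(pop_a = pop_a, pop_b = pop_b, n_loci = nrow(comp),
                  theta = theta, ci_low = NA_real_, ci_high = NA_real_,
                  n_boot = 0L)
    class(out) <- c("pairwise_fst_ci", class(out))
    return(out)
  }
  draw <- function() {
    idx <- sample.int(nrow(comp), replace = TRUE)
    sum(comp$a[idx]) / sum(comp$a[idx] + comp$b[idx] + comp$cc[idx])
  }
  thetas <- if (is.null(seed)) {
    replicate(n_boot, draw())
  } else {
    withr::with_seed(seed, replicate(n_boot, draw()))
  }
  qs <- quantile(thetas, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                 na.rm = TRUE)
  out <- tibble(pop_a = pop_a, pop_b = pop_b, n_loci = nrow(comp),
                theta = theta, ci_low = qs[1], ci_high = qs[2],
                n_boot = as.integer(n_boot))
  attr(out, "boot_thetas") <- thetas
  class(out) <- c("pairwise_fst_ci", class(out))
  out
}
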