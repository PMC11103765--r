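## Small in-code fixtures shared across the suite.

# genotype table from a wide character matrix (rows = individuals)
geno_from_matrix <- function(m, population = "pop1", sample_type = "tissue") {
  tibble::as_tibble(m, rownames = "individual") |>
    tidyr::pivot_longer(-individual, names_to = "locus_id",
                        values_to = "call") |>
    dplyr::mutate(population = rep_len(population, dplyr::n()),
                  sample_type = rep_len(sample_type, dplyr::n())) |>
    genotype_tbl()
}

# a genotype table with per-locus given counts of hom1/het/hom2/missing
geno_from_counts <- function(locus_id, hom1, het, hom2, missing = 0,
                             population = "pop1") {
  n <- hom1 + het + hom2 + missing
  tibble::tibble(
    individual = sprintf("i%03d", seq_len(n)),
    population = population,
    locus_id = locus_id,
    call = c(rep("hom1", hom1), rep("het", het), rep("hom2", hom2),
             rep("missing", missing))
  ) |> genotype_tbl()
}

random_geno <- function(n_ind, loci_tbl, miss_prob = 0.1, seed = 1) {
  withr::with_seed(seed, {
    tidyr::expand_grid(individual = sprintf("i%03d", seq_len(n_ind)),
                       locus_id = loci_tbl$locus_id) |>
      dplyr::mutate(call = sample(c("hom1", "het", "hom2", "missing"),
                                  dplyr::n(), replace = TRUE,
                                  prob = c((1 - miss_prob) * c(0.3, 0.4, 0.3),
                                           miss_prob))) |>
      genotype_tbl()
  })
}

random_primer <- function(n = 20, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Independent Weir-Cockerham (1984) theta: plain loops over loci and
# populations, ratio of summed variance components.  Deliberately written
# without reusing any package internals.
oracle_theta <- function(geno) {
  geno <- geno[geno$call %in% c("hom1", "het", "hom2"), ]
  loci <- unique(geno$locus_id)
  pops <- unique(geno$population)
  r <- length(pops)
  A <- B <- C <- 0
  for (l in loci) {
    n <- p <- h <- numeric(r)
    for (k in seq_len(r)) {
      g <- geno[geno$locus_id == l & geno$population == pops[k], ]
      n[k] <- nrow(g)
      if (n[k] == 0) next
      p[k] <- (2 * sum(g$call == "hom1") + sum(g$call == "het")) / (2 * n[k])
      h[k] <- sum(g$call == "het") / n[k]
    }
    if (any(n < 1)) next
    nbar <- mean(n)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc == 0) next
    A <- A + a; B <- B + b; C <- C + cc
  }
  A / (A + B + C)
}

# brute-force survivor enumeration for filter_candidates (independent of the
# package's vectorized path): applies each rule by direct counting
oracle_survivors <- function(geno, loci, cfg) {
  called <- geno[geno$call %in% c("hom1", "het", "hom2"), ]
  ok <- character(0)
  stats <- list()
  for (l in loci$locus_id) {
    g_all <- geno[geno$locus_id == l, ]
    g <- called[called$locus_id == l, ]
    miss <- 1 - nrow(g) / nrow(g_all)
    p <- if (nrow(g)) {
      (2 * sum(g$call == "hom1") + sum(g$call == "het")) / (2 * nrow(g))
    } else NA
    he <- 2 * p * (1 - p)
    maf <- min(p, 1 - p)
    pass <- miss < cfg$max_missing && !is.na(he) && he > cfg$min_he &&
      (cfg$min_maf <= 0 || maf > cfg$min_maf)
    if (cfg$min_spacing_bp > 0 && pass) {
      row <- loci[loci$locus_id == l, ]
      others <- loci[loci$scaffold == row$scaffold & loci$locus_id != l, ]
      if (nrow(others) && any(abs(others$position - row$position) <=
                              cfg$min_spacing_bp)) pass <- FALSE
    }
    if (pass) { ok <- c(ok, l); stats[[l]] <- he }
  }
  if (cfg$one_per_scaffold && length(ok)) {
    keep <- character(0)
    for (s in unique(loci$scaffold[loci$locus_id %in% ok])) {
      cand <- loci[loci$locus_id %in% ok & loci$scaffold == s, ]
      cand$he <- unlist(stats[cand$locus_id])
      cand <- cand[order(-cand$he, cand$position), ]
      keep <- c(keep, cand$locus_id[1])
    }
    ok <- keep
  }
  sort(ok)
}
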