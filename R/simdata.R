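#' Configuration for the synthetic GT-seq study generator
#'
#' Parameterizes an island-model study emulating a panel-validation design:
#' structured diploid populations with a target Fst under the
#' Balding-Nichols model, per-locus amplicon reads with sequencing error and
#' allelic dropout, and sample-type read-depth profiles (hair roughly
#' ultra-low depth, buccal swab moderate, tissue high).
#'
#' Defaults describe the study conditions the package is validated under:
#' four sites of 10 squirrels each at Fst 0.10 (within the 0.067-0.129
#' range typical of the system), 200 biallelic panel loci, Poisson depth
#' with means 2 / 30 / 100 reads for hair / swab / tissue, a 0.001 per-read
#' false-allele rate and 118-base single-end reads.
#'
#' @param n_pops Number of populations.
#' @param fst_target Target Fst in (0, 1) for the Balding-Nichols model.
#' @param n_individuals_per_pop Diploid individuals per population.
#' @param n_loci Number of biallelic loci.
#' @param ancestral_freq Ancestral allele-frequency distribution:
#'   `list(dist = "uniform", lo =, hi =)` or `list(dist = "beta", a =, b =)`.
#' @param depth_profiles Named vector of mean read depths per sample type.
#' @param depth_model `"poisson"` or `"negbin"`.
#' @param negbin_dispersion Size parameter when `depth_model = "negbin"`.
#' @param error_rate Per-read probability of carrying the opposite allele's
#'   probe (false allele).
#' @param dropout Per-allele, per-individual-locus amplification failure
#'   probability for heterozygotes.
#' @param read_length Read length in bases (>= probe length).
#' @param probe_len In-silico probe length (odd; the SNP sits at its center).
#' @param sample_type Sample type assigned to simulated individuals.
#' @param seed Integer seed; mandatory, every stochastic operation derives
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 4, fst_target = 0.10,
                       n_individuals_per_pop = 10, n_loci = 200,
                       ancestral_freq = list(dist = "uniform",
                                             lo = 0.1, hi = 0.9),
                       depth_profiles = c(hair = 2, swab = 30, tissue = 100),
                       depth_model = c("poisson", "negbin"),
                       negbin_dispersion = 5,
                       error_rate = 0.001, dropout = 0,
                       read_length = 118, probe_len = 15,
                       sample_type = "tissue", seed = 1L) {
  depth_model <- match.arg(depth_model)
  stopifnot(is.numeric(seed), length(seed) == 1,
            error_rate >= 0, error_rate <= 1, dropout >= 0, dropout <= 1,
            read_length >= probe_len, probe_len %% 2 == 1,
            sample_type %in% names(depth_profiles))
  if (fst_target <= 0 || fst_target >= 1) {
    abort("fst_target must lie strictly inside (0, 1)")
  }
  structure(list(n_pops = n_pops, fst_target = fst_target,
                 n_individuals_per_pop = n_individuals_per_pop,
                 n_loci = n_loci, ancestral_freq = ancestral_freq,
                 depth_profiles = depth_profiles, depth_model = depth_model,
                 negbin_dispersion = negbin_dispersion,
                 error_rate = error_rate, dropout = dropout,
                 read_length = read_length, probe_len = probe_len,
                 sample_type = sample_type, seed = as.integer(seed)),
            class = "sim_config")
}

draw_ancestral <- function(cfg, n) {
  af <- cfg$ancestral_freq
  switch(af$dist,
         uniform = stats::runif(n, af$lo, af$hi),
         beta = rbeta(n, af$a, af$b),
         abort("ancestral_freq$dist must be 'uniform' or 'beta'"))
}

#' Simulate per-population allele frequencies (Balding-Nichols)
#'
#' Ancestral allele-1 frequencies are drawn from the configured
#' distribution; each population's frequency is then Beta-distributed
#' around the ancestral value with concentration set by the target Fst:
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`.
#'
#' @param cfg A [sim_config()].
#' @return Tibble `locus_id`, `ancestral_p`, `population`, `p` (allele-1
#'   frequency).
#' @export
sim_population_freqs <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    p0 <- draw_ancestral(cfg, cfg$n_loci)
    f <- cfg$fst_target
    tidyr::expand_grid(
      locus_id = sprintf("L%04d", seq_len(cfg$n_loci)),
      population = sprintf("pop%d", seq_len(cfg$n_pops))
    ) %>%
      mutate(ancestral_p = rep(p0, each = cfg$n_pops),
             p = rbeta(n(), .data$ancestral_p * (1 - f) / f,
                       (1 - .data$ancestral_p) * (1 - f) / f)) %>%
      select("locus_id", "ancestral_p", "population", "p")
  })
}

#' Simulate a panel locus table
#'
#' Random flanking sequence per locus with the SNP at a fixed offset, so
#' that in-silico probes (centered on the SNP) match reads exactly in
#' error-free mode.  One locus per scaffold by default.
#'
#' @param cfg A [sim_config()].
#' @param snp_offset 0-based offset of the SNP within the flank (default
#'   places the probe at bases 11..25 of the read).
#' @return A [locus_tbl()] with `flank` (allele-1 version of the amplicon).
#' @export
sim_loci <- function(cfg, snp_offset = 17) {
  stopifnot(inherits(cfg, "sim_config"))
  half <- (cfg$probe_len - 1) / 2
  stopifnot(snp_offset - half >= 0,
            snp_offset + half < cfg$read_length)
  withr::with_seed(cfg$seed + 1L, {
    n <- cfg$n_loci
    bases <- c("A", "C", "G", "T")
    flank <- vapply(seq_len(n), function(i) {
      paste(sample(bases, cfg$read_length, replace = TRUE), collapse = "")
    }, character(1))
    a1 <- substr(flank, snp_offset + 1, snp_offset + 1)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1), character(1),
                 USE.NAMES = FALSE)
    probe_at <- function(fl, allele) {
      p <- substr(fl, snp_offset + 1 - half, snp_offset + 1 + half)
      substr(p, half + 1, half + 1) <- allele
      p
    }
    loci <- tibble(
      locus_id = sprintf("L%04d", seq_len(n)),
      scaffold = sprintf("scaf%04d", seq_len(n)),
      position = sample(1e4:1e6, n, replace = TRUE),
      allele1 = a1, allele2 = a2,
      probe1 = mapply(probe_at, flank, a1, USE.NAMES = FALSE),
      probe2 = mapply(probe_at, flank, a2, USE.NAMES = FALSE),
      flank = flank, snp_offset = snp_offset
    )
    ## regenerate any colliding probes deterministically is overkill at this
    ## scale; collisions across random 15-mers are vanishingly rare, but fail
    ## loudly if they happen
    if (anyDuplicated(c(loci$probe1, loci$probe2))) {
      abort("probe collision in simulated panel; change the seed")
    }
    locus_tbl(loci)
  })
}

#' Simulate truth genotypes under Hardy-Weinberg equilibrium
#'
#' Each individual's allele-1 dosage is Binomial(2, p) with its
#' population's allele frequency.
#'
#' @param freqs Output of [sim_population_freqs()].
#' @param cfg A [sim_config()].
#' @return A [genotype_tbl()] of truth calls with population and
#'   sample-type metadata.
#' @export
sim_genotypes <- function(freqs, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed + 2L, {
    grid <- tidyr::expand_grid(
      population = sprintf("pop%d", seq_len(cfg$n_pops)),
      ind = seq_len(cfg$n_individuals_per_pop)
    ) %>%
      mutate(individual = sprintf("%s_i%03d", .data$population, .data$ind)) %>%
      tidyr::expand_grid(locus_id = sprintf("L%04d", seq_len(cfg$n_loci)))
    grid <- left_join(grid, freqs[, c("locus_id", "population", "p")],
                      by = c("locus_id", "population"))
    dose1 <- rbinom(nrow(grid), 2, grid$p) # copies of allele 1
    grid %>%
      mutate(call = c("hom2", "het", "hom1")[dose1 + 1],
             sample_type = cfg$sample_type) %>%
      select("individual", "population", "sample_type", "locus_id",
             "call") %>%
      genotype_tbl()
  })
}

sim_depth <- function(n, lambda, cfg) {
  if (cfg$depth_model == "poisson") rpois(n, lambda)
  else rnbinom(n, size = cfg$negbin_dispersion, mu = lambda)
}

#' Simulate amplicon reads from truth genotypes
#'
#' Per individual and locus, read depth is drawn from the configured model
#' at the sample type's mean.  Heterozygote reads sample each allele with
#' probability one half, unless that allele has dropped out (amplification
#' failure), in which case every read comes from the surviving allele; with
#' probability `error_rate` a read carries the opposite allele's probe.
#' Reads embed the allele probe in the locus flanking sequence and carry a
#' constant quality string.
#'
#' @param truth Truth genotypes from [sim_genotypes()].
#' @param loci Locus table from [sim_loci()] (must carry `flank` and
#'   `snp_offset`).
#' @param cfg A [sim_config()].
#' @param out_dir When given, one FASTQ file per individual is written
#'   there and paths are returned.
#' @return List with `tallies` (tibble `individual`, `locus_id`, `depth`,
#'   `n1`, `n2` of true allele-probe counts after error), `reads` (named
#'   list of character vectors, present when `out_dir` is `NULL`) and
#'   `fastq_files` (named vector of paths when `out_dir` is given).
#' @export
sim_reads <- function(truth, loci, cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$read_length < max(nchar(loci$probe1))) {
    abort("read_length is shorter than the probe length")
  }
  if (!all(c("flank", "snp_offset") %in% names(loci))) {
    abort("`loci` must carry flank and snp_offset (see sim_loci())")
  }
  truth <- genotype_tbl(truth)
  loci <- arrange(as_tibble(loci), .data$locus_id)
  read_for <- function(fl, off, allele) {
    substr(fl, off + 1, off + 1) <- allele
    fl
  }
  inds <- unique(truth$individual)
  withr::with_seed(cfg$seed + 3L, {
    per_ind <- lapply(inds, function(id) {
      sub <- truth[truth$individual == id, ]
      sub <- left_join(sub, loci, by = "locus_id")
      lambda <- cfg$depth_profiles[[sub$sample_type[1]]]
      depth <- sim_depth(nrow(sub), lambda, cfg)
      n1 <- integer(nrow(sub)); n2 <- integer(nrow(sub))
      reads <- vector("list", nrow(sub))
      for (i in seq_len(nrow(sub))) {
        d <- depth[i]
        if (d == 0) next
        call <- sub$call[i]
        if (call == "het") {
          alive <- c(TRUE, TRUE)
          if (cfg$dropout > 0) {
            alive <- stats::runif(2) >= cfg$dropout
            if (!any(alive)) { depth[i] <- 0L; next }
          }
          from1 <- if (all(alive)) stats::runif(d) < 0.5 else rep(alive[1], d)
        } else {
          from1 <- rep(call == "hom1", d)
        }
        if (cfg$error_rate > 0) {
          flip <- stats::runif(d) < cfg$error_rate
          from1 <- xor(from1, flip)
        }
        n1[i] <- sum(from1); n2[i] <- d - n1[i]
        allele <- ifelse(from1, sub$allele1[i], sub$allele2[i])
        reads[[i]] <- vapply(allele, read_for, character(1),
                             fl = sub$flank[i], off = sub$snp_offset[i],
                             USE.NAMES = FALSE)
      }
      list(tallies = tibble(individual = id, locus_id = sub$locus_id,
                            depth = depth, n1 = n1, n2 = n2),
           reads = unlist(reads) %||% character(0))
    })
  })
  tallies <- purrr::map_dfr(per_ind, "tallies")
  reads <- setNames(lapply(per_ind, `[[`, "reads"), inds)
  if (is.null(out_dir)) {
    return(list(tallies = tallies, reads = reads, fastq_files = NULL))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- setNames(file.path(out_dir, paste0(inds, ".fastq")), inds)
  for (id in inds) {
    write_fastq(reads[[id]], files[[id]], id_prefix = id)
  }
  list(tallies = tallies, reads = NULL, fastq_files = files)
}

write_fastq <- function(seqs, path, id_prefix = "read") {
  n <- length(seqs)
  if (n == 0) {
    file.create(path)
    return(invisible(path))
  }
  qual <- vapply(nchar(seqs), function(l) strrep("I", l), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", id_prefix, "_", seq_len(n), "\n", seqs, "\n+\n",
                    qual), con, sep = "\n")
  invisible(path)
}

#' Emulate a low-coverage genotype caller
#'
#' For every called truth cell, samples `depth` reads: a heterozygote whose
#' reads all come from one chromosome is observed as the corresponding
#' homozygote (allelic dropout by sampling), while homozygotes are never
#' observed as heterozygotes in this error-free mode.  At depth `d` the
#' het-to-hom miscall probability is `2 * 0.5^d`.
#'
#' @param truth Truth genotype table.
#' @param depth Reads sampled per cell (>= 1).
#' @param seed Integer seed.
#' @return A [genotype_tbl()] of low-coverage calls.
#' @export
sim_lowcov_calls <- function(truth, depth, seed = 1L) {
  stopifnot(depth >= 1)
  truth <- genotype_tbl(truth)
  withr::with_seed(seed, {
    k <- rbinom(nrow(truth), depth, 0.5) # reads from chromosome 1
    observed <- truth$call
    het <- observed == "het"
    observed[het & k == depth] <- "hom1"
    observed[het & k == 0] <- "hom2"
    mutate(truth, call = observed)
  })
}

#' Simulate a full synthetic GT-seq study
#'
#' Convenience wrapper chaining [sim_loci()], [sim_population_freqs()],
#' [sim_genotypes()] and [sim_reads()].
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory for FASTQ and CSV artifacts.
#' @return List with `loci`, `freqs`, `truth`, and the [sim_reads()]
#'   output (`tallies`, `reads`/`fastq_files`).
#' @export
sim_gtseq_study <- function(cfg = sim_config(), out_dir = NULL) {
  loci <- sim_loci(cfg)
  freqs <- sim_population_freqs(cfg)
  truth <- sim_genotypes(freqs, cfg)
  rd <- sim_reads(truth, loci, cfg, out_dir = out_dir)
  if (!is.null(out_dir)) {
    readr::write_csv(loci, file.path(out_dir, "loci.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth_genotypes.csv"))
    readr::write_csv(rd$tallies, file.path(out_dir, "truth_tallies.csv"))
    readr::write_csv(distinct(truth, .data$individual, .data$population,
                              .data$sample_type),
                     file.path(out_dir, "popmap.csv"))
  }
  c(list(loci = loci, freqs = freqs, truth = truth, config = cfg), rd)
}
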