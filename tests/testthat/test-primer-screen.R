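## Frozen expected melting temperatures come from an independent
## nearest-neighbor calculation with the unified parameter table at
## 50 mM monovalent salt and C_T/4 = 62.5 nM, computed before the
## implementation was written.

test_that("nearest-neighbor Tm matches the independent oracle to 0.5 C", {
  expect_equal(melting_temperature("AGCTGATCCGTAAGGCTTAC"), 53.536,
               tolerance = 0.5 / 53.536)
  expect_equal(melting_temperature("ACGTGGTCCAGTTCAATCTG"), 54.264,
               tolerance = 0.5 / 54.264)
  ## self-complementary sequences get the symmetry entropy term
  expect_equal(melting_temperature("ATATATATATATATATAT"), 22.1607,
               tolerance = 0.03)
  expect_equal(melting_temperature("GCGCGCGCGCGCGCGCGC"), 75.306,
               tolerance = 0.01)
})

test_that("Tm is reverse-complement symmetric and increases with GC", {
  for (seed in 1:8) {
    n <- sample(18:24, 1)
    s <- random_primer(n, seed = seed)
    expect_equal(melting_temperature(s), melting_temperature(revcomp(s)))
  }
  expect_lt(melting_temperature("ATATATATATATATATAT"),
            melting_temperature("GCGCGCGCGCGCGCGCGC"))
  expect_error(melting_temperature("ACGTN"), "non-ACGT")
  expect_error(melting_temperature("ACGT"), "at least 8")
})

test_that("hairpin detection finds constructed stems and ignores poly-A", {
  hp <- hairpin_tm(paste0("ACGTACGT", strrep("T", 10), revcomp("ACGTACGT")))
  expect_false(is.na(hp))
  expect_true(is.na(hairpin_tm(strrep("A", 18))))
  ## a long GC stem is more stable than a short AT stem (oracle values:
  ## 12-bp GC stem 60.495, 8-bp AT stem -10.652)
  gc_hp <- hairpin_tm(paste0("GCGCGCGCGCGC", "TTTT", revcomp("GCGCGCGCGCGC")))
  at_hp <- hairpin_tm(paste0("ATTAATTA", "CCCC", revcomp("ATTAATTA")))
  expect_gt(gc_hp, at_hp)
  expect_gt(gc_hp, 50)
  expect_lt(at_hp, 0)
})

test_that("hairpin respects the minimum loop length", {
  ## GCAT/ATGC is the only self-complementary stem in this construct, so
  ## the loop length is unambiguous (2 bases)
  s <- paste0("GCAT", "TT", revcomp("GCAT"))
  expect_true(is.na(hairpin_tm(s, min_loop = 3)))
  expect_false(is.na(hairpin_tm(s, min_loop = 2)))
})

test_that("heterodimer Tm is symmetric and hits the full-duplex limit", {
  a <- "ACGTGGTCCAGTTCAATCTG"
  expect_equal(heterodimer_tm(a, revcomp(a)), melting_temperature(a),
               tolerance = 1e-10)
  expect_true(is.na(heterodimer_tm(strrep("A", 20), strrep("A", 20))))
  for (seed in 1:6) {
    x <- random_primer(20, seed = seed)
    y <- random_primer(20, seed = seed + 100)
    expect_equal(heterodimer_tm(x, y), heterodimer_tm(y, x))
  }
})

test_that("heterodimer finds the best window over all offsets", {
  ## brute-force oracle: align a against revcomp(b) at every offset, take
  ## the hottest contiguous complementary run of >= 4 bp
  brute_dimer <- function(a, b) {
    rb <- revcomp(b)
    best <- NA_real_
    for (off in (-(nchar(rb) - 1)):(nchar(a) - 1)) {
      run <- 0
      for (i in seq_len(nchar(a) + nchar(rb))) {
        ia <- i; ib <- i - off
        ok <- ia >= 1 && ia <= nchar(a) && ib >= 1 && ib <= nchar(rb) &&
          substr(a, ia, ia) == substr(rb, ib, ib)
        if (ok) run <- run + 1 else run <- 0
        if (run >= 4) {
          stem <- substr(a, ia - run + 1, ia)
          tm <- melting_temperature(stem, min_len = 1)
          if (is.na(best) || tm > best) best <- tm
        }
      }
    }
    best
  }
  core <- "ACCGGTTACG"
  a <- paste0("GGGGG", core, "GGGGG")
  b <- paste0("AAAAA", revcomp(core), "AAAAA")
  expect_equal(heterodimer_tm(a, b), brute_dimer(a, b))
  for (seed in 1:4) {
    x <- random_primer(18, seed = seed + 40)
    y <- random_primer(21, seed = seed + 80)
    expect_equal(heterodimer_tm(x, y), brute_dimer(x, y))
  }
})

test_that("internal binding sites are found on both strands", {
  primer <- "ACGTGGTCCAGTTCAATCTG"
  seed <- substr(primer, 6, 20) # 3'-terminal 15-mer
  amp <- c(own = paste0(primer, strrep("G", 40)),
           foreign_fwd = paste0(strrep("C", 20), seed, strrep("T", 20)),
           foreign_rev = paste0(strrep("C", 20), revcomp(seed), strrep("T", 20)),
           clean = strrep("A", 60))
  hits <- find_internal_binding(primer, amp)
  expect_setequal(hits$amplicon_id[hits$strand == "+"],
                  c("own", "foreign_fwd"))
  expect_equal(hits$amplicon_id[hits$strand == "-"], "foreign_rev")
  expect_equal(hits$offset[hits$amplicon_id == "foreign_fwd"], 20)
  ## excluding the designed site leaves only the foreign hits
  hits2 <- find_internal_binding(
    primer, amp, exclude = tibble::tibble(amplicon_id = "own", offset = 5,
                                          strand = "+"))
  expect_false("own" %in% hits2$amplicon_id)
  expect_equal(nrow(find_internal_binding(strrep("GA", 10), amp["clean"])), 0)
  ## strand-specificity: the GA-repeat seed sits only on the minus strand of
  ## a CT-repeat amplicon
  ct_hits <- find_internal_binding(strrep("GA", 10), c(ct = strrep("CT", 40)))
  expect_true(nrow(ct_hits) > 0 && all(ct_hits$strand == "-"))
})

## six 22-mers pre-screened to pass all rules and to be mutually dimer-free
OK_PRIMERS <- c("CTATCTCAGCGCCTATGCCACT", "TCGACTGCGCGGTTAGGAGCAA",
                "TAAGATGTGCGTGGGCGCATGG", "GAGGTAATCGTAAGGTCGCGGT",
                "TGGAGGTCCGCCACACAACTAC", "ACGGACAGACCACTTTGCGTGA")

test_that("screen_panel applies the rule cascade and conserves candidates", {
  short <- "ACGTACG"                  # LENGTH (and Tm out of range)
  cold  <- "ATTATAATATATTATAATAT"     # TM_RANGE (low)
  stem  <- "GCGCGCGCGCGC"
  hairp <- paste0(stem, "TTTT", revcomp(stem)) # 28 bp -> LENGTH + HAIRPIN
  primers <- tibble::tibble(
    locus_id = c("P1", "P2", "P3", "P4", "P5"),
    fwd = c(OK_PRIMERS[1], OK_PRIMERS[2], short, cold, hairp),
    rev = c(OK_PRIMERS[3], OK_PRIMERS[4], OK_PRIMERS[5], OK_PRIMERS[6],
            OK_PRIMERS[5])
  )
  rep <- screen_panel(primers, cfg = screen_config())
  expect_s3_class(rep, "screen_report")
  led <- attr(rep, "ledger")
  expect_equal(led$candidates, 5)
  expect_equal(led$retained + led$removed, led$candidates)
  expect_true(all(rep$pass[rep$locus_id %in% c("P1", "P2")]))
  expect_equal(led$retained, 2)
  expect_true("LENGTH" %in% rep$codes[[which(rep$locus_id == "P3")]])
  expect_true("TM_RANGE" %in% rep$codes[[which(rep$locus_id == "P4")]])
  expect_true("HAIRPIN" %in% rep$codes[[which(rep$locus_id == "P5")]])
  ## codes are reported in cascade order
  for (cs in rep$codes) {
    expect_equal(cs, cs[order(match(cs, c("LENGTH", "TM_RANGE", "HAIRPIN",
                                          "HETERODIMER", "INTERNAL_SITE")))])
  }
  expect_error(screen_panel(primers[c(1, 1), ]), "duplicate")
})

test_that("full-length reverse complements are flagged as heterodimers", {
  a <- OK_PRIMERS[1]
  primers <- tibble::tibble(locus_id = c("Q1", "Q2"),
                            fwd = c(a, revcomp(a)),
                            rev = OK_PRIMERS[3:4])
  rep <- screen_panel(primers)
  expect_true(all(!rep$pass))
  expect_true(all(vapply(rep$codes, function(x) "HETERODIMER" %in% x,
                         logical(1))))
})

test_that("internal-site failures respect the designed sites", {
  fwd <- OK_PRIMERS[1]
  rev <- OK_PRIMERS[2]
  mid <- random_primer(40, seed = 9)
  amp_ok <- paste0(fwd, mid, revcomp(rev))
  ## second amplicon embeds fwd's 3' seed internally -> INTERNAL_SITE
  seed15 <- substr(fwd, nchar(fwd) - 14, nchar(fwd))
  amp_bad <- paste0(rev, strrep("T", 10), seed15, strrep("C", 10),
                    revcomp(fwd))
  primers <- tibble::tibble(locus_id = c("R1", "R2"),
                            fwd = c(fwd, rev))
  primers$rev <- c(rev, fwd)
  rep <- screen_panel(primers,
                      amplicons = c(R1 = amp_ok, R2 = amp_bad),
                      cfg = screen_config(heterodimer_tm_max = 100))
  expect_true("INTERNAL_SITE" %in% rep$codes[[which(rep$locus_id == "R1")]])
  r1 <- screen_panel(primers[1, ], amplicons = c(R1 = amp_ok),
                     cfg = screen_config(heterodimer_tm_max = 100))
  expect_false("INTERNAL_SITE" %in% r1$codes[[1]])
})

test_that("raising the hairpin bound never adds HAIRPIN failures", {
  primers <- tibble::tibble(
    locus_id = sprintf("H%d", 1:6),
    fwd = vapply(1:6, function(i) random_primer(22, seed = i), character(1)),
    rev = vapply(7:12, function(i) random_primer(22, seed = i), character(1))
  )
  n_fail <- vapply(c(0, 20, 40, 60), function(mx) {
    rep <- screen_panel(primers, cfg = screen_config(hairpin_tm_max = mx,
                                                     heterodimer_tm_max = 1e6))
    sum(vapply(rep$codes, function(x) "HAIRPIN" %in% x, logical(1)))
  }, numeric(1))
  expect_true(all(diff(n_fail) <= 0))
})

test_that("primer mix formulation assigns quartile concentrations", {
  perf8 <- tibble::tibble(locus_id = sprintf("L%d", 1:8),
                          share = c(0.30, 0.25, 0.15, 0.10, 0.08, 0.06,
                                    0.04, 0.02))
  mix8 <- formulate_primer_mix(perf8)
  expect_equal(sum(mix8$concentration_nM == 80), 2)
  expect_equal(sum(mix8$concentration_nM == 320), 2)
  expect_equal(sum(mix8$concentration_nM == 160), 4)
  expect_equal(mix8$concentration_nM[mix8$locus_id == "L1"], 80)
  expect_equal(mix8$concentration_nM[mix8$locus_id == "L8"], 320)

  perf4 <- tibble::tibble(locus_id = sprintf("L%d", 1:4),
                          share = c(4, 3, 2, 1))
  mix4 <- formulate_primer_mix(perf4)
  expect_equal(sum(mix4$concentration_nM == 80), 1)
  expect_equal(sum(mix4$concentration_nM == 320), 1)
  expect_equal(sum(mix4$concentration_nM == 160), 2)

  ## uniform performance: nothing is strictly top or bottom quartile
  tied <- formulate_primer_mix(tibble::tibble(locus_id = sprintf("L%d", 1:8),
                                              share = rep(0.125, 8)))
  expect_true(all(tied$concentration_nM == 160))

  expect_warning(m3 <- formulate_primer_mix(
    tibble::tibble(locus_id = c("a", "b", "c"), share = 3:1)), "quartile")
  expect_true(all(m3$concentration_nM == 160))
})

test_that("quartile counts never exceed ceil(n/4) and codes are valid", {
  for (seed in 1:6) {
    n <- sample(4:17, 1)
    perf <- withr::with_seed(seed, tibble::tibble(
      locus_id = sprintf("L%02d", 1:n),
      share = sample(c(stats::runif(n - 2), 0.5, 0.5))))
    mix <- formulate_primer_mix(perf)
    expect_true(all(mix$concentration_nM %in% c(80, 160, 320)))
    expect_lte(sum(mix$concentration_nM == 80), ceiling(n / 4))
    expect_lte(sum(mix$concentration_nM == 320), ceiling(n / 4))
  }
})

test_that("panel bookkeeping arithmetic is conserved", {
  led <- panel_ledger(c(neutral = 10, adaptive = 4),
                      removed = list(c(neutral = 3, adaptive = 1),
                                     c(neutral = 2, adaptive = 0)))
  expect_equal(led$final_panel, c(5, 3, 8))
  expect_equal(led$candidates_round2, c(7, 3, 10))
  expect_error(panel_ledger(c(a = 2), removed = list(c(a = 5))), "exceed")
})
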