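#' Primer screening configuration
#'
#' Design-rule thresholds for multiplex primer screening: 18-24 bases,
#' annealing temperature between 58 and 63 degrees C, hairpins failing when
#' their stem melts strictly above 50 degrees C, heterodimers failing at
#' 50 degrees C or higher (inclusive bound), and no binding sites inside any
#' expected amplicon.
#'
#' @param min_len,max_len Allowed primer length range (bases).
#' @param tm_lo,tm_hi Allowed annealing temperature range (degrees C,
#'   inclusive).
#' @param hairpin_tm_max Hairpin stems melting strictly above this fail.
#' @param heterodimer_tm_max Heterodimers at or above this fail.
#' @param forbid_internal_binding Check 3'-seed binding sites inside the
#'   expected amplicons.
#' @param salt_mM,primer_nM Thermodynamic conditions, see
#'   [melting_temperature()].
#' @return A `screen_config` list.
#' @export
screen_config <- function(min_len = 18, max_len = 24, tm_lo = 58, tm_hi = 63,
                          hairpin_tm_max = 50, heterodimer_tm_max = 50,
                          forbid_internal_binding = TRUE,
                          salt_mM = 50, primer_nM = 250) {
  stopifnot(min_len <= max_len, tm_lo <= tm_hi)
  structure(list(min_len = min_len, max_len = max_len, tm_lo = tm_lo,
                 tm_hi = tm_hi, hairpin_tm_max = hairpin_tm_max,
                 heterodimer_tm_max = heterodimer_tm_max,
                 forbid_internal_binding = forbid_internal_binding,
                 salt_mM = salt_mM, primer_nM = primer_nM),
            class = "screen_config")
}

#' Find internal binding sites of a primer within amplicons
#'
#' Exact occurrences of the primer's 3'-terminal seed (last `seed_len`
#' bases, or the whole primer when shorter) on either strand of each
#' amplicon.  The 3' end is what drives mispriming, hence the anchored seed.
#' Reverse-strand hits are reported at the forward-strand offset of the
#' reverse-complemented seed.
#'
#' @param primer A single DNA string.
#' @param amplicons Named character vector of amplicon sequences (names are
#'   amplicon ids) or a data frame with `amplicon_id`, `seq`.
#' @param seed_len Seed length (default 15).
#' @param exclude Optional data frame of designed sites to ignore, with
#'   columns `amplicon_id`, `offset`, `strand`.
#' @return Tibble of hits: `amplicon_id`, `offset` (0-based, half-open on
#'   the forward strand), `strand` (`"+"`/`"-"`).
#' @export
find_internal_binding <- function(primer, amplicons, seed_len = 15,
                                  exclude = NULL) {
  check_dna(primer)
  stopifnot(length(primer) == 1)
  if (is.data.frame(amplicons)) {
    amp <- setNames(amplicons$seq, amplicons$amplicon_id)
  } else {
    amp <- amplicons
  }
  if (length(amp) == 0) abort("`amplicons` must be non-empty")
  if (is.null(names(amp))) names(amp) <- paste0("amp", seq_along(amp))
  seed <- if (nchar(primer) > seed_len) {
    substr(primer, nchar(primer) - seed_len + 1, nchar(primer))
  } else primer
  seeds <- c("+" = seed, "-" = revcomp(seed))
  hits <- purrr::map_dfr(names(amp), function(id) {
    purrr::map_dfr(c("+", "-"), function(strand) {
      m <- gregexpr(seeds[[strand]], amp[[id]], fixed = TRUE)[[1]]
      if (m[1] == -1) return(tibble())
      tibble(amplicon_id = id, offset = as.integer(m) - 1L, strand = strand)
    })
  })
  if (nrow(hits) && !is.null(exclude) && nrow(exclude)) {
    hits <- anti_join(hits, as_tibble(exclude),
                      by = c("amplicon_id", "offset", "strand"))
  }
  hits
}

primer_failures <- function(seq, role, locus_id, others, amplicons, cfg) {
  codes <- character(0)
  len <- nchar(seq)
  if (len < cfg$min_len || len > cfg$max_len) codes <- c(codes, "LENGTH")
  tm <- melting_temperature(seq, cfg$salt_mM, cfg$primer_nM, min_len = 1)
  if (tm < cfg$tm_lo || tm > cfg$tm_hi) codes <- c(codes, "TM_RANGE")
  hp <- hairpin_tm(seq, salt_mM = cfg$salt_mM, primer_nM = cfg$primer_nM)
  if (!is.na(hp) && hp > cfg$hairpin_tm_max) codes <- c(codes, "HAIRPIN")
  dim_tms <- vapply(others, function(o) {
    heterodimer_tm(seq, o, salt_mM = cfg$salt_mM, primer_nM = cfg$primer_nM)
  }, numeric(1))
  if (length(dim_tms) && any(!is.na(dim_tms) &
                             dim_tms >= cfg$heterodimer_tm_max)) {
    codes <- c(codes, "HETERODIMER")
  }
  if (cfg$forbid_internal_binding && length(amplicons)) {
    seed_len <- 15
    seed <- if (nchar(seq) > seed_len) seed_len else nchar(seq)
    ## designed site of this primer within its own amplicon
    own <- NULL
    if (locus_id %in% names(amplicons)) {
      amp_len <- nchar(amplicons[[locus_id]])
      own <- if (role == "fwd") {
        tibble(amplicon_id = locus_id, offset = nchar(seq) - seed, strand = "+")
      } else {
        tibble(amplicon_id = locus_id, offset = amp_len - nchar(seq),
               strand = "-")
      }
    }
    hits <- find_internal_binding(seq, amplicons, exclude = own)
    if (nrow(hits)) codes <- c(codes, "INTERNAL_SITE")
  }
  codes
}

#' Screen a multiplex primer panel against the design rules
#'
#' Applies, per locus, the rules LENGTH, TM_RANGE, HAIRPIN, HETERODIMER and
#' INTERNAL_SITE in that order, recording every failed rule (not only the
#' first).  Heterodimers are evaluated against every other primer in the
#' pool, pair partner included.  A locus passes iff its failure list is
#' empty.
#'
#' @param primers Data frame with `locus_id`, `fwd`, `rev`.
#' @param amplicons Optional named character vector (or data frame) of
#'   expected amplicon sequences, named by locus id.
#' @param cfg A [screen_config()].
#' @return A `screen_report`: tibble with `locus_id`, `pass`, `codes`
#'   (list-column), `failure` (comma string).  Attribute `"ledger"` holds the
#'   candidates / removed-by-reason / retained bookkeeping.
#' @export
screen_panel <- function(primers, amplicons = character(0),
                         cfg = screen_config()) {
  primers <- as_tibble(primers)
  stopifnot(all(c("locus_id", "fwd", "rev") %in% names(primers)))
  if (anyDuplicated(primers$locus_id)) {
    abort("duplicate locus_id in primer table")
  }
  check_dna(primers$fwd, "fwd"); check_dna(primers$rev, "rev")
  if (is.data.frame(amplicons)) {
    amplicons <- setNames(amplicons$seq, amplicons$amplicon_id)
  }
  pool <- c(setNames(primers$fwd, paste0(primers$locus_id, ".fwd")),
            setNames(primers$rev, paste0(primers$locus_id, ".rev")))
  res <- purrr::map(seq_len(nrow(primers)), function(i) {
    id <- primers$locus_id[i]
    f_others <- pool[names(pool) != paste0(id, ".fwd")]
    r_others <- pool[names(pool) != paste0(id, ".rev")]
    codes <- union(
      primer_failures(primers$fwd[i], "fwd", id, f_others, amplicons, cfg),
      primer_failures(primers$rev[i], "rev", id, r_others, amplicons, cfg)
    )
    ## fixed rule order for reporting
    codes[order(match(codes, c("LENGTH", "TM_RANGE", "HAIRPIN",
                               "HETERODIMER", "INTERNAL_SITE")))]
  })
  report <- tibble(
    locus_id = primers$locus_id,
    pass = lengths(res) == 0,
    codes = res,
    failure = vapply(res, paste, character(1), collapse = ",")
  )
  by_reason <- table(factor(
    unlist(lapply(res, function(x) x[1])),
    levels = c("LENGTH", "TM_RANGE", "HAIRPIN", "HETERODIMER",
               "INTERNAL_SITE")
  ))
  attr(report, "ledger") <- list(
    candidates = nrow(report),
    retained = sum(report$pass),
    removed = sum(!report$pass),
    removed_by_first_reason = as.list(by_reason)
  )
  class(report) <- c("screen_report", class(report))
  report
}

#' Formulate pooled primer-mix concentrations from locus performance
#'
#' Primers in the top quartile of on-target read share are down-weighted to
#' 80 nM, the bottom quartile is boosted to 320 nM, and everything else
#' stays at the standard 160 nM.  A tied group only counts as top (or
#' bottom) quartile when the whole group fits within `floor(n/4)` ranks, so
#' uniform performance leaves every locus at 160 nM.
#'
#' @param performance Data frame with `locus_id` and `share` (on-target read
#'   share, >= 0), or a named numeric vector.
#' @return Tibble `locus_id`, `share`, `concentration_nM`.
#' @export
formulate_primer_mix <- function(performance) {
  if (!is.data.frame(performance)) {
    performance <- tibble(locus_id = names(performance),
                          share = unname(performance))
  }
  performance <- as_tibble(performance)
  stopifnot(all(c("locus_id", "share") %in% names(performance)),
            all(performance$share >= 0))
  n <- nrow(performance)
  out <- performance %>% arrange(desc(.data$share), .data$locus_id)
  if (n < 4) {
    warn("fewer than 4 loci: quartiles undefined, all primers at 160 nM")
    out$concentration_nM <- 160
    return(out)
  }
  k <- floor(n / 4)
  ## "max" tie ranks: a tied block qualifies only if it fits entirely
  top_rank <- rank(-out$share, ties.method = "max")
  bot_rank <- rank(out$share, ties.method = "max")
  out$concentration_nM <- ifelse(top_rank <= k, 80,
                                 ifelse(bot_rank <= k, 320, 160))
  out
}

#' Panel optimization bookkeeping
#'
#' Staged arithmetic of panel attrition: designed candidates minus the loci
#' removed at each optimization round, per SNP class and in total.
#'
#' @param designed Named integer vector of designed primer sets per class,
#'   e.g. `c(neutral = 510, adaptive = 131)`.
#' @param removed List of named integer vectors, one per optimization round.
#' @return Tibble with one row per class plus a `total` row: `designed`,
#'   `removed_round<k>`, `candidates_round<k>` (entering round k) and
#'   `final_panel`.
#' @export
panel_ledger <- function(designed, removed) {
  stopifnot(is.numeric(designed), !is.null(names(designed)), is.list(removed))
  classes <- names(designed)
  out <- tibble(class = c(classes, "total"),
                designed = unname(c(designed, sum(designed))))
  current <- out$designed
  for (k in seq_along(removed)) {
    rem <- removed[[k]][classes]
    stopifnot(!anyNA(rem))
    rem <- unname(c(rem, sum(rem)))
    out[[paste0("candidates_round", k)]] <- current
    out[[paste0("removed_round", k)]] <- rem
    current <- current - rem
    if (any(current < 0)) abort("removals exceed available candidates")
  }
  out$final_panel <- current
  out
}

#' Primer-to-assay conversion rate
#'
#' Percentage of attempted loci retained in the working panel.
#'
#' @param attempted Number of loci attempted.
#' @param excluded Number excluded during testing.
#' @return List with `retained` and `rate_pct` (0-100, unrounded).
#' @export
conversion_rate <- function(attempted, excluded) {
  stopifnot(attempted > 0, excluded >= 0, excluded <= attempted)
  list(retained = attempted - excluded,
       rate_pct = 100 * (attempted - excluded) / attempted)
}
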