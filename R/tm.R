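## Nearest-neighbor duplex thermodynamics, unified parameter set
## (SantaLucia 1998 / Allawi & SantaLucia 1997).  dH in kcal/mol,
## dS in cal/(mol K).  Dinucleotides are collapsed onto the ten unique
## duplexes via reverse-complement equivalence.

NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
## terminal (initiation) penalties per duplex end
NN_INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
NN_INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
R_GAS <- 1.987 # cal/(mol K)

tm_nn_one <- function(seq, salt_mM, primer_nM) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  steps <- paste0(b[-n], b[-1])
  dh <- sum(NN_DH[steps]) + NN_INIT_DH[b[1]] + NN_INIT_DH[b[n]]
  ds <- sum(NN_DS[steps]) + NN_INIT_DS[b[1]] + NN_INIT_DS[b[n]]
  if (seq == revcomp(seq)) ds <- ds - 1.4 # self-complementary symmetry term
  ## entropy salt correction: 0.368 * (N-1) * ln[Na+]
  ds <- ds + 0.368 * (n - 1) * log(salt_mM / 1000)
  ct <- primer_nM * 1e-9 / 4 # non-self-complementary duplex factor
  unname(1000 * dh / (ds + R_GAS * log(ct)) - 273.15)
}

#' Nearest-neighbor melting temperature of a primer
#'
#' Duplex melting temperature from the unified nearest-neighbor parameter
#' set with an entropy salt correction, at the given monovalent salt and
#' primer concentrations.  `Tm(s)` equals `Tm(revcomp(s))`.
#'
#' @param seq Character vector of DNA sequences (A/C/G/T), length >= 8 each.
#' @param salt_mM Monovalent cation concentration in mM (default 50).
#' @param primer_nM Total strand concentration in nM (default 250); the
#'   duplex term uses `C_T/4`.
#' @param min_len Minimum sequence length accepted (default 8).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AGCTGATCCGTAAGGCTTAC")
melting_temperature <- function(seq, salt_mM = 50, primer_nM = 250,
                                min_len = 8) {
  check_dna(seq)
  if (any(nchar(seq) < min_len)) {
    abort(sprintf("sequences must be at least %d bases long", min_len))
  }
  vapply(seq, tm_nn_one, numeric(1), salt_mM = salt_mM,
         primer_nM = primer_nM, USE.NAMES = FALSE)
}

## duplex Tm of a stem sequence without the length guard (stems can be short)
stem_tm <- function(seq, salt_mM, primer_nM) {
  vapply(seq, tm_nn_one, numeric(1), salt_mM = salt_mM,
         primer_nM = primer_nM, USE.NAMES = FALSE)
}

#' Most stable hairpin stem of a primer
#'
#' Exhaustive ungapped search for self-complementary stems of at least
#' `min_stem` base pairs separated by a loop of at least `min_loop` bases.
#' The reported value is the duplex melting temperature of the most stable
#' stem; full secondary-structure folding is deliberately out of scope --
#' this is a screening heuristic.
#'
#' @param seq A single DNA string.
#' @param min_loop Minimum loop length in bases (default 3).
#' @param min_stem Minimum stem length in base pairs (default 4).
#' @inheritParams melting_temperature
#' @return Stem melting temperature in degrees C, or `NA_real_` when no
#'   qualifying stem exists.
#' @export
hairpin_tm <- function(seq, min_loop = 3, min_stem = 4,
                       salt_mM = 50, primer_nM = 250) {
  check_dna(seq)
  stopifnot(length(seq) == 1)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  comp <- chartr("ACGT", "TGCA", seq)
  best <- NA_real_
  if (n < 2 * min_stem + min_loop) return(best)
  for (len in min_stem:floor((n - min_loop) / 2)) {
    for (i in 1:(n - 2 * len - min_loop + 1)) {
      for (j in (i + len + min_loop):(n - len + 1)) {
        stem5 <- substr(seq, i, i + len - 1)
        ## stem pairs when the 3' arm read 5'->3' is the revcomp of the 5' arm
        stem3 <- substr(seq, j, j + len - 1)
        if (stem3 == revcomp(stem5)) {
          tm <- stem_tm(stem5, salt_mM, primer_nM)
          if (is.na(best) || tm > best) best <- tm
        }
      }
    }
  }
  best
}

#' Best primer-primer heterodimer
#'
#' Slides one primer along the reverse complement of the other and scores
#' every ungapped stretch of consecutive complementary base pairs of at
#' least `min_stem` bp with the nearest-neighbor duplex melting temperature.
#' Symmetric in its two arguments; for a primer against its exact reverse
#' complement it reduces to [melting_temperature()].
#'
#' @param a,b Single DNA strings.
#' @inheritParams hairpin_tm
#' @return Melting temperature of the most stable complementary stretch in
#'   degrees C, or `NA_real_` when none reaches `min_stem`.
#' @export
heterodimer_tm <- function(a, b, min_stem = 4, salt_mM = 50, primer_nM = 250) {
  check_dna(a); check_dna(b)
  stopifnot(length(a) == 1, length(b) == 1)
  rb <- revcomp(b)
  na <- nchar(a); nb <- nchar(rb)
  best <- NA_real_
  for (off in (-(nb - 1)):(na - 1)) {
    lo <- max(1, 1 + off); hi <- min(na, nb + off)
    if (hi - lo + 1 < min_stem) next
    av <- substring(a, lo:hi, lo:hi)
    bv <- substring(rb, (lo:hi) - off, (lo:hi) - off)
    match <- av == bv
    r <- rle(match)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_stem)) {
      stem <- substr(a, lo + starts[k] - 1, lo + ends[k] - 1)
      tm <- stem_tm(stem, salt_mM, primer_nM)
      if (is.na(best) || tm > best) best <- tm
    }
  }
  best
}
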