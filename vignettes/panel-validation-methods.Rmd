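---
title: "Methods: panel design, allele-ratio genotyping and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: panel design, allele-ratio genotyping and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtseqr)
library(dplyr)
```

gtseqr implements the computational side of developing and validating a
GT-seq (Genotyping-in-Thousands by sequencing) SNP panel: selecting
candidate SNPs from an existing genotype matrix, screening multiplex primers
thermodynamically, calling genotypes from amplicon reads by allele ratios,
quantifying concordance between genotyping methods, and computing the
population-genetic statistics used to judge whether a panel reproduces the
biology seen by heavier sequencing approaches. A synthetic-data generator
ties the pieces together so every claim in this vignette is demonstrable
without access to real samples.

## Candidate SNP selection

Panel candidates are filtered from called genotypes, not reads. For each
locus we compute missingness (the fraction of individuals with no diploid
call — both the depth-based `missing` code and the ratio-dead-zone `nocall`
count), the allele frequency among called genotypes, and the expected
heterozygosity $H_e = 2p(1-p)$. The default thresholds — missingness
$< 0.4$, $H_e > 0.1$, one SNP per scaffold — are the neutral-candidate
criteria typically used when distilling a reduced-representation SNP
catalogue into an amplicon panel; the additional flags (minor allele
frequency $> 0.02$, spacing $> 10\,$kb, biallelic-only, minimum read depth)
mirror the maximum-likelihood pipeline filters used for the comparison
dataset. All thresholds are strict inequalities, following the convention
that a locus sitting exactly on a bound is rejected.

Two rules needed decisions the filtering convention leaves open:

* **One SNP per scaffold.** Among surviving loci on a scaffold we keep the
  one with the highest $H_e$, breaking ties by smallest position. This
  maximizes panel informativeness and is deterministic.
* **Spacing.** A locus fails when *any* other candidate on the same
  scaffold lies within the minimum spacing. Judging distance against the
  full candidate table (rather than greedily against already-accepted loci)
  makes the rule independent of the other thresholds, idempotent, and
  monotone: relaxing any single threshold can never shrink the survivor
  set. The price is that both members of a close pair are rejected rather
  than one; for panel design, where close pairs are rare and suspect
  anyway, we consider this the better-behaved convention.

`min_reads` masks genotypes backed by too few reads before the missingness
rule, and therefore requires a per-genotype depth table; without one the
rule is skipped with a notice, since a genotype matrix alone carries no
depth information.

## Primer screening thermodynamics

Primer rules follow standard multiplex design practice: length 18–24 bases,
annealing temperature 58–63 °C, no stable hairpins (stem melting strictly
above 50 °C fails), no primer–primer heterodimers (50 °C *or higher* fails —
the inclusive bound deliberately differs from the hairpin's exclusive one,
tracking the wording of the design protocol the package emulates), and no
binding sites of the primer's 3′ seed inside any expected amplicon.

Melting temperatures use the unified nearest-neighbor parameter set
(SantaLucia 1998; Allawi & SantaLucia 1997) with the entropy salt
correction $\Delta S' = \Delta S + 0.368\,(N-1)\ln[\mathrm{Na}^+]$, default
50 mM monovalent salt and 250 nM total strand concentration (the duplex
term uses $C_T/4$; self-complementary sequences get the symmetry entropy
term). Tests pin fixed sequences against values computed with an
independent nearest-neighbor calculator before this implementation was
written, to ±0.5 °C.

Hairpin and heterodimer detection are exhaustive ungapped searches for
complementary stems of ≥ 4 bp (hairpins additionally require a loop of
≥ 3 bases); the reported temperature is the duplex Tm of the best stem.
This is a screening heuristic, not a secondary-structure prediction: full
dynamic-programming folding is out of scope, and vendor tools used for real
panels will not agree absolutely. What the package guarantees is the
ordering and threshold behaviour its tests assert. Internal binding uses
exact matching of the primer's 3′-terminal 15 bases (the whole primer when
shorter) on both strands, because 3′ anchoring is what drives mispriming;
the primer's own designed site is excluded.

Primer-mix formulation follows the standard re-balancing scheme: loci in
the top quartile of on-target read share drop to 80 nM, the bottom quartile
rises to 320 nM, everything else stays at 160 nM. Ranks use descending
share with "max" tie ranks, so a tied block qualifies as top (or bottom)
quartile only when the entire block fits within $\lfloor n/4 \rfloor$
ranks; uniform performance therefore leaves every locus at 160 nM, which is
the intended no-op.

## Allele-ratio genotyping

Genotypes are called from per-allele probe counts in single-end FASTQ
reads. Counting is exact, forward-strand, full-probe substring matching
(implemented with Biostrings' Aho–Corasick dictionaries); a read increments
at most one locus-allele counter — loci are scanned in sorted id order,
allele 1 before allele 2 — and reads matching probes of several loci are
assigned to the first and reported, since they indicate a panel defect.
Quality strings are read and ignored; no trimming or mismatch tolerance is
applied, keeping the counting deterministic.

With $n_1$ and $n_2$ the allele counts and $r = n_1/n_2$:

* fewer than 10 reads → `missing`;
* $r > 10$ → homozygous allele 1 ($n_2 = 0$ gives $r = +\infty$, the limit
  of the rule);
* $r < 0.1$ → homozygous allele 2;
* $0.2 \le r \le 5$ → heterozygous;
* otherwise — the dead zones $(0.1, 0.2)$ and $(5, 10]$ — `nocall`.

The dead zones are deliberately preserved rather than absorbed into a
neighbouring call: the published thresholds simply do not define those
ratios, and inventing calls there would silently change downstream
statistics. `nocall` is distinct from `missing` in the data model but both
count as "not genotyped" for missingness, success rates and concordance.

At heterozygous depth $d$ with unbiased allele sampling the probability of
seeing only one allele is $2(1/2)^d$ — 0.25 at $d = 3$, negligible at
$d = 30$. Under the full ratio rule at $d = 12$, exhaustive binomial
enumeration gives a het-miscall probability of $26/4096 \approx 0.63\%$
(the $n_1 \in \{0, 1, 11, 12\}$ tails). Both numbers are verified by
simulation in the test suite and recomputed by the acceptance script.

## Genotype concordance

Two genotype tables are compared over their shared individuals and loci.
Cells called by both methods are classified as concordant or into exactly
one of three mismatch categories: method A homozygous / B heterozygous,
A heterozygous / B homozygous, or opposite homozygotes. For biallelic loci
a het–het mismatch is structurally impossible (there is only one
heterozygous genotype), which the report asserts rather than tabulates.

The headline discordance rate is the ratio of means — mean discordant loci
per individual over mean loci called by both. A mean-of-ratios variant
(average of per-individual rates) is provided behind a flag because
published summary tables computed from unbalanced per-individual
denominators are not always reproducible from their printed means, which
suggests that aggregation differs between studies; the package asserts
nothing against numbers it cannot reproduce. `recompute_excluding()`
recomputes the rate with chosen categories treated as concordant — the
standard way of asking how much of the disagreement is explained by
allelic dropout in the lower-coverage method.

## Population-genetic validation

Per population (sites with at least 8 individuals by default, matching the
usual site-level analysis rule) the package reports observed
heterozygosity, the sample-size-corrected gene diversity
$H_s = \frac{\tilde n}{\tilde n - 1}\left(1 - \sum p_i^2 -
\frac{H_o}{2\tilde n}\right)$ (Nei 1987), and
$F_{IS} = 1 - \sum H_o / \sum H_s$ over polymorphic loci. The reported
"expected heterozygosity" is the corrected $H_s$; whether published figures
use corrected or raw gene diversity is often unstated, and the corrected
form is what the standard hierarchical F-statistics software computes, so
comparability argues for it.

Pairwise $F_{ST}$ is the Weir & Cockerham (1984) estimator: per-locus
variance components $a$ (among populations), $b$ (among individuals within
populations) and $c$ (within individuals), with the multilocus estimate the
ratio of sums $\sum a / \sum(a+b+c)$ — the recommended multilocus form, not
the mean of per-locus ratios. Negative estimates are retained; loci with
zero total variance are skipped. Confidence intervals bootstrap loci (not
individuals) with replacement and report empirical 2.5%/97.5% percentiles,
reproducible under a fixed seed. Tests verify the estimator against an
independently written plain-loop implementation, the analytic value
$\theta = 1$ for fixed differences, near-zero for a randomly split
panmictic sample, and parameter recovery under the island model below;
a 60-replicate experiment checks that the 95% interval covers the
generating $F_{ST}$ at near-nominal frequency.

## The synthetic study generator

`sim_config()` describes a structured-population amplicon study:

* **Population structure.** Balding–Nichols: ancestral allele frequencies
  drawn uniform on (0.1, 0.9) by default, population frequencies
  Beta-distributed around them with concentration set by a target $F_{ST}$.
  The default target 0.10 sits in the middle of the pairwise range
  (0.067–0.129) typical of the fragmented ground-squirrel system this kind
  of panel is built for. Genotypes are Hardy–Weinberg draws within
  populations.
* **Study size.** Defaults of 4 populations × 10 individuals × 200 loci
  echo a small multi-site validation study (four sites passing the
  8-individual rule; a ~200-locus neutral panel). Statistical tests in the
  package use explicit sizes instead of the defaults where precision
  demands it — e.g. 2 × 30 individuals and 2000 loci for $F_{ST}$ recovery,
  chosen so the estimator's sampling noise (±0.003) sits well inside the
  ±0.02 recovery band; and 100 loci at depth 100 for the end-to-end run,
  enough for per-population $F_{IS}$ to resolve within ±0.05 of zero.
* **Reads.** Per individual × locus, depth is Poisson (or negative
  binomial) with a per-sample-type mean — defaults 2 (hair), 30 (swab),
  100 (tissue), qualitatively matching the on-target read disparity between
  degraded hair extracts, buccal swabs and tissue. Heterozygote reads
  sample each allele with probability ½; an allele can drop out entirely
  (amplification failure) with configurable probability; each read carries
  the opposite allele's probe with probability `error_rate` (a false
  allele, default $10^{-3}$). Reads embed the probe at a fixed offset in
  random flanking sequence with constant quality, so exact-match counting
  recovers the truth tallies verbatim in error-free mode.
* **Low-coverage comparison calls.** `sim_lowcov_calls()` emulates a
  low-depth caller by sampling $d$ reads per cell: heterozygotes whose
  reads all come from one chromosome are observed as homozygotes, and
  homozygotes are never observed as heterozygotes in error-free mode. This
  reproduces the characteristic asymmetry of comparisons against
  low-coverage reduced-representation data (het→hom mismatches dominate),
  and injecting heavy symmetric contamination instead reverses the
  asymmetry — the package's testbed for the heterozygote-excess /
  negative-$F_{IS}$ phenomenon repeatedly reported for amplicon panels.

What the generator does *not* emulate: linkage between loci, coalescent
ancestry, PCR duplicates, index hopping, primer-competition dynamics in the
multiplex, or quality-score structure. Passing tests on simulated data
therefore demonstrate the correctness of the algorithms under the stated
model, not field performance on degraded samples.

## Numerical and interface conventions

* Every stochastic operation takes or derives from an explicit integer
  seed; fixed seed means bit-identical output.
* Genotypes travel as long tibbles (`individual`, `population`,
  `sample_type`, `locus_id`, `call`) so dplyr verbs compose; wide CSV
  (0/1/2/NA dosage or symbolic codes) and biallelic VCF (GT field, REF as
  allele 1, `./.` missing, 1-based positions) are the interchange formats.
  FASTA/FASTQ I/O goes through Biostrings; VCF through vcfR.
* Fitted results expose broom-style `tidy()`/`glance()` methods and
  `plot_*()` helpers (ggplot2).
* The command-line entry point (`inst/cli/gtseq-panel.R`) is a thin
  optparse wrapper over the exported functions with subcommands `select`,
  `screen`, `mix`, `genotype`, `concord`, `popstats`, `simulate`; every CSV
  it writes carries a comment header recording the package version,
  parameters and seed.

## Known limitations

* Thermodynamic screening is desk-scale: ungapped stems, no dangling-end or
  mismatch corrections, no full fold. Agreement with vendor pipelines is
  directional, not absolute.
* Probe counting is exact-match; a single sequencing error inside a probe
  drops the read. At the read depths amplicon panels produce this costs
  little sensitivity, but counts are not error-corrected.
* The $F_{IS}$/heterozygote-excess machinery demonstrates mechanisms on
  simulated data; it cannot adjudicate which mechanism explains any
  particular real dataset.
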