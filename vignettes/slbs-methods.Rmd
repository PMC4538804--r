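---
title: "Single-cell locus-specific bisulfite sequencing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell locus-specific bisulfite sequencing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slbs)
```

## The assay and its statistical model

Targeted single-cell bisulfite sequencing measures DNA methylation at the
CpG sites of a handful of PCR amplicons (typically gene promoters) in one
cell at a time. Bisulfite deaminates unmethylated cytosine to uracil, read
as thymine after PCR; 5-methylcytosine resists and reads as cytosine. A
single diploid cell contributes at most two template molecules per locus,
so after whole-genome amplification (MDA) and Sanger sequencing each
cell-locus pair yields one consensus trace in which a position covered by
two discordant alleles appears as an overlapping C+T double peak, encoded
here with the IUPAC code `Y`.

An *epimutation* is a cell-specific departure from the bulk-tissue
baseline at a single CpG: *demethylating* (read unmethylated where the
bulk is methylated) or *methylating* (the converse). The epimutation rate
is the number of altered cell-by-CpG observations divided by the total
number of evaluable cell-by-CpG observations, pooled over all regions.
This pooled denominator -- rather than a baseline-stratified one -- is the
only definition under which the published event counts and printed rates
are mutually consistent, and it is what `summarize_epimutations()`
computes.

Because an unconverted cytosine is indistinguishable from a methylated
one, two chemistry artefacts mimic epimutations:

* *conversion failure* (an unmethylated C stays C) mimics a methylating
  event;
* *over-conversion* (a methylated C reads T) mimics a demethylating event.

The assay's internal control is the conversion rate of cytosines outside
CpG context, which are essentially never methylated in non-pluripotent
cells: `compute_conversion_qc()` counts, per cell and locus, the non-CpG
cytosines read as T (converted) versus C or Y (not). Methylating events
are then tested against this background with an exact test (below).
Demethylating events have no analogous internal control; their possible
inflation by over-conversion is a stated limitation of the assay.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `rate_demethylating`, `rate_methylating` | 0 | per-allele epimutation probabilities per CpG (dimensionless) |
| `conversion_failure_rate` | 0.005 | P(unmethylated C stays C); the optimized protocol converts ~99.5% of non-CpG cytosines |
| `overconversion_rate` | 0.002 | P(methylated C reads T); the protocol reports this only qualitatively ("occasional"), so the default is an assumed small magnitude, not a measured value |
| `allelic_dropout_prob` | 0.10 | P(one allele only amplifies), the reported MDA allelic bias |
| `amplicon_success_prob` | 0.40 | P(any product) for single cells; use 0.99 for the 100-cell control regime |
| `non_cpg_methylation_rate` | 0 | CHH methylation, relevant for neurons; reads as C and is deliberately confounded with conversion failure, as in the real assay |
| `min_identity` (calling) | 0.90 | anchor acceptance, identity over non-wildcard columns |
| `min_conversion` (QC) | 0.95 | per-cell-locus conversion threshold; the source protocol rejects an under-converted regime (~0.80) and keeps the optimized one (~0.994) but states no number -- 0.95 is this package's choice and cleanly separates the two |

## The simulator and its truth ledger

`simulate_experiment()` draws, per locus, a cell x allele x CpG state
array from the bulk profile (per-allele independent epimutation flips;
`MIXED` bulk CpGs are drawn at their methylated fraction and never
flipped), then per cell: amplicon dropout, allelic dropout (one uniformly
chosen allele), per-allele chemistry errors, and the Sanger consensus.
Every planted event is logged in a truth ledger
(`cell_id, locus, allele_index, position, event_kind`), which recovery
tests compare against pipeline output. All randomness flows from
`config$seed` through R's global RNG in a documented draw order, so a
given seed and configuration reproduce byte-identical FASTA and ledger
files.

Epimutations are planted per allele. In diploid mode a single-allele flip
surfaces as a `Y` (called `HEMI`) and is counted as **one** event -- the
counting rule of the source assay, which assumes one represented allele
unless two peaks are visible. Haploid mode (`ploidy = 1`) makes the
per-observed-unit rate the exact estimand and is the default for
parameter-recovery tests.

What the generator does *not* emulate: chromatogram signal levels and
base-quality, PCR/MDA point errors and chimeras, bisulfite-induced
fragmentation, and cell doublets. Consensus mixtures other than {C, T}
render as `N` and are excluded downstream, mirroring the fact that only
C/T double peaks are interpretable in the real traces. Passing tests
therefore validate the statistical pipeline, not trace-level base
calling.

## Read anchoring

Reads are anchored to the *fully converted* reference (all C to T) by
global alignment (match +1, mismatch -1, gap -2). Reference cytosine
positions are wildcards accepting `C`, `T` or `Y`, since their read-out
is the signal being measured; acceptance requires at least 0.90 identity
over the non-wildcard columns. Ties are broken deterministically
(mismatch over gap, gap in the reference before gap in the read). A read
of reference length whose non-wildcard columns all match takes a fast
path that skips the dynamic program; this is exact, because any gapped
alignment of equal-length sequences costs at least one gap pair (-4)
against at most a wildcard mismatch (-1).

## Epimutation statistics

`classify_cpg()` maps each retained call to `DEMETHYLATING`,
`METHYLATING`, `CONCORDANT` or `NOT_EVALUABLE` (ambiguous call or `MIXED`
bulk). `fisher_exact_two_sided()` is an internal implementation of the
exact conditional test with the point-probability two-sided definition
(sum of hypergeometric probabilities no greater than the observed one; a
relative tolerance of 1e-7 guards ties), computed in log space via
`lchoose`. The test suite checks it exhaustively against brute-force
enumeration for every 2x2 table with grand total up to 40 and against the
reference implementation in `stats`. The methylating-vs-background table
is `rbind(c(n_methylating, total_cpgs - n_methylating),
c(non_cpg_nonconverted, non_cpg_converted))`.

## Numerical and design choices

* **Coordinates.** 0-based half-open everywhere (BED convention);
  CpG indices are 0-based ordinals. A terminal cytosine with no following
  base counts as non-CpG, which slightly widens QC denominators.
* **Rounding.** Display percentages round half away from zero to one
  decimal; unrounded values are always emitted alongside, because the
  published table's own rounding is internally inconsistent (16/601
  prints as 2.7 but 10/601 as 1.6).
* **`Y` at a non-CpG cytosine** counts as non-converted (at least one
  allele escaped conversion) -- the conservative choice for QC.
* **QC threshold vs amplicon width.** A cell-locus pair with `e`
  evaluable non-CpG cytosines and one conversion failure has rate
  `(e-1)/e`, which clears the 0.95 threshold only for `e >= 20`.
  Amplicons with fewer informative cytosines silently censor the
  background failures out of the significance comparison and bias it
  toward rejection; the benchmark fixture and the null-control test are
  therefore built on amplicons with at least 20 evaluable non-CpG
  cytosines per failure-carrying cell.
* **`MIXED` bulk CpGs** are excluded from epimutation denominators. The
  source data never scores epimutations against a partially methylated
  baseline; how such sites would enter the published table is
  undecidable, so exclusion is the conservative reading.
* **Degenerate inputs.** A read covering no non-CpG cytosine is
  QC-undefined: retained but unscored. An empty call set yields an empty
  summary with no totals row. Zero-margin 2x2 tables give p = 1.

## The benchmark fixture

`generate_hepatocyte_fixture()` rebuilds, deterministically and without
RNG, a dataset shaped like the published single-hepatocyte experiment:
eight regions with CpG counts (2, 4, 2, 3, 2, 4, 4, 3), cell counts
(17, 12, 33, 66, 24, 34, 11, 9), 16 demethylating and 10 methylating
planted events, and 17 planted conversion failures out of 3296 evaluable
non-CpG cytosines. Event `j` of a region goes to cell `j` at CpG ordinal
`j mod n_cpgs`; non-conversions are assigned round-robin across cells
from cell 0. The published per-region conversion denominators sum to
3313 while the published pooled denominator is 3296; the fixture
reproduces the pooled totals row exactly (the quantity all downstream
statistics use) and the per-region fractions approximately, which it
realises by masking surplus non-CpG positions with `N` per cell (masked
positions leave QC denominators). Running the calling and summary steps
on the fixture yields exactly 206 cells, 601 CpGs, 16 and 10 events,
3279/3296 conversions (99.48%), and a methylating-vs-background p of
0.0049.

## Problem sizes used in the test suite

Stochastic properties are checked at sizes chosen to make binomial bands
tight enough to be meaningful while keeping the default suite quick:
parameter recovery uses 5000 haploid cell-by-CpG units per rate (rates
0.005, 0.027, 0.1; exact central 99% binomial acceptance intervals); the
null-control property uses 200 seeds of 50 cells x 4 CpGs with a
40-cytosine background; the ledger's binomial law is checked by
chi-square over 120 seeds of 200 trials; the Fisher implementation is
verified exhaustively for all tables with grand total up to 40.

## Known limitations

Only the top strand is modelled (the complementary G-to-A readout is a
separate assay design); there is no multi-read consensus per cell, no
quality-aware base calling, and no multiple-testing correction across
loci (the source analysis reports a single pooled test). Demethylating
rates carry an unquantifiable over-conversion component; the simulator
exposes `overconversion_rate` so users can explore its impact, but the
pipeline cannot correct for it.
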