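---
title: "Methods: quantifying and comparing chloroplast C-to-U RNA editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying and comparing chloroplast C-to-U RNA editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastedit)
```

## The measurement problem

Chloroplast transcripts are edited at a fixed, small catalogue of cytidines
(33 known sites in the Arabidopsis plastome), each converted to uridine in
some fraction of transcript molecules. That fraction — the editing
efficiency — is the quantity of interest: it shifts when the nuclear-encoded
editing machinery (MORF/ORRM-type factors) is perturbed. At the cDNA level
an edited molecule reads T where the reference has C, so efficiency is an
allele-fraction estimation problem at known positions, with two measurement
routes:

* **Digital (RNA-seq pileup).** At a catalogued site, count reads carrying
  the edited base and reads carrying the unedited base, and estimate
  efficiency as `e / (e + u)`. Counting is strand-aware: the catalogue
  stores each gene's sense strand, so at a `+` site the informative
  reference-forward bases are T (edited) and C (unedited), while at a `−`
  site they are A and G. Any other base is recorded (`n_other`) but excluded
  from the denominator, since only the T/C dimorphism is informative about
  editing; deletions and reference skips contribute to no category. A site
  with no informative coverage has efficiency `NA`, never 0 — an absent
  measurement is not an unedited site.

* **Sanger (chromatogram peak areas).** In a mixed-template trace the edited
  fraction appears as the relative height of the T peak over the C peak at
  one basecall. We integrate per-channel peak areas and estimate efficiency
  as `area_T / (area_T + area_C)`. The normalised fraction (rather than the
  raw ratio `area_T / area_C`) is used because efficiencies are bounded
  percentages; the raw ratio is reported alongside for transparency.

Both estimators are maximum-likelihood under a binomial sampling model of
independent transcript molecules; the pileup route additionally assumes
reads sample molecules independently (no de-duplication or mate-overlap
collapse is applied by default, because typical editing studies inspect raw
pileups the same way — an optional future extension, not a default).

## Pileup conventions and filters

`count_bases_at_site()` / `quantify_all()` apply two hygiene filters with
standard defaults: minimum base quality 20 and minimum mapping quality 20
(phred-scaled). Manual inspection workflows these functions replace apply no
explicit thresholds, so both filters accept 0 to reproduce raw tallies; 20
is the conventional pileup floor that removes most miscalls without biasing
the T/C balance (miscalls are not strand- or allele-directional). Raising
either threshold can only remove reads, never add them (a tested
monotonicity property).

## Peak-area conventions

Chromatogram "area" needs an explicit convention; this package's is:

* **Window**: from the midpoint between a basecall and its predecessor to
  the midpoint to its successor (trace edges at the termini). This is
  deterministic, parameter-free and respects local peak spacing.
* **Baseline**: the minimum intensity within the window, times the window
  length, subtracted from the raw sum. Areas are therefore nonnegative and
  a flat channel integrates to zero.

No curve fitting is performed: the convention is testable against
closed-form Gaussian integrals (the unit tests verify the windowed,
baseline-subtracted discrete sum against the analytic expression within 2%)
and behaves predictably on degenerate traces. The efficiency estimate is
exactly scale-invariant (both areas scale together) and, on noise-free
two-peak traces, recovers the simulated mixture within 1% across the whole
\[0, 1\] range (limited only by integer rounding of intensities).

One consequence is worth stating plainly: because the baseline is a windowed
*minimum*, per-scan noise enters the area multiplied by the window length.
At 5%-of-amplitude per-scan noise this propagates to roughly ±0.05 standard
deviation on a single-trace estimate — for any realistic peak width, since
the baseline term scales with window length over peak width, which the
midpoint rule fixes. Single noisy traces are therefore honest to about one
part in twenty, and the package's repeated-seed validation of the noisy
regime checks the mean over 100 seeds (which recovers the mixture to well
under 0.05) together with a dispersion bound, rather than asserting a
per-trace guarantee the estimator cannot give.

## Differential editing

Replicate base counts are pooled by exact summation within each condition
before testing — the design this package targets has two biological
replicates per condition, and pooling is how such data are classically
analysed. Each testable site (both pooled conditions have informative
coverage > 0) contributes a 2×2 table, edited/unedited × condition, tested
with the two-sided Fisher's exact test under the minimum-likelihood rule:
the p-value sums hypergeometric probabilities of all tables with the
observed margins whose probability does not exceed the observed table's
(relative tolerance 1e-7, the convention of standard implementations; the
implementation is vectorised and verified against exhaustive enumeration
over all margins up to 50 and against `stats::fisher.test`).

Bonferroni correction uses `m` = the number of testable sites in the run (33
when the full catalogue is testable). Untestable sites are excluded from `m`
— multiplying by tests never performed would be arbitrary — and reported as
`NA` rows, and `m` is user-overridable for studies that prefer a fixed
family size. Significance is `p_adj < alpha` with `alpha = 0.05`.

Pooling before testing is a known limitation, inherited deliberately from
the design this package models: it ignores between-replicate
(over)dispersion, so a site genuinely variable between replicates can reach
significance on pooled counts. With two replicates there is little power to
estimate dispersion anyway; users needing replicate-aware inference should
treat flagged sites with small deltas cautiously.

## Expression arithmetic

The expression module is intentionally plain arithmetic with explicit
conventions:

* **CPM**: `count / library_total × 1e6` per sample; columns sum to 1e6.
* **Expressed-gene filters**: CPM strictly above a threshold in at least
  `min_samples` samples. The three presets are (2 CPM, ≥9 of 10),
  (0.5 CPM, ≥11 of 12) and (0.5 CPM, ≥3 of 4); "above" is read as strict
  inequality, with a flag to switch, and the boundary is unit-tested.
* **SDEG calling**: this package does not fit a negative-binomial model
  (that is what edgeR/DESeq2 are for). `sdeg_call()` is a documented simple
  stand-in: log2 fold change from group-mean CPM with pseudocount 0.5, and a
  two-sided exact binomial test of each gene's pooled count split against
  the library-size expectation, BH-corrected. Thresholds are |log2FC| ≥ 1
  and FDR < 1e-4 ("0.01%" read literally as a percent). The binomial test
  ignores biological dispersion and is anti-conservative for variable genes;
  the fold-change gate carries the specificity, which suffices for the
  well-separated planted effects the simulators produce but is not a
  substitute for a dispersion-aware model on real data.
* **Overlap percentages** are rounded half-up to one decimal, matching how
  such percentages are printed.
* **Set enrichment** is flat-set Fisher (same shared test), with a Haldane
  0.5 correction on the odds ratio when a cell is zero. No GO-hierarchy
  logic (elim-style algorithms) is attempted.
* **2^−ΔΔCt**: technical replicates are averaged to a mean Ct per
  sample/gene first; the calibrator sample's relative expression is exactly
  1 by construction.
* **Row Z-scores** use the sample standard deviation (n − 1); constant rows
  become zeros with a warning rather than NaNs.

## What the simulators emulate — and what they do not

`simulate_site_reads()` / `simulate_experiment()` draw each read's edited
state Bernoulli(true efficiency), then miscall the observed base uniformly
to one of the other three bases with probability `error_rate`. The uniform
miscall model makes the estimator's bias closed-form — the expected
informative fraction is `ε(1−e) + (1−ε)e/3` over `(1 − 2e/3)` of reads —
which the deep-coverage tests verify (at ε = 0.75, e = 0.001 the estimate
still rounds to 75%). Reads are 50 bp, fully aligned, strand-flagged to
match the site, over a bundled 10-kb synthetic plastome with genes on both
strands so strand handling is always exercised. The bundled 33-site
catalogue uses real plastid gene names and literature-style codon numbering
but synthetic coordinates on that synthetic reference (files named
`synthetic_*`); real analyses must supply a real catalogue and reference.

The reference perturbation preset (`scenario_knockdown33()`) shifts 8 of 33
sites from 0.8 to 0.5 efficiency at 2000× per replicate, two replicates per
condition — effect sizes and depths at which the pooled Fisher test has
essentially full power, so the detected-site count is stable across seeds;
`scenario_null33()` is the matched null used to verify family-wise error
control (the fraction of null datasets with any significant site stays
within the Bonferroni bound; Fisher's discreteness makes it conservative).

What is *not* modelled: position- or context-dependent error profiles,
mapping ambiguity, splicing, duplicate reads, partial read overlap of
paired mates, between-replicate dispersion in editing, and transcript-level
count simulation. Passing tests therefore demonstrate correctness of the
arithmetic and the sampling behaviour under a clean binomial world, not
robustness to alignment artefacts in real libraries.

`simulate_trace()` builds Gaussian peaks (sd = spacing/4) at each basecall,
with the target position's amplitude split between C and T channels by the
true mixture, additive Gaussian noise, and integer-rounded, zero-floored
intensities as processed trace data have. `simulate_count_matrix()` draws
negative-binomial counts with log-normal baseline means (sdlog 0.7 around
the requested median) and dispersion 0.01 by default — the squared
biological CV conventional for genetically identical model-organism
replicates, which matches the replicated inbred-seedling designs this
package emulates; planted fold changes multiply group-B means, and an
optional near-silent block (mean 0.05) exercises the expressed-gene filters.

## Numerical choices and degenerate inputs

* Fisher p-values of saturated support (every table as or less likely than
  observed) are set to exactly 1, avoiding cumulative-sum rounding below 1.
* `NA` handling is explicit everywhere: efficiency `NA` iff no informative
  reads; delta `NA` iff either efficiency is; untestable sites never enter
  the Bonferroni family.
* Catalogue coordinates are 1-based inclusive; BED export is 0-based
  half-open, width-1, sorted.
* All generators scope their RNG with `withr::with_seed`: identical seeds
  give bit-identical output and the caller's RNG stream is untouched.
* Validation problem sizes were chosen to make the test suite a few minutes
  of CPU: exhaustive Fisher equivalence over all 2×2 tables with margins
  ≤ 50; 100 seeded knockdown datasets and 500 seeded null datasets for
  power and FWER; 1000 binomial replicates for estimator unbiasedness; 100
  seeded noisy traces; 1000-gene matrices with 50 planted four-fold genes
  for SDEG recovery.

## Known limitations

Pooled Fisher testing without dispersion modelling (above); the simple SDEG
stand-in; no novel-site discovery (the catalogue is an input); no
mitochondrial catalogue; ab1 support reads the processed channel tags of
ABIF files and the package's own plain-text dialect only — raw CCD data and
exotic ABIF variants are out of scope; and the bundled catalogue's
coordinates are synthetic by design.
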