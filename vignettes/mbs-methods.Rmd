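---
title: "Barcode-family consensus calling: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-family consensus calling: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbscall)
```

## The procedure

`mbscall` implements the four-step molecular-barcoding analysis for
amplicon panels:

1. **Tagging** (simulated): each input molecule receives a random barcode
   before amplification, so all reads derived from one molecule share one
   barcode.
2. **Alignment**: every read pair is placed on the amplicon it matches best
   under ungapped sliding placement; amplicon copies with a catalogued
   indel applied (the exon-19 deletion) act as additional references, which
   is the gapped second pass for known indel hotspots. Mates are merged
   into a single reference-coordinate record; overlapping-mate
   disagreements become `N`.
3. **Family grouping**: exact-match grouping on (barcode, amplicon).
4. **Consensus**: per position, the majority symbol wins if its fraction of
   covering members is at least `min_agreement`; otherwise the position is
   ambiguous and can never support a call. Families smaller than
   `min_family_size` are rejected.

Variant calling then runs identically on either arm: allele frequency is
`100 * alt_support / depth`, with depth denominated in consensus families
(MBS arm) or merged read pairs (raw arm); a call requires frequency
`>= min_af` (boundary inclusive) **and** support `>= min_alt_support`.

### Assumptions

* Reads are reference-anchored amplicon reads in FR orientation; there is
  no split mapping, soft clipping or novel-indel discovery. Novel indels
  outside the catalog are a documented non-goal.
* Barcodes identify molecules exactly. Barcode sequencing errors, which
  fragment families in real data, are not modelled (see Limitations).
* The panel is small enough that full sliding placement per read is cheap
  (the compiled kernel scans every offset of every reference with a prefix
  filter and early exit).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `min_family_size` | 2 | reads | A singleton family cannot outvote its own errors; 2 is the weakest setting that enables error removal. Vendor pipelines do not publish their value, so it is exposed as a knob. |
| `min_agreement` | 0.7 | fraction | Majority threshold per consensus position; ties at exactly the threshold are kept (`>=`). A 1-vs-1 split in a family of two is below 0.7 and yields `N`. |
| `min_af` | 0.5 | % | The design detection limit of the assay; boundary inclusive. |
| `min_alt_support` | 3 | families/reads | A bare percentage threshold at low depth calls single-molecule noise; requiring three independent supporting units suppresses it. |
| `max_mismatch` | 0.2 | fraction | Reads whose best placement still mismatches >20% of bases are dropped and counted. |
| `molecules_per_amplicon` | 2000 | molecules | Sampling depth of the simulated library; at 2,000 molecules a 0.5% variant is ~10 molecules. |
| `barcode_length` | 12 | nt | Birthday bound `n²/(2·4^L)` gives ~0.12 expected collisions per amplicon at 2,000 molecules; length 10 would give ~1.9. |
| `reads_mean`, `reads_dispersion` | 3, Inf | pairs | Read pairs per molecule, negative binomial; `Inf` dispersion = Poisson. |
| `pcr_error_rate` | 1e-4 | /base/duplication | Polymerase errors shared by a random subset of a family. |
| `seq_error_rate` | 0.005 | /base/read | Independent per-read errors. |

## What the simulator emulates — and what it does not

The generator emulates HaloPlex-HS-style barcoded amplicon data: uniform
random barcodes tagging individual molecules, truth variants carried
per-molecule with probability equal to their true fraction, a
Poisson/negative-binomial family-size distribution, PCR errors introduced
at a single pre-sequencing duplication (per-base Bernoulli errors on one of
two copies, each read drawn from either copy), independent per-base
sequencing errors, and constant Q30 qualities. Artifact injection adds
alt-supporting pairs with fresh barcodes at family size one — *systematic*
artifacts in strictly more than half of the samples, *singleton* artifacts
private to one.

It does **not** emulate: position- or context-dependent error spectra,
quality-score variation, barcode sequencing errors, adapter/primer
chemistry, GC or length bias, strand asymmetry (no duplex consensus), or
contamination. Passing tests therefore demonstrate that the consensus,
filtering and statistics machinery behaves as specified under the stated
error model — not that the pipeline is validated on real instrument data.

The published molecule counts, family-size distribution and platform error
rates for the original libraries are not available; the defaults above were
chosen once as realistic for a deep hotspot panel and are exposed in
`sim_config()` rather than hard-coded.

## Numerical and design choices

* **Coordinates** are 0-based half-open everywhere internally; 1-based only
  in the TSV/VCF-dialect reports. Deletions are left-aligned with an
  anchor base.
* **Barcode transport**: the barcode travels in the read name after the
  last `:`, keeping the pipeline two-file; `read_tagged_fastq()` also
  accepts a separate index FASTQ as an alternative dialect.
* **Alignment tie-break**: plain amplicon references are scored before
  indel-applied ones, so a read not spanning the deletion junction is
  interpreted without the deletion.
* **Consensus tie-break**: at exact `min_agreement` the base is kept; exact
  count ties between symbols resolve to the first in A,C,G,T,– order (they
  are below any threshold > 0.5 whenever they matter).
* **"More than half"** in the systematic-artifact filter is strict
  (`> n/2`), and the filter runs before any cross-arm or replicate
  comparison; it is idempotent.
* **Reproducibility denominator** is `matched + orphan`, i.e. the union of
  the two call sets — the convention recovered from the 6/11 = 55%
  arithmetic of replicate comparisons. Reported reproducibility is rounded
  to whole percent, concordance to one decimal.
* **AF difference** for compound-mutation pairs is rounded to two decimals,
  matching the precision at which the allele-frequency table reports it.
* **Exact tests** use the minimum-likelihood two-sided convention (sum of
  probabilities of all margin-fixed tables with probability not exceeding
  the observed, ties included), which reproduces standard software output
  for the bundled cohort tables. Enumeration uses log-factorials; a guard
  refuses tables whose composition bound exceeds 1e7 and points to the
  Monte-Carlo estimator (`freeman_halton_mc()`, Patefield sampling via
  `r2dtable`). The Freeman–Halton routine reduces to the dedicated 2×2
  routine on 2×2 input; both are cross-checked against
  `stats::fisher.test` in the test suite.
* **t-tests from summaries** use the pooled-variance form: the Welch
  statistic is grossly inconsistent with the published age and tumour-size
  p-values, the pooled form reproduces them. From the rounded tumour-size
  summaries the pooled form gives p = 0.0147 where 0.014 was published;
  this is expected round-trip loss, and the report keeps the computed
  value.
* **pStage ambiguity**: the published pStage row is footnoted as an exact
  test but its p-value (0.012) matches the Pearson chi-square
  (exact enumeration gives ≈0.025). `cohort_stats_report()` therefore
  reports both methods for r×2 tables and takes no side.
* **Degenerate inputs**: zero depth, empty call-set pairs, fewer than two
  matched calls, zero expected cells and sub-minimum group sizes all raise
  errors rather than returning silent defaults.

## Study problem sizes

The bundled end-to-end experiments run at sizes chosen to make their
statistical checks meaningful while staying desk-scale: the replicate
experiment uses 6 samples × 2 libraries on the three-amplicon EGFR
ex18/ex20/ex21 subset, 2,000 molecules per amplicon, truth fractions all
≥ 5%, with 4 singleton artifact sites per sample at 1% — the artifact
burden that reproduces the orphan-call behaviour of raw-arm replicate
comparisons, while barcode consensus rejects the same injections as
family-size-1 noise. Allele-fraction recovery runs 20 seeds at fractions
0.005–0.5 and checks each estimate against its 3-SD binomial band; the
artifact-reduction cohort uses 28 samples at 120–300 molecules per
amplicon.

## Known limitations

* No duplex (double-strand) consensus; a PCR error on the sampled strand
  of a single-duplication molecule can reach consensus if it dominates the
  family (bounded by `pcr_error_rate`).
* No barcode-error clustering: in real data, barcode sequencing errors
  create spurious small families; with `min_family_size = 2` most are
  rejected, but family counts would be inflated.
* Insertions can be simulated through the catalog machinery but are not
  called; only catalogued deletions have calling support.
* The exact-test enumerator is designed for cohort-sized tables (hundreds
  of subjects, few cells), not for large sparse tables.
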