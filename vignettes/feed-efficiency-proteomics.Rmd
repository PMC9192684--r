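---
title: "Feed-efficiency phenotyping and adipose proteomics with rfiprot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed-efficiency phenotyping and adipose proteomics with rfiprot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfiprot)
```

## The problem

Identifying feed-efficient dairy cows requires measuring individual dry
matter intake (DMI), which is expensive; molecular markers that separate
efficient from inefficient animals would let herds select without weighing
every feed bunk. `rfiprot` implements the computational chain such a study
needs: score cows by residual feed intake (RFI) from daily performance
records, classify the extremes, quantify adipose-tissue proteins from
label-free peptide intensities, call differentially abundant proteins
(DAPs) between the efficiency groups, test annotation terms for
over-representation, and quantify candidate genes by ΔΔCt qPCR. A seeded
synthetic-data module generates every input with known ground truth so the
whole chain is testable without raw mass-spectrometry data.

## Residual feed intake

Energy-corrected milk (ECM) rescales milk yield to a standard energy
density (3.5% fat, 3.5% protein, 5% lactose milk at 0.714 Mcal/kg):

$$\mathrm{ECM} = \mathrm{milk} \times
  \frac{0.3887\,\mathrm{fat\%} + 0.2356\,\mathrm{protein\%} +
        0.1653\,\mathrm{lactose\%}}{3.1338}$$

Predicted intake follows an NRC-style equation with an early-lactation lag
ramp:

$$\widehat{\mathrm{DMI}} = (0.36\,\mathrm{ECM} + 0.123\,\mathrm{BW}^{0.73})
  \times \left(1 - e^{-0.22\,(\mathrm{DIM}/7 + 5.67)}\right)$$

**Sign of the lag rate.** The coefficient is sometimes printed as
$d = -0.22$ inside $1 - e^{-d(\mathrm{DIM}/7+e)}$, which read literally
gives a large negative factor and negative intakes. We store the rate as a
positive magnitude and compute $1 - e^{-0.22(\mathrm{DIM}/7 + 5.67)}$, the
only reading that yields the (0, 1) intake ramp NRC-style lactation curves
describe. At 110 days in milk the ramp is already at 0.991, so the choice
matters mostly for fresh cows.

RFI is the window mean of actual intake minus the window mean of
*daily* predictions: ECM and predicted DMI are evaluated day by day and
then averaged (the default window is 35 days), so body-weight and
days-in-milk drift inside the window is honoured rather than collapsed
into window-mean inputs. `classify_efficiency()` sorts by RFI and labels
the lowest `floor(0.2 N)` cows HEF (high efficiency — they ate *less* than
predicted) and the highest `floor(0.2 N)` LEF. Ties at a boundary break by
cow id so the assignment is reproducible. The efficiency ratio ECM/DMI is
reported alongside but does not participate in classification: how the two
criteria would jointly rank cows is not specified anywhere we could adopt
a rule from, so the unambiguous RFI ordering decides and ECM/DMI remains a
descriptive column. `regression_rfi()` offers the classic
residual-of-regression variant (intake on ECM and metabolic body weight
$BW^{0.75}$) for users without fitted intake-equation coefficients.

## Label-free quantification

`tic_normalize()` scales each sample so its summed observed intensity
(total ion current) equals the **median** raw TIC across samples — the
median rather than the mean so one aberrant injection cannot drag every
scale factor. `rollup_top3()` estimates protein abundance as the
arithmetic mean of the protein's three most abundant peptides (all of
them when only one or two exist). Peptide rank is **global** — by mean
intensity across all samples — not per sample, so every sample is
quantified from the same peptide set; this is the usual Top3/Hi-3
convention and keeps between-sample ratios unbiased by per-sample rank
flips (a `per_sample = TRUE` switch exists for sensitivity analysis).

Missing values: intensities absent or recorded as 0 in input files are
treated as *missing*, never as zero — label-free pipelines fail to observe
low-abundance peptides rather than measure their absence — and no
imputation is applied. A protein's abundance is missing in a sample only
when all of its selected peptides are missing there.

`pca_summary()` runs sample-level PCA on complete-case proteins, centered
but not unit-scaled (log intensities already share a scale; a `scale.`
flag is provided). Log transforms are base 2 wherever user-visible; the
t statistics are base-invariant.

## Differential abundance

Group comparison keeps two scales deliberately side by side: the fold
change is the **ratio of arithmetic means on the normalized raw scale**,
while the test is Student's two-sample equal-variance t on **log2**
values. Fold changes are displayed in the signed convention
($r$ if $r \ge 1$, else $-1/r$), so a halving is $-2$. A protein is a DAP
when $p \le 0.05$ **and** $|FC| \ge 1.5$, both boundaries inclusive. No
multiple-testing correction enters the default call — the raw-p-plus-FC
filter is the convention this analysis family uses — but a
Benjamini–Hochberg column is always emitted for downstream use. Proteins
with fewer than two observations in a group are reported `untested` rather
than dropped, preserving the quantified universe as the enrichment
background. The volcano ranking uses the standard pi-score
$-\log_{10}(p) \times \log_2 FC$; the name circulates without a fixed
formula, so this definition is a documented convention of the package.
`export_heatmap_matrix()` z-scores each DAP row with the sample (n−1)
standard deviation; zero-variance rows export as zeros with a warning.

## Enrichment

`hypergeom_enrich()` computes the upper-tail probability
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$, for each term of a
GMT annotation file, after intersecting every term with the background.
The default background is the quantified-protein universe — the set
actually at risk of being called differential; a whole-genome background
is equally common in the field, so the argument is exposed rather than
hard-coded. Terms with fewer than 2 background members are skipped (and
listed), since a single-member term can only produce p = K/N trivialities.
Adjustment is Benjamini–Hochberg. `category_fractions()` gives the
pie-chart style per-term percentages used to summarize GO categories;
terms overlap, so percentages do not sum to 100.

## qPCR relative quantification

`select_reference()` picks the reference gene whose raw Ct has the
smallest standard deviation across all samples — "most consistent" made
operational; geNorm/NormFinder-style pairwise metrics are out of scope.
`ddct_rq()` assumes perfect per-cycle doubling (efficiency exactly 2, the
ΔΔCt assumption): per sample $\Delta Ct = Ct_{target} - Ct_{ref}$, raw
$RQ = 2^{-\Delta Ct}$, and the reported RQ divides by the mean raw RQ of
the control group, anchoring the control mean at exactly 1. Technical
replicates are averaged on the Ct scale on input. Group comparison reuses
the equal-variance t-test on log2(RQ) — the two-sample special case of a
GLM on log expression — and reports means on the RQ scale.

## What the synthetic generators emulate

All generators are pure functions of their configuration and seed, and
every truth object is emitted beside the data, never consumed by the
functions under test.

* `simulate_herd()` — 155 cows, 35-day window, days in milk 80–140, body
  weight 590 ± 35 kg, milk 47 ± 5 kg/d, composition around fat 3.05%,
  protein 2.98%, lactose 4.91% (typical mid-lactation Holstein
  magnitudes). Each cow's latent intake offset (SD 2.0 kg/d) is added to
  her predicted intake along with 1.0 kg/d daily noise; with 35 days of
  averaging the offset dominates, which is why estimated RFI recovers the
  true offset ordering at Spearman ≥ 0.9.
* `simulate_peptides()` — 2,260 proteins, truncated-geometric 1–30
  peptides each (mean ≈ 8), 5 vs 5 samples, log-normal abundances and
  peptide response factors, per-sample TIC multipliers (log-SD 0.2),
  within-group CV 20%, and 43 up- / 58 down-spiked proteins with |FC|
  log-uniform in [1.5, 80] applied at the protein level (all peptides of
  a protein shift together, the rollup's own assumption). Missingness
  (10% overall) is left-censored-like: the miss probability decreases
  linearly in intensity rank, so low-abundance peptides vanish
  preferentially while the overall rate stays at the configured value;
  set `missing_rate = 0` for clean oracle tests.
* **Spikes avoid the dominant bulk.** Spiked proteins are drawn from the
  lower half of the base-abundance distribution. TIC normalization is
  only valid when the bulk of the signal mass is non-differential; with
  fold changes reaching 80×, spiking a protein from the log-normal upper
  tail moves the total ion current itself, and the normalizer would then
  shift every null protein and flood the DAP call with false positives.
  Real differential regulatory proteins are rarely the dominant mass
  fraction, so the restriction is also the realistic choice. Under it the
  default design yields DAP counts close to the configured 101 spikes and
  sub-2% false flags among nulls.
* `simulate_annotations()` — random GMT-style terms over the protein
  universe, with one designated term sampling its members at configurable
  odds (default 8×) from a supplied "interesting" set; odds 1 makes it an
  ordinary null term.
* `simulate_ct()` — Ct tables under perfect doubling: a per-sample loading
  shift shared by all genes (which must cancel through the reference), a
  gene-specific stability SD for each reference candidate (GAPDH 0.1
  cycles, the others 0.3–0.6, so the intended reference is recoverable),
  0.2-cycle target noise, and case-group target Cts displaced by
  $-\log_2$(true ratio). Default target ratios are RBM39 0.37, ITGAV
  0.78, STAT2 1.03, DDX39A 0.77 (case/control).

What passing these tests does **not** show about real data: the generators
draw independent log-normal noise — no correlated peptide interference,
retention-time drift, batch structure, shared-peptide protein groups, or
non-ignorable missingness beyond the rank censoring — so recovery rates
here are upper bounds on what equally sized real designs achieve.

## Numerical choices and edge cases

* Zero pooled variance in the t-test is handled explicitly (t = 0, p = 1
  for equal means; ±Inf, p = 0 otherwise), using the same degeneracy
  threshold `t.test()` applies before erroring on constant data.
* `pi_score()` caps p = 0 at the smallest positive double before the log.
* A protein matrix must be strictly positive before `log_transform()`;
  zeros are an upstream missing-value policy error, and the message says
  so.
* Quantile ties in classification and SD ties in reference-gene selection
  break lexicographically; both are reported.
* Post-normalization TICs agree to 1e-6 relative; the conservation test
  asserts exactly that bound.

## Problem sizes used by the test suite

The packaged checks run the full default design once (2,260 proteins,
155 cows) and keep the heavier property suites at reduced but
representative sizes: oracle equivalence enumerates all hypergeometric
configurations to N = 12 and 1,000 random t-test instances; the null
false-positive check uses 2,000 proteins; qPCR recovery averages 100
seeds. These sizes make the suite complete in well under a minute per
module while leaving every statistical conclusion at its stated
tolerance.

## Known limitations

* No imputation, batch correction, moderated (empirical-Bayes) tests or
  mixed-model repeated-measures comparisons; the package tests exactly
  the two-group design it targets.
* Enrichment is over-representation only; depletion and gene-set
  permutation methods are out of scope.
* ΔΔCt assumes amplification efficiency 2 for every gene; no standard
  curves or efficiency correction.
* The pipeline treats the herd table and the proteome samples as separate
  inputs; it does not verify that the 5 + 5 proteome samples correspond to
  classified extreme cows.
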