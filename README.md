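# rfiprot

Feed-efficiency phenotyping and label-free proteomics for dairy cattle.

Selecting feed-efficient dairy cows requires measuring what each cow eats
versus what her size and production predict she should eat. `rfiprot`
implements that phenotyping step and the downstream molecular analysis a
tissue-proteomics study of efficiency needs, as a single tested R
pipeline:

1. **Residual feed intake (RFI)** from daily performance records.
   Energy-corrected milk
   `ECM = milk × (0.3887·fat% + 0.2356·protein% + 0.1653·lactose%) / 3.1338`,
   NRC-style predicted intake
   `DMI_hat = (0.36·ECM + 0.123·BW^0.73) × (1 − exp(−0.22·(DIM/7 + 5.67)))`,
   `RFI = mean(DMI) − mean(DMI_hat)` over a 35-day window, and
   classification of the lowest/highest 20% of RFI as HEF/LEF
   (high/low feed efficiency; low RFI = efficient).
2. **Label-free protein quantification**: total-ion-current normalization
   to the median sample TIC, top-3 peptide rollup (globally ranked
   peptides; the mean of all peptides when only one or two exist), log2
   transform and complete-case PCA quality control.
3. **Differential abundance**: two-sample equal-variance t-tests on log2
   abundances, signed fold changes as ratios of raw-scale arithmetic means
   (`−1/r` when `r < 1`), DAP flag at `p ≤ 0.05` and `|FC| ≥ 1.5` (both
   inclusive), volcano pi-scores `−log10(p)·log2FC`, BH column, z-scored
   heatmap export.
4. **Hypergeometric enrichment** of GMT annotation terms among the DAPs
   against the quantified-protein background, with BH adjustment and
   per-term category fractions.
5. **ΔΔCt qPCR**: reference-gene selection by Ct stability, relative
   quantities normalized so the control-group mean is exactly 1, and
   log-scale group tests.
6. **Seeded synthetic-data generators** (herd, peptide table, annotation
   sets, Ct tables) with ground truth, so every stage has a closed
   verification loop.

## Worked example

```r
library(rfiprot)

## herd scoring: 155 simulated cows, 35-day window
herd   <- simulate_herd(n_cows = 155, seed = 42)
scores <- classify_efficiency(score_cows(herd$records, window_days = 35))
head(scores[, c("cow_id", "mean_dmi", "mean_ecm", "pred_dmi", "rfi",
                "ecm_per_dmi", "class")], 3)
#>   cow_id mean_dmi mean_ecm pred_dmi    rfi ecm_per_dmi class
#> 1 cow059    20.30    38.27    26.42 -6.124       1.886   HEF
#> 2 cow018    20.79    40.24    26.37 -5.570       1.935   HEF
#> 3 cow039    21.70    40.30    26.58 -4.877       1.857   HEF
table(scores$class)
#> HEF LEF MID
#>  31  31  93
```

The three most efficient cows ate 5–6 kg/d less than their milk output,
body weight and lactation stage predict (negative RFI), and the 20%
fraction puts 31 cows in each extreme group of the 155.

```r
## proteome: 2,260 proteins, 5 HEF vs 5 LEF, 101 spiked
sim <- simulate_peptides(seed = 42)
pm  <- rollup_top3(tic_normalize(sim$table)$table)
d   <- diff_abundance(pm, sim$groups)   # case HEF vs control LEF
sum(d$is_dap)
#> [1] 110                                # 4.9% of 2,260 quantified proteins
d[order(d$p)[1:3], c("protein_id", "fc_signed", "p", "pi_score")]
#>  protein_id fc_signed        p pi_score
#>       P0593     -77.4 7.69e-14    -82.3
#>       P0216     -83.7 1.03e-12    -76.6
#>       P1286      33.0 2.66e-12     58.4

## enrichment of the planted annotation term
ann <- simulate_annotations(d$protein_id,
                            sim$truth$protein_id[sim$truth$spiked],
                            seed = 42)
enr <- hypergeom_enrich(d$protein_id[d$is_dap], d$protein_id,
                        ann$annotations)
head(enr[, c("term_id", "N", "K", "n", "k", "p_hyper", "p_adj")], 2)
#>  term_id    N  K   n  k  p_hyper    p_adj
#>     T001 2260 68 110 20 1.20e-11 2.39e-10
#>     T016 2260 65 110  8 1.21e-02 1.21e-01
```

110 proteins pass `p ≤ 0.05, |FC| ≥ 1.5` (the design plants 101 true
spikes); fold changes are signed, so `-77.4` means 77-fold *lower* in HEF.
The planted term T001 tops the enrichment table: 20 of the 110 DAPs carry
it versus 68 of the 2,260 background proteins.

```r
## qPCR: reference selection and relative quantification
ct  <- simulate_ct(seed = 42)           # true HEF/LEF ratio for RBM39: 0.37
sel <- select_reference(ct$records, c("GAPDH", "UXT", "BRPS2", "EIF4E", "ACTB"))
rq  <- ddct_rq(ct$records, "RBM39", sel$reference, control_group = "LEF")
cmp <- compare_rq(rq)
sprintf("reference %s; HEF mean RQ %.2f, LEF mean RQ %.2f, p = %.3f",
        sel$reference, cmp$mean_case, cmp$mean_ctrl, cmp$p)
#> [1] "reference GAPDH; HEF mean RQ 0.34, LEF mean RQ 1.00, p = 0.000"
```

GAPDH is picked as the most Ct-stable candidate, the control (LEF) mean RQ
is 1 by construction, and the recovered HEF mean (0.34) sits at the
configured true ratio of 0.37.

Single formulas work standalone:

```r
compute_ecm(50.3, 2.99, 2.86, 4.86)   # 42.36 kg/d
predict_dmi(40.4, 575.4, 110)         # 27.02 kg/d
```

## Running the whole pipeline

`run_pipeline()` executes rfi → quantify → diffabund → enrich → qpcr from
one config (a list or a YAML/JSON file), writes every table under an
output directory and records MD5 hashes in `manifest.json`; identical
inputs and config reproduce identical hashes. A thin command-line wrapper
lives at `inst/scripts/rfiprot-pipeline.R`:

```sh
Rscript inst/scripts/rfiprot-pipeline.R --config run.yaml
```

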