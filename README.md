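# azasynergy

Analysis toolkit for studies of azacitidine (AZA) drug combinations in
leukemia cells, built around four computational procedures:

1. **Pooled shRNA screen hit calling** — depth normalization,
   per-hairpin log2 fold changes, the 5-of-8 sign-consistency trend
   rule for gene-level hits, and a permutation significance test with
   Benjamini–Hochberg adjustment. Includes the coverage arithmetic for
   screen planning (cells to transduce, maintenance floor).
2. **Chou–Talalay synergy scoring** — median-effect fits
   (fa/fu = (D/Dm)^m, fitted on the linearized scale), IC50 as Dm, and
   the combination index CI = d1/Dx1(fa) + d2/Dx2(fa) at each observed
   combination point, classified into the conventional synergy bands
   (synergism ≤ 0.85, additive 0.9–1.1, antagonism > 1.2, with
   "slight" labels in the gaps).
3. **SLAM-seq nascent RNA** — nascent reads defined by ≥ 2 T>C
   conversions, 3′UTR-to-gene collapsing, and differential nascent
   expression via a negative-binomial score test with trend-shrunk
   moment dispersions (cutoffs FDR ≤ 0.01, |log2FC| ≥ 1).
4. **Nascent proteome (AHA/ClickIT)** — the MaxQuant protein-group
   filter cascade (QC flags → no-AHA background with a 10-fold rescue →
   DMSO-zero), affected-protein calls at ≥ 75% PSM reduction, and
   hypergeometric transcript–protein overlap statistics.

Every stage has a synthetic-data generator with planted ground truth
(`gen_screen_counts()`, `gen_dose_response()` / `gen_combination()`,
`gen_slamseq_counts()`, `gen_protein_groups()`), so the whole pipeline
is exercisable and testable without any external download.
`run_pipeline()` chains everything from one seeded configuration and
writes TSV outputs plus a checksummed manifest.

## Worked example

Screen planning for a 912-gene × 8-hairpin library at 1000× coverage
and 10% infection efficiency:

```r
library(azasynergy)
rc <- required_cells(library_design())
rc$cells_to_transduce_2sf        # 7.3e7  cells to transduce
rc$minimum_maintained_cells_2sf  # 7.3e6  maintenance floor
```

Fit two single agents and score a combination (synthetic data with a
planted CI of 0.6):

```r
aza  <- gen_dose_response(m = 1.4, Dm = 1.0, doses = c(0.25, 0.5, 1, 2, 4),
                          n_replicates = 4, noise_sd = 2, seed = 1,
                          drug_id = "AZA")
c646 <- gen_dose_response(m = 1.1, Dm = 8.0, doses = c(2, 4, 8, 16, 32),
                          n_replicates = 4, noise_sd = 2, seed = 2,
                          drug_id = "C646")
fit_aza  <- fit_median_effect(aza$dose_um,
                              viability_to_fa(aza$pct_live, 100),
                              drug_id = "AZA")
fit_c646 <- fit_median_effect(c646$dose_um,
                              viability_to_fa(c646$pct_live, 100),
                              drug_id = "C646")
fit_aza
#> Median-effect fit [AZA]: m = 1.388, Dm = 1.021, r = 0.9962 (n = 20)
fit_c646
#> Median-effect fit [C646]: m = 1.086, Dm = 8.155, r = 0.9948 (n = 20)

combo <- gen_combination(fit_aza, fit_c646,
                         expand.grid(dose_a_um = c(0.5, 1, 2), dose_b_um = 8),
                         target_ci = 0.6)
tab <- data.frame(dose_a_um = combo$dose_a_um, dose_b_um = combo$dose_b_um,
                  replicate = 1L, pct_live = combo$pct_live)
score_combinations(tab, fit_aza, fit_c646)[, c("dose_a", "dose_b",
                                               "fa_observed", "ci", "label")]
#>   dose_a dose_b fa_observed  ci     label
#> 1    0.5      8       0.742 0.6 synergism
#> 2    1.0      8       0.811 0.6 synergism
#> 3    2.0      8       0.885 0.6 synergism
```

The fitted m and Dm land on the generating parameters within assay
noise (r is the correlation of the linearized fit), and the recovered
CI of 0.6 at every dose pair matches the planted value — synergism
under the band convention.

Call screen hits on a synthetic screen with 10% of genes planted as
depleted at 4-fold:

```r
sim <- gen_screen_counts(screen_sim_config(n_genes = 60, frac_depleted = 0.1,
                                           effect_log2fc = 2, seed = 42))
hits <- analyze_screen(sim$counts, sim$condition, sim$gene_id,
                       n_permutations = 500, seed = 42)
head(hits[order(hits$p_value, hits$avg_log2fc), ], 3)
#>      gene_id n_shrnas_detected n_consistent direction avg_log2fc
#> 37 gene_0037                 8            7  depleted  -1.563080
#> 36 gene_0036                 8            8  depleted  -1.555618
#> 49 gene_0049                 8            7  depleted  -1.503479
#>    passes_trend_rule     p_value        fdr
#> 37              TRUE 0.001996008 0.01497006
#> 36              TRUE 0.001996008 0.01497006
#> 49              TRUE 0.001996008 0.01497006
```

The top-ranked genes are planted depleted genes: 6–8 of their 8
hairpins fall in the treated arm, the average fold change is strongly
negative, and the permutation p-value sits at the resolution floor
1/(1+500).

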