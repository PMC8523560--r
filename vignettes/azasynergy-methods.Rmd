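---
title: "Methods: screen hit calling, synergy scoring, nascent RNA and protein analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen hit calling, synergy scoring, nascent RNA and protein analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azasynergy)
```

azasynergy packages four analysis stages that together characterize how
CBP/p300 inhibition modifies the response of leukemia cells to
azacitidine: a pooled shRNA loss-of-function screen, Chou–Talalay
combination-index scoring of drug pairs, SLAM-seq nascent-transcript
quantification, and a nascent-proteome (AHA pulse) PSM analysis.  Every
stage has a synthetic-data generator with planted ground truth, so the
whole pipeline is testable end to end without any external dataset.
This vignette documents the models, the tunable parameters, and the
design decisions behind each stage.

## Pooled shRNA screen

A pooled screen infects cells with a hairpin library at low titre
(single-copy integration), selects, treats half the population, and
sequences the integrated hairpins in both arms.  Depletion of a gene's
hairpins under treatment means the gene product was required to survive
the drug; enrichment means its loss conferred resistance.

**Coverage arithmetic.**  For a library of $L$ constructs kept at
$R$-fold representation with infection efficiency $e$,
`required_cells()` returns $L R / e$ cells to transduce and a
maintenance floor of $L R$ cells, both also rounded to two significant
figures (the precision at which screen protocols quote them).  The
default design (912 genes × 8 hairpins, 1000×, 10%) gives
$7.3\times10^7$ and $7.3\times10^6$.

**Hit calling.**  Counts are depth-normalized to reads per million;
per-hairpin fold changes are
$\log_2\!\frac{\overline{\mathrm{RPM}}_{trt} + c}{\overline{\mathrm{RPM}}_{ctl} + c}$
with pseudocount $c = 0.5$ RPM (finite fold changes for dropouts,
rank-preserving elsewhere).  A gene is a candidate hit when at least 5
of its 8 hairpins move in the same direction — the *trend rule*.  Fold
changes of exactly zero count toward neither sign; genes detected with
fewer hairpins are scored under the same absolute threshold (a 5-of-6
gene can pass) and are identifiable via `n_shrnas_detected`.  The gene
score averages over **all** detected hairpins, not only the consistent
ones: the consistency requirement selects genes, the average should not
be additionally biased by it.

Note that the trend rule alone is permissive: under the null, 8
independent signs land 5-or-more on one side with probability
$2\sum_{k=5}^{8}\binom{8}{k}2^{-8} \approx 0.73$.  Significance comes
from the accompanying permutation test: the observed statistic is the
absolute mean hairpin log2 fold change, and the null draws same-size
hairpin sets from the whole library without replacement, with the
add-one correction $p = (1 + \#\{|\bar{x}^*| \ge |\bar{x}|\})/(1 + B)$.
A resampling null was chosen over a rotation gene-set test because it
is fully specified by the package itself, exact under exchangeability,
and directly testable against enumeration on small libraries.
Benjamini–Hochberg adjustment is applied across genes.

## Drug-pair synergy (median-effect / combination index)

Viability is mapped to the fraction affected
$f_a = 1 - \mathrm{live}_{trt}/\mathrm{live}_{veh}$, clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-3}$ because the
linearizing transform $\log(f_a/f_u)$ is undefined at the boundaries
(dose–response software conventionally excludes such points).  The
median-effect model $f_a/f_u = (D/D_m)^m$ is fitted by ordinary least
squares of $\log_{10}(f_a/f_u)$ on $\log_{10} D$; $D_m$ doubles as the
IC50 (one model serves both purposes; a four-parameter logistic is out
of scope).  The linear correlation $r$ is reported with every fit and a
non-positive slope is flagged rather than silently used.

The combination index at an observed combined effect is
$\mathrm{CI} = d_1/D_{x,1}(f_a) + d_2/D_{x,2}(f_a)$ with
$D_x = D_m (f_a/f_u)^{1/m}$.  CI is evaluated per observed combination
point (non-constant-ratio design, matching experiments that titrate one
drug against a fixed near-IC50 dose of the other).  With replicated
viability, $f_a$ is computed per replicate, CI on the replicate-mean
$f_a$, and per-replicate CIs are summarized by their standard deviation.
Classification uses the conventional printed bands — synergism up to
0.85 (inclusive), additive 0.9–1.1, antagonism above 1.2 — with the gaps
filled by "slight" labels and all edges configurable; the defaults make
the labels a partition of $(0, \infty)$.

Two identities anchor the implementation: a sham self-combination
(a drug combined with itself at split doses) must give CI = 1 exactly,
and the inverse generator `gen_combination()` followed by
`combination_index()` must recover the target CI; both are enforced to
tight numerical tolerance in the test suite.

## Nascent RNA (SLAM-seq)

4-thiouridine incorporated into nascent transcripts is alkylated so
that reverse transcription misreads it, leaving T>C conversions in
reads from newly synthesized RNA.  `classify_nascent_reads()` counts a
read as nascent when it carries ≥ 2 conversions (one conversion is too
easily produced by sequencing error or an unmasked SNP); reads mapping
to different 3′UTR annotations of one gene are summed by
`collapse_utrs()`.

`differential_nascent()` tests treated against control nascent counts
per gene:

* **Normalization** — median-of-ratios size factors computed on the
  *total* count matrix, not the nascent one: a difference in labelling
  efficiency between samples would otherwise masquerade as global
  repression.
* **Fold change** — $\log_2$ of normalized condition means with a 0.5
  pseudocount.
* **Significance** — a two-sided negative-binomial score test.  The
  per-gene dispersion is a method-of-moments estimate from pooled
  within-condition variances, shrunk toward the fitted mean–dispersion
  trend $\alpha(\mu) = a_0 + a_1/\mu$ with a prior weight of 10
  residual-df equivalents; the null common mean is the root of the NB
  score equation, which makes the statistic exactly antisymmetric under
  swapping condition labels.  This statistic is the package's own,
  deliberately simple and fully documented; it is not intended to agree
  numerically with any particular external differential-expression
  tool.
* **Calling** — genes with BH FDR ≤ 0.01 and $|\log_2\mathrm{FC}| \ge 1$
  are classed up/down; overlap analyses conventionally relax the FDR
  cutoff to 0.1, so both cutoffs are plain parameters.

## Nascent proteome (AHA / ClickIT)

Azidohomoalanine pulse labelling with click-chemistry enrichment yields
MaxQuant protein groups whose PSM counts act as semi-quantitative
abundances of newly synthesized proteins.  The filter cascade runs in a
fixed order: (1) drop groups flagged potential contaminant, reverse
(decoy), or identified only by site; (2) drop groups detected in the
no-AHA background channel unless their mean DMSO PSM count is ≥ 10-fold
the background count (high-abundance proteins inevitably bleed into the
negative control); (3) drop groups with PSM = 0 in any DMSO replicate
(not quantifiable at baseline).  The three criteria are mutually
independent, so the retained set is order-invariant — asserted in the
tests — but the per-stage attrition log is order-dependent and is
reported.

A retained protein is *affected* when its PSM reduction
$1 - \overline{\mathrm{PSM}}_{trt}/\overline{\mathrm{PSM}}_{DMSO}$
reaches 0.75, or when it disappears entirely.  The cutoff is inclusive
(≥ 0.75) by default with a strict-mode flag, since both conventions
appear in practice; replicate aggregation is the arithmetic mean.
`overlap_stats()` reports the intersection of affected-protein genes
with repressed nascent-transcript genes as a percentage of each set,
plus an upper-tail hypergeometric p-value as supplementary output.
Protein-to-gene mapping is taken from an explicit mapping column — no
identifier inference.

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* of each data type,
not the biology:

* **Screen** — negative-binomial counts (dispersion 0.05) around
  per-hairpin baselines that vary log-normally (sd 0.25 on the log2
  scale, emulating cloning/representation noise) with mean 1000
  (≈ 1000× sequencing coverage); planted genes shift
  `frac_active_shrnas` of their hairpins by $\pm$`effect_log2fc` in the
  treated arm only.
* **Dose–response** — exact median-effect curves plus Gaussian noise on
  the percent-live scale, truncated to [0, 100] (the physical bounds of
  a viability assay).
* **SLAM-seq** — per UTR, Poisson numbers of labelled and unlabelled
  reads; each read's conversion count is Binomial(`n_t_sites`, p) with
  p = 0.1 for labelled reads and 0.001 otherwise.  These rates describe
  an efficient labelling chemistry and are simulator parameters, not
  measured values.  Repression scales the labelled-read yield only.
* **Proteome** — Poisson PSM counts, flag and background assignments by
  configured fractions, and a multiplicative treated-condition
  reduction (default 0.1, consistent with the near-disappearance of
  nascent proteins such experiments show).

Not modelled: raw reads and alignment artefacts, SNP-induced
conversions, UTR-length or GC biases, peptide-level identification, and
correlations between stages.  Passing the recovery tests therefore
demonstrates that the *estimators* are correct and calibrated under
their assumed noise models — it does not certify performance on real
data, where alignment and identification artefacts dominate.

All generators take a single seed and derive one RNG sub-stream per
gene or protein, so enlarging a simulation leaves the existing units'
draws unchanged and every table is byte-identical across runs with the
same seed.

## Numerical choices and operating points

* fa clipping $\varepsilon = 10^{-3}$; combination-root tolerance
  1e−12; dispersion floor 1e−8.
* The recovery checks run at deliberately chosen operating points:
  screens of 300 genes at baseline 500 with $|\log_2\mathrm{FC}| = 2$
  on 5 of 8 hairpins; SLAM-seq at 150 genes × 2 UTRs × 600 reads (the
  high-depth regime where per-gene fold-change error is ≈ 0.15);
  proteome recovery at 800 proteins, PSM mean 20, reduction factor 0.1;
  Dm recovery over 500 simulated assays at 6 doses × 4 replicates with
  2%-live noise.  These sizes make every stochastic check reproducible
  in seconds while leaving comfortable statistical margins.
* A sensitivity boundary worth knowing: with 3 Poisson replicates the
  75% PSM-reduction cutoff sits about one resampling standard deviation
  below a planted reduction of 0.8 at PSM mean 20, so recall of such
  borderline proteins is ≈ 80%, rising above 99% at reduction factor
  0.1.  Detection of *borderline* reductions is limited by counting
  noise, not by the implementation.

## Interface

The package is driven from R: each stage is an exported function, and
`run_pipeline()` executes the full synthetic pipeline (simulate →
screen / synergy / SLAM-seq / proteome → overlap) from a
`pipeline_config()` or a YAML file, writing every stage table as TSV
plus a manifest with seeds, row counts and MD5 checksums.  Identical
configuration and seed reproduce identical outputs byte for byte.  A
shell-level wrapper was considered and dropped: the audience for these
analyses works in R, and a function surface composes better with
custom upstream and downstream steps.

## Known limitations

* The permutation null assumes hairpin exchangeability across the
  library; strong global shifts (most of the library depleted) would
  deflate its power, and the trend rule by itself is not a significance
  statement.
* The NB score test uses a normal approximation to the score statistic;
  at very low counts (gene totals below ~10 reads) its p-values become
  conservative.
* CI classification bands are conventions, not inference: no
  uncertainty is attached to a CI value beyond the per-replicate spread.
* The hypergeometric overlap p-value treats gene sets as exchangeable
  draws from the universe and ignores detectability bias between
  transcriptomics and proteomics.
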