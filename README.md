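# snostatus

Most annotated vertebrate snoRNAs are never detected in expression data.
`snostatus` implements a complete pipeline for asking *why*: it computes
sequence, structure and genomic-context features of C/D and H/ACA box
snoRNAs, labels their binary expression status from replicate TPM tables,
trains an ensemble of classifiers to predict that status, and explains the
predictions with Shapley-additive attributions. A self-contained synthetic
cohort generator (genome FASTA + GTF + branchpoints + TPM tables + truth
manifest) exercises the whole chain end to end.

The package is aimed at transcriptomics researchers studying noncoding RNA
biogenesis who want a tested, reusable implementation of these analyses for
their own annotations and abundance data.

## The model in brief

**Features.** For each snoRNA the pipeline derives:

- **Box score** — motifs are located by Hamming distance to their consensus:
  the C box (RUGAUGA, ≤3 mismatches) in the first 20 nt, the D box (CUGA,
  ≤2 mismatches) in the last 20 nt, the internal C′/D′ pair minimising the
  summed distance with D′ upstream of C′, and exact-only H (ANANNA, in
  unpaired hinge positions) and ACA (last 10 nt) motifs. Motifs that cannot
  be identified contribute their full length, so scores range over [0, 22]
  for C/D and {0, 3, 6, 9} for H/ACA; 0 means perfect boxes.
- **Global stability** — the minimum free energy (kcal/mol) of the snoRNA
  fold (ViennaRNA `RNAfold`).
- **Terminal stem** — the 15-nt genomic flanks extended 5 nt into the
  snoRNA body (3 nt at the H/ACA 3′ end, sparing the ACA motif) are
  co-folded (`RNAcofold`); the duplex MFE is the stem stability and a
  length score counts intermolecular paired nucleotides minus gap
  nucleotides inside the stem.
- **Genomic context** — host-gene assignment (same-strand overlap), intron
  ranks and length, exon distances, distance from the snoRNA 3′ end to the
  highest-probability branchpoint, plus categorical host metadata.

**Labels.** A gene is *expressed* iff its replicate-averaged abundance
exceeds 1 TPM in at least one tissue.

**Prediction.** Features are one-hot encoded (the repeated `intergenic`
indicator kept once), split 10/80/10 into tuning/training/test sets across
10 stratified iterations whose test sets partition all snoRNAs, and
standardised with training-set statistics. Five classifier families are
grid-tuned (stratified 3-fold CV) and trained per iteration; the final call
per snoRNA is the majority vote of logistic regression, SVM and random
forest (kNN and gradient boosting are fitted for comparison but excluded
from the vote by default, as they overfit). Cross-species prediction reuses
a human-trained model and human training-set scaling on the top-4 feature
set.

**Interpretation.** Shapley-additive contributions (exact closed form for
linear models, exact coalition enumeration for small models, antithetic
permutation sampling otherwise — additive to machine precision in every
mode) are aggregated into per-feature predictive ranks across models and
iterations, per-snoRNA decision traces, and motif frequency logos with
cumulative Shannon entropies.

## Worked example

```r
library(snostatus)

# generate a 200-snoRNA synthetic cohort and analyse it end to end
cfg <- synthetic_config(n_snornas = 200, seed = 42)
generate_cohort(cfg, "cohort")
res <- run_cohort_pipeline("cohort", "results", seed = 42)

glance(res$fit)
#> # A tibble: 1 × 6
#>       n accuracy sensitivity specificity   auc proportion_expressed
#>   <int>    <dbl>       <dbl>       <dbl> <dbl>                <dbl>
#> 1   200    0.855       0.803       0.884 0.893                 0.36

head(res$rank_summary, 5)
#> # A tibble: 5 × 5
#>   feature                 median_rank mean_rank min_rank max_rank
#>   <chr>                         <dbl>     <dbl>    <int>    <int>
#> 1 host_expressed                  1        1.4         1        5
#> 2 host_not_expressed              2        3.53        1       16
#> 3 terminal_stem_stability         4        6.73        3       20
#> 4 box_score                       5.5      7.53        3       23
#> 5 noncoding                       8.5     10.8         3       22
```

Each snoRNA is predicted exactly once across the 10 test sets; `glance()`
summarises the pooled ensemble calls (accuracy, sensitivity, specificity,
trapezoidal AUC and the predicted expressed proportion). The rank summary
aggregates per-(model, iteration) predictive ranks: the ensemble predicts
held-out status with AUC ≈ 0.89 and the strongest generative drivers of
this synthetic cohort — host expression, terminal stem stability and box
score — surface at the top of the ranking (at n = 200 the weaker
global-stability effect is still rank-noisy; it joins the top five on
larger cohorts, as the test suite verifies at n = 2,000). `plot_roc(res$fit)` and `plot_rank_distribution(res$ranks)` draw the
corresponding figures, and `tidy(res$fit)` returns the per-snoRNA
prediction records with confusion categories.

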