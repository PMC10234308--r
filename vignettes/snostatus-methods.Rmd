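---
title: "Predicting snoRNA expression status: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting snoRNA expression status: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`snostatus` treats snoRNA expression as a binary phenotype — *expressed* or
*not expressed* in a tissue panel — and asks which intrinsic and contextual
features of a snoRNA locus predict it. This vignette documents the model and
procedure, the tunable parameters and their defaults, what the synthetic
cohort generator does and does not emulate, the numerical conventions, and
the design decisions taken where the problem was genuinely open.

## The feature model

### Box score

C/D box snoRNAs carry C (RUGAUGA, R a purine) and D (CUGA) boxes near their
termini plus internal C′/D′ copies; H/ACA box snoRNAs carry an H box
(ANANNA) in the single-stranded hinge between their two hairpins and an ACA
triplet canonically 3 nt from the 3′ end. The box score sums the Hamming
distances of the located motifs to their consensus; motifs that cannot be
located contribute their full length:

* C box: searched within the first 20 nt, exact matches preferred, up to 3
  mismatches tolerated, otherwise absent (contributing 7). Equal-distance
  candidates resolve to the one nearest the 5′ end.
* D box: last 20 nt, up to 2 mismatches (otherwise contributing 4), ties to
  the 3′-most candidate.
* C′/D′: the interior (21st to 21st-to-last nucleotide) is scanned for the
  ordered, non-overlapping D′-then-C′ pair minimising the summed distance.
  No mismatch cap applies; an interior shorter than 11 nt leaves both
  unfound (contributing 11). Ties resolve lexicographically on (D′ offset,
  C′ offset). The terminal 20-nt exclusion prevents the C′/D′ search from
  re-detecting the terminal C/D boxes.
* H box: exact matches only, and all six motif positions must be unpaired
  in the minimum-free-energy structure — the operational reading of
  "hinge". Without a structure the search falls back to the interior
  window, with a warning.
* ACA: exact matches in the last 10 nt, 3′-most occurrence.

C/D scores therefore range over [0, 22] and H/ACA scores over
{0, 3, 6, 9}; 0 means perfect boxes. The maximum C/D score observed on
random sequences stays below the degenerate-case bound of 22 because the
uncapped C′/D′ search almost always finds a partially matching pair.

### Folding features

Global stability is the MFE (kcal/mol) of the snoRNA fold. The terminal
stem co-folds two strands: the 15-nt upstream flank plus the first 5
snoRNA nucleotides, and the last 5 (C/D) or 3 (H/ACA) snoRNA nucleotides
plus the 15-nt downstream flank — the shorter H/ACA extension spares the
ACA motif, which is assumed not to pair in the stem. Stem stability is the
co-fold MFE; the stem length score counts nucleotides in intermolecular
pairs (two per pair by default; a `pairs` mode counts one) minus gap
nucleotides. "Gap" is operationalised as unpaired positions strictly
between the outermost and innermost intermolecular pair on each strand;
positions involved in intramolecular pairs within that span count neither
as stem nor as gap. This reading makes the score decrease monotonically as
gaps are inserted into a fixed pairing, matching its intent as an
approximate stem length. Both the counting mode and the folding engine are
configurable; the default engine shells out to ViennaRNA
(`RNAfold`/`RNAcofold`, default parameters, batched), and a built-in
maximum-complementarity scorer (pair weights GC = 3, AU = 2, GU = 1,
energy = −Σweights/2) exists for engine-free environments — it is not a
thermodynamic model and its magnitudes are not comparable.

### Genomic context

Coordinates are 0-based half-open internally; GTF I/O converts at the
boundary, eliminating off-by-one ambiguity from distance arithmetic. A host
gene is a same-strand overlapping gene; with several candidates the
smallest gene fully containing the snoRNA wins (then the smallest
overlapping), a deterministic rule the data format does not itself dictate.
Intron context uses, among host transcripts whose intron fully contains the
snoRNA, the one with the smallest containing intron (ties by transcript
id): total introns, intron length, intron rank from each end, relative 3′
rank, and exon distances measured on the coding strand. These
transcript-choice and multi-host rules are deliberate determinism choices
on questions the underlying data leave open. Exon-overlapping snoRNAs are
flagged and carry missing context. Branchpoint distance is the non-negative
magnitude between the snoRNA 3′ end and the highest-probability branchpoint
in its intron (probability ties to the nearer one); branchpoints are
consumed as input, not predicted.

## Labels

A gene is expressed iff its replicate-averaged abundance is strictly
greater than 1 TPM in at least one tissue. Host status
(`host_expressed` / `host_not_expressed` / `intergenic`) applies the same
rule to a host-level abundance table, which may come from an independent
study; hosts absent from the table are treated as not detected (with a
warning) rather than erroring.

## Classification protocol

One-hot encoding is fit on the full table before splitting (so category
levels are global); every host-related parent category regenerates an
`intergenic` indicator, kept once. Ten stratified splits assign each snoRNA
to exactly one test set (10%), with the remainder split 1:8 into tuning and
training; standardisation (population variance; binary columns included) is
fit on training rows only and applied to all other rows — including other
species' rows, which are scaled with the human training statistics.
Zero-variance columns scale to 0. Intron features that are structurally
missing for intergenic snoRNAs are imputed with raw zeros before scaling by
default (`impute = "median"` is available); the intergenic indicator
carries the distinction either way.

Grids for the five families are necessarily package defaults (the original
search spaces are not recoverable): ridge logistic regression over 5
log-spaced penalties, SVM kernel × cost, random forest tree count × node
size (3×3), kNN k ∈ {3, 5, 11}, gradient boosting rounds × depth (3×3) —
all user-overridable via `model_specs()`. Tuning is exhaustive grid search
by mean accuracy over stratified 3-fold CV, ties to the earlier grid row;
on very small tuning sets the fold count drops to the minority-class count,
and below 2 the first grid point is used with a warning. The ensemble call
is the majority of logistic regression, SVM and random forest; kNN and
gradient boosting are fitted and reported but excluded from the vote by
default because they overfit (train/test accuracy gap), a finding the
configuration can revisit. The ensemble score used for its ROC curve is
the unweighted mean of the three members' positive-class scores (each
family's score is first mapped monotonically into [0, 1]); per-family ROC
curves are unaffected by these monotone maps. AUC is computed by trapezoid
over the threshold sweep. The positive class is *expressed* throughout.
A single master seed derives all per-iteration seeds by fixed offsets, so
the whole protocol — splits, tuning folds, fits, attributions — regenerates
byte-identically.

## Shapley attribution

Contributions are computed on each model's decision score: the linear link
for logistic regression (exact closed form, `w_j (x_j − mean(background))`)
and the positive-class score otherwise, via exact coalition enumeration up
to 8 features and antithetic permutation sampling beyond. Permutation
sampling telescopes exactly, so the additivity identity
`baseline + Σ contributions = output` holds to machine precision in every
mode — this is asserted, not approximated. The background is the model's
own training rows, capped at 100 (sampled under the master seed). Ranks
are computed per (model, iteration) from the mean absolute contribution,
rank 1 the largest, ties by feature name; pooling uses both classes'
attributions in absolute value.

One-hot encoding splits a categorical feature into complementary
indicator columns that necessarily share — and therefore dilute — one
underlying signal's credit: in a cohort where host expression drives
status, `host_expressed`, `host_not_expressed` and `intergenic` all rank
highly while each alone under-states the driver. `rank_features()`
therefore accepts a column-to-parent grouping (`feature_groups()`):
because Shapley values are additive, summing a snoRNA's signed
contributions within a block yields the exact attribution of the grouped
feature, and ranks can be computed at that granularity. Column-level
ranks remain the default output; grouped ranks are what the package's
driver-recovery checks use, since the generative drivers live at parent
granularity. The shared `intergenic` indicator is grouped with host
expression, of which it is the third state. Decision traces order a single snoRNA's
contributions by magnitude. Logo statistics return position frequency
matrices, per-position Shannon entropies (bits) and their cumulative sum,
plus the proportion of snoRNAs in which the motif was found; a
Kolmogorov–Smirnov utility compares position-frequency vectors between
groups.

## The synthetic cohort generator

The generator emits a complete, self-consistent study: one chromosome per
snoRNA carrying either a host gene (2–8 introns, exons 80–200 nt, the
hosting intron sized to the planted upstream/downstream distances) or a
bare intergenic locus; planted motifs at canonical positions (C at offset
3–6, D ending 3–6 nt from the 3′ end, an interior D′/C′ pair, mid-sequence
H, ACA 3 nt from the 3′ end) mutated at a truncated-geometric number of
positions per motif; flanks whose first downstream nucleotides reverse-
complement the last upstream ones over an engineered block of 0–15 nt; a
branchpoint adenosine 18–44 nt upstream of the 3′ splice site; and
C/U-rich background composition to limit accidental motifs.

Expression status is generated from *measured* features — the pipeline is
run on the emitted files — so imperfect planting cannot decouple features
from labels: P(expressed) = logistic(s·β·z + b), with z the within-cohort
standardised box score, global stability, stem stability and host
expression. The coefficients are per-SD effects (−0.8, −0.3, −0.5, +1.5)
with steepness s = 2 and the intercept solved so the mean probability hits
the target expressed fraction (default 0.35, near the ~31% seen in real
annotation-wide surveys); labels are then flipped at the noise rate
(default 0.05). Two points deserve emphasis. First, a type-split stability
coefficient (positive for C/D, negative for H/ACA — the nuance real data
show) makes the pooled linear effect of stability cancel almost exactly at
a 70/30 type mix, so linear classifiers provably cannot recover stability
as a driver and its predictive rank collapses; since the generator's
purpose is a cohort whose known drivers are recoverable, the default uses
a single negative coefficient (stability promotes expression, the dominant
direction), and the type-specific nuance is left to users via `beta`.
Second, the coefficients act on standardised features rather than raw
kcal/mol and Hamming units: on raw scales the fixed ±1.5-logit host effect
is negligible against sequence features whose raw spread is tens of units,
which again would make a known driver unrecoverable. The steepness default
places cohort discriminability in the high-0.8 AUC range, comparable to
published annotation-wide classifiers, while label noise keeps it away
from 1.

Expressed genes draw lognormal tissue means (μ = 2, σ = 1 on the log
scale — arbitrary magnitudes; only the >1 TPM semantics matter) conditioned
on exceeding 1 TPM in at least one of 7 tissues; non-expressed genes draw
uniform means below 1 TPM. Replicates (3 per tissue) multiply the tissue
mean by lognormal noise renormalised so the replicate mean equals the
tissue mean exactly, guaranteeing the emitted tables round-trip to the
generated labels. A host-level TPM table encodes the sampled host statuses
the same way. Everything is deterministic given the seed, file for file.

What the generator does *not* emulate: realistic intergenic sequence
composition, paralogous snoRNA families and their shared sequence,
alternative isoform structure, read-level noise or mapping artefacts, and
correlated categorical metadata (targets, promoter type and NMD flags are
sampled independently of the label). Passing tests on synthetic cohorts
therefore demonstrate that the pipeline's machinery is correct and that
known drivers are recoverable under the stated generative model — not that
the same features drive any particular real data set.

## Problem sizes and numerics

The test suite exercises oracle equivalence on 500 random sequences
(motif search), 120 (C′/D′ enumeration) and 200 co-folded duplexes; the
parameter-recovery study uses a 2,000-snoRNA cohort with 10 iterations and
a 10-row attribution background with one antithetic permutation pair per
instance — sizes chosen to give stable rank estimates from ~2,000 attributed
test rows per family. The smoke determinism study uses 50 snoRNAs.
Degenerate inputs are handled explicitly: sequences shorter than a motif
yield not-found hits; interiors shorter than 11 nt leave C′/D′ unfound;
empty branchpoint sets, exon-overlapping snoRNAs and intergenic loci
propagate missing context; single-class truth yields NA AUC; zero-variance
columns scale to zero. All tie-breaks (motif candidates, transcript choice,
probability ties, grid order, rank ties) are total orders, making every
output deterministic under a fixed seed.

## Known limitations

Single-lambda ridge fits are evaluated at the requested penalty on a short
descending path (a glmnet reliability requirement). The SVM score is a
sigmoid-squashed decision value, not a calibrated probability — adequate
for voting, ROC and attribution, all of which are monotone-invariant per
model. kNN stores its training set rather than a parametric fit. The
complementarity fallback engine maximises weighted pairing and should not
be used for quantitative stability comparisons. Cross-species transfer
assumes the species' features are computed identically and scaled with the
training statistics of the source species; no domain adaptation is
attempted.
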