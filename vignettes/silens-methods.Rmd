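---
title: "silens: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{silens: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

silens annotates noncoding single-nucleotide variants with silencer and
enhancer activity learned from DNA sequence, and aggregates those
annotations into locus-level disease statistics and cell-type regression
features. This vignette documents the model, the procedures, the tunable
parameters, and the design decisions that were genuinely open.

## Candidate elements from chromatin marks

Regulatory candidates are called per sample from three peak sets:

* **Enhancers** — DNase accessibility peaks that overlap an H3K27ac peak
  (any overlap, >= 1 bp) and have no H3K27me3 peak intersecting the 400-bp
  window centred on the DNase-peak midpoint.
* **Silencers** — DNase peaks that overlap an H3K27me3 peak but carry no
  H3K27ac in their central 400 bp, together with H3K27me3 peaks that
  overlap neither DNase nor H3K27ac peaks. H3K27me3 alone is a weak
  silencer proxy; requiring accessibility or full isolation is what makes
  the class specific.

Each element becomes a 1-kb window about the originating peak midpoint
(`floor((start0 + end0)/2)` for even-length peaks). Windows overlapping a
promoter (TSS +/- 1 kb by default — the extent is not fixed by the
underlying data conventions, so it is a configurable parameter) or an exon
of an annotated gene are removed, as are windows crossing a chromosome
edge (dropped rather than padded: padding would fabricate sequence).

Two clauses of the silencer definition are ambiguous in the source
material and were fixed as follows: the "carries H3K27me3" clause is
evaluated on the whole DNase peak (the central-400-bp restriction applies
only to the *exclusion* marks, which is the literal reading), and
cell-type context labels use binary peak overlap with no read-count
weighting (no quantitative rule is given).

After pooling samples, redundancy is resolved by visiting elements in a
seeded random order and keeping an element unless it overlaps an
already-kept element by strictly more than 600 bp. Random retention (as
opposed to merging or re-centring) preserves the alignment between window
midpoints and peak midpoints; the seeded greedy visit is a deterministic
realisation of "retain one at random" for chained overlap groups, which
have no canonical unique solution. Controls are drawn from accessibility
peaks of unrelated biosamples, re-windowed to 1 kb, excluding anything
that overlaps a candidate element or the defining peak sets; roughly ten
controls per positive match the 1:9 evaluation mixture used throughout.

Chromosomes 7 and 8 are held out from training entirely and used only for
evaluation, so no test window shares local sequence context with training
data.

## The multitask sequence model

The scoring model is a 1-D convolutional network over one-hot DNA
(L x 4, columns A/C/G/T, N rows all-zero):

1. convolution, 64 kernels, width 4, stride 1 (ReLU);
2. max pooling, width 3, stride 2;
3. dropout 0.2;
4. convolution, 128 kernels, width 3, stride 1 (ReLU);
5. dropout 0.2;
6. dense 100, sigmoid;
7. dense 50, sigmoid;
8. per-context output groups with 3-way softmax over
   (enhancer, silencer, control) for nine cellular contexts — the bulk
   tissue plus eight brain cell types.

The loss is the sum over the nine contexts of the 3-class cross entropy.
Two output topologies are provided because the layer description admits
both: `shared_control_19` (default), where each context owns an enhancer
and a silencer logit and all contexts share one control logit (19 output
nodes), and `per_context_27` with an independent 3-node group per context.
Neither is asserted to be the "true" topology; they train to similar
quality on synthetic data.

The activation of the convolution layers is not specified in the source
description; ReLU is used, the standard choice for convolutional motif
detectors. The model is single-phase, operating on one-hot sequence only:
a large pre-trained epigenome phase is out of scope here, and the
enumerated stack above fully specifies the sequence-level network.

### Optimisation

No optimiser settings are published for this architecture, so the
defaults are the package's own, chosen once from optimisation diagnostics
on synthetic data and then frozen:

* adaptive-moment estimation (Adam), mini-batches of 64, ten epochs,
  seeded shuffling and dropout so that runs are reproducible under fixed
  BLAS threading;
* learning rate 2e-4 for the dense stack. The flatten layer feeds 63,488
  inputs into 100 sigmoid units; at the conventional 1e-3, Adam's
  per-parameter steps move each pre-activation by several units per
  update, saturating the sigmoids immediately (the network never leaves
  the uniform-prediction plateau). Rates at or below ~2e-4 train stably.
* a 3x learning-rate multiplier for the two convolution layers, plus
  optional decoupled weight decay on the dense weight matrices. Both
  address the same failure mode at desk scale: the 6.35-million-parameter
  dense stack can memorise a few thousand training windows faster than
  the convolution kernels learn motifs, which yields excellent training
  loss and chance-level held-out performance. The conv multiplier lets
  motif detectors form early; weight decay additionally penalises
  position-specific (memorising) solutions — for equal fit, weights
  spread evenly over positions have far smaller L2 norm.
* optional reverse-complement augmentation (each training window also
  presented reverse-complemented, labels copied), the standard
  augmentation for strand-symmetric regulatory signals;
* an output head initialised at five times the Glorot scale. This is the
  load-bearing optimisation choice: at standard scale, whether the
  network ever leaves the uniform-prediction plateau within ten epochs
  depends on the initialisation seed (the head's random projection of
  trunk features is often too weak to couple the class error back into
  the trunk); the wider head makes the coupling reliable across seeds, at
  the cost of two to three early epochs spent recalibrating the head.
* optional early stopping on validation loss (patience 5, best weights
  kept) when a validation split is supplied. The pipeline default trains
  on the full training partition for the fixed epoch budget instead:
  the class-weighted cross entropy is a poor selector of ranking quality
  here (it keeps drifting after discrimination has stabilised), and the
  chromosome holdout is never used for model selection either way.
* per-context class weights inverse to class frequency (the 1:1:10
  positive:control imbalance would otherwise dominate the loss); a
  `"none"` option disables this.

Class balancing, like every training choice above, lives in
`model_config()` and is recorded in the saved checkpoint.

## Calibration and variant scores

Raw softmax scores are calibrated per context and channel against the
held-out control elements: `FPR(s)` is the fraction of control scores at
least `s`, floored at `1/(N+1)` (add-one estimate) so that `log10 FPR` is
always finite. FPR is computed over controls only; this makes it
invariant to the positive fraction of whatever evaluation mixture the
controls came from. Thresholds `c_e,i` and `c_s,i` are the smallest
scores with FPR at or below 0.05.

A variant is classified by a three-branch rule on its 1-kb
reference-allele window: inside a repressive-mark peak it is a silencer
variant if its silencer score exceeds `c_s,i` in at least one context;
inside an active-mark peak, an enhancer variant by the symmetric rule;
inside a bare DNase peak it must exceed one channel's threshold in some
context while staying below the other channel's threshold in *all*
contexts. "Exceeds" is strict.

The allelic score is, per context,

$$\Delta = (\log_{10} FPR_e(\mathrm{ref}) - \log_{10} FPR_e(\mathrm{alt}))
 + (\log_{10} FPR_s(\mathrm{alt}) - \log_{10} FPR_s(\mathrm{ref}))$$

oriented so that an alternate allele that gains activation or loses
repression is positive. The formula as conventionally printed has the
enhancer difference in the opposite order, which contradicts its own
stated sign semantics; the implementation follows the semantics and keeps
the literal form behind `literal_sign = TRUE`. Delta-activity is exactly
antisymmetric under allele swap, zero for identical windows, and finite
everywhere thanks to the FPR floor. Significance is a two-tailed 5%
quantile call against a background panel of delta values from the same
model over a large variant set, with the percentiles taken over the
pooled signed distribution (not per sign).

## Locus statistics

Gene loci tile each chromosome: gene body plus flanking intergenic
sequence, split at the midpoint between adjacent gene bodies (the flank
rule is not specified by the source material; the midpoint split is the
parameter-free choice that makes loci a partition). Runs of adjacent
gene loci that each contain an associated variant are merged; a merged
region is kept as a susceptibility locus when its variant count beats the
genome-wide average by an exact binomial upper-tail test at p < 0.003
(the test behind this printed cut-off is not named; the same binomial
form as the class tests is assumed). With `pi0` the locus-length fraction
of the genome, silencer enrichment is
`P_S = P(X >= n_S), X ~ Bin(N_S, pi0)`, and similarly `P_E`; classes are
SL (only `P_S < 0.005`), EN (only `P_E`), ENSL (both), UC (neither).
Promoter/exon enrichment (`P_ep`, cut 0.05) is annotated but does not
change the class — the alternative (excluding such loci from
classification) is not taken because nothing in the definitions requires
it. Genome size is always the sum of the supplied chromosome lengths, so
synthetic genomes work unchanged. Cross-disease overlap uses the same
binomial form with the genome-wide associated fraction `w_d` supplied by
the user (deriving `w_d` by linkage-disequilibrium expansion of GWAS
catalogues is out of scope).

The two-sided enrichment test used for figure-style comparisons is the
exact minimum-likelihood-sum binomial test, i.e. `stats::binom.test`.

## Regulatory impact and subtype regression

Accessibility peaks re-windowed to 1 kb and scored by the model get, per
cell-type context,

$$RI^c = I_E \cdot (-\log_{10} FPR_E^c) - I_S \cdot (-\log_{10} FPR_s^c)$$

with `I_E`/`I_S` indicating overlap with tissue H3K27ac/H3K27me3 peaks.
The orientation again follows the stated semantics (enhancer evidence
positive); the literal printed form is the negation and is available
behind a flag. A gene's regulatory domain is the 200-kb window around its
TSS plus its introns; gene-level RI is the sum over peaks in the domain,
then each cell-type column is scaled by its maximum *absolute* value —
plain division by the maximum would be undefined for all-negative RI
columns, so the sign-preserving variant is used. Scaling happens once on
the full table, before any train/test split, matching the global "scaled
to a maximum of 1" description; the mild leakage this implies is noted
and accepted as the described procedure.

Subtype expression is regressed on the cell-type columns with the lasso
at a fixed penalty of 1e-4 under the `1/(2n)` squared-error objective
(identical to a scikit-learn `Lasso(alpha = 1e-4)`), fitted by
`glmnet` without standardisation. Per trial a fresh 10-fold gene
partition is drawn; the trial RMSE is the mean over held-out folds, the
reported RMSE the mean over trials, and the reported weights the average
over all fold-models. The shuffled baseline repeats the identical
procedure with the response permuted each trial.

## The synthetic-data generator

Every stage is testable without external downloads because the generator
plants known truth:

* **Genome** — i.i.d. bases at GC 0.41 on three 8-Mb chromosomes, one of
  them named chr7 so the default holdout is non-empty. (Three 2-Mb
  chromosomes cannot hold the default element counts at the minimum
  element spacing; 8 Mb is the smallest round size that does, with
  headroom.)
* **Elements** — 800 enhancers, 800 silencers and 8,000 background-pool
  controls on a 2.4-kb centre grid (windows never overlap, so
  deduplication is the identity by construction — deduplication gets its
  own adversarial fixtures in the unit tests). Enhancers carry 3-6 copies
  of activator motifs, silencers 3-6 repressor copies, controls none; the
  motif sets are disjoint 9-10-mers. Peak files are emitted so that the
  element-construction rules recover the truth exactly, with silencers
  split between the accessible (DNase + H3K27me3) and isolated-H3K27me3
  definitions. Silencer windows are re-drawn at slightly lower GC than
  the genome, mimicking the lower GC of repressed elements in real data;
  this is cosmetic and never asserted. Cell-type accessibility peaks
  cover each element with probability 0.45 per cell type.
* **Variants** — 400 disrupting variants substitute the central base of a
  planted motif copy (activation loss in enhancers, repression loss in
  silencers; ground-truth delta-activity signs -1 and +1), 400 neutral
  variants sit inside elements at least 50 bp from any motif; all carry
  association p-values below 1e-5. Substitutions are complementary
  transversions (A to T, C to G), which destroy the exact-match motif
  while leaving window GC unchanged — a GC-shifting allele would mix a
  compositional effect of its own into the planted direction label,
  since silencer windows legitimately trend AT-rich.
* **Locus scenario** — equally sized genes on one chromosome with
  designated, isolated single-gene susceptibility loci of each class; the
  generator verifies at construction that enriched channels beat the
  class cut by 10x and background channels miss it by 10x, and fails
  loudly otherwise.
* **Subtype expression** — `y = Xw + e` from planted mixed-sign weights
  and Gaussian noise (sd 0.05), scaled to maximum absolute value 1.

What passing on this data does *not* show: real regulatory grammar is
degenerate (position-weight matrices, not exact k-mers), marks are noisy
and correlated with GC and repeats, and real effect sizes are far
smaller. The synthetic results certify the machinery — construction
rules, training loop, calibration, classification arithmetic — not
biological performance.

## Problem sizes and runtime

The default end-to-end run (`run_pipeline()`) trains on roughly 8,600
windows for six epochs and evaluates on the chr7 holdout; on one CPU core
the whole pipeline — simulation through subtype regression — completes in
around ten minutes, with training dominating. The subtype stage uses
2,000 genes, 7 cell-type features and 10-fold x 20 trials; the lasso at
one fixed penalty makes each fold-fit a few milliseconds, so the printed
100-trial protocol is also cheap (`fit_subtype_model(trials = 100)`) —
20 trials is the pipeline default purely because the estimate is already
stable there.

## Known limitations

* The model is sequence-only and single-phase; without large-scale
  pre-training it should not be expected to reach published accuracy on
  real epigenomes.
* Deduplication resolves chained overlap groups greedily in seeded random
  order; a different seed retains a different (equally valid) element.
* The empirical FPR is a step function; scores between adjacent control
  order statistics share a value, so delta-activity is quantised at
  resolution `~1/N` of the control set.
* Multi-allelic variants and indels are out of scope throughout.
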