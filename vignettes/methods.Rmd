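---
title: "Modelling siRNA efficacy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling siRNA efficacy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sirnadesign)
```

## The problem

A small interfering RNA (siRNA) silences a gene when its guide (antisense)
strand loads into RISC and directs cleavage of the complementary mRNA.
Measured knockdown varies enormously between guides against the same
transcript, and the determinants are a mixture of thermodynamics (duplex
stability, the 5′/3′ end-stability differential that governs which strand
RISC keeps), position-specific base preferences, and the local mRNA context
of the target site. `sirnadesign` models normalized knockdown efficacy in
[0, 1] from the 19-nt guide and a 57-nt window of its target, and wraps the
predictor in a design pipeline that scans a transcript, screens candidates,
and ranks them.

## Data model

Guides are harmonized to 19 nt: native 19-mers pass through, 21-mers lose
the two 3′-overhang nucleotides at positions 20–21, anything else is
rejected. The target site is the exact reverse complement of the guide on
the mRNA sense strand; the context window extends 19 nt on each side of the
19-nt site (57 nt total), padding with the symbol `X` when the site is
closer than 19 nt to a transcript end. All coordinates are 0-based,
half-open.

Inhibition values are normalized per source dataset by the dataset maximum,
so efficacy is a fraction of the best knockdown observed in that screen;
records at or above 70% of the maximum are labelled positive. Ties at the
threshold count as positive (the threshold rule alone does not fix tie
handling; the inclusive reading is this package's convention). For
cross-dataset protocols, training records with more than 80% global-alignment
identity (Needleman–Wunsch, match 1 / mismatch 0 / gap −1, identity =
matches / alignment length including gaps, tie-break diagonal > up > left)
to any test record are removed — strictly greater, so a pair at exactly 80%
is retained.

## Feature channels

**Thermodynamics.** The nearest-neighbor model of RNA duplex stability is
additive over dinucleotide stacks. We vendored the Xia et al. (1998)
Watson–Crick ΔG°37 parameters (10 unique stacks, reverse-complement
symmetric, initiation +4.09 kcal/mol, +0.45 kcal/mol per AU-closed end) as a
versioned TSV. The 26-feature vector per guide comprises: whole-duplex ΔG;
the guide's own single-strand minimum free energy (pluggable engine — the
ViennaRNA `RNAfold` binary when present, otherwise a naive single-stem scan
that reports 0 for sequences without a self-complementary ≥4-mer); mean
stack ΔG of the two terminal stacks at each end; their difference
(`asymmetry_ddg = end5 − end3`, the strand-selection asymmetry signal — it
flips sign exactly under reverse complement, which is the operation that
physically swaps the duplex ends); GC fraction; and the 4 + 16 mono- and
dinucleotide fractions. Two terminal stacks is the standard 2-bp end
differential of the siRNA asymmetry literature; it is configurable.

**Per-position embeddings.** A pretrained RNA language-model adapter serves
L×640 matrices from a cache of pre-computed per-sequence files (plain-text
array container; `X` positions are zeroed because the padding symbol is
outside any RNA model's vocabulary). Without a cache the adapter downgrades
— loudly — to a deterministic fallback whose row for position *i*, base *b*
is a fixed pseudo-random vector keyed by (*b*, *i*): the same shape
contract, reproducible across processes, and informative enough that the
whole pipeline is testable without any weight download. A one-hot L×5
channel over {A, C, G, U, X} feeds the sequence encoders and is the channel
saliency gradients are taken with respect to.

## The network

Two *independent* encoders (no shared parameters; every matrix carries a
unique id so independence is auditable) process the siRNA (19×5) and mRNA
(57×5) one-hot inputs through, in order: a 3×3 single-channel 2D
convolution (16 output channels, zero 'same' padding), a max pooling and
then an average pooling of width 2 along the embedding axis (the 19/57-step
sequence axis is kept intact until the flatten), a bidirectional LSTM with
64 units per direction, a two-layer post-norm transformer encoder
(d_model = 128 = BiLSTM output width, 8 heads, feed-forward 256), and a
flatten. The BiLSTM already injects position information, so no separate
positional encoding is added before the attention layers. Fusion is plain
concatenation — "equal weights" means no learned gating — of the two
flattened encoder outputs, the position-means of the two pretrained
embedding matrices, and the standardized thermodynamic vector, into an MLP
(one hidden layer of 64, ReLU) ending in a sigmoid score.

Feeding the 57×640 pretrained matrix into fusion *flattened* would
contribute ~36k inputs and drown every other channel, so the pretrained
group enters as position-mean vectors (640 per sequence); the per-position
information flows through the one-hot encoders instead. This is the
package's reading of an otherwise open fusion design, and the ablation
switches treat it as its own feature group.

The network, and the reverse-mode automatic differentiation underneath it,
are implemented in base R on BLAS matrices; convolution, pooling, BiLSTM
and multi-head attention are fused operations with hand-derived backward
passes, each verified against central finite differences in the test suite.

## Training and its numerical choices

The score is trained as a regression on normalized efficacy with mean
squared error (binary cross-entropy is available by configuration); binary
metrics (AUC, area under precision–recall, F1 at 0.5) are computed post hoc,
and PCC is computed against the continuous efficacies. Optimization is Adam
(lr 1e−3, β = 0.9/0.999), batch size 64, early stopping on validation loss
with patience 10.

Three safeguards matter when a sigmoid regression head sits on ~11,000
fused inputs:

* the output layer is zero-initialized, so training starts at score 0.5
  with well-scaled first gradients regardless of the fused width;
* the logit is soft-clamped, `z ← 12·tanh(z/12)` — identity near the
  origin, smoothly bounded beyond ±12 — so the sigmoid derivative never
  underflows to exactly zero and an overshooting optimizer can always
  recover (an unbounded logit with Adam's scale-free steps can saturate
  irrecoverably within a handful of updates);
* gradients are clipped to global norm 5.

Training is deterministic given the seed (and a deterministic BLAS); fold
assignment is stratified by label with fold sizes differing by at most one,
each record validated exactly once in k-fold cross-validation, and the
held-out fold doubles as the early-stopping split. Feature standardization
(thermodynamics and pooled embeddings) is fit on the training rows only.

## What the synthetic generator emulates

The generator plays the role of a single-laboratory efficacy screen.
Transcripts are i.i.d. at a target GC content; sites are uniform; the
noiseless efficacy is a logistic of
`2.0·asymmetry_ddg + 0.5·[pos1 ∈ {A,G}] + 0.5·[pos19 = U] − 1.0·|GC − 0.5|`
plus Gaussian noise (σ = 0.1) after the link, clipped to [0, 1]; raw
inhibition is 100× that score and then goes through the same normalization
and 70%-labelling as real data. The planted terms are exactly the signals
the field reports for functional siRNAs — terminal asymmetry, A/G at the
guide 5′ end, U at the 3′ end, moderate GC — and, deliberately, only
features the model can access, so a failure to recover them localizes bugs
to the model/training stack rather than the biology. The weights were fixed
once when the generator was written, scaled so the asymmetry term (s.d.
≈ 0.8 kcal/mol across random 19-mers) dominates the logit; truth scores are
stored beside every generated table.

What it does **not** emulate: inter-laboratory normalization artifacts,
chemically modified nucleotides, position-dependent measurement error,
transcript secondary-structure effects on efficacy (structure *is* modelled
for off-target accessibility), and realistic transcript base composition.
Passing the recovery experiments therefore demonstrates that the estimator
and pipeline work, not that the defaults are optimal for any particular
published screen.

At the generator's study conditions — 2,000 records, default rule, default
model — held-out AUC and PCC comfortably clear 0.80 / 0.60 (the acceptance
experiment), a label-shuffled control sits at AUC ≈ 0.5, and the dataset-mean
saliency at the planted cells (position 1 A/G, position 19 U) exceeds the
map-wide mean in most independent training replicates. The test suite runs
the recovery at 2,000 records with 4 epochs, the shuffled control at 2
epochs, and 5 saliency replicates at 700 records × 3 epochs; these sizes
were chosen as the smallest at which the planted effects are recovered with
comfortable margins.

## Interpretation

Saliency is the absolute gradient of the score with respect to the one-hot
siRNA channel, per position and base, other inputs held fixed — plain
gradient magnitude, not SmoothGrad or integrated gradients, and taken on the
one-hot channel even when pretrained embeddings are active so attribution
stays per-base. Dataset maps are element-wise means over records, hence
invariant to record order. Base-preference maps are the difference of
class-conditional base frequencies per position; each position's four
entries sum to zero by construction. Both render to a numeric TSV (always)
and an optional heatmap.

## Design pipeline

A 19-nt sliding window at step 1 yields exactly L−18 candidates; each
guide is the reverse complement of its window. Functionality rules
(documented defaults, each independently evaluated and recorded in a
per-candidate trail): GC fraction within [0.30, 0.65]; no single-base run
of 5 or more; no literal mirror palindrome of 7 nt or longer. The
palindrome rule is deliberately the *string-mirror* reading: a
reverse-complement palindrome of odd length cannot exist, and
complementarity-based readings reject essentially every alternating-purine/
pyrimidine guide, which is not the rule's intent. Rule-failing candidates
are removed by default (configurable to label-only).

Toxicity labels combine immune-stimulatory motif hits (UGUGU, GUCCUUCA,
CUGAAUU, scanned on both strands with all overlapping occurrences) and an
exact-match toxic-seed blacklist over guide positions 2–8 (the 7-mer seed
convention); the blacklist ships empty because no consensus published list
is bundled — it is an editable data file.

Off-target labels use a site-accessibility score in the PITA spirit against
a user-supplied "interested mRNA set": for every exact seed match, pairing
is extended to the maximal contiguous complementary run,
`ΔΔG = ΔG_duplex − ΔG_open` with
`ΔG_open = MFE(window) − MFE(window, site forced single-stranded)` over the
site ± 70 nt; `ΔG_open ≤ 0`, so a site buried in structure scores less
favorably. A candidate whose best ΔΔG is at or below −10 kcal/mol (default,
configurable — no published threshold is asserted) receives the off-target
label. Scores from an external quantitative miRNA-targeting model can be
joined from its tabular output (adapter only; the external model is not
re-implemented). Labels never modify predicted efficacy; the final report
is sorted by predicted efficacy, ties broken by site position, with
TSV/BED6 writers and per-filter summary counts.

## Known limitations

* The nearest-neighbor table covers Watson–Crick RNA/RNA stacks at 37 °C
  only — no wobble pairs, dangling ends, or temperature dependence; the
  duplex term assumes full complementarity at the site.
* The naive folding fallback is a single-stem scan: adequate as a degenerate
  engine for tests, not a substitute for a real MFE engine in analyses that
  depend on `ΔG_open`.
* The MLP head and several encoder hyperparameters (kernel, channels,
  pooling axis, feed-forward width) are this package's documented defaults
  where the architecture family leaves them open; all are exposed in
  `sirna_config()`.
* Training in base R is CPU-bound; the defaults target datasets of a few
  thousand records. Larger screens work but scale linearly.
* Normalization by dataset maximum is the minimal reading of
  "0–100% inhibition efficiency"; screens with saturated or non-positive
  maxima need a different strategy (the clipping contract is explicit).
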