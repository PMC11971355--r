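---
title: "plantmeth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plantmeth: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

plantmeth detects 5-methylcytosine (5mC) from nanopore-style raw signal in
the three plant sequence contexts — CpG, CHG and CHH (H ∈ {A, C, T}). This
vignette explains the statistical model, the pipeline around it, the
parameters that matter, what the built-in simulator does and does not
emulate, and the design choices made where the design was genuinely open.

## The problem

Cytosine methylation perturbs the ionic current of a nanopore while the
modified base and its neighbours transit the pore. Given basecalled reads
aligned to a reference, per-base signal segments recovered from the
basecaller's move table, and per-cytosine bisulfite (BS-seq) frequencies for
supervision, the task is: for every read covering a cytosine site of a given
motif class, estimate the probability that the molecule is methylated at
that site; then aggregate per-read calls into per-site methylation
frequencies. CHH is the hard class: it is asymmetric (strand-specific) and
high-methylation CHH sites are rare in plant genomes, so the training set
must be balanced carefully over sequence contexts.

## Feature extraction

Reads are screened with the standard low-quality-alignment filter:
MAPQ ≥ 20, primary-alignment fraction (read length minus soft-clipped bases
over read length) ≥ 80%, and mapping identity ≥ 80%. Raw signal is
standardized per read by the median shift and the (unscaled) median absolute
deviation, `z = (x - median(x)) / median(|x - median(x)|)`; a zero MAD
(constant signal) maps to all zeros rather than dividing by zero.

For each covered motif cytosine the k-mer of **read** bases centered on the
aligned base is taken in the molecule's own 5'→3' orientation (k odd,
default 13). Records are skipped when the center read base is not C or the
window runs off the read; insertions contribute read bases to the window and
a deleted site is simply uncovered. Per base of the k-mer, 15 signals are
sampled from its standardized segment and two matrices are assembled:

* a k×5 sequence-feature matrix — mean and standard deviation of the 15
  sampled signals, basecall quality, the segment's raw sample count, and the
  base encoded A=0, C=1, G=2, T=3;
* a k×15 signal matrix of the sampled values themselves.

Two under-determined details were fixed as follows. Sampling 15 values from
a segment of n samples uses the deterministic evenly spaced indices
`floor(j·n/15)` for n ≥ 15 and cyclic repetition for n < 15 — deterministic,
order-preserving, and RNG-free. The per-base mean/sd are computed over the
15 sampled values (not the full segment), keeping the emitted matrix
self-consistent; at typical dwell counts the difference is negligible.

## The classifier

The model is a triple-encoder network. A sequence branch embeds the base
identity (learned 4×`embed_dim` embedding) and joins the four numeric
columns, projecting to `seq_dim`; a signal branch projects the 15 signals to
`sig_dim`. Each branch is encoded independently (2 layers each by default),
the per-position outputs are concatenated — which is why
`combine_dim = seq_dim + sig_dim` is enforced — and a third, collaborative
encoder (3 layers) encodes the joint sequence. A feedforward head emits
two-class probabilities. Per-position concatenation (rather than pooling
then concatenating) is the only reading under which the stated dimension
arithmetic (128 + 128 = 256) type-checks.

Two encoder variants sit behind one contract:

* **bilstm** — stacked bidirectional LSTMs; each layer emits the
  concatenated forward/backward hidden state per position, and the terminal
  representation is the concatenation of the final forward and final
  backward hidden states of the last combine layer (the hidden vectors at
  each scan's end).
* **transformer** — BERT-style blocks (multi-head self-attention and a
  feedforward sublayer, each wrapped in residual connection and layer
  normalization). Attention is position-blind, so sinusoidal positional
  encodings `PE(pos, 2i) = sin(pos·10000^(−2i/d))`,
  `PE(pos, 2i+1) = cos(pos·10000^(−2i/d))` are added at both branch inputs.
  The terminal representation is the center-position hidden vector.

Each of the three encoders can be disabled by configuration (identity
pass-through) for ablation studies; the model still type-checks because the
branch projections already produce the branch dimensions.

The network and its training loop are implemented directly in R on a small
reverse-mode automatic-differentiation engine (`R/tape.R`). The engine
records matrix operations on a tape and back-propagates in reverse creation
order; its gradients are validated against central finite differences in the
test suite for both encoder variants. This keeps the package dependency-free
at the cost of raw speed, which is adequate at the problem sizes below.

## Training

Positive and negative training sites are selected from BS-seq: negatives at
zero methylation frequency; CHH positives above per-motif thresholds
(CAA > 0.95; CAC/CAT/CTA/CTT/CTC > 0.90; CCA/CCT/CCC > 0.85), CHG positives
above 0.98, and CpG sites using > 0.99 / < 0.02 bands; every site needs
coverage of at least 5 (inclusive — the source material wavers between
"≥ 5" and "above 5×", so the floor is a parameter with an inclusive
default).

The labeled pool is balanced by the strict per-k-mer rule: only k-mers
occurring in both classes survive, and each contributes
`min(n_pos, n_neg, k_max)` samples per side, drawn uniformly without
replacement. The result is exactly 1:1 overall and per k-mer. Note a
desk-scale consequence: at k = 9 a specific genomic site usually owns its
k-mer, so the positive/negative k-mer intersection is only non-trivial once
the genome is large enough for contexts to recur (tens of kilobases in the
simulator); this mirrors, in miniature, why the original training corpus
needed several genomes.

Optimization follows the published recipe: Adam (β₁ = 0.9, β₂ = 0.999),
cross-entropy loss, global gradient-norm clipping (default 1.0), initial
learning rate 0.001 (bilstm) or 0.0005 (transformer) decreased by 80% with
each epoch (`lr·0.2^epoch`), dropout between stacked layers, a stratified
1% internal test split used to keep the best-performing parameters, and
early stopping when that held-out accuracy has not improved for `patience`
epochs. Batch size, epoch budget and the dropout rate are not specified in
the source material and are exposed in `meth_train_control()` /
`meth_model_config()` with defaults 256, 20 and 0.2.

**Desk-scale adaptation.** The published schedule assumes epochs of tens of
millions of samples; the learning rate has decayed 125-fold by epoch 4, so
with a few thousand records almost all optimization happens in the first two
epochs. The package's own validation experiments therefore train with batch
size 16 and dropout 0.1 (more updates per high-learning-rate epoch, less
regularization for small data), keeping the published learning rates, decay,
clipping and early stopping unchanged. These are configuration choices, not
changes to the method.

## Calling and aggregation

Per-read probabilities feed the adaptive threshold rule: probabilities in
[0.2, 0.9) are binned into 70 intervals of width 0.01; each bin's left
endpoint represents it; the left endpoint of the least-occupied bin becomes
the dataset threshold P_th (for a well-separated bimodal distribution this
falls between the modes, minimizing the sum of false positives and false
negatives). Ties break toward the smallest endpoint (the more sensitive
choice) and calls outside the range are excluded from both numerator and
denominator — out-of-range handling is not pinned down by the source and
exclusion keeps bin proportions comparable across datasets. If no call lands
in the range the function refuses and instructs a fall back to P_th = 0.5.
A read is called methylated iff P_m ≥ P_th (inclusive). For read-level
benchmark metrics, in contrast, the probability-comparison rule (P_m > 0.5;
ties unmethylated) is used.

Sites aggregate strand-specifically — the two cytosines of a CpG pair are
distinct sites — as methylated reads over total reads, with sites under a
coverage floor (default 10) flagged unquantified. Depth for downsampling is
defined as aligned bases over genome length, not read count. Site-level
agreement with BS-seq is the Pearson correlation over sites quantified by
both assays at ≥ 5× each. Read-level evaluation reports F1, accuracy,
recall, precision, AUC (rank statistic, ties at one half) and average
precision, averaged over seeded balanced replicates; scarce positives may be
oversampled with SMOTE (interpolation between nearest minority neighbours)
at the feature level.

## The synthetic data generator

No public signal-level generative model exists for this platform, so the
simulator is test scaffolding with the statistical structure the caller
assumes, not a physical pore model:

* a seeded random reference with configurable GC content;
* a deterministic k-mer level table (order 6 by default) giving each
  context an expected signal level, drawn once from a fixed-spread uniform;
* per-site true frequencies from a user mixture (point masses allow fully
  methylated / unmethylated spikes);
* per read: uniform start/strand, per-covered-site Bernoulli molecule
  states, per-base dwell `1 + Poisson(dwell_mean − 1)` (guaranteeing ≥ 1
  sample), and Gaussian samples around the context level, shifted by δ
  (default 1.5, σ = 1) for **every base whose context k-mer contains a
  methylated cytosine** — methylation is known to perturb neighbouring
  signal, and this adjacency is exactly what the k-mer features exploit;
* exact alignments (optional substitution errors exercise the identity
  filter), high-quality basecall scores drawn from a fixed distribution;
* a matched BS-seq report: per-site Poisson coverage and binomial methylated
  counts at `p = freq(1−e) + (1−freq)e` for conversion-error rate `e`;
  zero-coverage sites are absent.

For study conditions the package treats as realistic: 15% of CHH sites fully
methylated and 85% unmethylated, reflecting the low CHH methylation content
(roughly 1–17%) reported across angiosperms and the scarcity of positives
that motivates k-mer balancing in the first place. The adjacency of the
level shift makes some negative records genuinely ambiguous (a methylated
neighbour within the context window shifts part of a negative site's
signal), which keeps desk-scale accuracies realistically below 100%.

What the simulator does **not** emulate: pore physics, homopolymer and
basecall errors beyond substitutions, dwell/level autocorrelation, 5hmC as a
distinct state (treated jointly with 5mC throughout), mappability artefacts,
or BS-seq conversion biases beyond a symmetric error rate. Passing tests on
synthetic data therefore demonstrate the pipeline's internal correctness and
the learnability of signal-level shifts, not field performance on real
flowcell data.

## Validation problem sizes

The package's acceptance experiments (see `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`) use a 140 kb genome at 10× under the 15%
fully-methylated / 85% unmethylated CHH regime. The signal-recovery check
trains on 5,000 k-mer-balanced records (k = 9, δ = 3σ, encoder dims 64 —
half the full-scale configuration) and evaluates on a held-out balanced set;
the chance-level null repeats this at δ = 0 on a 60 kb genome (context
diversity is irrelevant when there is no effect to learn). The site-
quantification experiment reuses the genome at 30× with true frequencies on
the grid {0, 0.25, 0.5, 0.75, 1} (weights 0.6/0.1/0.1/0.1/0.1, keeping the
low-methylation regime while exercising partial levels), calls a 12 kb
window of sites with the adaptive threshold, aggregates at minimum coverage
10 and correlates with the truth. Its quantification model trains on a
14,000-record draw of the same balanced pool for two epochs — the published
schedule concentrates essentially all learning there. These sizes were
chosen so a single-CPU run completes in minutes while the k-mer intersection
and coverage are large enough for the balancing and aggregation rules to
engage nontrivially.

A candid note on that last experiment: at this scale the model sees roughly
2,900 of the 36,864 possible CHH-centered 9-mers, and must infer a random
4,096-entry context level table from them; together with the adjacency of
the methylation shift (a methylated neighbour inside a context window
partially shifts an unmethylated site's signal), this bounds the site-level
truth correlation near r ≈ 0.9 — the per-site systematic error is the
dominant term, not the binomial sampling noise at 30×. Larger genomes and
training pools move r toward this bound but cannot pass it without
substantially more training than a desk-scale run allows.

## Known limitations

* The autodiff engine favours clarity over speed; training beyond ~10⁵
  records or dims ≫ 128 calls for a compiled backend.
* The native signal-alignment dialect carries signal inline as text; real
  pod5/BAM ingestion is out of scope, though the SAM-with-move-table parser
  accepts the standard tag layout with externally supplied signal.
* Per-motif-class models are separate checkpoints sharing one architecture;
  no cross-context transfer is attempted.
* The Bi-LSTM variant feeds per-position outputs (not final states) from the
  branch encoders into the combine encoder, extracting final states only at
  the terminal stage; the source describes final-state extraction only for
  the terminal representation, and this is the reading that preserves
  per-position structure for the collaborative encoder.
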