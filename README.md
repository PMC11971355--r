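# plantmeth

Signal-level detection of 5-methylcytosine (5mC) for plant genomes from
nanopore-style raw signal, in all three plant sequence contexts — CpG, CHG
and CHH (H ∈ {A, C, T}). CHH methylation is strand-asymmetric, rare
(roughly 1–17% content across angiosperms) and the hardest to call, yet it
is central to transposon silencing; plantmeth implements a complete,
desk-scale pipeline for training and evaluating a signal-level CHH/CHG/CpG
caller against bisulfite (BS-seq) ground truth.

## What the package does

* **Feature extraction.** Reads are filtered (MAPQ ≥ 20, aligned fraction
  ≥ 80%, mapping identity ≥ 80%); per-read signal is standardized by median
  shift and MAD scale, `z = (x − median(x)) / median(|x − median(x)|)`. For
  each covered motif cytosine, the k-mer of read bases centered on the site
  (default k = 13) yields a k×5 sequence-feature matrix (per base: mean and
  sd of 15 sampled standardized signals, basecall quality, raw sample count,
  base encoding) and a k×15 matrix of the sampled signals.
* **Classifier.** A triple-encoder network: independent sequence and signal
  encoders (feature dimension 128 each by default), per-position
  concatenation into a collaborative encoder (dimension 256), and a
  feedforward two-class head. Bidirectional-LSTM and Transformer encoder
  variants (the latter with sinusoidal positional encoding
  `PE(pos,2i) = sin(pos·10000^(−2i/d))`, `PE(pos,2i+1) = cos(·)`) sit behind
  one configuration contract; each encoder can be ablated. The network and
  its reverse-mode autodiff are implemented in base R and verified against
  finite differences.
* **Training.** High-confidence sites from BS-seq (per-motif frequency
  thresholds, e.g. CAA > 0.95, CCA/CCT/CCC > 0.85 for CHH positives;
  negatives at zero frequency), strict per-k-mer 1:1 class balancing capped
  at `k_max`, Adam (β₁ = 0.9, β₂ = 0.999) with initial learning rate 0.001
  (Bi-LSTM) / 0.0005 (Transformer) decreased by 80% each epoch,
  cross-entropy, gradient clipping, dropout, early stopping on a stratified
  1% held-out split.
* **Calling.** Per-read methylation probabilities P_m; an adaptive dataset
  threshold P_th chosen as the left endpoint of the least-occupied of 70
  probability bins over [0.2, 0.9); strand-specific per-site frequencies
  (methylated reads / total reads) with a coverage floor; depth
  downsampling; read-level metrics (F1, accuracy, precision, recall, AUC,
  AP, with SMOTE for scarce positives) and site-level Pearson correlation
  against BS-seq.
* **Synthetic data.** A seeded simulator generates a reference, per-site
  truth frequencies, signal-bearing reads (k-mer level table + methylation
  level shift applied to every base whose context contains a methylated C +
  Gaussian noise, dwell ≥ 1 per base) and a matched binomial BS-seq report,
  so the whole pipeline is testable end-to-end with no real data.

## Worked example

Simulate a 40 kb genome with 15% fully methylated CHH sites and a 3σ
methylation level shift, train a small Bi-LSTM caller on BS-seq-selected
k-mer-balanced records, and quantify site frequencies:

```r
library(plantmeth)

cfg <- sim_config(genome_length = 40000, depth = 10, meth_level_shift = 3,
                  seed = 7)
ref    <- generate_reference(cfg)
levels <- kmer_level_table(6, seed = 7)
truth  <- assign_truth_frequencies(ref, "CHH",
            list(list(weight = 0.85, freq = 0),
                 list(weight = 0.15, freq = 1)), seed = 7)
reads  <- simulate_reads(ref, truth, levels, cfg)
bsseq  <- simulate_bsseq_report(truth, cfg$bs_coverage, 0, seed = 7)

sites    <- locate_motif_sites(ref, "CHH")
features <- extract_read_features(reads, sites, k = 9)
labeled  <- label_features(features,
                           select_reference_sites(bsseq, "CHH", 5))
balanced <- balance_features(labeled, k_max = 400, seed = 1)

fit <- meth_train(balanced,
  meth_model_config("bilstm", k = 9, seq_dim = 32, sig_dim = 32,
                    combine_dim = 64, embed_dim = 8, clf_dim = 32,
                    dropout = 0.1),
  meth_train_control(batch_size = 16, epochs = 3, test_fraction = 0.1,
                     seed = 1))
print(fit)

calls <- predict(fit, features)             # all records, not just labeled
p_th  <- select_threshold(calls$p_meth)
print(p_th)
calls <- call_methylation(calls, p_th)
site_calls <- aggregate_site_frequencies(calls, min_coverage = 5)
res <- pearson_site_correlation(site_calls, bsseq, min_cov_each = 5)
cat(sprintf("site-level Pearson r = %.3f over %d sites\n", res$r, res$n_sites))
```

Output from this exact script (R 4.3, single CPU, about two minutes):

```
meth_model (bilstm encoder, k = 9): 102690 parameters
trained on 2666 samples (296 held out), best epoch 1, val acc 0.9595
adaptive threshold P_th = 0.62 (70 bins over [0.2, 0.9))
site-level Pearson r = 0.762 over 5847 sites
```

The printed numbers mean: the k-mer-balanced pool held 2,962 records (1:1
positives:negatives by construction, of which 10% were held out); the
internal held-out accuracy reached about 0.96; the adaptive threshold landed
in the sparse valley between the two probability modes of the call
distribution; and the per-site frequencies recovered from the reads
correlate at r ≈ 0.76 with the matched BS-seq report over the 5,847 sites
both assays quantify at ≥ 5×. At this small training scale most remaining
error comes from sites whose 9-mer context never occurs in the balanced
pool; the acceptance experiments (140 kb genome) push read-level accuracy to
about 0.97 and site-level truth correlation to about 0.9.

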