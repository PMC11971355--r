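# Shared fixture builders. Everything is generated in code under fixed seeds.

# A hand-built read with fully known segments, on a tiny reference.
# ref chr1: "AATCGATCGGAC..." style sequence passed in; read aligns exactly.
make_plain_read <- function(seq, ref_start = 0L, strand = "+",
                            dwells = NULL, signal = NULL, quals = NULL,
                            mapq = 60L, cigar = NULL, nm = 0L,
                            read_id = "r1", chrom = "chr1") {
  n <- nchar(seq)
  if (is.null(dwells)) dwells <- rep(4L, n)
  if (is.null(signal)) signal <- seq_len(sum(dwells)) / 10
  if (is.null(quals)) quals <- rep(30L, n)
  if (is.null(cigar)) cigar <- paste0(n, "M")
  signal_read(read_id = read_id, basecalled_seq = seq, qualities = quals,
              signal = signal, move_lens = dwells, chrom = chrom,
              ref_start = ref_start, strand = strand, cigar = cigar,
              mapq = mapq, nm = nm)
}

# Small full simulation shared across tests (memoised per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(genome_length = 2000, read_length_mean = 300, depth = 8,
                      meth_level_shift = 3, noise_sd = 1, bs_coverage = 30,
                      seed = 42)
    ref <- generate_reference(cfg)
    tbl <- kmer_level_table(6, seed = 42)
    truth <- assign_truth_frequencies(
      ref, "CHH",
      list(list(weight = 0.5, freq = 0), list(weight = 0.5, freq = 1)),
      seed = 42)
    reads <- simulate_reads(ref, truth, tbl, cfg)
    sites <- locate_motif_sites(ref, "CHH")
    cache <<- list(cfg = cfg, ref = ref, tbl = tbl, truth = truth,
                   reads = reads, sites = sites)
    cache
  }
})

# Independent brute-force motif scanner: walks every position of the sequence
# and of its reverse complement with plain string ops.
brute_motif_sites <- function(ref, context_class) {
  out <- list()
  for (chrom in names(ref)) {
    s <- ref[[chrom]]
    L <- nchar(s)
    for (i in seq_len(L - 2)) {
      tri <- substr(s, i, i + 2)
      if (substr(tri, 1, 1) == "C" && classify_trinuc(tri) == context_class)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, pos = i - 1L, strand = "+",
          context = context_class, trinuc = tri)
    }
    rc <- revcomp(s)
    for (i in seq_len(L - 2)) {
      tri <- substr(rc, i, i + 2)
      if (substr(tri, 1, 1) == "C" && classify_trinuc(tri) == context_class)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, pos = L - i, strand = "-",
          context = context_class, trinuc = tri)
    }
  }
  df <- do.call(rbind, out)
  df <- df[order(df$chrom, df$pos, df$strand), ]
  rownames(df) <- NULL
  df
}

# Independent re-implementation of the k-mer balancing pseudocode, written
# directly from its printed form; returns per-k-mer selected counts.
brute_balance_counts <- function(pos_kmers, neg_kmers, k_max) {
  K_pos <- unique(pos_kmers)
  K_neg <- unique(neg_kmers)
  K_comm <- intersect(K_neg, K_pos)
  KNUM_pos <- table(pos_kmers)
  KNUM_neg <- table(neg_kmers)
  counts <- integer(0)
  for (km in K_comm)
    counts[km] <- min(KNUM_pos[[km]], KNUM_neg[[km]], k_max)
  counts
}

# Pair-ordering AUC: fraction of positive-negative pairs ranked correctly,
# ties counted one half.
brute_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}
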