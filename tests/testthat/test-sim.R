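test_that("reference generation is seeded and honours composition", {
  cfg <- sim_config(genome_length = 1000, seed = 7)
  expect_identical(generate_reference(cfg), generate_reference(cfg))

  pure_gc <- generate_reference(sim_config(genome_length = 500,
                                           gc_fraction = 1, seed = 1))
  expect_true(all(strsplit(pure_gc[[1]], "")[[1]] %in% c("G", "C")))

  half <- generate_reference(sim_config(genome_length = 1e5,
                                        gc_fraction = 0.5, seed = 2))
  gc <- mean(strsplit(half[[1]], "")[[1]] %in% c("G", "C"))
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)

  expect_error(sim_config(genome_length = 0), "positive")
  expect_error(sim_config(gc_fraction = 1.2), "proportion")
})

test_that("k-mer level table is complete and reproducible", {
  tbl <- kmer_level_table(4, seed = 3)
  expect_length(tbl, 4^4)
  expect_false(any(duplicated(names(tbl))))
  expect_identical(unclass(tbl), unclass(kmer_level_table(4, seed = 3)))
  expect_false(identical(unclass(tbl), unclass(kmer_level_table(4, seed = 4))))
})

test_that("truth assignment covers every motif site with mixture frequencies", {
  cfg <- sim_config(genome_length = 40000, seed = 5)
  ref <- generate_reference(cfg)
  zero <- assign_truth_frequencies(ref, "CHH",
                                   list(list(weight = 1, freq = 0)), seed = 5)
  expect_true(all(zero$freq == 0))
  expect_identical(nrow(zero), nrow(locate_motif_sites(ref, "CHH")))

  mix <- assign_truth_frequencies(
    ref, "CHH",
    list(list(weight = 0.5, freq = 0), list(weight = 0.5, freq = 1)),
    seed = 6)
  expect_gt(nrow(mix), 1e4)
  frac1 <- mean(mix$freq == 1)
  expect_gt(frac1, 0.47)
  expect_lt(frac1, 0.53)

  expect_identical(nrow(assign_truth_frequencies(
    c(chr1 = "ACGT"), "CHH", list(list(weight = 1, freq = 0)))), 0L)
  expect_error(assign_truth_frequencies(ref, "CNN",
                                        list(list(weight = 1, freq = 0))),
               "unknown motif class")
  expect_error(assign_truth_frequencies(
    ref, "CHH", list(list(weight = 0.4, freq = 0))), "sum to 1")
})

test_that("simulated reads conserve signal and respect the move table", {
  sim <- small_sim()
  for (r in sim$reads) {
    expect_identical(sum(r$move_lens), length(r$signal))
    expect_true(all(r$move_lens >= 1L))
    expect_identical(length(r$qualities), nchar(r$basecalled_seq))
  }
  again <- simulate_reads(sim$ref, sim$truth, sim$tbl, sim$cfg)
  expect_identical(sim$reads[[1]], again[[1]])
  expect_identical(sim$reads[[length(sim$reads)]], again[[length(again)]])
})

test_that("methylation shifts signal by delta exactly where a methylated C is in context", {
  cfg0 <- sim_config(genome_length = 1500, read_length_mean = 200, depth = 4,
                     meth_level_shift = 0, seed = 9)
  ref <- generate_reference(cfg0)
  tbl <- kmer_level_table(6, seed = 9)
  all1 <- assign_truth_frequencies(ref, "CHH",
                                   list(list(weight = 1, freq = 1)), seed = 9)
  all0 <- assign_truth_frequencies(ref, "CHH",
                                   list(list(weight = 1, freq = 0)), seed = 9)
  # delta = 0: fully methylated and fully unmethylated molecules emit
  # identical signal under the same seed (the no-effect null)
  r1 <- simulate_reads(ref, all1, tbl, cfg0)
  r0 <- simulate_reads(ref, all0, tbl, cfg0)
  expect_identical(lapply(r1, `[[`, "signal"), lapply(r0, `[[`, "signal"))

  # delta = 3 sigma: the same construction isolates the shift exactly
  cfg3 <- sim_config(genome_length = 1500, read_length_mean = 200, depth = 4,
                     meth_level_shift = 3, noise_sd = 1, seed = 9)
  r1 <- simulate_reads(ref, all1, tbl, cfg3)
  r0 <- simulate_reads(ref, all0, tbl, cfg3)
  diffs <- unlist(mapply(function(a, b) a$signal - b$signal, r1, r0,
                         SIMPLIFY = FALSE))
  expect_true(any(diffs != 0))
  expect_true(all(abs(diffs[diffs != 0] - 3) < 1e-9))
  # per-context sample-mean check: the mean state difference of affected
  # samples estimates the configured shift
  affected <- mapply(function(a, b) which(a$signal != b$signal), r1, r0,
                     SIMPLIFY = FALSE)
  est <- mean(unlist(mapply(function(a, idx) a$signal[idx], r1, affected,
                            SIMPLIFY = FALSE))) -
    mean(unlist(mapply(function(b, idx) b$signal[idx], r0, affected,
                       SIMPLIFY = FALSE)))
  expect_lt(abs(est - 3) / 3, 0.1)
})

test_that("separability of the mean-signal classifier is monotone in delta", {
  deltas <- c(0, 0.5, 1, 2)
  aucs <- vapply(seq_along(deltas), function(i) {
    cfg <- sim_config(genome_length = 1200, read_length_mean = 200, depth = 8,
                      meth_level_shift = deltas[i], noise_sd = 1,
                      seed = 100 + i)
    ref <- generate_reference(sim_config(genome_length = 1200, seed = 55))
    tbl <- kmer_level_table(6, seed = 55)
    sites <- locate_motif_sites(ref, "CHH")
    all1 <- assign_truth_frequencies(ref, "CHH",
                                     list(list(weight = 1, freq = 1)),
                                     seed = 1)
    all0 <- assign_truth_frequencies(ref, "CHH",
                                     list(list(weight = 1, freq = 0)),
                                     seed = 1)
    f1 <- extract_read_features(simulate_reads(ref, all1, tbl, cfg),
                                sites, k = 9)
    cfg2 <- cfg; cfg2$seed <- cfg$seed + 5000L
    f0 <- extract_read_features(simulate_reads(ref, all0, tbl, cfg2),
                                sites, k = 9)
    # 1-D classifier: center-base mean standardized signal, baseline removed
    # by pairing records of the same k-mer context
    center_mean <- function(f) data.frame(kmer = f$info$kmer,
                                          m = f$seq[, 5, 1])
    a <- center_mean(f1); a$lab <- 1
    b <- center_mean(f0); b$lab <- 0
    common <- intersect(a$kmer, b$kmer)
    d <- rbind(a[a$kmer %in% common, ], b[b$kmer %in% common, ])
    base <- tapply(d$m[d$lab == 0], d$kmer[d$lab == 0], mean)
    plantmeth:::.auc_rank(d$lab, d$m - base[d$kmer])
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
  expect_lt(aucs[1], 0.6)
  expect_gt(aucs[4], 0.9)
})

test_that("bisulfite reports are binomial around the truth and drop uncovered sites", {
  sim <- small_sim()
  rep1 <- simulate_bsseq_report(
    transform(sim$truth, freq = 1), bs_coverage = 20,
    bs_conversion_error = 0, seed = 3)
  expect_true(all(rep1$freq == 1))

  half <- transform(sim$truth, freq = 0.5)
  big <- do.call(rbind, replicate(4, half, simplify = FALSE))
  rep2 <- simulate_bsseq_report(big, bs_coverage = 50, 0, seed = 4)
  expect_gt(nrow(rep2), 1000)
  expect_gt(mean(rep2$freq), 0.48)
  expect_lt(mean(rep2$freq), 0.52)

  rep3 <- simulate_bsseq_report(sim$truth, bs_coverage = 1, 0, seed = 5)
  expect_lt(nrow(rep3), nrow(sim$truth)) # zero-coverage sites absent
  expect_true(all(rep3$total >= 1))

  expect_error(simulate_bsseq_report(sim$truth, bs_coverage = 0, 0, 1),
               ">= 1")
})
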