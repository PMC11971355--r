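test_that("adaptive threshold selection bins [0.2, 0.9) into 70 intervals", {
  set.seed(1)
  p <- runif(5000, 0.2, 0.8999)
  th <- select_threshold(p)
  expect_length(th$bin_edges, 70)
  expect_length(th$bin_proportions, 70)
  expect_equal(th$bin_edges, 0.2 + 0.01 * (0:69))
  expect_equal(sum(th$bin_proportions), 1)
})

test_that("the threshold lands on the least-occupied bin", {
  # bimodal scores with a unique empty bin at [0.55, 0.56)
  p <- c(runif(400, 0.20, 0.55), runif(400, 0.56, 0.90))
  p <- p[p < 0.55 | p >= 0.56]
  # ensure every other in-range bin is occupied
  p <- c(p, 0.2 + 0.01 * (0:69) + 0.005)
  p <- p[p < 0.555 | p >= 0.56]
  th <- select_threshold(p)
  expect_identical(th$p_th, 0.55)

  # identical occupancy in every bin: ties break to the smallest endpoint
  even <- rep(0.2 + 0.01 * (0:69) + 0.005, each = 3)
  expect_identical(select_threshold(even)$p_th, 0.20)

  # out-of-range calls are excluded from numerator and denominator
  th2 <- select_threshold(c(even, rep(0.99, 1000), rep(0.01, 1000)))
  expect_identical(th2$p_th, 0.20)
  expect_equal(sum(th2$bin_proportions), 1)

  expect_error(select_threshold(c(0.05, 0.95)), "0.5")
})

test_that("calls use the inclusive threshold rule", {
  calls <- data.frame(p_meth = c(0.55, 0.549, 1.0, 0.0))
  out <- call_methylation(calls, 0.55)
  expect_identical(out$methylated, c(TRUE, FALSE, TRUE, FALSE))
  th <- select_threshold(runif(100, 0.2, 0.9))
  out2 <- call_methylation(data.frame(p_meth = c(th$p_th, th$p_th - 0.001)),
                           th)
  expect_identical(out2$methylated, c(TRUE, FALSE))
  all1 <- call_methylation(data.frame(p_meth = rep(1, 5)), 0.89)
  expect_true(all(all1$methylated))
})

test_that("site aggregation is strand-specific and coverage-flagged", {
  calls <- data.frame(
    chrom = "chr1",
    pos = c(rep(10L, 5), rep(10L, 3), rep(11L, 9)),
    strand = c(rep("+", 5), rep("-", 3), rep("+", 9)),
    context = "CpG",
    methylated = c(TRUE, TRUE, TRUE, FALSE, FALSE, # +10: 3/5
                   TRUE, FALSE, FALSE,             # -10: 1/3
                   rep(TRUE, 9)))                  # +11: 9/9
  agg <- aggregate_site_frequencies(calls, min_coverage = 10)
  expect_identical(nrow(agg), 3L)
  plus10 <- agg[agg$pos == 10 & agg$strand == "+", ]
  expect_identical(plus10$freq, 0.6)
  minus10 <- agg[agg$pos == 10 & agg$strand == "-", ]
  expect_identical(minus10$coverage, 3L)
  expect_identical(minus10$freq, 1 / 3)
  # a CpG pair on opposite strands stays two records
  expect_identical(sum(agg$pos == 10), 2L)
  # 9 reads with min_coverage 10 is unquantified
  expect_false(agg$quantified[agg$pos == 11])
  expect_true(all(!agg$quantified[agg$coverage < 10]))
})

test_that("downsampling reaches the target depth deterministically", {
  sim <- small_sim()
  L <- nchar(sim$ref[[1]])
  aligned <- function(reads) sum(vapply(reads, function(r)
    nchar(r$basecalled_seq), numeric(1)))
  full_depth <- aligned(sim$reads) / L
  expect_gt(full_depth, 6)

  # target above the realized depth returns everything
  expect_identical(downsample_reads(sim$reads, full_depth + 5, L, 1),
                   sim$reads)

  ds <- downsample_reads(sim$reads, 2, L, seed = 9)
  expect_lt(length(ds), length(sim$reads))
  realized <- aligned(ds) / L
  expect_gte(realized, 2)
  expect_lt(abs(realized - 2) / 2, 0.15) # one read overshoot at most

  expect_identical(downsample_reads(sim$reads, 2, L, seed = 9), ds)

  depths <- vapply(c(1, 2, 4, 6), function(t)
    aligned(downsample_reads(sim$reads, t, L, seed = 5)) / L, numeric(1))
  expect_true(all(diff(depths) >= 0))

  expect_error(downsample_reads(list(), 5, L), "empty")
  expect_error(downsample_reads(sim$reads, 0, L), "positive")
})

test_that("site-frequency correlation follows the textbook formula", {
  a <- data.frame(chrom = "c", pos = 1:3, strand = "+",
                  coverage = 10L, freq = c(0, 0.5, 1))
  b <- data.frame(chrom = "c", pos = 1:3, strand = "+",
                  total = 10L, freq = c(0.1, 0.4, 0.9))
  res <- pearson_site_correlation(a, b, min_cov_each = 5)
  x <- c(0, 0.5, 1); y <- c(0.1, 0.4, 0.9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_hand)
  expect_identical(res$n_sites, 3L)

  ident <- pearson_site_correlation(a, transform(b, freq = a$freq), 5)
  expect_equal(ident$r, 1.0)

  expect_error(pearson_site_correlation(a, transform(b, freq = 0.5), 5),
               "zero variance")
  expect_error(pearson_site_correlation(a[1, ], b[1, ], 5), "fewer than 2")
  # coverage gating drops sites below the floor on either side
  b2 <- b; b2$total <- c(10L, 2L, 10L)
  expect_identical(pearson_site_correlation(a, b2, 5)$n_sites, 2L)
})

test_that("single-molecule metrics match confusion-matrix arithmetic", {
  # perfect separation
  perfect <- single_molecule_metrics(rep(c(1, 0), each = 20),
                                     rep(c(0.9, 0.1), each = 20),
                                     replicates = 2, seed = 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$ap, 1)

  # TP=8 FP=2 FN=2 TN=8 fixture: all four headline metrics are 0.8
  labels <- c(rep(1, 10), rep(0, 10))
  probs <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 2), rep(0.1, 8))
  m <- single_molecule_metrics(labels, probs, replicates = 1,
                               n_per_class = 10, seed = 1)
  expect_identical(m$tp, 8L)
  expect_identical(m$fp, 2L)
  expect_identical(m$fn, 2L)
  expect_identical(m$tn, 8L)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$accuracy, 0.8)

  # AUC example: every positive outranks every negative
  m2 <- single_molecule_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.3),
                                replicates = 1, n_per_class = 2, seed = 1)
  expect_equal(m2$auc, 1.0)

  expect_error(single_molecule_metrics(c(1, 1), c(0.2, 0.3)), "single-class")
})

test_that("rank AUC equals brute-force pair ordering with ties at one half", {
  set.seed(33)
  for (trial in 1:20) {
    n <- sample(5:50, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # forces ties
    expect_equal(plantmeth:::.auc_rank(labels, scores),
                 brute_auc(labels, scores))
  }
})

test_that("SMOTE interpolates along minority segments", {
  # identical minority points: synthetic points coincide with them
  same <- matrix(rep(c(1, 2, 3), 5), nrow = 5, byrow = TRUE)
  syn <- smote_oversample(same, 7, k_neighbors = 2, seed = 1)
  expect_identical(nrow(syn), 7L)
  expect_true(all(apply(syn, 1, function(v) all(v == c(1, 2, 3)))))

  # two distinct points: every synthetic point lies on the segment
  two <- rbind(c(0, 0), c(1, 2))
  syn2 <- smote_oversample(two, 50, k_neighbors = 1, seed = 2)
  expect_true(all(syn2[, 1] >= 0 & syn2[, 1] <= 1))
  expect_true(all(syn2[, 2] >= 0 & syn2[, 2] <= 2))
  expect_equal(syn2[, 2], 2 * syn2[, 1]) # collinear

  expect_identical(nrow(smote_oversample(two, 0, 1, 1)), 0L)
  expect_identical(smote_oversample(two, 5, 1, seed = 3),
                   smote_oversample(two, 5, 1, seed = 3))
  expect_error(smote_oversample(two[1, , drop = FALSE], 5, 1), "at least 2")
  expect_error(smote_oversample(two, 5, k_neighbors = 2), "exceed")
})
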