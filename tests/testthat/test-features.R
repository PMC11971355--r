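test_that("motif sites are located on both strands with class precedence", {
  # palindromic CpG
  cpg <- locate_motif_sites(c(chr1 = "ACGT"), "CpG")
  expect_identical(cpg$pos, c(1L, 2L))
  expect_identical(cpg$strand, c("+", "-"))

  # hand enumeration of CCTG on both strands
  chh <- locate_motif_sites(c(chr1 = "CCTG"), "CHH")
  expect_identical(nrow(chh), 1L)
  expect_identical(chh$pos, 0L)
  expect_identical(chh$trinuc, "CCT")
  chg <- locate_motif_sites(c(chr1 = "CCTG"), "CHG")
  expect_identical(chg$pos, c(1L, 3L))
  expect_identical(chg$strand, c("+", "-"))
  expect_identical(chg$trinuc, c("CTG", "CAG"))

  expect_error(locate_motif_sites(c(chr1 = "ACGT"), "CHW"), "unknown motif")
})

test_that("motif site finder agrees with a brute-force scanner", {
  ref <- generate_reference(sim_config(genome_length = 1000, seed = 13))
  for (cls in c("CpG", "CHG", "CHH")) {
    got <- locate_motif_sites(ref, cls)
    want <- brute_motif_sites(ref, cls)
    expect_identical(got$pos, want$pos)
    expect_identical(got$strand, want$strand)
    expect_identical(got$trinuc, want$trinuc)
  }
})

test_that("motif-centered k-mer counts match brute-force enumeration", {
  expect_identical(count_motif_kmers(3, "CHH"), 9)
  expect_identical(count_motif_kmers(9, "CpG"), 16384)
  expect_error(count_motif_kmers(8, "CHH"), "odd")
  # independent enumeration of all 4^7 7-mers by base-4 digit decomposition
  v <- 0:(4^7 - 1)
  c1 <- (v %/% 4^3) %% 4 # center position (0-based index 3), A=0 C=1 G=2 T=3
  c2 <- (v %/% 4^2) %% 4
  c3 <- (v %/% 4^1) %% 4
  is_h <- function(x) x != 2
  expect_identical(count_motif_kmers(7, "CHH"),
                   as.numeric(sum(c1 == 1 & is_h(c2) & is_h(c3))))
  expect_identical(count_motif_kmers(7, "CHG"),
                   as.numeric(sum(c1 == 1 & is_h(c2) & c3 == 2)))
  expect_identical(count_motif_kmers(7, "CpG"),
                   as.numeric(sum(c1 == 1 & c2 == 2)))
})

test_that("alignment filter applies the three thresholds in order", {
  r <- make_plain_read(strrep("ACGT", 25))
  expect_true(filter_alignment(r)$keep)

  r$mapq <- 19L
  expect_identical(filter_alignment(r)$reason, "mapq")

  # 21 of 100 bases soft-clipped: aligned fraction 0.79
  clipped <- make_plain_read(strrep("ACGT", 25), cigar = "21S79M")
  expect_identical(filter_alignment(clipped)$reason, "aligned_fraction")

  # identity 79/100 < 0.8
  lowid <- make_plain_read(strrep("ACGT", 25), nm = 21L)
  expect_identical(filter_alignment(lowid)$reason, "identity")

  ok <- make_plain_read(strrep("ACGT", 25), cigar = "5S95M", nm = 9L,
                        mapq = 60L)
  expect_true(filter_alignment(ok)$keep) # fraction 0.95, identity ~0.905
})

test_that("median/MAD standardization matches hand computation", {
  expect_identical(standardize_signal(c(1, 2, 3, 4, 100)),
                   c(-2, -1, 0, 1, 97))
  expect_identical(standardize_signal(c(5, 5, 5)), c(0, 0, 0))
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(101)
    z <- standardize_signal(x)
    expect_equal(median(z), 0)
    expect_equal(median(abs(z - median(z))), 1)
  }
  expect_error(standardize_signal(numeric(0)), "empty")
})

test_that("signal sampling uses even spacing or cyclic repetition", {
  sample_signals <- plantmeth:::sample_signals
  x20 <- seq_len(20)
  expect_identical(sample_signals(x20, 15L),
                   x20[floor((0:14) * 20 / 15) + 1])
  expect_identical(sample_signals(c(10, 20, 30, 40), 15L),
                   c(10, 20, 30, 40, 10, 20, 30, 40, 10, 20, 30, 40, 10, 20, 30))
  expect_identical(sample_signals(seq_len(15), 15L), seq_len(15))
})

test_that("extracted records have the contracted shapes and center base", {
  sim <- small_sim()
  fe <- extract_read_features(sim$reads[1:8], sim$sites, k = 13)
  expect_gt(n_features(fe), 0)
  expect_identical(dim(fe$seq), c(n_features(fe), 13L, 5L))
  expect_identical(dim(fe$sig), c(n_features(fe), 13L, 15L))
  expect_true(all(substr(fe$info$kmer, 7, 7) == "C"))
  expect_true(all(nchar(fe$info$kmer) == 13L))

  expect_warning(out <- extract_features(make_plain_read("ACGTA"),
                                         sim$sites, k = 7),
                 "exceeds read length")
  expect_identical(n_features(out), 0L)
})

test_that("per-base features equal brute-force recomputation from raw segments", {
  # a fully hand-checkable read: CHH site at read pos 2 (CCT? construct)
  seq <- "TACGACCTAGT" # + strand CHH sites inside
  ref <- c(chr1 = seq)
  sites <- locate_motif_sites(ref, "CHH")
  dwells <- c(3L, 20L, 4L, 9L, 15L, 2L, 7L, 5L, 16L, 3L, 8L)
  set.seed(4)
  signal <- rnorm(sum(dwells), 0, 2)
  quals <- sample(10:40, 11, replace = TRUE)
  r <- make_plain_read(seq, dwells = dwells, signal = signal, quals = quals)
  k <- 5L
  fe <- extract_features(r, sites, k = k)
  expect_gt(n_features(fe), 0)
  std <- (signal - median(signal)) / median(abs(signal - median(signal)))
  ends <- cumsum(dwells)
  starts <- ends - dwells + 1L
  for (i in seq_len(n_features(fe))) {
    center <- fe$info$pos[i] + 1L # 0-based pos on a 1:1 alignment
    for (j in seq_len(k)) {
      b <- center + j - (k + 1L) %/% 2L
      seg <- std[starts[b]:ends[b]]
      n <- length(seg)
      s15 <- if (n >= 15) seg[floor((0:14) * n / 15) + 1] else
        seg[((0:14) %% n) + 1]
      expect_equal(fe$sig[i, j, ], s15, tolerance = 1e-6)
      expect_equal(fe$seq[i, j, 1], mean(s15), tolerance = 1e-6)
      expect_equal(fe$seq[i, j, 2], sd(s15), tolerance = 1e-6)
      expect_identical(fe$seq[i, j, 3], as.numeric(quals[b]))
      expect_identical(fe$seq[i, j, 4], as.numeric(dwells[b]))
      expect_identical(fe$seq[i, j, 5],
                       as.numeric(c(A = 0, C = 1, G = 2, T = 3)[
                         substr(seq, b, b)]))
    }
  }
})

test_that("records are skipped when the center read base is not C", {
  # reference CHH site at pos 3 ("CAT"), but the read carries a T there
  ref <- c(chr1 = "AATCATTAGGT")
  sites <- locate_motif_sites(ref, "CHH")
  expect_true(3L %in% sites$pos[sites$strand == "+"])
  good <- make_plain_read("AATCATTAGGT")
  mism <- make_plain_read("AATTATTAGGT", nm = 1L)
  k <- 3L
  expect_true(3L %in% extract_features(good, sites, k)$info$pos)
  expect_false(3L %in% extract_features(mism, sites, k)$info$pos)
})

test_that("minus-strand extraction works in the molecule's own orientation", {
  sim <- small_sim()
  fe <- extract_read_features(sim$reads, sim$sites, k = 9)
  minus <- which(fe$info$strand == "-")
  expect_gt(length(minus), 0)
  # the read k-mer of an error-free minus-strand record equals the reverse
  # complement of the forward reference window around the site
  s <- sim$ref[[1]]
  for (i in minus[1:25]) {
    p <- fe$info$pos[i] + 1L
    expect_identical(fe$info$kmer[i], revcomp(substr(s, p - 4L, p + 4L)))
  }
  for (i in which(fe$info$strand == "+")[1:25]) {
    p <- fe$info$pos[i] + 1L
    expect_identical(fe$info$kmer[i], substr(s, p - 4L, p + 4L))
  }
})

test_that("reference-site selection applies the per-motif thresholds", {
  truth <- data.frame(
    chrom = "c", pos = 1:8 * 10L, strand = "+", context = "CHH",
    trinuc = c("CAA", "CCA", "CHH1", "CAA", "CAC", "CCC", "CAT", "CTA"),
    meth = c(96, 86, 0, 0, 91, 84, 95, 90),
    total = c(100, 100, 100, 100, 100, 100, 100, 100))
  truth$trinuc[3] <- "CAA"
  truth$freq <- truth$meth / truth$total
  sel <- select_reference_sites(truth, "CHH", min_coverage = 5)
  expect_identical(sel$positives$pos, c(10L, 20L, 50L, 70L)) # .96,.86,.91,.95
  expect_identical(sel$negatives$pos, c(30L, 40L))
  # CCC at 0.84 and CTA at exactly 0.90 fail their strict thresholds
  expect_false(60L %in% sel$positives$pos)
  expect_false(80L %in% sel$positives$pos)

  # coverage below the minimum excludes a zero-frequency site
  low <- data.frame(chrom = "c", pos = 5L, strand = "+", context = "CHH",
                    trinuc = "CAA", meth = 0, total = 4, freq = 0)
  sel2 <- select_reference_sites(low, "CHH", min_coverage = 5)
  expect_identical(nrow(sel2$negatives), 0L)

  # CpG overrides the zero rule with the < 0.02 band
  cpg <- data.frame(chrom = "c", pos = c(1L, 2L, 3L), strand = "+",
                    context = "CpG", trinuc = "CGA",
                    meth = c(100, 1, 99), total = 100,
                    freq = c(1, 0.01, 0.99))
  sel3 <- select_reference_sites(cpg, "CpG")
  expect_identical(sel3$positives$pos, 1L)
  expect_identical(sel3$negatives$pos, 2L)

  bad <- truth; bad$trinuc[1] <- "CGG"
  expect_error(select_reference_sites(bad, "CHH"), "unknown CHH motif")
})

test_that("labeling joins records to reference sites and drops the rest", {
  sim <- small_sim()
  fe <- extract_read_features(sim$reads[1:10], sim$sites, k = 9)
  bs <- simulate_bsseq_report(sim$truth, 30, 0, seed = 2)
  refsites <- select_reference_sites(bs, "CHH", 5)
  lab <- label_features(fe, refsites)
  expect_true(all(!is.na(lab$info$label)))
  expect_lte(n_features(lab), n_features(fe))
  # spot-check a labeled record against the truth table
  key <- paste(sim$truth$chrom, sim$truth$pos, sim$truth$strand)
  for (i in seq_len(min(20, n_features(lab)))) {
    tr <- sim$truth$freq[match(paste(lab$info$chrom[i], lab$info$pos[i],
                                     lab$info$strand[i]), key)]
    expect_identical(lab$info$label[i], as.integer(tr == 1))
  }
})
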