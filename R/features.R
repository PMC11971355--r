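#' Feature record container
#'
#' Holds per-cytosine, per-read feature records: an info table and the k x 5
#' sequence-feature and k x 15 signal-feature arrays. Sequence-feature columns
#' are, per base of the k-mer: mean of the 15 sampled standardized signals,
#' their standard deviation, basecall quality, number of raw signal samples
#' for the base, and the base encoded A=0, C=1, G=2, T=3.
#'
#' @param info data.frame with columns `read_id`, `chrom`, `pos`, `strand`,
#'   `kmer`, `label` (0/1/NA).
#' @param seq numeric array `n x k x 5`.
#' @param sig numeric array `n x k x 15`.
#' @param k odd k-mer length.
#' @return object of class `meth_features`.
#' @export
meth_features <- function(info, seq, sig, k) {
  n <- nrow(info)
  stopifnot(identical(dim(seq), c(n, as.integer(k), 5L)) ||
              identical(dim(seq), as.integer(c(n, k, 5))),
            identical(dim(sig), as.integer(c(n, k, 15))))
  structure(list(info = info, seq = seq, sig = sig, k = as.integer(k)),
            class = "meth_features")
}

#' @export
print.meth_features <- function(x, ...) {
  cat(sprintf("meth_features: %d records, k = %d (%d labeled)\n",
              nrow(x$info), x$k, sum(!is.na(x$info$label))))
  invisible(x)
}

#' Number of feature records
#' @param features a `meth_features` object.
#' @return integer count.
#' @export
n_features <- function(features) nrow(features$info)

#' Subset feature records by index
#' @param features a `meth_features` object.
#' @param idx integer index vector.
#' @return a `meth_features` object.
#' @export
features_subset <- function(features, idx) {
  meth_features(features$info[idx, , drop = FALSE],
                features$seq[idx, , , drop = FALSE],
                features$sig[idx, , , drop = FALSE], features$k)
}

#' Combine feature sets
#' @param ... `meth_features` objects with equal k.
#' @return a `meth_features` object.
#' @export
features_rbind <- function(...) {
  fs <- Filter(function(f) n_features(f) > 0, list(...))
  if (!length(fs)) stop_fmt("nothing to combine")
  k <- fs[[1]]$k
  stopifnot(all(vapply(fs, `[[`, integer(1), "k") == k))
  info <- do.call(rbind, lapply(fs, `[[`, "info"))
  n <- nrow(info)
  bindmat <- function(field, d3) {
    m <- do.call(rbind, lapply(fs, function(f) matrix(f[[field]], nrow(f$info))))
    array(m, c(n, k, d3))
  }
  meth_features(info, bindmat("seq", 5L), bindmat("sig", 15L), k)
}

#' Read-filtering thresholds
#'
#' Defaults follow the standard low-quality-alignment screen: MAPQ >= 20,
#' primary-alignment length (read length minus soft-clipped bases) at least
#' 80% of the read, and mapping identity at least 80%.
#'
#' @param min_mapq minimum mapping quality.
#' @param min_aligned_fraction minimum aligned fraction of the read.
#' @param min_identity minimum mapping identity.
#' @return object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_mapq = 20, min_aligned_fraction = 0.80,
                              min_identity = 0.80) {
  stopifnot(min_aligned_fraction >= 0, min_aligned_fraction <= 1,
            min_identity >= 0, min_identity <= 1)
  structure(list(min_mapq = min_mapq,
                 min_aligned_fraction = min_aligned_fraction,
                 min_identity = min_identity), class = "filter_thresholds")
}

#' Keep/drop decision for an aligned read
#'
#' Drops a read when its MAPQ is below `min_mapq`, when the fraction of
#' non-soft-clipped bases falls below `min_aligned_fraction`, or when the
#' mapping identity (matching columns over alignment columns, from the edit
#' distance) falls below `min_identity`. Never throws on a valid record.
#'
#' @param read a `signal_read`.
#' @param thresholds a [filter_thresholds()].
#' @return list with `keep` (logical) and `reason`
#'   (`NA`, `"mapq"`, `"aligned_fraction"` or `"identity"`).
#' @export
filter_alignment <- function(read, thresholds = filter_thresholds()) {
  if (read$mapq < thresholds$min_mapq)
    return(list(keep = FALSE, reason = "mapq"))
  ops <- cigar_ops(read$cigar)
  read_len <- nchar(read$basecalled_seq)
  soft <- sum(ops$len[ops$op == "S"])
  if ((read_len - soft) / read_len < thresholds$min_aligned_fraction)
    return(list(keep = FALSE, reason = "aligned_fraction"))
  aligned_cols <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "D")])
  if ((aligned_cols - read$nm) / aligned_cols < thresholds$min_identity)
    return(list(keep = FALSE, reason = "identity"))
  list(keep = TRUE, reason = NA_character_)
}

#' Median/MAD signal standardization
#'
#' `(x - median(x)) / MAD(x)` with the raw (unscaled) median absolute
#' deviation `MAD = median(|x - median(x)|)`. A zero MAD (constant-signal
#' degenerate case) yields an all-zero output.
#'
#' @param signal non-empty numeric vector.
#' @return standardized numeric vector.
#' @export
standardize_signal <- function(signal) {
  if (!length(signal)) stop_fmt("cannot standardize an empty signal array")
  med <- stats::median(signal)
  m <- stats::median(abs(signal - med))
  if (m == 0) return(rep(0, length(signal)))
  (signal - med) / m
}

# Sample exactly n_out values from a base's standardized signal segment:
# >= n_out samples -> evenly spaced deterministic indices floor(j*n/n_out);
# fewer -> cyclic repetition. No RNG.
sample_signals <- function(x, n_out = 15L) {
  n <- length(x)
  if (n >= n_out) x[floor((seq_len(n_out) - 1L) * n / n_out) + 1L]
  else x[((seq_len(n_out) - 1L) %% n) + 1L]
}

.BASE_CODE <- c(A = 0, C = 1, G = 2, T = 3)

#' Extract per-cytosine feature records from one read
#'
#' For each motif site covered by an aligned read base, takes the k-mer of
#' read bases centered on that base (read-space window, in the molecule's own
#' 5'->3' orientation), standardizes the read's raw signal by median/MAD once,
#' samples 15 signals per base from its move-table segment, and assembles the
#' k x 5 sequence-feature and k x 15 signal-feature matrices. Records are
#' skipped when the center read base is not C on the molecule's strand or when
#' the window runs off the read.
#'
#' @param read a `signal_read` that passed filtering.
#' @param sites data.frame of motif sites (see [locate_motif_sites()]).
#' @param k odd k-mer length (default 13).
#' @return a `meth_features` object (possibly empty).
#' @export
extract_features <- function(read, sites, k = 13) {
  if (k %% 2 == 0) stop_fmt("k must be odd")
  read_len <- nchar(read$basecalled_seq)
  empty <- meth_features(
    data.frame(read_id = character(0), chrom = character(0), pos = integer(0),
               strand = character(0), kmer = character(0), label = integer(0),
               stringsAsFactors = FALSE),
    array(0, c(0, k, 5)), array(0, c(0, k, 15)), k)
  if (k > read_len) {
    warning(sprintf("k = %d exceeds read length %d; no features extracted",
                    k, read_len))
    return(empty)
  }
  ops <- cigar_ops(read$cigar)
  ref_span <- sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
  cand <- sites[sites$chrom == read$chrom & sites$strand == read$strand &
                  sites$pos >= read$ref_start &
                  sites$pos < read$ref_start + ref_span, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  ro <- ref_to_read_pos(read, cand$pos)
  # convert reference-orientation read positions to molecule order
  mol <- if (read$strand == "+") ro else read_len - 1L - ro
  half <- (k - 1L) %/% 2L
  ok <- !is.na(mol) & mol - half >= 0L & mol + half <= read_len - 1L
  center <- substring(read$basecalled_seq, mol + 1L, mol + 1L)
  ok <- ok & !is.na(center) & center == "C"
  cand <- cand[ok, , drop = FALSE]
  mol <- mol[ok]
  n <- nrow(cand)
  if (!n) return(empty)
  std <- standardize_signal(read$signal)
  starts <- move_starts(read$move_lens)
  seqa <- array(NA_real_, c(n, k, 5))
  siga <- array(NA_real_, c(n, k, 15))
  ch <- strsplit(read$basecalled_seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(n)) {
    bidx <- (mol[i] - half):(mol[i] + half) + 1L # 1-based base indices
    for (j in seq_len(k)) {
      b <- bidx[j]
      seg <- std[starts[b]:(starts[b] + read$move_lens[b] - 1L)]
      s15 <- sample_signals(seg, 15L)
      siga[i, j, ] <- s15
      seqa[i, j, ] <- c(mean(s15), stats::sd(s15), read$qualities[b],
                        read$move_lens[b], .BASE_CODE[[ch[b]]])
    }
  }
  info <- data.frame(
    read_id = read$read_id, chrom = cand$chrom, pos = cand$pos,
    strand = cand$strand,
    kmer = substring(read$basecalled_seq, mol - half + 1L, mol + half + 1L),
    label = NA_integer_, stringsAsFactors = FALSE)
  meth_features(info, seqa, siga, k)
}

#' Extract features from a read set, applying the alignment filter
#'
#' @param reads list of `signal_read` records.
#' @param sites data.frame of motif sites.
#' @param k odd k-mer length.
#' @param thresholds a [filter_thresholds()]; `NULL` skips filtering.
#' @return a `meth_features` object; attribute `"dropped"` tabulates filter
#'   reasons.
#' @export
extract_read_features <- function(reads, sites, k = 13,
                                  thresholds = filter_thresholds()) {
  dropped <- character(0)
  out <- list()
  for (r in reads) {
    if (!is.null(thresholds)) {
      fl <- filter_alignment(r, thresholds)
      if (!fl$keep) { dropped <- c(dropped, fl$reason); next }
    }
    f <- extract_features(r, sites, k)
    if (n_features(f) > 0) out[[length(out) + 1L]] <- f
  }
  res <- if (length(out)) do.call(features_rbind, out)
  else meth_features(
    data.frame(read_id = character(0), chrom = character(0), pos = integer(0),
               strand = character(0), kmer = character(0), label = integer(0),
               stringsAsFactors = FALSE),
    array(0, c(0, k, 5)), array(0, c(0, k, 15)), k)
  attr(res, "dropped") <- table(dropped)
  res
}

# Per-motif positive-selection thresholds for CHH (strictly greater than).
.CHH_POS_THRESHOLDS <- c(CAA = 0.95,
                         CAC = 0.90, CAT = 0.90, CTA = 0.90, CTT = 0.90,
                         CTC = 0.90,
                         CCA = 0.85, CCT = 0.85, CCC = 0.85)

#' Select high-confidence reference sites from a bisulfite report
#'
#' Applies the per-motif screening rules: negatives are sites with zero
#' methylation frequency; CHH positives require frequency above a per-motif
#' threshold (CAA > 0.95; CAC/CAT/CTA/CTT/CTC > 0.90; CCA/CCT/CCC > 0.85);
#' CHG positives require > 0.98; CpG uses > 0.99 for positives and < 0.02 for
#' negatives. All sites must reach `min_coverage`.
#'
#' @param truth data.frame of site records (from [read_cytosine_report()] or
#'   [simulate_bsseq_report()]).
#' @param context_class one of `"CpG"`, `"CHG"`, `"CHH"`.
#' @param min_coverage minimum bisulfite coverage (inclusive, default 5).
#' @return list with data.frames `positives` and `negatives`.
#' @export
select_reference_sites <- function(truth, context_class, min_coverage = 5) {
  .check_context_class(context_class)
  t <- truth[truth$context == context_class & truth$total >= min_coverage, ,
             drop = FALSE]
  if (context_class == "CHH") {
    unknown <- setdiff(unique(t$trinuc), names(.CHH_POS_THRESHOLDS))
    if (length(unknown))
      stop_fmt("unknown CHH motif(s) in threshold table: %s",
               paste(unknown, collapse = ", "))
    pos <- t[t$freq > .CHH_POS_THRESHOLDS[t$trinuc], , drop = FALSE]
    neg <- t[t$freq == 0, , drop = FALSE]
  } else if (context_class == "CHG") {
    pos <- t[t$freq > 0.98, , drop = FALSE]
    neg <- t[t$freq == 0, , drop = FALSE]
  } else {
    pos <- t[t$freq > 0.99, , drop = FALSE]
    neg <- t[t$freq < 0.02, , drop = FALSE]
  }
  list(positives = pos, negatives = neg)
}

#' Label feature records against reference site sets
#'
#' Matches records on (chrom, pos, strand): records at positive sites get
#' label 1, at negative sites label 0; all other records are dropped.
#'
#' @param features a `meth_features` object.
#' @param reference list with `positives` and `negatives` data.frames (from
#'   [select_reference_sites()]).
#' @return a labeled `meth_features` object.
#' @export
label_features <- function(features, reference) {
  key <- function(d) paste(d$chrom, d$pos, d$strand)
  fk <- key(features$info)
  lab <- rep(NA_integer_, length(fk))
  lab[fk %in% key(reference$positives)] <- 1L
  lab[fk %in% key(reference$negatives)] <- 0L
  out <- features_subset(features, which(!is.na(lab)))
  out$info$label <- lab[!is.na(lab)]
  out
}
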