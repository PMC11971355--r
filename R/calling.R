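#' Adaptive methylation threshold selection
#'
#' Divides the probability range [0.2, 0.9) into 70 intervals of width 0.01,
#' takes each interval's left endpoint as its representative value, bins the
#' calls by methylation probability, and selects the left endpoint of the
#' least-occupied bin as the dataset threshold `P_th` (minimising the sum of
#' false positives and false negatives for a bimodal call distribution).
#' Proportions are relative to the calls inside the range; ties are broken
#' toward the smallest endpoint.
#'
#' @param p_meth numeric vector of per-read methylation probabilities.
#' @return object of class `threshold_result`: list with `p_th`, `bin_edges`
#'   (the 70 left endpoints) and `bin_proportions`.
#' @export
select_threshold <- function(p_meth) {
  edges <- 0.2 + 0.01 * (0:69)
  inside <- p_meth >= 0.2 & p_meth < 0.9
  if (!any(inside))
    stop_fmt(paste("no calls with probability in [0.2, 0.9);",
                   "fall back to P_th = 0.5"))
  bin <- findInterval(p_meth[inside], c(edges, 0.9), rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = 70L)
  prop <- counts / sum(counts)
  structure(list(p_th = edges[which.min(prop)], bin_edges = edges,
                 bin_proportions = prop), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("adaptive threshold P_th = %.2f (%d bins over [0.2, 0.9))\n",
              x$p_th, length(x$bin_edges)))
  invisible(x)
}

#' Binary methylation calls at a threshold
#'
#' A read is called methylated when `p_meth >= P_th` (inclusive).
#'
#' @param calls data.frame with a `p_meth` column (see [model_forward()]).
#' @param threshold a `threshold_result` or a plain numeric threshold.
#' @return `calls` with a logical `methylated` column added.
#' @export
call_methylation <- function(calls, threshold) {
  p_th <- if (inherits(threshold, "threshold_result")) threshold$p_th
  else as.numeric(threshold)
  calls$methylated <- calls$p_meth >= p_th
  calls
}

#' Aggregate per-read calls into per-site methylation frequencies
#'
#' Per (chrom, pos, strand): frequency = methylated reads / total reads.
#' Strands are never merged, so the two cytosines of a CpG pair are reported
#' separately. Sites with coverage below `min_coverage` are retained but
#' flagged unquantified.
#'
#' @param calls data.frame with `chrom`, `pos`, `strand`, `methylated` and
#'   optionally `context`.
#' @param min_coverage minimum reads for a site to count as quantified
#'   (default 10).
#' @return data.frame (`chrom`, `pos`, `strand`, `context`, `coverage`,
#'   `meth_reads`, `freq`, `quantified`), sorted by (chrom, pos, strand).
#' @export
aggregate_site_frequencies <- function(calls, min_coverage = 10) {
  if (!nrow(calls)) stop_fmt("no calls to aggregate")
  key <- paste(calls$chrom, calls$pos, calls$strand, sep = "\r")
  agg <- stats::aggregate(calls$methylated,
                          by = list(key = key), FUN = function(v)
                            c(cov = length(v), meth = sum(v)))
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    pos = as.integer(vapply(parts, `[`, character(1), 2L)),
    strand = vapply(parts, `[`, character(1), 3L),
    coverage = as.integer(agg$x[, "cov"]),
    meth_reads = as.integer(agg$x[, "meth"]),
    stringsAsFactors = FALSE)
  out$context <- if (!is.null(calls$context))
    calls$context[match(agg$key, key)] else NA_character_
  out$freq <- out$meth_reads / out$coverage
  out$quantified <- out$coverage >= min_coverage
  out <- out[order(out$chrom, out$pos, out$strand),
             c("chrom", "pos", "strand", "context", "coverage", "meth_reads",
               "freq", "quantified")]
  rownames(out) <- NULL
  out
}

#' Downsample reads to a target sequencing depth
#'
#' Reads are sampled uniformly without replacement (seeded) until the
#' cumulative aligned bases divided by the genome length first reaches the
#' target depth; depth is defined over aligned bases, not read counts. A
#' target at or above the realized depth returns all reads.
#'
#' @param reads list of `signal_read` records.
#' @param target_depth desired fold coverage (> 0).
#' @param genome_length total reference length in bases.
#' @param seed integer seed.
#' @return subset of `reads`.
#' @export
downsample_reads <- function(reads, target_depth, genome_length, seed = 1) {
  if (!length(reads)) stop_fmt("empty read set")
  if (target_depth <= 0) stop_fmt("target_depth must be positive")
  aligned <- vapply(reads, function(r) {
    ops <- cigar_ops(r$cigar)
    sum(ops$len[ops$op %in% c("M", "=", "X")])
  }, numeric(1))
  if (sum(aligned) / genome_length <= target_depth) return(reads)
  ord <- withr::with_seed(as.integer(seed), sample.int(length(reads)))
  cum <- cumsum(aligned[ord]) / genome_length
  take <- seq_len(which(cum >= target_depth)[1])
  reads[sort(ord[take])]
}

#' Pearson correlation between called and bisulfite site frequencies
#'
#' Restricts to sites quantified by both assays at `min_cov_each` coverage,
#' pairs the frequencies by (chrom, pos, strand), and computes the standard
#' Pearson correlation.
#'
#' @param site_calls data.frame from [aggregate_site_frequencies()].
#' @param truth bisulfite site records (e.g. from [read_cytosine_report()]).
#' @param min_cov_each minimum coverage required of each assay (default 5).
#' @return list with `r` and `n_sites`.
#' @export
pearson_site_correlation <- function(site_calls, truth, min_cov_each = 5) {
  a <- site_calls[site_calls$coverage >= min_cov_each, , drop = FALSE]
  b <- truth[truth$total >= min_cov_each, , drop = FALSE]
  key_a <- paste(a$chrom, a$pos, a$strand)
  key_b <- paste(b$chrom, b$pos, b$strand)
  common <- intersect(key_a, key_b)
  if (length(common) < 2)
    stop_fmt("undefined correlation: fewer than 2 shared quantified sites")
  x <- a$freq[match(common, key_a)]
  y <- b$freq[match(common, key_b)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_fmt("undefined correlation: zero variance in a frequency vector")
  list(r = stats::cor(x, y), n_sites = length(common))
}

# AUC by the rank statistic (Mann-Whitney); average ranks count ties as 1/2.
.auc_rank <- function(labels, scores) {
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_fmt("AUC undefined: single-class label vector")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Average precision (area under the precision-recall curve), processing
# thresholds at unique score values so ties are handled as one step.
.average_precision <- function(labels, scores) {
  if (all(labels == labels[1]))
    stop_fmt("AP undefined: single-class label vector")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  last <- !duplicated(sc, fromLast = TRUE) # last index of each unique score
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / sum(labels == 1)
  sum(diff(c(0, rec)) * prec)
}

.confusion_metrics <- function(labels, called) {
  tp <- sum(labels == 1 & called)
  fp <- sum(labels == 0 & called)
  fn <- sum(labels == 1 & !called)
  tn <- sum(labels == 0 & !called)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn, precision = precision,
       recall = recall, f1 = f1, accuracy = (tp + tn) / length(labels))
}

#' Read-level (single-molecule) evaluation metrics
#'
#' Computes F1, accuracy, recall and precision from the confusion matrix of
#' the probability-comparison call (`p > 0.5`), AUC by the rank statistic and
#' AP as the area under the precision-recall curve. With `replicates > 1`,
#' balanced subsets of `n_per_class` samples per class are drawn with distinct
#' seeded replicates and the metrics are averaged.
#'
#' @param labels integer 0/1 labels.
#' @param probabilities methylation probabilities.
#' @param replicates number of seeded evaluation replicates (default 3).
#' @param n_per_class samples drawn per class per replicate; default is the
#'   minority class size.
#' @param seed integer seed.
#' @return list of averaged metrics (`f1`, `accuracy`, `recall`, `precision`,
#'   `auc`, `ap`) plus the full-data confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
single_molecule_metrics <- function(labels, probabilities, replicates = 3L,
                                    n_per_class = NULL, seed = 1) {
  stopifnot(length(labels) == length(probabilities))
  if (all(labels == labels[1]))
    stop_fmt("AUC/AP undefined: single-class label vector")
  ipos <- which(labels == 1)
  ineg <- which(labels == 0)
  if (is.null(n_per_class)) n_per_class <- min(length(ipos), length(ineg))
  one <- function(idx) {
    lab <- labels[idx]
    p <- probabilities[idx]
    cm <- .confusion_metrics(lab, p > 0.5)
    c(f1 = cm$f1, accuracy = cm$accuracy, recall = cm$recall,
      precision = cm$precision, auc = .auc_rank(lab, p),
      ap = .average_precision(lab, p))
  }
  reps <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(replicates), function(r)
      one(c(resample(ipos, min(n_per_class, length(ipos))),
            resample(ineg, min(n_per_class, length(ineg))))))
  })
  avg <- colMeans(do.call(rbind, reps))
  cm <- .confusion_metrics(labels, probabilities > 0.5)
  c(as.list(avg), list(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                       replicates = replicates))
}

#' SMOTE oversampling of a minority feature set
#'
#' Each synthetic vector is `x + lambda * (x_nn - x)` with `lambda` uniform in
#' [0, 1] and `x_nn` one of the `k_neighbors` nearest minority neighbors of a
#' uniformly drawn minority point `x`. Deterministic under `seed`.
#'
#' @param x numeric matrix, one minority sample per row.
#' @param n_new number of synthetic rows to generate.
#' @param k_neighbors neighborhood size (must be < `nrow(x)`).
#' @param seed integer seed.
#' @return numeric matrix with `n_new` rows.
#' @export
smote_oversample <- function(x, n_new, k_neighbors = 5L, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop_fmt("SMOTE needs at least 2 minority samples")
  if (nrow(x) <= k_neighbors)
    stop_fmt("minority set size (%d) must exceed k_neighbors (%d)",
             nrow(x), k_neighbors)
  if (n_new == 0) return(x[0, , drop = FALSE])
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  nn <- apply(d, 1L, function(row) order(row)[seq_len(k_neighbors)])
  nn <- if (is.matrix(nn)) t(nn) else matrix(nn, ncol = 1L)
  withr::with_seed(as.integer(seed), {
    base <- sample.int(nrow(x), n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    lambda <- stats::runif(n_new)
    x[base, , drop = FALSE] +
      lambda * (x[pick, , drop = FALSE] - x[base, , drop = FALSE])
  })
}
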