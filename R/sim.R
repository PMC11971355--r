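#' Simulator configuration
#'
#' Parameters of the synthetic nanopore/bisulfite generator. Signal is modeled
#' per base as `dwell` samples drawn from
#' `Normal(level(context k-mer) + shift * any-methylated-C-in-context, noise_sd)`,
#' where the context k-mer is the `context_order`-mer covering the base. The
#' methylation-induced level shift therefore bleeds into neighboring bases
#' whose context windows contain the methylated cytosine.
#'
#' @param genome_length reference length in bases.
#' @param gc_fraction expected GC content, in `[0, 1]`.
#' @param read_length_mean mean read length in bases.
#' @param depth mean fold coverage of the simulated read set.
#' @param context_order k of the k-mer level table (default 6).
#' @param meth_level_shift signal-level shift added when a methylated C lies
#'   inside a base's context k-mer (signal units).
#' @param noise_sd per-sample Gaussian noise standard deviation (signal units).
#' @param dwell_mean mean samples per base; dwells are `1 + Poisson(dwell_mean - 1)`
#'   so every base gets at least one sample.
#' @param bs_coverage mean fold coverage of the matched bisulfite report.
#' @param bs_conversion_error probability that a bisulfite call flips state
#'   (incomplete conversion / over-conversion), in `[0, 1]`.
#' @param sub_error_rate per-base substitution rate in the basecalled sequence
#'   (exercises the mapping-identity filter; default 0).
#' @param seed integer seed; every generator is deterministic given the seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 20000, gc_fraction = 0.4,
                       read_length_mean = 2000, depth = 20,
                       context_order = 6, meth_level_shift = 1.5,
                       noise_sd = 1.0, dwell_mean = 9,
                       bs_coverage = 30, bs_conversion_error = 0.005,
                       sub_error_rate = 0, seed = 1) {
  cfg <- list(genome_length = genome_length, gc_fraction = gc_fraction,
              read_length_mean = read_length_mean, depth = depth,
              context_order = context_order,
              meth_level_shift = meth_level_shift, noise_sd = noise_sd,
              dwell_mean = dwell_mean, bs_coverage = bs_coverage,
              bs_conversion_error = bs_conversion_error,
              sub_error_rate = sub_error_rate, seed = as.integer(seed))
  for (f in c("gc_fraction", "bs_conversion_error", "sub_error_rate"))
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop_fmt("%s must be a proportion in [0, 1]", f)
  for (f in c("genome_length", "read_length_mean", "depth", "context_order",
              "bs_coverage", "noise_sd"))
    if (!is_count(cfg[[f]]))
      stop_fmt("%s must be a positive number", f)
  if (!is.numeric(cfg$dwell_mean) || cfg$dwell_mean < 1)
    stop_fmt("dwell_mean must be >= 1 (every base emits at least one sample)")
  if (cfg$meth_level_shift < 0) stop_fmt("meth_level_shift must be >= 0")
  if (cfg$genome_length < cfg$context_order)
    stop_fmt("genome_length must be at least context_order")
  structure(cfg, class = "sim_config")
}

#' Deterministic k-mer signal level table
#'
#' Assigns every possible k-mer of the configured order an expected signal
#' level, drawn once from a fixed-spread uniform so distinct contexts have
#' distinct baseline currents. Regeneration from the same seed is identical.
#'
#' @param order k-mer order (default 6).
#' @param seed integer seed.
#' @return named numeric vector of length `4^order`, class `kmer_level_table`.
#' @export
kmer_level_table <- function(order = 6, seed = 1) {
  stopifnot(is_count(order), order >= 1)
  bases <- c("A", "C", "G", "T")
  kmers <- bases
  if (order > 1) for (i in 2:order) kmers <- as.vector(outer(kmers, bases, paste0))
  lv <- withr::with_seed(as.integer(seed), stats::runif(length(kmers), -2, 2))
  names(lv) <- sort(kmers)
  structure(lv, order = order, seed = as.integer(seed), class = "kmer_level_table")
}

#' Generate a random reference genome
#'
#' @param config a [sim_config()].
#' @return named character vector with one chromosome `"chr1"`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gc <- config$gc_fraction
  seq <- withr::with_seed(config$seed, paste(
    sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
    collapse = ""))
  c(chr1 = seq)
}

#' Assign true methylation frequencies to motif sites
#'
#' Every site of the motif class on both strands receives a frequency drawn
#' from a mixture. Each mixture component is a list with a `weight` and either
#' a point-mass `freq` or a `sampler` function of `n` returning frequencies;
#' point masses support planting fully methylated / unmethylated spikes.
#'
#' @param ref named character vector of chromosome sequences.
#' @param context_class one of `"CpG"`, `"CHG"`, `"CHH"`.
#' @param mixture list of components, e.g.
#'   `list(list(weight = 0.8, freq = 0), list(weight = 0.2, freq = 1))`;
#'   weights must sum to 1.
#' @param seed integer seed.
#' @return data.frame (`chrom`, `pos` 0-based, `strand`, `context`, `trinuc`,
#'   `freq`), one row per motif site.
#' @export
assign_truth_frequencies <- function(ref, context_class, mixture, seed = 1) {
  .check_context_class(context_class)
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop_fmt("mixture weights must sum to 1")
  sites <- locate_motif_sites(ref, context_class)
  n <- nrow(sites)
  sites$freq <- withr::with_seed(as.integer(seed), {
    comp <- sample.int(length(mixture), n, replace = TRUE, prob = w)
    f <- numeric(n)
    for (j in seq_along(mixture)) {
      idx <- which(comp == j)
      if (!length(idx)) next
      m <- mixture[[j]]
      f[idx] <- if (!is.null(m$sampler)) m$sampler(length(idx)) else m$freq
    }
    f
  })
  if (any(sites$freq < 0 | sites$freq > 1))
    stop_fmt("mixture produced frequencies outside [0, 1]")
  sites
}

# Expected signal level per molecule base: k-mer table level plus the
# methylation shift wherever a methylated C falls inside the base's context
# window. `mol` is the molecule sequence 5'->3', `mol_ext` the same with
# `flank` extra context bases on each side, `meth_idx` 1-based methylated
# positions in molecule coordinates.
.base_levels <- function(mol_ext, len, flank, order, offset, table, meth_idx,
                         shift) {
  starts <- seq_len(len) + flank - offset
  kmers <- substring(mol_ext, starts, starts + order - 1L)
  lv <- unname(table[kmers])
  lv[is.na(lv)] <- 0 # windows containing pad characters
  if (length(meth_idx) && shift != 0) {
    hit <- logical(len)
    for (m in meth_idx) {
      lo <- max(1L, m - (order - 1L - offset))
      hi <- min(len, m + offset)
      if (lo <= hi) hit[lo:hi] <- TRUE
    }
    lv <- lv + shift * hit
  }
  lv
}

#' Simulate aligned signal-bearing reads
#'
#' Reads sample a start and strand uniformly; each covered site of the truth
#' table flips a Bernoulli coin with its frequency to set the molecule's
#' methylation state; each base emits `1 + Poisson(dwell_mean - 1)` signal
#' samples around its context level (shifted where a methylated C is in
#' context); alignments are exact to the sampled origin.
#'
#' @param ref named character vector of chromosome sequences.
#' @param truth data.frame from [assign_truth_frequencies()].
#' @param level_table a [kmer_level_table()].
#' @param config a [sim_config()].
#' @return list of `signal_read` records (see [signal_read()]).
#' @export
simulate_reads <- function(ref, truth, level_table, config) {
  stopifnot(inherits(config, "sim_config"), inherits(level_table, "kmer_level_table"))
  if (!length(ref) || any(nchar(ref) == 0)) stop_fmt("empty reference")
  if (config$depth <= 0) stop_fmt("depth must be positive")
  order <- attr(level_table, "order")
  offset <- 2L # base sits at 0-based offset 2 of its context k-mer
  flank <- order
  withr::with_seed(config$seed + 1L, {
    reads <- list()
    rid <- 0L
    for (chrom in names(ref)) {
      s <- ref[[chrom]]
      L <- nchar(s)
      tch <- truth[truth$chrom == chrom, , drop = FALSE]
      n_reads <- max(1L, ceiling(config$depth * L / config$read_length_mean))
      for (i in seq_len(n_reads)) {
        len <- round(stats::rnorm(1, config$read_length_mean,
                                  0.1 * config$read_length_mean))
        len <- max(order + 1L, min(len, L))
        start <- sample.int(L - len + 1L, 1L) - 1L # 0-based
        strand <- sample(c("+", "-"), 1L)
        lo <- start - flank
        hi <- start + len - 1L + flank
        idx <- pmax(0L, pmin(L - 1L, lo:hi))
        ext_fwd <- paste(substring(s, idx + 1L, idx + 1L), collapse = "")
        mol_ext <- if (strand == "+") ext_fwd else revcomp(ext_fwd)
        mol <- substr(mol_ext, flank + 1L, flank + len)
        # methylation states of covered same-strand sites
        cov <- tch[tch$strand == strand & tch$pos >= start &
                     tch$pos < start + len, , drop = FALSE]
        meth_idx <- integer(0)
        if (nrow(cov)) {
          state <- stats::rbinom(nrow(cov), 1L, cov$freq) == 1L
          mp <- cov$pos[state]
          meth_idx <- if (strand == "+") mp - start + 1L
                      else start + len - mp
        }
        levels <- .base_levels(mol_ext, len, flank, order, offset, level_table,
                               meth_idx, config$meth_level_shift)
        dwell <- 1L + stats::rpois(len, config$dwell_mean - 1)
        signal <- stats::rnorm(sum(dwell), rep(levels, dwell), config$noise_sd)
        quals <- pmax(2L, pmin(50L, round(stats::rnorm(len, 30, 4))))
        nm <- 0L
        seq_bc <- mol
        if (config$sub_error_rate > 0) {
          sub <- which(stats::runif(len) < config$sub_error_rate)
          if (length(sub)) {
            ch <- strsplit(mol, "", fixed = TRUE)[[1]]
            for (p in sub)
              ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
            seq_bc <- paste(ch, collapse = "")
            nm <- length(sub)
          }
        }
        rid <- rid + 1L
        reads[[rid]] <- signal_read(
          read_id = sprintf("read_%05d", rid), basecalled_seq = seq_bc,
          qualities = quals, signal = signal, move_lens = dwell,
          chrom = chrom, ref_start = start, strand = strand,
          cigar = paste0(len, "M"), mapq = 60L, nm = nm)
      }
    }
    reads
  })
}

#' Simulate a bisulfite cytosine report matched to a truth table
#'
#' Per site, total coverage is `Poisson(bs_coverage)` and the methylated count
#' is `Binomial(total, p)` with `p = freq * (1 - e) + (1 - freq) * e`, `e`
#' being the conversion-error rate. Sites drawing zero coverage are absent
#' from the report.
#'
#' @param truth data.frame from [assign_truth_frequencies()].
#' @param bs_coverage mean fold coverage (>= 1).
#' @param bs_conversion_error state-flip probability in `[0, 1]`.
#' @param seed integer seed.
#' @return data.frame (`chrom`, `pos` 0-based, `strand`, `context`, `trinuc`,
#'   `meth`, `total`, `freq`, `quantified`), Bismark-report-like content.
#' @export
simulate_bsseq_report <- function(truth, bs_coverage, bs_conversion_error = 0,
                                  seed = 1) {
  if (!is.numeric(bs_coverage) || bs_coverage < 1)
    stop_fmt("bs_coverage must be >= 1")
  if (bs_conversion_error < 0 || bs_conversion_error > 1)
    stop_fmt("bs_conversion_error must be in [0, 1]")
  withr::with_seed(as.integer(seed), {
    total <- stats::rpois(nrow(truth), bs_coverage)
    p <- clamp01(truth$freq * (1 - bs_conversion_error) +
                   (1 - truth$freq) * bs_conversion_error)
    meth <- stats::rbinom(nrow(truth), total, p)
    out <- truth[total > 0, c("chrom", "pos", "strand", "context", "trinuc")]
    out$meth <- meth[total > 0]
    out$total <- total[total > 0]
    out$freq <- out$meth / out$total
    out$quantified <- TRUE
    rownames(out) <- NULL
    out
  })
}
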