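#' Read and write reference FASTA
#'
#' Thin wrappers over Biostrings keeping the package's internal representation
#' (named character vector of chromosome sequences).
#'
#' @param path FASTA file path.
#' @return `read_reference_fasta`: named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_reference_fasta
#' @param ref named character vector of chromosome sequences.
#' @return `write_reference_fasta`: `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref), path)
  invisible(path)
}

#' Read a Bismark-style cytosine report
#'
#' Tab-separated records: chrom, 1-based position, strand, methylated count,
#' unmethylated count, context class, trinucleotide. Positions are converted
#' to 0-based internally; zero-coverage records are retained but flagged
#' unquantified (frequency `NA`).
#'
#' @param path report file path.
#' @return data.frame (`chrom`, `pos` 0-based, `strand`, `context`, `trinuc`,
#'   `meth`, `total`, `freq`, `quantified`).
#' @export
read_cytosine_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos1", "strand", "meth",
                                        "unmeth", "context", "trinuc"),
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer", "character",
                                         "character"),
                          quote = "", comment.char = "")
  bad <- which(df$meth < 0 | df$unmeth < 0 | is.na(df$meth) | is.na(df$unmeth))
  if (length(bad))
    stop_fmt("cytosine report %s: negative or missing counts at line %d",
             path, bad[1])
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad))
    stop_fmt("cytosine report %s: bad strand at line %d", path, bad[1])
  total <- df$meth + df$unmeth
  data.frame(chrom = df$chrom, pos = df$pos1 - 1L, strand = df$strand,
             context = df$context, trinuc = df$trinuc, meth = df$meth,
             total = total,
             freq = ifelse(total > 0, df$meth / total, NA_real_),
             quantified = total > 0, stringsAsFactors = FALSE)
}

#' Write a Bismark-style cytosine report
#'
#' @param report data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `trinuc`, `meth`, `total`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(report, path) {
  stopifnot(all(report$meth <= report$total))
  out <- data.frame(chrom = report$chrom, pos1 = report$pos + 1L,
                    strand = report$strand, meth = report$meth,
                    unmeth = report$total - report$meth,
                    context = report$context, trinuc = report$trinuc)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read feature records
#'
#' Feature TSV: read_id, chrom, pos (0-based), strand, k-mer, label
#' (0/1/NA as `.`), the flattened k x 5 sequence-feature matrix and the
#' flattened k x 15 signal matrix, both comma-separated at six decimals.
#' A header line records k; an empty set writes the header only.
#'
#' @param features a `meth_features` object (see [extract_features()]).
#' @param path file path.
#' @return `write_feature_file`: `path`, invisibly.
#' @export
write_feature_file <- function(features, path) {
  stopifnot(inherits(features, "meth_features"))
  k <- features$k
  n <- nrow(features$info)
  hdr <- sprintf("#plantmeth-features-v1\tk=%d", k)
  lines <- hdr
  if (n > 0) {
    fmt6 <- function(m) apply(m, 1, function(v)
      paste(sprintf("%.6f", v), collapse = ","))
    seqflat <- fmt6(matrix(features$seq, n, k * 5))
    sigflat <- fmt6(matrix(features$sig, n, k * 15))
    lab <- ifelse(is.na(features$info$label), ".",
                  as.character(features$info$label))
    lines <- c(lines, paste(features$info$read_id, features$info$chrom,
                            features$info$pos, features$info$strand,
                            features$info$kmer, lab, seqflat, sigflat,
                            sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_feature_file
#' @return `read_feature_file`: a `meth_features` object.
#' @export
read_feature_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#plantmeth-features-v1"))
    stop_fmt("%s: not a feature file (missing header)", path)
  k <- as.integer(sub(".*k=", "", lines[1]))
  body <- lines[-1]
  n <- length(body)
  info <- data.frame(read_id = character(n), chrom = character(n),
                     pos = integer(n), strand = character(n),
                     kmer = character(n), label = integer(n),
                     stringsAsFactors = FALSE)
  seqm <- matrix(NA_real_, n, k * 5)
  sigm <- matrix(NA_real_, n, k * 15)
  for (i in seq_len(n)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 8L)
      stop_fmt("%s: parse error at line %d (expected 8 fields, found %d)",
               path, i + 1L, length(f))
    sq <- as.numeric(strsplit(f[7], ",", fixed = TRUE)[[1]])
    sg <- as.numeric(strsplit(f[8], ",", fixed = TRUE)[[1]])
    if (length(sq) != k * 5 || length(sg) != k * 15)
      stop_fmt("%s: parse error at line %d (feature lengths %d/%d, expected %d/%d)",
               path, i + 1L, length(sq), length(sg), k * 5, k * 15)
    info$read_id[i] <- f[1]; info$chrom[i] <- f[2]
    info$pos[i] <- as.integer(f[3]); info$strand[i] <- f[4]
    info$kmer[i] <- f[5]
    info$label[i] <- if (f[6] == ".") NA_integer_ else as.integer(f[6])
    seqm[i, ] <- sq; sigm[i, ] <- sg
  }
  meth_features(info, array(seqm, c(n, k, 5)), array(sigm, c(n, k, 15)), k)
}

#' Write per-read methylation calls
#'
#' @param calls data.frame with columns `read_id`, `chrom`, `pos`, `strand`,
#'   `p_meth` and optionally `call`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_read_calls <- function(calls, path) {
  out <- data.frame(read_id = calls$read_id, chrom = calls$chrom,
                    pos = calls$pos, strand = calls$strand,
                    p_meth = sprintf("%.6f", calls$p_meth),
                    call = if (!is.null(calls$call)) calls$call else ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_read_calls
#' @return `read_read_calls`: the calls data.frame.
#' @export
read_read_calls <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c("character", "character", "integer",
                                   "character", "numeric", "character"),
                    stringsAsFactors = FALSE)
}

#' Write per-site methylation calls (bedMethyl-like)
#'
#' Columns: chrom, start (0-based), end (start + 1), context class, coverage,
#' strand, methylation frequency as a percentage with one decimal. Records are
#' written sorted by (chrom, pos, strand); strands are never merged, so a CpG
#' pair yields two rows.
#'
#' @param calls data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `coverage`, `meth_reads`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_site_calls <- function(calls, path) {
  need <- c("chrom", "pos", "strand", "context", "coverage", "meth_reads")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop_fmt("site calls missing column(s): %s",
                             paste(miss, collapse = ", "))
  bad <- which(calls$meth_reads > calls$coverage | calls$coverage <= 0)
  if (length(bad))
    stop_fmt("invalid site record %s:%d:%s (meth_reads %d, coverage %d)",
             calls$chrom[bad[1]], calls$pos[bad[1]], calls$strand[bad[1]],
             calls$meth_reads[bad[1]], calls$coverage[bad[1]])
  o <- order(calls$chrom, calls$pos, calls$strand)
  calls <- calls[o, , drop = FALSE]
  out <- data.frame(chrom = calls$chrom, start = calls$pos,
                    end = calls$pos + 1L, context = calls$context,
                    coverage = calls$coverage, strand = calls$strand,
                    pct = sprintf("%.1f", 100 * calls$meth_reads / calls$coverage))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
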