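#' Write reads in the native signal-alignment dialect
#'
#' A self-describing tab-separated text format carrying the raw signal inline,
#' so the whole pipeline runs without any binary-format dependency. One line
#' per read: read_id, chrom, ref_start (0-based), strand, mapq, nm, cigar,
#' basecalled sequence, comma-separated qualities, comma-separated per-base
#' move-segment lengths, comma-separated signal samples (full precision).
#'
#' @param reads list of `signal_read` records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_alignments <- function(reads, path) {
  for (r in reads) validate_signal_read(r)
  lines <- c(
    "#plantmeth-signal-v1",
    "#read_id\tchrom\tref_start\tstrand\tmapq\tnm\tcigar\tseq\tquals\tmoves\tsignal",
    vapply(reads, function(r) paste(
      r$read_id, r$chrom, r$ref_start, r$strand, r$mapq, r$nm, r$cigar,
      r$basecalled_seq,
      paste(r$qualities, collapse = ","),
      paste(r$move_lens, collapse = ","),
      paste(sprintf("%.17g", r$signal), collapse = ","),
      sep = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

.parse_native_line <- function(line, lineno) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) != 11L)
    stop_fmt("line %d: expected 11 fields, found %d", lineno, length(f))
  rec <- try(signal_read(
    read_id = f[1], chrom = f[2], ref_start = as.integer(f[3]), strand = f[4],
    mapq = as.integer(f[5]), nm = as.integer(f[6]), cigar = f[7],
    basecalled_seq = f[8],
    qualities = as.integer(strsplit(f[9], ",", fixed = TRUE)[[1]]),
    move_lens = as.integer(strsplit(f[10], ",", fixed = TRUE)[[1]]),
    signal = as.numeric(strsplit(f[11], ",", fixed = TRUE)[[1]])),
    silent = TRUE)
  if (inherits(rec, "try-error"))
    stop_fmt("malformed record at line %d: %s", lineno,
             trimws(attr(rec, "condition")$message))
  rec
}

#' Parse signal-bearing alignments
#'
#' Reads the native dialect, or a SAM text dialect whose records carry an
#' ONT-style stride-annotated move vector in the `mv:B:c` tag (the raw signal
#' is then supplied separately through `signals`, playing the role of the
#' signal file). Records violating the `signal_read` invariants stop parsing
#' with a positional diagnostic; nothing is silently dropped.
#'
#' @param path input file path.
#' @param dialect `"native"` or `"sam"`.
#' @param signals for the SAM dialect, a named list mapping read_id to its
#'   numeric signal array.
#' @return list of `signal_read` records.
#' @export
parse_signal_alignments <- function(path, dialect = c("native", "sam"),
                                    signals = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path)
  if (dialect == "native") {
    body <- which(!startsWith(lines, "#"))
    return(lapply(body, function(i) .parse_native_line(lines[i], i)))
  }
  body <- which(!startsWith(lines, "@") & nzchar(lines))
  lapply(body, function(i) .parse_sam_line(lines[i], i, signals))
}

.sam_tag <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(paste0("^", tag, ":[AifZHB]:?"), "", hit[1])
}

.parse_sam_line <- function(line, lineno, signals) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 11L)
    stop_fmt("line %d: SAM record has fewer than 11 fields", lineno)
  flag <- as.integer(f[2])
  minus <- bitwAnd(flag, 16L) > 0L
  seq_sam <- f[10]
  qual_sam <- f[11]
  seq_mol <- if (minus) revcomp(seq_sam) else seq_sam
  quals <- utf8ToInt(qual_sam) - 33L
  if (minus) quals <- rev(quals)
  mv <- .sam_tag(f[-(1:11)], "mv")
  if (is.null(mv))
    stop_fmt("line %d: unusable record, missing mv move-table tag", lineno)
  mvv <- strsplit(mv, ",", fixed = TRUE)[[1]]
  if (mvv[1] != "c" || length(mvv) < 3L)
    stop_fmt("line %d: malformed mv tag", lineno)
  stride <- as.integer(mvv[2])
  moves <- as.integer(mvv[-(1:2)])
  if (is.na(stride) || stride < 1L || anyNA(moves))
    stop_fmt("line %d: malformed mv tag", lineno)
  nm <- .sam_tag(f[-(1:11)], "NM")
  ns <- .sam_tag(f[-(1:11)], "ns") # number of signal samples, if present
  if (is.null(signals) || is.null(signals[[f[1]]]))
    stop_fmt("line %d: unusable record, no signal supplied for read %s",
             lineno, f[1])
  signal <- as.numeric(signals[[f[1]]])
  n_samples <- if (!is.null(ns)) as.integer(ns) else length(signal)
  if (n_samples != length(signal))
    stop_fmt("line %d: ns tag (%s) disagrees with supplied signal length %d",
             lineno, ns, length(signal))
  # Reconstruct per-base segments: moves mark, per stride-sized signal chunk,
  # whether a new base starts there. Base i spans from its chunk start to the
  # chunk before the next base's start; the last base runs to the signal end.
  if (length(moves) * stride < n_samples || moves[1] != 1L)
    stop_fmt("line %d: move vector does not cover the signal", lineno)
  starts <- (which(moves == 1L) - 1L) * stride + 1L
  if (length(starts) != nchar(seq_mol))
    stop_fmt("line %d: move table marks %d bases but sequence has %d",
             lineno, length(starts), nchar(seq_mol))
  if (any(starts > n_samples))
    stop_fmt("line %d: move table advances past the signal end", lineno)
  move_lens <- diff(c(starts, n_samples + 1L))
  rec <- try(signal_read(
    read_id = f[1], chrom = f[3], ref_start = as.integer(f[4]) - 1L,
    strand = if (minus) "-" else "+", mapq = as.integer(f[5]), cigar = f[6],
    basecalled_seq = seq_mol, qualities = quals, signal = signal,
    move_lens = move_lens, nm = if (is.null(nm)) 0L else as.integer(nm)),
    silent = TRUE)
  if (inherits(rec, "try-error"))
    stop_fmt("malformed record at line %d: %s", lineno,
             trimws(attr(rec, "condition")$message))
  rec
}

#' Write reads as SAM text with a move-table tag
#'
#' Emits the optional real-data-shaped surface: SAM mandatory columns plus
#' `mv:B:c` (stride 1: one move flag per signal sample), `NM:i` and `ns:i`.
#' Signal itself is not stored in SAM; [parse_signal_alignments()] takes it
#' through its `signals` argument.
#'
#' @param reads list of `signal_read` records.
#' @param path output file path.
#' @param ref_lengths named integer vector of chromosome lengths for `@SQ`.
#' @return named list of signal arrays keyed by read_id (what a signal file
#'   would hold), invisibly.
#' @export
write_sam_alignments <- function(reads, path, ref_lengths) {
  for (r in reads) validate_signal_read(r)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  body <- vapply(reads, function(r) {
    minus <- r$strand == "-"
    seq_sam <- if (minus) revcomp(r$basecalled_seq) else r$basecalled_seq
    quals <- if (minus) rev(r$qualities) else r$qualities
    moves <- integer(length(r$signal))
    moves[move_starts(r$move_lens)] <- 1L
    paste(r$read_id, if (minus) 16L else 0L, r$chrom, r$ref_start + 1L,
          r$mapq, r$cigar, "*", 0L, 0L, seq_sam,
          intToUtf8(quals + 33L),
          sprintf("NM:i:%d", r$nm),
          sprintf("ns:i:%d", length(r$signal)),
          paste0("mv:B:c,1,", paste(moves, collapse = ",")),
          sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(stats::setNames(lapply(reads, `[[`, "signal"),
                            vapply(reads, `[[`, character(1), "read_id")))
}
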