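#' Construct and validate an aligned signal-bearing read
#'
#' One basecalled read with its raw signal and the move table linking each
#' base to its span of signal samples. The basecalled sequence, qualities and
#' move table are stored in the molecule's own 5'->3' (sequencing) order;
#' `strand` records the alignment orientation and `cigar` is in reference
#' orientation, as in SAM.
#'
#' @param read_id read identifier.
#' @param basecalled_seq basecalled sequence over A/C/G/T, molecule order.
#' @param qualities integer per-base quality scores.
#' @param signal numeric raw-signal array (signal units).
#' @param move_lens integer per-base signal-segment lengths (>= 1); segments
#'   are contiguous and tile the signal array exactly.
#' @param chrom reference name.
#' @param ref_start 0-based leftmost reference position of the alignment.
#' @param strand `"+"` or `"-"`.
#' @param cigar CIGAR string consuming exactly `nchar(basecalled_seq)` read bases.
#' @param mapq mapping quality, 0-60.
#' @param nm edit distance to the reference (NM).
#' @return object of class `signal_read`.
#' @export
signal_read <- function(read_id, basecalled_seq, qualities, signal, move_lens,
                        chrom, ref_start, strand, cigar, mapq, nm = 0L) {
  x <- structure(list(
    read_id = as.character(read_id), basecalled_seq = as.character(basecalled_seq),
    qualities = as.integer(qualities), signal = as.numeric(signal),
    move_lens = as.integer(move_lens), chrom = as.character(chrom),
    ref_start = as.integer(ref_start), strand = as.character(strand),
    cigar = as.character(cigar), mapq = as.integer(mapq), nm = as.integer(nm)),
    class = "signal_read")
  validate_signal_read(x)
  x
}

#' Validate a signal_read's invariants
#'
#' @param x a `signal_read`.
#' @return `x` invisibly; stops with a diagnostic on the first violation.
#' @export
validate_signal_read <- function(x) {
  n <- nchar(x$basecalled_seq)
  id <- x$read_id
  if (length(x$qualities) != n)
    stop_fmt("read %s: %d qualities for %d bases", id, length(x$qualities), n)
  if (length(x$move_lens) != n)
    stop_fmt("read %s: %d move segments for %d bases", id, length(x$move_lens), n)
  if (any(x$move_lens < 1L))
    stop_fmt("read %s: move segment of length < 1", id)
  if (sum(x$move_lens) != length(x$signal))
    stop_fmt("read %s: move segments sum to %d but signal has %d samples",
             id, sum(x$move_lens), length(x$signal))
  if (!x$strand %in% c("+", "-"))
    stop_fmt("read %s: strand must be + or -", id)
  if (is.na(x$mapq) || x$mapq < 0 || x$mapq > 60)
    stop_fmt("read %s: mapq outside 0-60", id)
  ops <- cigar_ops(x$cigar)
  consumed <- sum(ops$len[ops$op %in% c("M", "=", "X", "I", "S")])
  if (consumed != n)
    stop_fmt("read %s: cigar consumes %d read bases but sequence has %d",
             id, consumed, n)
  invisible(x)
}

#' Parse a CIGAR string into operations
#'
#' @param cigar CIGAR string.
#' @return data.frame with columns `op` and `len`.
#' @export
cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*")
    stop_fmt("missing cigar")
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(lens) != length(ops) ||
      nchar(cigar) != sum(nchar(lens)) + length(ops))
    stop_fmt("malformed cigar '%s'", cigar)
  data.frame(op = ops, len = lens, stringsAsFactors = FALSE)
}

# Per-base signal segment starts (1-based into the signal array).
move_starts <- function(move_lens) {
  cumsum(c(1L, move_lens[-length(move_lens)]))
}

# Map 0-based reference positions to 0-based read positions in reference
# orientation. Returns an integer vector aligned with `ref_pos`; NA where the
# reference base is deleted or outside the alignment.
ref_to_read_pos <- function(read, ref_pos) {
  ops <- cigar_ops(read$cigar)
  out <- rep(NA_integer_, length(ref_pos))
  rp <- read$ref_start # 0-based ref cursor
  qp <- 0L             # 0-based read cursor (ref orientation)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      hit <- ref_pos >= rp & ref_pos < rp + len
      out[hit] <- qp + (ref_pos[hit] - rp)
      rp <- rp + len; qp <- qp + len
    } else if (op %in% c("I", "S")) {
      qp <- qp + len
    } else if (op %in% c("D", "N")) {
      rp <- rp + len
    } # H, P consume nothing here
  }
  out
}
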