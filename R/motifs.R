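#' Classify a cytosine trinucleotide context
#'
#' The 3-mer is read 5'->3' on the strand carrying the cytosine, starting at
#' the C. `CG.` is CpG (takes precedence), `C.G` is CHG, and `CHH` covers the
#' rest, with H being A, C or T.
#'
#' @param trinuc character vector of 3-mers whose first base is C.
#' @return character vector over `"CpG"`, `"CHG"`, `"CHH"` (`NA` for 3-mers
#'   containing non-ACGT bases).
#' @export
classify_trinuc <- function(trinuc) {
  stopifnot(all(nchar(trinuc) == 3L))
  if (any(substr(trinuc, 1L, 1L) != "C"))
    stop_fmt("trinucleotide context must start with C")
  b2 <- substr(trinuc, 2L, 2L)
  b3 <- substr(trinuc, 3L, 3L)
  out <- rep(NA_character_, length(trinuc))
  ok <- b2 %in% c("A", "C", "G", "T") & b3 %in% c("A", "C", "G", "T")
  out[ok & b2 == "G"] <- "CpG"
  out[ok & b2 != "G" & b3 == "G"] <- "CHG"
  out[ok & b2 != "G" & b3 != "G"] <- "CHH"
  out
}

.check_context_class <- function(context_class) {
  if (!is.character(context_class) || length(context_class) != 1L ||
      !context_class %in% c("CpG", "CHG", "CHH"))
    stop_fmt("unknown motif class '%s' (must be CpG, CHG or CHH)",
             paste(context_class, collapse = ","))
  context_class
}

#' Locate cytosine motif sites on both strands of a reference
#'
#' Scans every chromosome for cytosines whose trinucleotide context (starting
#' at the C, read 5'->3' on the C-bearing strand) matches the requested class.
#' Minus-strand cytosines appear as G on the forward sequence; their positions
#' are reported in forward-strand coordinates, as in Bismark cytosine reports.
#' Sites whose 3-mer context would run past the chromosome end are skipped.
#'
#' @param ref named character vector of chromosome sequences.
#' @param context_class one of `"CpG"`, `"CHG"`, `"CHH"`.
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `trinuc`.
#' @export
locate_motif_sites <- function(ref, context_class) {
  .check_context_class(context_class)
  stopifnot(is.character(ref), length(ref) >= 1L, !is.null(names(ref)))
  scan_one <- function(chrom) {
    s <- ref[[chrom]]
    L <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    # forward strand: C with two bases of right context
    ip <- which(ch == "C")
    ip <- ip[ip + 2L <= L]
    trip <- substring(s, ip, ip + 2L)
    clsp <- if (length(ip)) classify_trinuc(trip) else character(0)
    keepp <- !is.na(clsp) & clsp == context_class
    # reverse strand: G on forward with two bases of left context
    im <- which(ch == "G")
    im <- im[im - 2L >= 1L]
    trim <- revcomp(substring(s, im - 2L, im))
    clsm <- if (length(im)) classify_trinuc(trim) else character(0)
    keepm <- !is.na(clsm) & clsm == context_class
    n_hit <- sum(keepp) + sum(keepm)
    data.frame(
      chrom = rep(chrom, n_hit),
      pos = c(ip[keepp] - 1L, im[keepm] - 1L),
      strand = c(rep("+", sum(keepp)), rep("-", sum(keepm))),
      context = rep(context_class, n_hit),
      trinuc = c(trip[keepp], trim[keepm]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(names(ref), scan_one))
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count distinct k-mers centered on a cytosine motif
#'
#' Counts k-mers whose central base is the C of a motif of the given class,
#' with the motif occupying the center and the two following positions
#' (e.g. all 9-mers centered on a CHH motif: 4^6 * 9 = 36,864).
#'
#' @param k odd k-mer length, k >= 3.
#' @param context_class one of `"CpG"`, `"CHG"`, `"CHH"`.
#' @return numeric count.
#' @export
count_motif_kmers <- function(k, context_class) {
  .check_context_class(context_class)
  if (!is_count(k) || k < 3 || k %% 2 == 0)
    stop_fmt("k must be an odd integer >= 3, got %s", format(k))
  bases <- c("A", "C", "G", "T")
  tri <- as.vector(outer(outer("C", bases, paste0), bases, paste0))
  n_motifs <- sum(classify_trinuc(tri) == context_class)
  4^(k - 3) * n_motifs
}
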