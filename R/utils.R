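#' @keywords internal
"_PACKAGE"

# Base complement lookup; sequences are uppercase ACGT (N allowed, maps to N).
.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, uppercase).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(.COMP[ch])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

# sample() misbehaves when x is a single integer; this never does.
resample <- function(x, size) x[sample.int(length(x), size)]

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
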