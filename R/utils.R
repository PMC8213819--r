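# Shared low-level helpers: IUPAC alphabet, reverse complement, rolling means,
# integer encoding of DNA. Everything downstream assumes uppercase A/C/G/T/N
# plus IUPAC ambiguity codes in patterns.

#' IUPAC nucleotide code table
#'
#' Named list mapping each IUPAC nucleotide code to the set of concrete bases
#' it allows. `N` allows all four bases.
#'
#' @format Named list of character vectors.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.IUPAC_FROM <- "ACGTRYSWKMBDHVN-"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN-"

#' Reverse complement of a nucleotide or IUPAC string
#'
#' Complements IUPAC ambiguity codes correctly (e.g. `R` -> `Y`), preserves
#' gap characters (`-`), and reverses the sequence.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("TAATGA")   # "TCATTA"
#' revcomp("YCCCNNGGGR")  # its own reverse complement
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- chartr(.IUPAC_FROM, .IUPAC_TO, toupper(s))
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# split a sequence string into a character vector of single bases
.seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

# rolling mean with truncated (not NA) edge windows; NAs in x are dropped
# from both numerator and denominator of the affected windows
.roll_mean_trunc <- function(x, w) {
  n <- length(x)
  if (w < 1) stop("window must be >= 1")
  if (w >= n) w <- n
  xz <- ifelse(is.na(x), 0, x)
  cs <- c(0, cumsum(xz))
  ct <- c(0, cumsum(!is.na(x)))
  hl <- (w - 1L) %/% 2L
  hr <- w %/% 2L
  i <- seq_len(n)
  left <- pmax(1L, i - hl)
  right <- pmin(n, i + hr)
  num <- cs[right + 1L] - cs[left]
  den <- ct[right + 1L] - ct[left]
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

.BASES <- c("A", "C", "G", "T")

# integer encoding: A=1 C=2 G=3 T=4, anything else NA
.dna_int <- function(chars) match(chars, .BASES)

.validate_iupac <- function(pattern) {
  ch <- .seq_chars(pattern)
  bad <- setdiff(unique(ch), names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC character(s) in pattern: ", paste(bad, collapse = ", "))
  }
  if (length(ch) < 1) stop("pattern must have length >= 1")
  ch
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# GRanges constructor tolerant of length-0 ranges with a scalar seqname
.gr <- function(chrom, ranges) {
  GenomicRanges::GRanges(rep(chrom, length(ranges)), ranges)
}
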