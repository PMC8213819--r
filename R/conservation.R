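# Per-base conservation tracks, percent-identity profiles from pairwise
# alignments, and conserved-segment calling. A track is a dense numeric
# vector anchored at a genomic position; missing coverage is NA, never 0.

#' Construct a per-base conservation track
#'
#' @param chrom Chromosome name.
#' @param start 1-based genomic position of the first score.
#' @param score Numeric vector, one value per base; `NA` marks bases with no
#'   coverage.
#' @return An object of class `conservation_track`.
#' @export
conservation_track <- function(chrom, start, score) {
  stopifnot(length(chrom) == 1, length(start) == 1, start >= 1)
  structure(list(chrom = as.character(chrom), start = as.integer(start),
                 score = as.numeric(score)),
            class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat("conservation_track on", x$chrom, "spanning",
      x$start, "-", x$start + length(x$score) - 1L,
      sprintf("(%d bases, %d missing)\n",
              length(x$score), sum(is.na(x$score))))
  invisible(x)
}

#' Read a conservation track from bedGraph or wiggle
#'
#' Uses rtracklayer and expands interval scores to per-base resolution over
#' the covered span; bases inside the span with no record become `NA`.
#'
#' @param path Path to a bedGraph (`.bedgraph`/`.bg`) or wiggle (`.wig`)
#'   file covering a single chromosome.
#' @return A `conservation_track`.
#' @export
read_track <- function(path) {
  fmt <- if (grepl("\\.wig$", path, ignore.case = TRUE)) "wig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  chroms <- unique(as.character(GenomeInfoDb::seqnames(gr)))
  if (length(chroms) != 1) stop("track must cover a single chromosome")
  s0 <- min(BiocGenerics::start(gr))
  e0 <- max(BiocGenerics::end(gr))
  sc <- rep(NA_real_, e0 - s0 + 1L)
  for (i in seq_along(gr)) {
    idx <- (BiocGenerics::start(gr)[i] - s0 + 1L):(BiocGenerics::end(gr)[i] - s0 + 1L)
    sc[idx] <- gr$score[i]
  }
  conservation_track(chroms, s0, sc)
}

#' Write a conservation track as bedGraph
#'
#' @param track A `conservation_track`.
#' @param path Output path.
#' @export
write_track_bedgraph <- function(track, path) {
  ok <- !is.na(track$score)
  pos <- track$start - 1L + which(ok)   # 0-based starts on disk
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%.6g", track$chrom, pos - 1L, pos,
                     track$score[ok]), con)
  invisible(path)
}

#' Smooth a track with a centered rolling mean
#'
#' Edge windows are truncated rather than dropped; `NA` bases do not
#' contribute to either numerator or denominator.
#'
#' @param track A `conservation_track`.
#' @param window Window size in bases.
#' @return A smoothed `conservation_track`.
#' @export
smooth_track <- function(track, window) {
  conservation_track(track$chrom, track$start,
                     .roll_mean_trunc(track$score, window))
}

#' Percent-identity profile of a pairwise alignment
#'
#' PipMaker-style percent-identity plot: for each reference base, the
#' percentage of identical columns in a centered window of the given size
#' (truncated at the edges). Columns where the reference row carries a gap
#' are dropped entirely; a gap in the other row counts as a mismatch.
#'
#' @param ref_row,other_row Equal-length gapped rows over `A/C/G/T/N/-`.
#' @param window Window size in reference bases (>= 1).
#' @param chrom,start Coordinates to anchor the resulting track (defaults:
#'   `"aln"`, 1).
#' @return A `conservation_track` with values in `[0, 100]`, one per
#'   ungapped reference base.
#' @export
percent_identity_profile <- function(ref_row, other_row, window,
                                     chrom = "aln", start = 1L) {
  a <- .seq_chars(ref_row)
  b <- .seq_chars(other_row)
  if (length(a) != length(b)) stop("rows must have equal length")
  keep <- a != "-"
  if (!any(keep)) stop("empty alignment (reference all gaps)")
  if (window < 1) stop("window must be >= 1")
  a <- a[keep]
  b <- b[keep]
  ident <- as.numeric(a == b & b != "-")
  conservation_track(chrom, start, 100 * .roll_mean_trunc(ident, window))
}

#' Call conserved segments from a track
#'
#' Finds maximal runs of bases with score at or above a threshold, merges
#' runs separated by at most `merge_gap` sub-threshold bases, and discards
#' merged runs shorter than `min_len`. When no absolute `threshold` is
#' given, it defaults to the `percentile` quantile of the non-missing
#' scores.
#'
#' @param track A `conservation_track`.
#' @param threshold Absolute score cutoff; overrides `percentile`.
#' @param percentile Track quantile used when `threshold` is `NULL`
#'   (default 0.9).
#' @param min_len Minimum segment length in bases (default 50).
#' @param merge_gap Maximum sub-threshold gap to bridge (default 20).
#' @return [GenomicRanges::GRanges] of segments, sorted and non-overlapping,
#'   with metadata columns `mean_score` and `max_score` (computed over the
#'   segment's non-missing bases) and an attribute `threshold`.
#' @export
call_conserved_segments <- function(track, threshold = NULL, percentile = 0.9,
                                    min_len = 50L, merge_gap = 20L) {
  stopifnot(min_len >= 1, merge_gap >= 0)
  sc <- track$score
  if (is.null(threshold)) {
    threshold <- stats::quantile(sc, percentile, na.rm = TRUE, names = FALSE)
  }
  above <- !is.na(sc) & sc >= threshold
  if (any(above) && merge_gap > 0) {
    r <- rle(above)
    nr <- length(r$values)
    bridge <- !r$values & r$lengths <= merge_gap &
      seq_len(nr) > 1L & seq_len(nr) < nr
    r$values[bridge] <- TRUE
    above <- inverse.rle(r)
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  gs <- starts[keep]
  ge <- ends[keep]
  seg <- .gr(track$chrom,
             IRanges::IRanges(start = track$start + gs - 1L,
                              end = track$start + ge - 1L))
  stats_f <- function(f) {
    vapply(seq_along(gs), function(i) {
      v <- sc[gs[i]:ge[i]]
      if (all(is.na(v))) NA_real_ else f(v, na.rm = TRUE)
    }, numeric(1))
  }
  S4Vectors::mcols(seg)$mean_score <- stats_f(mean)
  S4Vectors::mcols(seg)$max_score <- stats_f(max)
  attr(seg, "threshold") <- threshold
  seg
}
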