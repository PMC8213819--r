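# Genomic coordinate model and interval arithmetic. Internally every interval
# is a GRanges in the Bioconductor convention (1-based, fully closed); printed
# coordinates enter and leave through an explicit convention tag because
# published coordinates mix conventions.

#' Supported printed-coordinate conventions
#' @export
COORDINATE_CONVENTIONS <- c(
  "zero_based_half_open",
  "one_based_fully_closed",
  "one_based_end_exclusive"
)

#' Parse a printed coordinate string into a GRanges
#'
#' Accepts strings of the form `"chr10: 23,806,234-23,807,226"` (whitespace
#' and thousands separators optional) together with the convention the
#' numbers were printed in, and returns a 1-based fully-closed [GRanges]
#' holding the same genomic bases. Zero-length intervals (possible under the
#' half-open and end-exclusive conventions) become zero-width ranges.
#'
#' @param text Coordinate string, `"chrom: start-end"`.
#' @param convention One of [COORDINATE_CONVENTIONS].
#' @return A length-1 [GenomicRanges::GRanges].
#' @examples
#' # a 993 bp deletion printed in fully-closed coordinates
#' interval_length(parse_interval("chr10: 23,806,234-23,807,226",
#'                                "one_based_fully_closed"))
#' # a 698 bp element printed in end-exclusive coordinates
#' interval_length(parse_interval("chr10: 23,806,280-23,806,978",
#'                                "one_based_end_exclusive"))
#' @export
parse_interval <- function(text, convention = COORDINATE_CONVENTIONS) {
  convention <- match.arg(convention)
  m <- regexec("^\\s*(\\S+?)\\s*:\\s*([0-9][0-9,]*)\\s*-\\s*([0-9][0-9,]*)\\s*$",
               text)
  parts <- regmatches(text, m)[[1]]
  if (length(parts) != 4) {
    stop("malformed coordinate string: ", text)
  }
  chrom <- parts[2]
  s <- as.numeric(gsub(",", "", parts[3], fixed = TRUE))
  e <- as.numeric(gsub(",", "", parts[4], fixed = TRUE))
  se <- switch(convention,
    zero_based_half_open    = c(s + 1, e),
    one_based_fully_closed  = c(s, e),
    one_based_end_exclusive = c(s, e - 1)
  )
  if (se[2] < se[1] - 1) {
    stop("start > end after conversion in: ", text)
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = se[1], end = se[2]))
}

#' Format a GRanges back into a printed coordinate string
#'
#' Inverse of [parse_interval()]: re-emits the numeric fields under the
#' requested convention so that parse/format round-trips are lossless.
#'
#' @param iv A [GenomicRanges::GRanges].
#' @param convention One of [COORDINATE_CONVENTIONS].
#' @param big_mark Thousands separator (default `","`; use `""` for none).
#' @return Character vector of coordinate strings.
#' @export
format_interval <- function(iv, convention = COORDINATE_CONVENTIONS,
                            big_mark = ",") {
  convention <- match.arg(convention)
  if (length(iv) == 0) return(character(0))
  s <- BiocGenerics::start(iv)
  e <- BiocGenerics::end(iv)
  out <- switch(convention,
    zero_based_half_open    = cbind(s - 1, e),
    one_based_fully_closed  = cbind(s, e),
    one_based_end_exclusive = cbind(s, e + 1)
  )
  fmt <- function(x) formatC(x, format = "d", big.mark = big_mark)
  paste0(as.character(GenomeInfoDb::seqnames(iv)), ": ",
         fmt(out[, 1]), "-", fmt(out[, 2]))
}

#' Interval length in base pairs
#'
#' @param iv A [GenomicRanges::GRanges].
#' @return Integer vector of widths.
#' @export
interval_length <- function(iv) {
  BiocGenerics::width(iv)
}

# restrict a GRanges to one chromosome and rebuild it with that single
# seqlevel so that set operations do not fight over seqinfo
.on_chrom <- function(gr, chrom) {
  if (length(gr) == 0) {
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges()))
  }
  keep <- as.character(GenomeInfoDb::seqnames(gr)) == chrom
  .gr(chrom, IRanges::ranges(gr[keep]))
}

#' Intergenic complement of an annotation within bounds
#'
#' Returns the sorted, non-overlapping complement of the union of all gene
#' and pseudogene footprints within `bounds`. The footprint of a gene is its
#' whole transcript interval (not exon-only), so UTRs and introns are
#' excluded from the intergenic space, as are standalone pseudogene
#' fragments.
#'
#' @param ann An [annotation_set()] or a [GenomicRanges::GRanges] of
#'   footprints.
#' @param bounds Length-1 [GenomicRanges::GRanges]; the searched span.
#' @return [GenomicRanges::GRanges] of intergenic intervals.
#' @export
intergenic_regions <- function(ann, bounds) {
  if (length(bounds) != 1) stop("bounds must be a single interval")
  chrom <- as.character(GenomeInfoDb::seqnames(bounds))[1]
  fp <- if (inherits(ann, "annotation_set")) gene_footprints(ann) else ann
  if (length(fp) > 0 &&
      !chrom %in% unique(as.character(GenomeInfoDb::seqnames(fp)))) {
    stop("annotation chromosome mismatch: no features on ", chrom)
  }
  fp <- GenomicRanges::reduce(.on_chrom(fp, chrom))
  bounds <- GenomicRanges::GRanges(chrom, IRanges::ranges(bounds))
  BiocGenerics::sort(GenomicRanges::setdiff(bounds, fp, ignore.strand = TRUE))
}

#' Remove masked (e.g. repeat) bases from a set of regions
#'
#' Every returned base lies in some input region and in no mask interval.
#' Abutting mask intervals behave identically to a single merged mask.
#'
#' @param regions [GenomicRanges::GRanges] of regions.
#' @param mask [GenomicRanges::GRanges] of masked intervals.
#' @return [GenomicRanges::GRanges] of unmasked sub-regions, sorted.
#' @export
subtract_mask <- function(regions, mask) {
  if (length(regions) == 0) return(regions)
  chroms <- unique(as.character(GenomeInfoDb::seqnames(regions)))
  out <- lapply(chroms, function(ch) {
    r <- .on_chrom(regions, ch)
    m <- GenomicRanges::reduce(.on_chrom(mask, ch))
    GenomicRanges::setdiff(r, m, ignore.strand = TRUE)
  })
  BiocGenerics::sort(do.call(c, out))
}
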