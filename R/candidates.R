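# The integrated discovery procedure: conserved segments, intersected with
# the intergenic and non-repetitive search space, annotated with motif
# content and ranked. One operation reproduces the element-discovery logic
# end to end; a config object fully determines a run.

#' Pipeline configuration for the candidate caller
#'
#' All thresholds in one serializable object. The conservation rule
#' defaults to a rolling-mean smoothing of the per-base track followed by
#' an absolute cutoff; set `cons_percentile` (and `cons_threshold = NULL`)
#' to use a track-quantile cutoff instead.
#'
#' @param bounds Optional [GenomicRanges::GRanges] restricting the search;
#'   default: the span of the conservation track.
#' @param smooth_window Rolling-mean window in bp applied to the track
#'   before segment calling (default 100).
#' @param cons_threshold Absolute score cutoff on the smoothed track
#'   (default 0.9, on the species-agreement scale of
#'   [derive_conservation()]).
#' @param cons_percentile Track quantile cutoff used when `cons_threshold`
#'   is `NULL`.
#' @param min_len,merge_gap Segment-calling parameters (defaults 50, 20).
#' @param hd_pattern Core homeodomain motif (default `"TAATNN"`).
#' @param oe_pattern O/E-like motif (default `"YCCCNNGGGR"`).
#' @param cluster_pattern,cluster_k,cluster_window Motif-cluster rule
#'   (default: 3 x `TAATGA` within 206 bp).
#' @param min_support Cross-species support fraction for a conserved motif
#'   call (default 0.8).
#' @param require_hd Gate candidates on containing at least one HD match
#'   (default `FALSE`: motif content annotates and ranks but does not
#'   gate).
#' @param seed Seed recorded with the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bounds = NULL, smooth_window = 100L,
                            cons_threshold = 0.9, cons_percentile = NULL,
                            min_len = 50L, merge_gap = 20L,
                            hd_pattern = "TAATNN",
                            oe_pattern = "YCCCNNGGGR",
                            cluster_pattern = "TAATGA", cluster_k = 3L,
                            cluster_window = 206L, min_support = 0.8,
                            require_hd = FALSE, seed = NULL) {
  if (is.null(cons_threshold) && is.null(cons_percentile)) {
    stop("one of cons_threshold or cons_percentile must be set")
  }
  structure(list(bounds = bounds, smooth_window = smooth_window,
                 cons_threshold = cons_threshold,
                 cons_percentile = cons_percentile, min_len = min_len,
                 merge_gap = merge_gap, hd_pattern = hd_pattern,
                 oe_pattern = oe_pattern,
                 cluster_pattern = cluster_pattern, cluster_k = cluster_k,
                 cluster_window = cluster_window,
                 min_support = min_support, require_hd = require_hd,
                 seed = seed),
            class = "pipeline_config")
}

#' Call candidate regulatory elements
#'
#' The full discovery procedure: (1) smooth the conservation track and call
#' conserved segments; (2) intersect with the intergenic, non-repetitive
#' search space; (3) annotate every surviving interval with motif content
#' (HD matches on the forward and on both strands, O/E matches,
#' k-within-window cluster hits, and — when an alignment is supplied —
#' phylogenetically conserved HD instances); (4) rank deterministically
#' (conserved-HD count, then mean conservation, ties by coordinate).
#'
#' @param genome Named character vector or [Biostrings::DNAStringSet]
#'   holding the cluster sequence (1-based position 1 = track position 1
#'   of `track$start`).
#' @param ann An `annotation_set` or footprint [GenomicRanges::GRanges].
#' @param mask Repeat-mask [GenomicRanges::GRanges].
#' @param track A `conservation_track` over the cluster.
#' @param aln Optional `multi_alignment` over the same reference sequence
#'   (used for conserved-motif support).
#' @param cfg A [pipeline_config()].
#' @return Object of class `candidate_set`: list with `candidates` (a
#'   [GenomicRanges::GRanges] with per-candidate annotation columns,
#'   ranked), `config`, and `threshold` (the cutoff actually applied).
#'   An empty search space yields an empty candidate set, not an error.
#' @export
call_candidates <- function(genome, ann, mask, track, aln = NULL,
                            cfg = pipeline_config()) {
  if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
  if (is.null(genome) || length(genome) == 0) stop("missing genome sequence")
  seqstr <- genome[[1]]
  sm <- smooth_track(track, cfg$smooth_window)
  segs <- call_conserved_segments(sm, threshold = cfg$cons_threshold,
                                  percentile = cfg$cons_percentile %||% 0.9,
                                  min_len = cfg$min_len,
                                  merge_gap = cfg$merge_gap)
  thr <- attr(segs, "threshold")
  bounds <- cfg$bounds %||% GenomicRanges::GRanges(
    track$chrom,
    IRanges::IRanges(track$start, track$start + length(track$score) - 1L))
  space <- subtract_mask(intergenic_regions(ann, bounds), mask)
  cand <- GenomicRanges::intersect(
    .gr(track$chrom, IRanges::ranges(segs)),
    .gr(track$chrom, IRanges::ranges(space)))
  cand <- cand[BiocGenerics::width(cand) >= cfg$min_len]
  n <- length(cand)
  ms <- numeric(n); mx <- numeric(n)
  hd_f <- integer(n); hd_b <- integer(n); oe <- integer(n)
  clh <- integer(n); hd_c <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- BiocGenerics::start(cand)[i]
    e <- BiocGenerics::end(cand)[i]
    ti <- (s - track$start + 1L):(e - track$start + 1L)
    ms[i] <- mean(track$score[ti], na.rm = TRUE)
    mx[i] <- max(track$score[ti], na.rm = TRUE)
    sub <- substring(seqstr, s, e)
    hd_f[i] <- nrow(scan_iupac(sub, cfg$hd_pattern, "forward"))
    hd_b[i] <- nrow(scan_iupac(sub, cfg$hd_pattern, "both"))
    oe[i] <- nrow(scan_iupac(sub, cfg$oe_pattern, "forward"))
    clh[i] <- nrow(find_motif_clusters(
      scan_iupac(sub, cfg$cluster_pattern, "both"),
      k = cfg$cluster_k, window = cfg$cluster_window))
    if (!is.null(aln)) {
      sa <- subset_alignment(aln, s, e)
      hd_c[i] <- nrow(conserved_motif_instances(sa, cfg$hd_pattern,
                                                cfg$min_support))
    }
  }
  S4Vectors::mcols(cand) <- S4Vectors::DataFrame(
    mean_score = ms, max_score = mx, hd_forward = hd_f, hd_both = hd_b,
    hd_conserved = hd_c, oe = oe, cluster_hits = clh)
  if (cfg$require_hd) cand <- cand[S4Vectors::mcols(cand)$hd_both >= 1]
  key <- S4Vectors::mcols(cand)$hd_conserved
  key[is.na(key)] <- 0L
  ord <- order(-key, -S4Vectors::mcols(cand)$mean_score,
               BiocGenerics::start(cand))
  cand <- cand[ord]
  S4Vectors::mcols(cand)$rank <- seq_along(cand)
  structure(list(candidates = cand, config = cfg, threshold = thr),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", length(x$candidates), "candidate(s), threshold",
      format(x$threshold, digits = 4), "\n")
  if (length(x$candidates) > 0) print(utils::head(report(x), 10))
  invisible(x)
}

#' Tabular report of a candidate set
#'
#' @param x A `candidate_set`.
#' @param convention Output coordinate convention for the printed
#'   coordinate column.
#' @param ... Unused.
#' @return `data.frame`: one row per candidate, sorted by rank, with
#'   coordinates, length, conservation stats, and motif tallies.
#' @export
report <- function(x, ...) UseMethod("report")

#' @rdname report
#' @export
report.candidate_set <- function(x,
                                 convention = "one_based_fully_closed",
                                 ...) {
  cand <- x$candidates
  data.frame(
    rank = S4Vectors::mcols(cand)$rank,
    chrom = as.character(GenomeInfoDb::seqnames(cand)),
    start = BiocGenerics::start(cand),
    end = BiocGenerics::end(cand),
    coords = format_interval(cand, convention),
    length = interval_length(cand),
    mean_score = S4Vectors::mcols(cand)$mean_score,
    max_score = S4Vectors::mcols(cand)$max_score,
    hd_forward = S4Vectors::mcols(cand)$hd_forward,
    hd_both = S4Vectors::mcols(cand)$hd_both,
    hd_conserved = S4Vectors::mcols(cand)$hd_conserved,
    oe = S4Vectors::mcols(cand)$oe,
    cluster_hits = S4Vectors::mcols(cand)$cluster_hits,
    stringsAsFactors = FALSE)
}

#' Machine-readable JSON report of a candidate set
#'
#' Byte-identical for identical inputs and config.
#'
#' @param x A `candidate_set`.
#' @param path Optional output path; when `NULL` the JSON text is
#'   returned.
#' @return JSON string (invisibly the path when writing to file).
#' @export
report_json <- function(x, path = NULL) {
  payload <- list(
    candidates = report(x),
    threshold = x$threshold,
    config = x$config[!vapply(x$config, is.null, logical(1)) &
                        names(x$config) != "bounds"])
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 10,
                          na = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(path))
  }
  txt
}
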