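# Degenerate (IUPAC) motif scanning on both strands, k-within-window motif
# cluster detection, and occurrence counting across sequence sets. Scanning
# is exact set membership per position, vectorized over the sequence: for an
# n-base sequence and m-base pattern it costs m logical sweeps of length n.

# logical hit vector for the forward strand of `pattern` over chars `sc`;
# an N in the sequence only satisfies a pattern position that is itself N
.scan_forward <- function(sc, pattern_chars) {
  n <- length(sc)
  m <- length(pattern_chars)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    allowed <- IUPAC_SETS[[pattern_chars[j]]]
    if (length(allowed) == 4L) allowed <- c(allowed, "N")
    ok <- ok & (sc[j:(n - m + j)] %in% allowed)
    if (!any(ok)) return(integer(0))
  }
  which(ok)
}

#' Does a sequence exactly satisfy an IUPAC pattern?
#'
#' @param seq Nucleotide string.
#' @param pattern IUPAC pattern of the same length.
#' @return Logical.
#' @export
iupac_satisfies <- function(seq, pattern) {
  pc <- .validate_iupac(pattern)
  sc <- .seq_chars(seq)
  if (length(sc) != length(pc)) return(FALSE)
  length(.scan_forward(sc, pc)) == 1L
}

#' Scan a sequence for a degenerate IUPAC motif
#'
#' Reports all and only the positions whose window satisfies the pattern on
#' the requested strand(s). A minus-strand match at a footprint means the
#' reverse complement of that window satisfies the pattern; a forward and a
#' reverse match with identical footprints are both reported. Windows
#' containing `N` in the sequence only match pattern positions that are
#' themselves `N`.
#'
#' @param seq Nucleotide string over `A/C/G/T/N`.
#' @param pattern IUPAC pattern string (e.g. `"TAATNN"`).
#' @param strands `"both"` (default), `"forward"`, or `"reverse"`.
#' @return `data.frame` with columns `start`, `end` (1-based, closed,
#'   footprint on the forward coordinate system), `strand`, and `match`
#'   (the strand-oriented matched sequence), sorted by `start` then strand.
#' @examples
#' scan_iupac("TAATGA", "TAATNN", "forward")
#' scan_iupac("TCATTA", "TAATNN", "both")   # one minus-strand hit
#' @export
scan_iupac <- function(seq, pattern, strands = c("both", "forward", "reverse")) {
  strands <- match.arg(strands)
  pc <- .validate_iupac(pattern)
  sc <- .seq_chars(seq)
  m <- length(pc)
  res <- list()
  if (strands %in% c("both", "forward")) {
    pos <- .scan_forward(sc, pc)
    if (length(pos) > 0) {
      res[[length(res) + 1L]] <- data.frame(
        start = pos, end = pos + m - 1L, strand = "+",
        match = vapply(pos, function(p)
          paste(sc[p:(p + m - 1L)], collapse = ""), character(1)),
        stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "reverse")) {
    rcpat <- .seq_chars(revcomp(pattern))
    pos <- .scan_forward(sc, rcpat)
    if (length(pos) > 0) {
      res[[length(res) + 1L]] <- data.frame(
        start = pos, end = pos + m - 1L, strand = "-",
        match = revcomp(vapply(pos, function(p)
          paste(sc[p:(p + m - 1L)], collapse = ""), character(1))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), match = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find clusters of k motif matches within a window
#'
#' Reports maximal groups of at least `k` matches whose first-start to
#' last-end span is at most `window` base pairs (inclusive). A group is
#' maximal if it is not contained in another qualifying group; overlapping
#' maximal groups are each reported once, in coordinate order.
#'
#' @param matches A match table from [scan_iupac()] (columns `start`,
#'   `end`), or any data.frame with those columns; need not be pre-sorted.
#' @param k Minimum number of matches per cluster (>= 1).
#' @param window Maximum span in bp.
#' @param semantics `"span"` (default; first start to last end) or
#'   `"pairwise"` (all pairwise start-to-start distances within `window`).
#' @return `data.frame` with one row per cluster: `start`, `end`,
#'   `n_matches`, `span`; attribute `"members"` holds the row indices (into
#'   the sorted match table) of each cluster's members.
#' @export
find_motif_clusters <- function(matches, k, window,
                                semantics = c("span", "pairwise")) {
  semantics <- match.arg(semantics)
  stopifnot(k >= 1)
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_matches = integer(0), span = integer(0))
  if (nrow(matches) < k) return(empty)
  ord <- order(matches$start, matches$end)
  st <- matches$start[ord]
  en <- matches$end[ord]
  n <- length(st)
  # j_i = largest j such that matches i..j fit the window rule
  jmax <- integer(n)
  for (i in seq_len(n)) {
    j <- i
    emax <- en[i]
    while (j < n) {
      cand_e <- max(emax, en[j + 1L])
      fits <- if (semantics == "span") {
        (cand_e - st[i] + 1L) <= window
      } else {
        (st[j + 1L] - st[i]) <= window
      }
      if (!fits) break
      j <- j + 1L
      emax <- cand_e
    }
    jmax[i] <- j
  }
  keep <- which(vapply(seq_len(n), function(i) {
    size_ok <- (jmax[i] - i + 1L) >= k
    maximal <- i == 1L || jmax[i - 1L] < jmax[i]
    size_ok && maximal
  }, logical(1)))
  if (length(keep) == 0) return(empty)
  members <- lapply(keep, function(i) ord[i:jmax[i]])
  out <- data.frame(
    start = st[keep],
    end = vapply(keep, function(i) max(en[i:jmax[i]]), integer(1)),
    n_matches = jmax[keep] - keep + 1L
  )
  out$span <- out$end - out$start + 1L
  attr(out, "members") <- members
  out
}

#' Count motif (or motif-cluster) occurrences across a sequence set
#'
#' @param seqs Named character vector of sequences (or a
#'   [Biostrings::DNAStringSet]).
#' @param pattern IUPAC pattern string.
#' @param k,window If both given, count clusters of `k` matches within
#'   `window` bp instead of single matches.
#' @param strands Passed to [scan_iupac()].
#' @return Named integer vector of counts.
#' @export
count_occurrences <- function(seqs, pattern, k = NULL, window = NULL,
                              strands = "both") {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  vapply(seqs, function(s) {
    hits <- scan_iupac(s, pattern, strands)
    if (is.null(k)) {
      nrow(hits)
    } else {
      nrow(find_motif_clusters(hits, k = k, window = window))
    }
  }, integer(1))
}
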