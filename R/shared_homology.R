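# Shared-homology discovery between two candidate elements, exact IUPAC
# match probabilities under a 0-order background, and FIMO-style database
# scanning with per-target Bonferroni over windows and Benjamini-Hochberg
# q-values across targets.

# maximal exact-match runs and X-drop extension along one diagonal.
# mv: logical match vector along the diagonal overlap; returns matrix of
# (start, end) index pairs into mv.
.extend_cores <- function(mv, seed_len, mismatch_penalty, xdrop) {
  r <- rle(mv)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  core <- which(r$values & r$lengths >= seed_len)
  if (length(core) == 0) return(NULL)
  n <- length(mv)
  blocks <- matrix(0L, nrow = length(core), ncol = 2)
  for (ci in seq_along(core)) {
    s <- starts[core[ci]]
    e <- ends[core[ci]]
    # extend right
    best <- 0; cur <- 0; beste <- e
    t <- e + 1L
    while (t <= n) {
      cur <- cur + if (mv[t]) 1 else -mismatch_penalty
      if (cur > best) { best <- cur; beste <- t }
      if (cur < best - xdrop) break
      t <- t + 1L
    }
    # extend left
    best <- 0; cur <- 0; bests <- s
    t <- s - 1L
    while (t >= 1L) {
      cur <- cur + if (mv[t]) 1 else -mismatch_penalty
      if (cur > best) { best <- cur; bests <- t }
      if (cur < best - xdrop) break
      t <- t - 1L
    }
    blocks[ci, ] <- c(bests, beste)
  }
  unique(blocks)
}

.blocks_one_strand <- function(ca, cb, seed_len, min_identity, min_len,
                               mismatch_penalty, xdrop) {
  na <- length(ca)
  nb <- length(cb)
  if (na < seed_len || nb < seed_len) return(NULL)
  ka <- vapply(seq_len(na - seed_len + 1L), function(i)
    paste(ca[i:(i + seed_len - 1L)], collapse = ""), character(1))
  kb <- vapply(seq_len(nb - seed_len + 1L), function(i)
    paste(cb[i:(i + seed_len - 1L)], collapse = ""), character(1))
  map <- split(seq_along(kb), kb)
  hit <- which(ka %in% names(map))
  if (length(hit) == 0) return(NULL)
  diags <- unique(unlist(lapply(hit, function(i) i - map[[ka[i]]])))
  out <- list()
  for (d in diags) {
    ia <- max(1L, 1L + d):min(na, nb + d)
    mv <- ca[ia] == cb[ia - d]
    blocks <- .extend_cores(mv, seed_len, mismatch_penalty, xdrop)
    if (is.null(blocks)) next
    for (bi in seq_len(nrow(blocks))) {
      s <- blocks[bi, 1]; e <- blocks[bi, 2]
      len <- e - s + 1L
      ident <- mean(mv[s:e])
      if (len < min_len || ident < min_identity) next
      a1 <- ia[1] + s - 1L
      out[[length(out) + 1L]] <- data.frame(
        start_a = a1, end_a = a1 + len - 1L,
        start_b = a1 - d, end_b = a1 - d + len - 1L,
        length = len, identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  res <- unique(do.call(rbind, out))
  res
}

#' Find ungapped homology blocks shared between two sequences
#'
#' Seeds on exact shared k-mers (both strands), extends each seed ungapped
#' in both directions with an X-drop rule (match +1, mismatch
#' `-mismatch_penalty`, stop when the running score drops `xdrop` below its
#' maximum, then trim to the score maximum), and reports deduplicated
#' blocks of at least `min_len` bases with identity at least
#' `min_identity`, sorted by `identity * length` descending.
#'
#' @param seq_a,seq_b Nucleotide strings.
#' @param seed_len Exact seed length (default 12; must be <= `min_len`).
#' @param min_identity Minimum block identity fraction (default 0.9).
#' @param min_len Minimum block length in bp (default 30).
#' @param both_strands Also search `seq_a` against the reverse complement
#'   of `seq_b` (default `TRUE`).
#' @param mismatch_penalty,xdrop Extension scoring knobs (defaults 4, 12).
#' @return `data.frame` with columns `start_a`, `end_a`, `start_b`,
#'   `end_b` (1-based closed, `b` coordinates always on the forward
#'   strand), `strand`, `length`, `identity`, `seq_a`, `seq_b`.
#' @export
find_shared_blocks <- function(seq_a, seq_b, seed_len = 12L,
                               min_identity = 0.9, min_len = 30L,
                               both_strands = TRUE,
                               mismatch_penalty = 4, xdrop = 12) {
  if (seed_len > min_len) stop("seed_len must be <= min_len")
  ca <- .seq_chars(seq_a)
  cb <- .seq_chars(seq_b)
  nb <- length(cb)
  fw <- .blocks_one_strand(ca, cb, seed_len, min_identity, min_len,
                           mismatch_penalty, xdrop)
  if (!is.null(fw) && nrow(fw) > 0) fw$strand <- "+"
  rv <- NULL
  if (both_strands) {
    cbr <- .seq_chars(revcomp(seq_b))
    rv <- .blocks_one_strand(ca, cbr, seed_len, min_identity, min_len,
                             mismatch_penalty, xdrop)
    if (!is.null(rv) && nrow(rv) > 0) {
      rv$strand <- "-"
      # map revcomp coordinates back to forward-strand b coordinates
      sb <- nb - rv$end_b + 1L
      eb <- nb - rv$start_b + 1L
      rv$start_b <- sb
      rv$end_b <- eb
    }
  }
  res <- rbind(fw, rv)
  if (is.null(res) || nrow(res) == 0) {
    return(data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      strand = character(0), length = integer(0),
                      identity = numeric(0), seq_a = character(0),
                      seq_b = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(res)
  res$seq_a <- substring(seq_a, res$start_a, res$end_a)
  res$seq_b <- substring(seq_b, res$start_b, res$end_b)
  res <- res[order(-(res$identity * res$length), res$start_a), ,
             drop = FALSE]
  res <- res[, c("start_a", "end_a", "start_b", "end_b", "strand",
                 "length", "identity", "seq_a", "seq_b")]
  rownames(res) <- NULL
  res
}

#' Exact single-window IUPAC match probability
#'
#' Probability that one random window drawn from a 0-order background
#' satisfies the pattern: the product over pattern positions of the summed
#' background frequencies of the allowed bases.
#'
#' @param pattern IUPAC pattern string.
#' @param background Named numeric vector of A/C/G/T frequencies summing
#'   to 1 (default uniform).
#' @return Probability in `[0, 1]`.
#' @examples
#' iupac_match_pvalue("ACGT")    # (1/4)^4
#' iupac_match_pvalue("TAATNN")  # same: N positions contribute 1
#' @export
iupac_match_pvalue <- function(pattern,
                               background = c(A = .25, C = .25,
                                              G = .25, T = .25)) {
  if (any(background < 0)) stop("degenerate background: negative frequency")
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background frequencies must sum to 1")
  }
  pc <- .validate_iupac(pattern)
  prod(vapply(pc, function(ch) sum(background[IUPAC_SETS[[ch]]]),
              numeric(1)))
}

# 0-order background frequencies estimated from a set of sequences
.background_freqs <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")),
                                      "", fixed = TRUE)),
                      levels = .BASES))
  f <- as.numeric(tab)
  if (sum(f) == 0) return(c(A = .25, C = .25, G = .25, T = .25))
  stats::setNames(f / sum(f), .BASES)
}

# P(X >= s) where X = number of matching positions of a fixed query against
# a random background window: Poisson-binomial tail via convolution
.poisbinom_tail <- function(probs, s) {
  dist <- 1
  for (p in probs) {
    dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  }
  sum(dist[(s + 1L):length(dist)])
}

#' Scan a sequence database for a motif with FDR-controlled q-values
#'
#' For each database sequence, scans every window on both strands and
#' computes an exact match probability under a 0-order background (by
#' default estimated from the database itself). In `"iupac"` mode a window
#' either satisfies the pattern or not; in `"mismatch"` mode the query is a
#' fixed sequence, windows are scored by match count, and the window
#' p-value is the exact Poisson-binomial tail of that count. The per-target
#' p-value is Bonferroni-corrected over the number of scanned windows
#' (both strands), and q-values are Benjamini-Hochberg across targets.
#'
#' @param query IUPAC pattern (`type = "iupac"`) or fixed nucleotide string
#'   (`type = "mismatch"`).
#' @param database Named character vector (or
#'   [Biostrings::DNAStringSet]) of target sequences.
#' @param background Named A/C/G/T frequencies; `NULL` (default) estimates
#'   them from the database.
#' @param type `"iupac"` or `"mismatch"`.
#' @return `data.frame` with one row per target: `target`, `start`,
#'   `strand` (best window), `score` (`-log2` of the window match
#'   probability), `n_windows`, `p_value`, `q_value`; sorted by `q_value`
#'   then `p_value`.
#' @export
scan_database_with_qvalues <- function(query, database, background = NULL,
                                       type = c("iupac", "mismatch")) {
  type <- match.arg(type)
  if (methods::is(database, "DNAStringSet")) {
    database <- as.character(database)
  }
  if (length(database) == 0) {
    return(data.frame(target = character(0), start = integer(0),
                      strand = character(0), score = numeric(0),
                      n_windows = integer(0), p_value = numeric(0),
                      q_value = numeric(0), stringsAsFactors = FALSE))
  }
  if (is.null(names(database))) {
    names(database) <- paste0("target", seq_along(database))
  }
  bg <- background %||% .background_freqs(database)
  qc <- .validate_iupac(query)
  m <- length(qc)
  rows <- lapply(names(database), function(nm) {
    s <- database[[nm]]
    nwin <- max(0L, nchar(s) - m + 1L)
    nwin_both <- 2L * nwin
    if (nwin == 0L) {
      return(data.frame(target = nm, start = NA_integer_,
                        strand = NA_character_, score = 0,
                        n_windows = 0L, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    if (type == "iupac") {
      hits <- scan_iupac(s, query, strands = "both")
      pwin <- iupac_match_pvalue(query, bg)
      if (nrow(hits) > 0) {
        p <- min(1, nwin_both * pwin)
        data.frame(target = nm, start = hits$start[1],
                   strand = hits$strand[1], score = -log2(pwin),
                   n_windows = nwin_both, p_value = p,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(target = nm, start = NA_integer_,
                   strand = NA_character_, score = 0,
                   n_windows = nwin_both, p_value = 1,
                   stringsAsFactors = FALSE)
      }
    } else {
      sc <- .seq_chars(s)
      score_windows <- function(chars, pat) {
        n <- length(chars)
        cnt <- integer(n - m + 1L)
        for (j in seq_len(m)) {
          cnt <- cnt + (chars[j:(n - m + j)] == pat[j])
        }
        cnt
      }
      fwd <- score_windows(sc, qc)
      rev_ <- score_windows(sc, .seq_chars(revcomp(query)))
      best_f <- which.max(fwd)
      best_r <- which.max(rev_)
      if (fwd[best_f] >= rev_[best_r]) {
        best_pos <- best_f; best_str <- "+"; best_s <- fwd[best_f]
      } else {
        best_pos <- best_r; best_str <- "-"; best_s <- rev_[best_r]
      }
      probs <- vapply(qc, function(ch) unname(bg[ch]), numeric(1))
      pwin <- .poisbinom_tail(probs, best_s)
      p <- min(1, nwin_both * pwin)
      data.frame(target = nm, start = best_pos, strand = best_str,
                 score = -log2(max(pwin, .Machine$double.xmin)),
                 n_windows = nwin_both, p_value = p,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$q_value, out$p_value, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
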