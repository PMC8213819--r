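# Independent brute-force oracles used to cross-check the implementations.
# These deliberately share no code with the package internals.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

iupac_table <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive O(n*m) sliding-window scan; seq N only satisfies pattern N
oracle_window_ok <- function(win, pat) {
  all(mapply(function(s, p) {
    allowed <- iupac_table[[p]]
    if (length(allowed) == 4) allowed <- c(allowed, "N")
    s %in% allowed
  }, strsplit(win, "")[[1]], strsplit(pat, "")[[1]]))
}

oracle_scan <- function(seq, pattern, strands = "both") {
  n <- nchar(seq)
  m <- nchar(pattern)
  out <- list()
  for (i in seq_len(max(0, n - m + 1))) {
    win <- substr(seq, i, i + m - 1)
    if (strands %in% c("both", "forward") && oracle_window_ok(win, pattern)) {
      out[[length(out) + 1]] <- data.frame(start = i, strand = "+")
    }
    if (strands %in% c("both", "reverse") &&
        oracle_window_ok(oracle_revcomp(win), pattern)) {
      out[[length(out) + 1]] <- data.frame(start = i, strand = "-")
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(0), strand = character(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# enumerate maximal above-threshold runs, bridge small gaps, filter length
oracle_segments <- function(score, threshold, min_len, merge_gap) {
  above <- which(!is.na(score) & score >= threshold)
  if (length(above) == 0) return(matrix(integer(0), ncol = 2))
  segs <- list(c(above[1], above[1]))
  for (p in above[-1]) {
    last <- segs[[length(segs)]]
    if (p - last[2] - 1 <= merge_gap) {
      segs[[length(segs)]][2] <- p
    } else {
      segs[[length(segs) + 1]] <- c(p, p)
    }
  }
  m <- do.call(rbind, segs)
  m[m[, 2] - m[, 1] + 1 >= min_len, , drop = FALSE]
}

# base-wise complement of footprints within bounds (all 1-based closed)
oracle_complement <- function(bound_start, bound_end, fp_start, fp_end) {
  bases <- bound_start:bound_end
  inside <- rep(FALSE, length(bases))
  for (i in seq_along(fp_start)) {
    hit <- bases >= fp_start[i] & bases <= fp_end[i]
    inside[hit] <- TRUE
  }
  bases[!inside]
}

# maximal qualifying k-in-window groups over sorted matches, by exhaustive
# enumeration of contiguous index ranges
oracle_clusters <- function(st, en, k, window) {
  ord <- order(st, en)
  st <- st[ord]; en <- en[ord]
  n <- length(st)
  valid <- function(i, j) {
    (j - i + 1) >= k && (max(en[i:j]) - st[i] + 1) <= window
  }
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!valid(i, j)) next
      contained <- FALSE
      for (i2 in seq_len(n)) {
        for (j2 in i2:n) {
          if ((i2 < i || j2 > j) && (i2 <= i && j2 >= j) && valid(i2, j2)) {
            contained <- TRUE
          }
        }
      }
      if (!contained) out[[length(out) + 1]] <- c(st[i], max(en[i:j]))
    }
  }
  unique(do.call(rbind, out))
}

# exact-match (identity 1.0) maximal diagonal runs of length >= min_len,
# forward strand only
oracle_diag_blocks <- function(a, b, min_len) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  out <- list()
  for (d in (-(nb - 1)):(na - 1)) {
    ia <- max(1, 1 + d):min(na, nb + d)
    mv <- ca[ia] == cb[ia - d]
    r <- rle(mv)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1
    for (ri in which(r$values & r$lengths >= min_len)) {
      a1 <- ia[1] + s[ri] - 1
      out[[length(out) + 1]] <- data.frame(
        start_a = a1, end_a = ia[1] + e[ri] - 1,
        start_b = a1 - d, length = r$lengths[ri])
    }
  }
  if (length(out) == 0) {
    return(data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), length = integer(0)))
  }
  do.call(rbind, out)
}

# hand Benjamini-Hochberg: q_i = min_{j: p_j >= p_i} (n * p_j / rank_j)
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# extract planted element sequences from a cluster simulation
element_seqs <- function(sim) {
  st <- BiocGenerics::start(sim$truth$elements)
  en <- BiocGenerics::end(sim$truth$elements)
  out <- substring(sim$seq[[1]], st, en)
  names(out) <- sim$truth$elements$element_id
  out
}

# reciprocal-overlap matching of called vs true intervals; returns counts
match_intervals <- function(called, truth, min_frac = 0.5) {
  hits <- 0L
  used <- rep(FALSE, length(called))
  for (i in seq_along(truth)) {
    ts <- BiocGenerics::start(truth)[i]; te <- BiocGenerics::end(truth)[i]
    for (j in seq_along(called)) {
      if (used[j]) next
      cs <- BiocGenerics::start(called)[j]; ce <- BiocGenerics::end(called)[j]
      ov <- max(0, min(te, ce) - max(ts, cs) + 1)
      if (ov >= min_frac * (te - ts + 1) && ov >= min_frac * (ce - cs + 1)) {
        hits <- hits + 1L
        used[j] <- TRUE
        break
      }
    }
  }
  list(matched = hits, n_called = length(called), n_true = length(truth))
}
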