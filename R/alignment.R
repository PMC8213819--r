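# Multi-species alignment container, coordinate projection between a
# reference's ungapped positions and alignment columns, and phylogenetic
# conservation calls for individual motif instances.

#' Construct a multi-species alignment
#'
#' @param rows Named character vector of equal-length gapped sequences over
#'   `A/C/G/T/N/-`.
#' @param ref Name of the reference species (default: first row).
#' @return An object of class `multi_alignment`.
#' @export
multi_alignment <- function(rows, ref = names(rows)[1]) {
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("rows must be named by species")
  }
  rows <- toupper(rows)
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("all rows must have equal length")
  if (!ref %in% names(rows)) stop("reference species not found: ", ref)
  structure(list(rows = rows, ref = ref, width = w),
            class = "multi_alignment")
}

#' @export
print.multi_alignment <- function(x, ...) {
  cat("multi_alignment:", length(x$rows), "species,", x$width,
      "columns, reference:", x$ref, "\n")
  invisible(x)
}

#' Read a multi-species alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file.
#' @param ref Reference species name (default: first record).
#' @return A `multi_alignment`.
#' @export
read_alignment_fasta <- function(path, ref = NULL) {
  ss <- Biostrings::readBStringSet(path)
  rows <- as.character(ss)
  multi_alignment(rows, ref = ref %||% names(rows)[1])
}

#' Write a multi-species alignment as aligned FASTA
#'
#' @param aln A `multi_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$rows), path)
  invisible(path)
}

#' Read alignment blocks from a MAF file
#'
#' Minimal MAF parser: each `a` paragraph becomes one `multi_alignment`
#' whose rows are named by the `src` field of its `s` lines.
#'
#' @param path Path to a MAF file.
#' @param ref Reference species (default: first row of each block).
#' @return List of `multi_alignment` objects, one per block.
#' @export
read_maf <- function(path, ref = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (!is.null(cur) && length(cur) > 0) {
      blocks[[length(blocks) + 1L]] <-
        multi_alignment(cur, ref = ref %||% names(cur)[1])
    }
    blocks
  }
  for (ln in lines) {
    if (grepl("^a", ln)) {
      blocks <- flush(cur, blocks)
      cur <- character(0)
    } else if (grepl("^s\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      # s src start size strand srcSize text
      cur[f[2]] <- f[7]
    }
  }
  flush(cur, blocks)
}

.ref_chars <- function(aln) .seq_chars(aln$rows[[aln$ref]])

#' Ungapped reference length of an alignment
#' @param aln A `multi_alignment`.
#' @export
ref_length <- function(aln) sum(.ref_chars(aln) != "-")

#' Project reference positions to alignment columns
#'
#' Returns, for each 1-based ungapped reference position, the alignment
#' column holding that reference character. The inverse mapping is provided
#' by [unproject_column()]; the round trip is the identity on non-gap
#' columns.
#'
#' @param aln A `multi_alignment`.
#' @param pos Integer vector of 1-based ungapped reference positions.
#' @return Integer vector of column indices.
#' @export
project_position <- function(aln, pos) {
  nongap <- which(.ref_chars(aln) != "-")
  if (any(pos < 1 | pos > length(nongap))) {
    stop("position out of range of ungapped reference")
  }
  nongap[pos]
}

#' Map alignment columns back to reference positions
#'
#' @param aln A `multi_alignment`.
#' @param col Integer vector of column indices; columns where the reference
#'   carries a gap map to `NA`.
#' @return Integer vector of 1-based ungapped reference positions.
#' @export
unproject_column <- function(aln, col) {
  rc <- .ref_chars(aln)
  if (any(col < 1 | col > length(rc))) stop("column out of range")
  cum <- cumsum(rc != "-")
  out <- cum[col]
  out[rc[col] == "-"] <- NA_integer_
  out
}

#' Extract the sub-alignment covering a reference interval
#'
#' @param aln A `multi_alignment`.
#' @param start,end 1-based ungapped reference positions (closed interval).
#' @return A `multi_alignment` over the columns spanned by those positions.
#' @export
subset_alignment <- function(aln, start, end) {
  cols <- project_position(aln, c(start, end))
  rows <- vapply(aln$rows, function(r) substr(r, cols[1], cols[2]),
                 character(1))
  multi_alignment(rows, ref = aln$ref)
}

#' Call phylogenetically conserved motif instances
#'
#' Scans the (gap-stripped) reference row for forward-strand matches of an
#' IUPAC pattern, then asks, for every match, which species' aligned window
#' (the columns of the match footprint, with that species' gaps dropped)
#' also satisfies the pattern. A species supports an instance only if its
#' gap-stripped window has exactly the pattern length and satisfies it; with
#' `exact_variant = TRUE` the window must equal the reference's matched
#' sequence letter-for-letter. The reference always supports its own match,
#' and the support fraction is taken over all species including the
#' reference.
#'
#' @param aln A `multi_alignment`.
#' @param pattern IUPAC pattern string.
#' @param min_support Minimum support fraction in `(0, 1]` (default 0.8).
#' @param exact_variant Require the identical variant in supporting species
#'   (default `FALSE`: any window satisfying the pattern supports).
#' @return `data.frame` with one row per conserved instance: `start`, `end`
#'   (ungapped reference coordinates), `match`, `support` (fraction),
#'   `n_supporting`, and `supporting` (comma-separated species names).
#' @export
conserved_motif_instances <- function(aln, pattern, min_support = 0.8,
                                      exact_variant = FALSE) {
  stopifnot(min_support > 0, min_support <= 1)
  refu <- gsub("-", "", aln$rows[[aln$ref]], fixed = TRUE)
  hits <- scan_iupac(refu, pattern, strands = "forward")
  n_sp <- length(aln$rows)
  out <- lapply(seq_len(nrow(hits)), function(i) {
    cols <- project_position(aln, c(hits$start[i], hits$end[i]))
    windows <- vapply(aln$rows, function(r) {
      gsub("-", "", substr(r, cols[1], cols[2]), fixed = TRUE)
    }, character(1))
    supp <- if (exact_variant) {
      windows == hits$match[i]
    } else {
      vapply(windows, iupac_satisfies, logical(1), pattern = pattern)
    }
    supp[aln$ref] <- TRUE
    frac <- sum(supp) / n_sp
    if (frac < min_support) return(NULL)
    data.frame(start = hits$start[i], end = hits$end[i],
               match = hits$match[i], support = frac,
               n_supporting = sum(supp),
               supporting = paste(names(aln$rows)[supp], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      match = character(0), support = numeric(0),
                      n_supporting = integer(0), supporting = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
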