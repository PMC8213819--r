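# Synthetic-data generators with recorded ground truth: a receptor-like gene
# cluster with planted regulatory elements, orthologous sequences across
# species on a star phylogeny, a species-agreement conservation track, and
# qPCR Ct tables. Everything the pipeline consumes can be generated here,
# deterministically per seed.

.SHITE30 <- "GTCGTTGCATCATAAAGTTTTCGCCGACTG"
.OE_INSTANCES <- c("TCCCAGGGGA", "CCCCGTGGGG", "TCCCTTGGGA")

# mutate one unprotected base of footprint [i, i+len-1] to a neutral base
# (C, or G if already C) so no new TAAT/ATTA can arise
.kill_footprint <- function(chars, i, len, protected) {
  idx <- i:(i + len - 1L)
  free <- idx[!protected[idx]]
  if (length(free) == 0) return(chars)  # fully planted; leave alone
  j <- free[(length(free) + 1L) %/% 2L]
  chars[j] <- if (chars[j] == "C") "G" else "C"
  chars
}

# remove all TAAT / ATTA words inside [from, to] whose footprint is not
# fully protected
.scrub_hd_words <- function(chars, from, to, protected) {
  repeat {
    sub <- chars[from:to]
    occ <- sort(unique(c(.scan_forward(sub, .seq_chars("TAAT")),
                         .scan_forward(sub, .seq_chars("ATTA")))))
    occ <- occ + from - 1L
    occ <- occ[!vapply(occ, function(i) all(protected[i:(i + 3L)]),
                       logical(1))]
    if (length(occ) == 0) break
    for (i in occ) chars <- .kill_footprint(chars, i, 4L, protected)
  }
  chars
}

# remove O/E-consensus windows inside [from, to] not fully protected.
# The mutated base must be one the consensus constrains (not the NN core),
# and must flip C<->G so no TAAT/ATTA can arise.
.scrub_oe_words <- function(chars, from, to, protected) {
  pc <- .validate_iupac("YCCCNNGGGR")
  constrained <- c(2L, 3L, 4L, 7L, 8L, 9L, 1L, 10L)
  repeat {
    occ <- .scan_forward(chars[from:to], pc) + from - 1L
    occ <- occ[!vapply(occ, function(i) all(protected[i:(i + 9L)]),
                       logical(1))]
    if (length(occ) == 0) break
    changed <- FALSE
    for (i in occ) {
      idx <- i + constrained - 1L
      j <- idx[!protected[idx]][1]
      if (is.na(j)) next
      chars[j] <- if (chars[j] == "C") "G" else "C"
      changed <- TRUE
    }
    if (!changed) break
  }
  chars
}

# motif layout for one element: returns data.frame(kind, seq, conserved)
# in left-to-right planting order
.element_layout <- function(style) {
  if (style == "triad") {
    data.frame(
      kind = c("HD", "OE", "HD", "HD", "HD", "OE", "SHITE",
               "HD", "OE", "HD", "HD"),
      seq = c("TAATCC", .OE_INSTANCES[1], "TAATGA", "TAATGA", "TAATGA",
              .OE_INSTANCES[2], .SHITE30, "TAATGT", .OE_INSTANCES[3],
              "TAATCG", "TAATAC"),
      conserved = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      kind = c("HD", "OE", "HD", "SHITE", "HD", "OE", "HD",
               "HD", "OE", "HD", "HD"),
      seq = c("TAATAG", .OE_INSTANCES[1], "TAATGA", .SHITE30, "TAATTA",
              .OE_INSTANCES[2], "TAATCA", "TAATGG", .OE_INSTANCES[3],
              "TAATCT", "TAATAC"),
      conserved = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                    FALSE, FALSE, FALSE, FALSE),
      stringsAsFactors = FALSE)
  }
}

#' Simulate a receptor-like gene cluster with planted regulatory elements
#'
#' Generates an i.i.d. background sequence carrying `n_genes` two-exon gene
#' models, a pseudogene fragment, repeat intervals, and `n_elements`
#' intergenic elements. Each element contains seven forward-strand core
#' homeodomain sites (`TAATNN`; four flagged as phylogenetically conserved),
#' three O/E-consensus sites (`YCCCNNGGGR`, not conserved), and a shared
#' 30-bp homology block common to all elements; the second element carries
#' a triple repeat of `TAATGA` within a 206-bp window, and the generator
#' guarantees that this triad is the only one in the cluster (incidental
#' background words that would blur the planted counts are scrubbed).
#' Everything is reproducible per seed and recorded in the returned truth.
#'
#' @param n_genes Number of gene models (default 15).
#' @param cluster_len Cluster length in bp (default 200000).
#' @param n_elements Number of planted elements (default 2).
#' @param element_len Element lengths in bp, recycled (default `c(700, 350)`;
#'   minimum 198).
#' @param element_gaps Intergenic gap indices (gap `i` lies between genes
#'   `i` and `i+1`) receiving the elements; default mirrors the studied
#'   cluster (gaps 1 and 6) when possible, otherwise spreads evenly.
#' @param repeat_density Fraction of the cluster covered by repeat
#'   intervals (default 0.1).
#' @param decoys Also plant conserved decoys inside an exon and inside a
#'   repeat, to exercise the intergenic and mask filters (default `TRUE`).
#' @param chrom Chromosome name of the emitted sequence.
#' @param seed Random seed.
#' @return A list of class `cluster_sim` with elements `seq` (named
#'   character), `chrom`, `annotation` (an `annotation_set`), `mask`
#'   ([GenomicRanges::GRanges]), `conserved` (interval/multiplier table for
#'   [simulate_orthologs()]), and `truth`.
#' @export
simulate_cluster <- function(n_genes = 15L, cluster_len = 200000L,
                             n_elements = 2L, element_len = c(700L, 350L),
                             element_gaps = NULL, repeat_density = 0.1,
                             decoys = TRUE, chrom = "chrSim", seed = 1L) {
  set.seed(seed)
  if (any(element_len < 198)) stop("element_len must be >= 198")
  chars <- sample(.BASES, cluster_len, replace = TRUE)
  protected <- rep(FALSE, cluster_len)

  # gene models: exon1 150, intron 750, exon2 1000
  glen <- 1900L
  centers <- round(cluster_len * seq_len(n_genes) / (n_genes + 1))
  jit <- round(stats::runif(n_genes, -400, 400))
  gstart <- pmax(200L, pmin(cluster_len - glen - 200L,
                            as.integer(centers - glen %/% 2L + jit)))
  gstart <- sort(gstart)
  if (any(diff(gstart) < glen + 400L)) {
    stop("infeasible packing: genes overlap; increase cluster_len")
  }
  gend <- gstart + glen - 1L
  strand_g <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(gstart, gend),
                                  strand = strand_g)
  S4Vectors::mcols(genes)$gene_id <- sprintf("gene%02d", seq_len(n_genes))
  S4Vectors::mcols(genes)$biotype <- "protein_coding"
  exons <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(c(gstart, gstart + 900L),
                     c(gstart + 149L, gend)))
  S4Vectors::mcols(exons)$gene_id <- rep(S4Vectors::mcols(genes)$gene_id, 2)
  exons <- BiocGenerics::sort(exons, ignore.strand = TRUE)

  # pseudogene fragment in a gap away from the element gaps
  element_len <- rep_len(as.integer(element_len), n_elements)
  if (is.null(element_gaps)) {
    element_gaps <- if (n_elements == 2L && n_genes >= 7L) {
      c(1L, 6L)
    } else {
      unique(pmax(1L, round(seq_len(n_elements) * (n_genes - 1) /
                              (n_elements + 1))))
    }
  }
  if (length(element_gaps) < n_elements) {
    stop("not enough distinct gaps for the requested elements")
  }
  pg_gap <- setdiff(seq_len(n_genes - 1L), element_gaps)
  pg_gap <- pg_gap[length(pg_gap) %/% 2L + 1L]
  pg_start <- as.integer((gend[pg_gap] + gstart[pg_gap + 1L]) %/% 2L - 150L)
  pseudo <- GenomicRanges::GRanges(chrom,
                                   IRanges::IRanges(pg_start,
                                                    pg_start + 299L))
  S4Vectors::mcols(pseudo)$gene_id <- "pseudo1"
  S4Vectors::mcols(pseudo)$biotype <- "pseudogene"

  # elements: scrub, plant motifs, re-scrub junctions
  styles <- ifelse(seq_len(n_elements) == 2L, "triad", "standard")
  el_start <- integer(n_elements)
  motif_rows <- list()
  for (i in seq_len(n_elements)) {
    gi <- element_gaps[i]
    L <- element_len[i]
    mid <- (gend[gi] + gstart[gi + 1L]) %/% 2L
    s <- as.integer(mid - L %/% 2L)
    if (s < gend[gi] + 150L || s + L - 1L > gstart[gi + 1L] - 150L) {
      stop("infeasible packing: element ", i, " does not fit its gap")
    }
    el_start[i] <- s
    e <- s + L - 1L
    chars <- .scrub_hd_words(chars, s, e, protected)
    lay <- .element_layout(styles[i])
    total <- sum(nchar(lay$seq))
    gap <- min(90L, (L - total) %/% (nrow(lay) + 1L))
    pos <- s + gap
    for (r in seq_len(nrow(lay))) {
      m <- .seq_chars(lay$seq[r])
      idx <- pos:(pos + length(m) - 1L)
      chars[idx] <- m
      protected[idx] <- TRUE
      motif_rows[[length(motif_rows) + 1L]] <- data.frame(
        element = i, kind = lay$kind[r], seq = lay$seq[r],
        start = pos, end = pos + length(m) - 1L,
        conserved = lay$conserved[r], stringsAsFactors = FALSE)
      pos <- pos + length(m) + gap
    }
    chars <- .scrub_hd_words(chars, s, e, protected)
    chars <- .scrub_oe_words(chars, s, e, protected)
  }
  el_end <- el_start + element_len - 1L
  elements <- .gr(chrom, IRanges::IRanges(el_start, el_end))
  S4Vectors::mcols(elements)$element_id <-
    sprintf("element%d", seq_len(n_elements))
  S4Vectors::mcols(elements)$style <- styles
  motifs <- if (length(motif_rows) > 0) {
    do.call(rbind, motif_rows)
  } else {
    data.frame(element = integer(0), kind = character(0),
               seq = character(0), start = integer(0), end = integer(0),
               conserved = logical(0), stringsAsFactors = FALSE)
  }

  # repeats in intergenic space, clear of elements
  blocked <- rep(FALSE, cluster_len)
  for (i in seq_len(n_genes)) blocked[gstart[i]:gend[i]] <- TRUE
  blocked[pg_start:(pg_start + 299L)] <- TRUE
  for (i in seq_len(n_elements)) {
    blocked[max(1L, el_start[i] - 100L):min(cluster_len,
                                            el_end[i] + 100L)] <- TRUE
  }
  target_bp <- round(repeat_density * cluster_len)
  rep_s <- integer(0)
  rep_e <- integer(0)
  placed <- 0L
  tries <- 0L
  while (placed < target_bp && tries < 10000L) {
    tries <- tries + 1L
    len <- sample(200:800, 1L)
    s <- sample.int(cluster_len - len, 1L)
    if (any(blocked[s:(s + len - 1L)])) next
    blocked[s:(s + len - 1L)] <- TRUE
    rep_s <- c(rep_s, s)
    rep_e <- c(rep_e, s + len - 1L)
    placed <- placed + len
  }
  rep_iv <- BiocGenerics::sort(
    .gr(chrom, IRanges::IRanges(rep_s, rep_e)))

  # conservation regime: background 1x, element body 0.05x, conserved
  # motifs frozen (0x), non-conserved planted motifs mutate at background
  # rate (1x) so they fail the cross-species support rule
  cons <- data.frame(start = el_start, end = el_end,
                     multiplier = rep(0.05, n_elements))
  ncm <- motifs[!motifs$conserved, ]
  cm <- motifs[motifs$conserved, ]
  cons <- rbind(cons,
                data.frame(start = ncm$start, end = ncm$end,
                           multiplier = rep(1, nrow(ncm))),
                data.frame(start = cm$start, end = cm$end,
                           multiplier = rep(0, nrow(cm))))

  decoy_iv <- GenomicRanges::GRanges(seqnames = character(0),
                                     ranges = IRanges::IRanges())
  if (decoys) {
    gmid <- (n_genes + 1L) %/% 2L
    dstart <- gstart[gmid] + 1000L   # inside exon2
    decoy_iv <- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(dstart, dstart + 249L))
    S4Vectors::mcols(decoy_iv)$decoy <- "exonic"
    big <- rep_iv[BiocGenerics::width(rep_iv) >= 300L]
    if (length(big) > 0) {
      rs <- BiocGenerics::start(big)[1] + 20L
      d2 <- GenomicRanges::GRanges(chrom, IRanges::IRanges(rs, rs + 249L))
      S4Vectors::mcols(d2)$decoy <- "repeat"
      decoy_iv <- c(decoy_iv, d2)
    }
    cons <- rbind(cons,
                  data.frame(start = BiocGenerics::start(decoy_iv),
                             end = BiocGenerics::end(decoy_iv),
                             multiplier = 0.05))
  }

  # make the planted TAATGA triad unique cluster-wide
  el_span <- .gr(chrom, IRanges::IRanges(el_start, el_end))
  repeat {
    seqstr <- paste(chars, collapse = "")
    hits <- scan_iupac(seqstr, "TAATGA", "both")
    cl <- find_motif_clusters(hits, k = 3L, window = 206L)
    if (nrow(cl) == 0) break
    members <- attr(cl, "members")
    kill <- integer(0)
    for (ci in seq_len(nrow(cl))) {
      hm <- hits[members[[ci]], ]
      hg <- .gr(chrom, IRanges::IRanges(hm$start, hm$end))
      inside <- IRanges::overlapsAny(hg, el_span, type = "within")
      if (all(inside)) next        # the planted triad
      kill <- c(kill, hm$start[!inside][1])
    }
    if (length(kill) == 0) break
    for (ks in unique(kill)) {
      chars <- .kill_footprint(chars, ks, 6L, protected)
    }
  }

  seqstr <- paste(chars, collapse = "")
  ann <- annotation_set(c(genes, pseudo), exons, source = "synthetic")
  truth <- list(elements = elements, motifs = motifs, genes = genes,
                pseudogene = pseudo, repeats = rep_iv, decoys = decoy_iv,
                conserved = cons,
                config = list(n_genes = n_genes, cluster_len = cluster_len,
                              n_elements = n_elements,
                              element_len = element_len,
                              element_gaps = element_gaps,
                              repeat_density = repeat_density,
                              decoys = decoys, seed = seed))
  structure(list(seq = stats::setNames(seqstr, chrom), chrom = chrom,
                 annotation = ann, mask = rep_iv, conserved = cons,
                 truth = truth),
            class = "cluster_sim")
}

#' Write simulated cluster inputs to standard files
#'
#' Emits FASTA (sequence), GFF3 (gene models), BED (repeat mask), and a
#' JSON truth file into `dir`.
#'
#' @param sim A `cluster_sim` from [simulate_cluster()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the paths written.
#' @export
write_cluster_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "cluster.fa"),
             gff3 = file.path(dir, "cluster.gff3"),
             mask = file.path(dir, "mask.bed"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$seq),
                              paths["fasta"])
  tx <- sim$annotation$transcripts
  gtype <- ifelse(S4Vectors::mcols(tx)$biotype == "pseudogene",
                  "pseudogene", "gene")
  gff_tx <- tx
  S4Vectors::mcols(gff_tx) <- S4Vectors::DataFrame(
    type = gtype, ID = S4Vectors::mcols(tx)$gene_id,
    biotype = S4Vectors::mcols(tx)$biotype,
    Parent = IRanges::CharacterList(vector("list", length(tx))))
  ex <- sim$annotation$exons
  gff_ex <- ex
  S4Vectors::mcols(gff_ex) <- S4Vectors::DataFrame(
    type = "exon", ID = NA_character_, biotype = NA_character_,
    Parent = IRanges::CharacterList(
      as.list(S4Vectors::mcols(ex)$gene_id)))
  rtracklayer::export(c(gff_tx, gff_ex), paths["gff3"], format = "gff3")
  rtracklayer::export(sim$mask, paths["mask"], format = "bed")
  tr <- sim$truth
  jsonlite::write_json(list(
    elements = as.data.frame(tr$elements),
    motifs = tr$motifs,
    conserved = tr$conserved,
    config = tr$config), paths["truth"], auto_unbox = TRUE, digits = NA)
  paths
}

#' Simulate orthologous sequences on a star phylogeny
#'
#' Derives each species row from the reference by independent per-site
#' substitution (Jukes-Cantor style: substitute with probability `p`,
#' uniformly over the three alternative bases), with the per-site
#' probability scaled by a multiplier inside designated conserved
#' intervals. No indels are introduced, so rows are trivially aligned
#' (column i = reference position i).
#'
#' @param ref Reference sequence (character string).
#' @param n_species Total number of rows including the reference
#'   (default 16).
#' @param probs Per-species branch substitution probabilities (length
#'   `n_species - 1`, each in `[0, 0.75)`); default a ramp from 0.08
#'   to 0.35.
#' @param conserved Optional `data.frame(start, end, multiplier)` applied
#'   in row order to build the per-site rate multiplier (multipliers in
#'   `[0, 1]`; later rows override earlier ones).
#' @param seed Random seed.
#' @return A `multi_alignment` (reference row first, named `"reference"`)
#'   with attribute `"truth"`: a list of mutated positions per species.
#' @export
simulate_orthologs <- function(ref, n_species = 16L, probs = NULL,
                               conserved = NULL, seed = 1L) {
  set.seed(seed)
  probs <- probs %||% seq(0.08, 0.35, length.out = n_species - 1L)
  if (length(probs) != n_species - 1L) {
    stop("probs must have length n_species - 1")
  }
  if (any(probs < 0 | probs >= 0.75)) stop("probs must be in [0, 0.75)")
  rc <- .seq_chars(ref)
  n <- length(rc)
  mult <- rep(1, n)
  if (!is.null(conserved) && nrow(conserved) > 0) {
    if (any(conserved$multiplier < 0 | conserved$multiplier > 1)) {
      stop("multiplier must be in [0, 1]")
    }
    for (r in seq_len(nrow(conserved))) {
      mult[conserved$start[r]:conserved$end[r]] <- conserved$multiplier[r]
    }
  }
  ri <- .dna_int(rc)
  rows <- vector("list", n_species)
  truth <- vector("list", n_species)
  rows[[1]] <- ref
  truth[[1]] <- integer(0)
  for (s in 2:n_species) {
    pr <- probs[s - 1L] * mult
    idx <- which(stats::runif(n) < pr & !is.na(ri))
    out <- rc
    if (length(idx) > 0) {
      alt <- ((ri[idx] - 1L + sample.int(3L, length(idx),
                                         replace = TRUE)) %% 4L) + 1L
      out[idx] <- .BASES[alt]
    }
    rows[[s]] <- paste(out, collapse = "")
    truth[[s]] <- idx
  }
  nm <- c("reference", sprintf("species%02d", seq_len(n_species - 1L)))
  aln <- multi_alignment(stats::setNames(unlist(rows), nm),
                         ref = "reference")
  attr(aln, "truth") <- stats::setNames(truth, nm)
  aln
}

#' Derive a species-agreement conservation track from an alignment
#'
#' A simple identity-based conservation proxy: for each reference base, the
#' fraction of species (reference included) whose aligned base equals the
#' reference base. Values lie in `[0, 1]`; species gaps count as
#' disagreement.
#'
#' @param aln A `multi_alignment`.
#' @param chrom,start Coordinates to anchor the track (defaults: the
#'   reference name, 1).
#' @return A `conservation_track`.
#' @export
derive_conservation <- function(aln, chrom = NULL, start = 1L) {
  rc <- .ref_chars(aln)
  cols <- which(rc != "-")
  if (length(cols) == 0) stop("empty alignment")
  refb <- rc[cols]
  acc <- integer(length(cols))
  for (r in aln$rows) {
    acc <- acc + (.seq_chars(r)[cols] == refb)
  }
  conservation_track(chrom %||% aln$ref, start, acc / length(aln$rows))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Ct(gene, sample) = baseline(gene) + sample offset - log2(fold) +
#' Normal(0, sigma), with technical-replicate noise on top. Housekeeping
#' genes have fold 1 in every genotype; fold changes below `fold_floor`
#' are floored (an abolished transcript still yields a finite, late Ct).
#'
#' @param true_folds `data.frame(gene, genotype, fold)` for the
#'   non-control genotypes; default emulates a double-enhancer-deletion
#'   experiment: 13 cluster genes abolished (fold `fold_floor`) and 3
#'   control receptor genes untouched, in one `"del"` genotype.
#' @param housekeeping Housekeeping gene names (default
#'   `c("Bgus", "Gnal", "Ncam")`).
#' @param control Control genotype name (default `"wt"`).
#' @param n_per_genotype Biological replicates (mice) per genotype
#'   (default 5).
#' @param n_reps Technical replicates per sample and gene (default 3).
#' @param sigma Biological Ct noise s.d. in cycles (default 0.2).
#' @param tech_sd Technical replicate noise s.d. (default 0.05).
#' @param sample_sd S.d. of the per-sample global Ct offset (RNA input
#'   variation removed by housekeeping normalization; default 0.5).
#' @param baseline Named baseline Ct per gene; default drawn uniformly in
#'   `[22, 28]`.
#' @param fold_floor Smallest representable fold (default `2^-10`).
#' @param seed Random seed.
#' @return List with `ct` (the Ct table) and `truth` (folds, baselines,
#'   parameters).
#' @export
simulate_qpcr <- function(true_folds = NULL,
                          housekeeping = c("Bgus", "Gnal", "Ncam"),
                          control = "wt", n_per_genotype = 5L, n_reps = 3L,
                          sigma = 0.2, tech_sd = 0.05, sample_sd = 0.5,
                          baseline = NULL, fold_floor = 2^-10, seed = 1L) {
  set.seed(seed)
  stopifnot(sigma >= 0, tech_sd >= 0, sample_sd >= 0)
  if (is.null(true_folds)) {
    cluster_genes <- c("Taar1", "Taar2", "Taar3", "Taar4", "Taar5",
                       "Taar6", "Taar7a", "Taar7b", "Taar7d", "Taar7e",
                       "Taar7f", "Taar8", "Taar9")
    control_genes <- c("OlfrA", "OlfrB", "OlfrC")
    true_folds <- data.frame(
      gene = c(cluster_genes, control_genes),
      genotype = "del",
      fold = c(rep(fold_floor, length(cluster_genes)),
               rep(1, length(control_genes))),
      stringsAsFactors = FALSE)
  }
  if (any(true_folds$fold <= 0)) stop("folds must be > 0")
  true_folds$fold <- pmax(true_folds$fold, fold_floor)
  genes <- union(unique(true_folds$gene), housekeeping)
  genotypes <- c(control, unique(true_folds$genotype))
  baseline <- baseline %||%
    stats::setNames(stats::runif(length(genes), 22, 28), genes)
  fold_of <- function(gene, genotype) {
    if (genotype == control || gene %in% housekeeping) return(1)
    hit <- true_folds$fold[true_folds$gene == gene &
                             true_folds$genotype == genotype]
    if (length(hit) == 0) 1 else hit[1]
  }
  rows <- list()
  for (gt in genotypes) {
    for (s in seq_len(n_per_genotype)) {
      sid <- paste0(gt, "_m", s)
      off <- stats::rnorm(1, 0, sample_sd)
      for (g in genes) {
        mu <- baseline[[g]] + off - log2(fold_of(g, gt)) +
          stats::rnorm(1, 0, sigma)
        for (r in seq_len(n_reps)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sid, genotype = gt, gene = g, replicate = r,
            ct = mu + stats::rnorm(1, 0, tech_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  ct <- do.call(rbind, rows)
  list(ct = ct,
       truth = list(true_folds = true_folds, baseline = baseline,
                    housekeeping = housekeeping, control = control,
                    params = list(n_per_genotype = n_per_genotype,
                                  n_reps = n_reps, sigma = sigma,
                                  tech_sd = tech_sd, sample_sd = sample_sd,
                                  fold_floor = fold_floor, seed = seed)))
}
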