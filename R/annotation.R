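# Gene-model container and annotation I/O. Readers lean on rtracklayer for
# the standard formats (GFF3 is 1-based fully closed, BED 0-based half-open);
# the container only keeps what the intergenic filter needs: per-gene
# transcript intervals, biotypes, and exon structure.

#' Construct an annotation set
#'
#' @param transcripts [GenomicRanges::GRanges] with one range per gene model
#'   and metadata columns `gene_id` and `biotype` (e.g. `"protein_coding"`,
#'   `"pseudogene"`).
#' @param exons Optional [GenomicRanges::GRanges] of exons with metadata
#'   column `gene_id`; every exon must lie within its gene's transcript
#'   interval.
#' @param source Provenance string (file path or `"synthetic"`).
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(transcripts, exons = NULL, source = NA_character_) {
  if (is.null(S4Vectors::mcols(transcripts)$gene_id)) {
    S4Vectors::mcols(transcripts)$gene_id <-
      paste0("gene", seq_along(transcripts))
  }
  if (is.null(S4Vectors::mcols(transcripts)$biotype)) {
    S4Vectors::mcols(transcripts)$biotype <- "protein_coding"
  }
  transcripts <- BiocGenerics::sort(transcripts, ignore.strand = TRUE)
  if (!is.null(exons) && length(exons) > 0) {
    ix <- match(S4Vectors::mcols(exons)$gene_id,
                S4Vectors::mcols(transcripts)$gene_id)
    if (anyNA(ix)) stop("exon with unknown gene_id")
    within <- BiocGenerics::start(exons) >= BiocGenerics::start(transcripts)[ix] &
      BiocGenerics::end(exons) <= BiocGenerics::end(transcripts)[ix]
    if (!all(within)) stop("exon outside its transcript interval")
    exons <- BiocGenerics::sort(exons, ignore.strand = TRUE)
  }
  structure(list(transcripts = transcripts, exons = exons, source = source),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$transcripts), "gene models",
      if (!is.null(x$exons)) paste0("(", length(x$exons), " exons)"),
      "\n  source:", x$source, "\n")
  invisible(x)
}

#' Gene/pseudogene footprints of an annotation set
#'
#' The union of all transcript intervals (all biotypes, pseudogenes
#' included); this is the space the intergenic filter removes.
#'
#' @param ann An `annotation_set`.
#' @return [GenomicRanges::GRanges] of merged footprints.
#' @export
gene_footprints <- function(ann) {
  GenomicRanges::reduce(ann$transcripts, ignore.strand = TRUE)
}

#' Read gene models from a GFF3 file
#'
#' Features of type `gene` or `pseudogene` become gene models; `exon`
#' features are attached by their `Parent`/`gene_id` attribute.
#'
#' @param path Path to a GFF3 file.
#' @return An `annotation_set`.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  tx <- gr[type %in% c("gene", "pseudogene")]
  gid <- tx$ID
  if (is.null(gid)) gid <- tx$Name
  bt <- tx$biotype
  if (is.null(bt)) bt <- ifelse(type[type %in% c("gene", "pseudogene")] ==
                                  "pseudogene", "pseudogene", "protein_coding")
  txo <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tx),
                                IRanges::ranges(tx))
  S4Vectors::mcols(txo)$gene_id <- as.character(gid)
  S4Vectors::mcols(txo)$biotype <- as.character(bt)
  ex <- gr[type == "exon"]
  exo <- NULL
  if (length(ex) > 0) {
    parent <- ex$Parent
    parent <- vapply(as.list(parent), function(p) as.character(p)[1],
                     character(1))
    exo <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(ex),
                                  IRanges::ranges(ex))
    S4Vectors::mcols(exo)$gene_id <- parent
  }
  annotation_set(txo, exo, source = path)
}

#' Read a mask track (e.g. repeats) from a BED file
#'
#' @param path Path to a BED file (0-based half-open on disk; rtracklayer
#'   converts to 1-based closed).
#' @return Merged, sorted [GenomicRanges::GRanges].
#' @export
read_mask_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  GenomicRanges::reduce(GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr),
                                               IRanges::ranges(gr)))
}
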