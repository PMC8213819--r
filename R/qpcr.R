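# qPCR deletion-effect analysis: 2^-ddCt relative expression with multi-gene
# housekeeping normalization, one-way ANOVA on dCt with Dunn-Sidak
# correction, and effect classification.
#
# "Geometric mean of the housekeeping genes" is implemented as the
# arithmetic mean of the housekeeping Ct values, which is algebraically
# identical to normalizing by the geometric mean of the housekeeping
# expression quantities 2^-Ct (the standard multi-reference-gene
# construction); the equivalence is unit-tested.

.check_ct_table <- function(tab) {
  need <- c("sample", "genotype", "gene", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    stop("Ct table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0)) {
    stop("all Ct values must be finite and > 0")
  }
  invisible(tab)
}

#' Read a qPCR Ct table from delimited text
#'
#' Expects columns `sample`, `genotype`, `gene`, `ct` and optionally
#' `replicate` (technical replicate index).
#'
#' @param path Path to a CSV (default) or TSV file.
#' @param sep Field separator.
#' @return `data.frame`.
#' @export
read_ct_table <- function(path, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  .check_ct_table(tab)
}

#' Per-sample, per-gene delta-Ct values
#'
#' Technical replicates are averaged within (sample, gene) first; then
#' dCt(gene, sample) = Ct(gene) - mean(Ct of housekeeping genes) within the
#' sample. Housekeeping genes themselves are retained in the output
#' (flagged), which makes the self-normalization property testable.
#'
#' @param tab Ct table (see [read_ct_table()]).
#' @param housekeeping Character vector of housekeeping gene names; every
#'   sample must carry all of them.
#' @return `data.frame` with columns `sample`, `genotype`, `gene`, `dct`,
#'   `is_housekeeping`.
#' @export
delta_ct <- function(tab, housekeeping) {
  .check_ct_table(tab)
  agg <- stats::aggregate(ct ~ sample + genotype + gene, data = tab,
                          FUN = mean)
  hk <- agg[agg$gene %in% housekeeping, ]
  counts <- table(hk$sample)
  all_samples <- unique(agg$sample)
  bad <- setdiff(all_samples, names(counts)[counts == length(housekeeping)])
  if (length(bad) > 0) {
    stop("missing housekeeping measurement in sample(s): ",
         paste(bad, collapse = ", "))
  }
  hk_mean <- tapply(hk$ct, hk$sample, mean)
  agg$dct <- agg$ct - as.numeric(hk_mean[as.character(agg$sample)])
  agg$is_housekeeping <- agg$gene %in% housekeeping
  agg[order(agg$gene, agg$genotype, agg$sample),
      c("sample", "genotype", "gene", "dct", "is_housekeeping")]
}

#' 2^-ddCt relative expression per gene and genotype
#'
#' ddCt = mean dCt(genotype) - mean dCt(control group); fold = 2^-ddCt.
#' The control group's fold is 1 by construction.
#'
#' @param dct Output of [delta_ct()].
#' @param control Name of the control genotype (e.g. `"wt"`).
#' @return `data.frame` with columns `gene`, `genotype`, `n`, `ddct`,
#'   `fold`.
#' @export
ddct_fold <- function(dct, control) {
  if (!control %in% dct$genotype) stop("control group not found: ", control)
  out <- lapply(split(dct, dct$gene), function(g) {
    ctrl <- g$dct[g$genotype == control]
    if (length(ctrl) == 0) {
      stop("gene absent in control group: ", g$gene[1])
    }
    per <- stats::aggregate(dct ~ genotype, data = g, FUN = mean)
    n <- stats::aggregate(dct ~ genotype, data = g, FUN = length)
    data.frame(gene = g$gene[1], genotype = per$genotype, n = n$dct,
               ddct = per$dct - mean(ctrl),
               fold = 2^-(per$dct - mean(ctrl)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dunn-Sidak family-wise adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for a family of `m` comparisons.
#'
#' @param p Numeric vector of p-values.
#' @param m Family size (>= 1).
#' @return Adjusted p-values in `[p, 1]`.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  1 - (1 - p)^m
}

#' One-way ANOVA on dCt with Dunn-Sidak correction
#'
#' For each gene, tests the null hypothesis of equal mean dCt across
#' genotypes with a two-sided one-way ANOVA F-test on the raw dCt values,
#' then applies the Sidak adjustment for a family of `family_size` genes.
#' A gene with zero within-group variance gets p = 1 if the group means are
#' equal and p = 0 otherwise.
#'
#' @param dct Output of [delta_ct()] (housekeeping rows are ignored).
#' @param family_size Number of comparisons in the family; defaults to the
#'   number of genes tested.
#' @return `data.frame` with columns `gene`, `p_value`, `p_adj`.
#' @export
anova_dunn_sidak <- function(dct, family_size = NULL) {
  d <- if (is.null(dct$is_housekeeping)) dct else dct[!dct$is_housekeeping, ]
  genes <- unique(d$gene)
  m <- family_size %||% length(genes)
  p <- vapply(genes, function(g) {
    gg <- d[d$gene == g, ]
    groups <- split(gg$dct, gg$genotype)
    groups <- groups[lengths(groups) > 0]
    if (length(groups) < 2 || any(lengths(groups) < 2)) {
      stop("need >= 2 groups with >= 2 observations each for gene ", g)
    }
    gm <- vapply(groups, mean, numeric(1))
    ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
    ssb <- sum(lengths(groups) * (gm - mean(gg$dct))^2)
    if (ssw <= 1e-10 * max(1, ssb)) {
      # degenerate: no within-group variance
      return(if (ssb <= 1e-10) 1 else 0)
    }
    fit <- stats::aov(dct ~ factor(genotype), data = gg)
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  data.frame(gene = genes, p_value = unname(p),
             p_adj = sidak_adjust(unname(p), m),
             stringsAsFactors = FALSE)
}

#' Classify deletion effects on expression
#'
#' `abolished` if fold <= `fold_abolished` and p_adj < `alpha`; `reduced`
#' if fold < 1 and p_adj < `alpha`; `spared` otherwise.
#'
#' @param folds Output of [ddct_fold()].
#' @param pvals Output of [anova_dunn_sidak()].
#' @param control Control genotype (its rows are dropped).
#' @param fold_abolished Fold threshold for "abolished" (default 0.05).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @return `data.frame` with columns `gene`, `genotype`, `fold`, `p_adj`,
#'   `effect`.
#' @export
classify_effect <- function(folds, pvals, control,
                            fold_abolished = 0.05, alpha = 0.05) {
  stopifnot(fold_abolished > 0, fold_abolished < 1, alpha > 0, alpha < 1)
  f <- folds[folds$genotype != control, ]
  f$p_adj <- pvals$p_adj[match(f$gene, pvals$gene)]
  f$effect <- ifelse(f$fold <= fold_abolished & f$p_adj < alpha, "abolished",
              ifelse(f$fold < 1 & f$p_adj < alpha, "reduced", "spared"))
  f[, c("gene", "genotype", "fold", "p_adj", "effect")]
}

#' Full qPCR deletion-effect pipeline
#'
#' Convenience wrapper: [delta_ct()] -> [ddct_fold()] +
#' [anova_dunn_sidak()] -> [classify_effect()].
#'
#' @param tab Ct table.
#' @param housekeeping Housekeeping gene names.
#' @param control Control genotype.
#' @param family_size ANOVA family size (default: number of non-housekeeping
#'   genes).
#' @param fold_abolished,alpha Passed to [classify_effect()].
#' @return List with elements `dct`, `folds`, `pvals`, `effects`.
#' @export
qpcr_pipeline <- function(tab, housekeeping, control, family_size = NULL,
                          fold_abolished = 0.05, alpha = 0.05) {
  dct <- delta_ct(tab, housekeeping)
  folds <- ddct_fold(dct[!dct$is_housekeeping, ], control)
  pvals <- anova_dunn_sidak(dct, family_size)
  effects <- classify_effect(folds, pvals, control, fold_abolished, alpha)
  list(dct = dct, folds = folds, pvals = pvals, effects = effects)
}
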