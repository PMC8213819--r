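# qPCR 2^-ddCt analysis: normalization, fold estimation, ANOVA with
# Dunn-Sidak correction, and effect classification.

mk_ct <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample = r[[1]], genotype = r[[2]], gene = r[[3]],
               ct = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
}

test_that("delta-Ct uses the mean of the housekeeping Cts within sample", {
  tab <- mk_ct(list(
    list("s1", "wt", "hk1", 20), list("s1", "wt", "hk2", 21),
    list("s1", "wt", "hk3", 22), list("s1", "wt", "tgt", 25)))
  d <- delta_ct(tab, c("hk1", "hk2", "hk3"))
  expect_equal(d$dct[d$gene == "tgt"], 4)
  # target equal to the housekeeping summary: dCt 0
  tab$ct[tab$gene == "tgt"] <- 21
  expect_equal(delta_ct(tab, c("hk1", "hk2", "hk3"))$dct[4], 0)
  # single housekeeping gene: plain difference
  d1 <- delta_ct(tab, "hk1")
  expect_equal(d1$dct[d1$gene == "tgt"], 1)
  # missing housekeeping measurement is an error
  expect_error(delta_ct(tab[tab$gene != "hk2", ], c("hk1", "hk2")),
               "missing housekeeping")
})

test_that("arithmetic mean of Cts equals geometric-mean normalization of quantities", {
  set.seed(211)
  hk_ct <- stats::runif(3, 18, 24)
  tgt_ct <- 27.3
  # normalizing 2^-Ct(target) by the geometric mean of the housekeeping
  # quantities 2^-Ct ...
  geo <- prod(2^-hk_ct)^(1 / 3)
  via_quantities <- -log2((2^-tgt_ct) / geo)
  # ... is identical to subtracting the arithmetic mean of housekeeping Cts
  via_cts <- tgt_ct - mean(hk_ct)
  expect_equal(via_quantities, via_cts)
  tab <- mk_ct(list(list("s1", "wt", "h1", hk_ct[1]),
                    list("s1", "wt", "h2", hk_ct[2]),
                    list("s1", "wt", "h3", hk_ct[3]),
                    list("s1", "wt", "tgt", tgt_ct)))
  d <- delta_ct(tab, c("h1", "h2", "h3"))
  expect_equal(d$dct[d$gene == "tgt"], via_quantities)
})

test_that("fold changes follow 2^-ddCt", {
  base <- list(
    list("w1", "wt", "g", 10), list("w2", "wt", "g", 10),
    list("w1", "wt", "hk", 10), list("w2", "wt", "hk", 10),
    list("m1", "mut", "hk", 10), list("m2", "mut", "hk", 10))
  shift <- function(delta) {
    tab <- mk_ct(c(base, list(list("m1", "mut", "g", 10 + delta),
                              list("m2", "mut", "g", 10 + delta))))
    d <- delta_ct(tab, "hk")
    f <- ddct_fold(d[!d$is_housekeeping, ], control = "wt")
    f$fold[f$genotype == "mut"]
  }
  expect_equal(shift(1), 0.5)    # one cycle later = half the expression
  expect_equal(shift(0), 1)
  expect_equal(shift(-2), 4)
  # control fold is 1 by construction
  tab <- mk_ct(c(base, list(list("m1", "mut", "g", 12),
                            list("m2", "mut", "g", 12))))
  d <- delta_ct(tab, "hk")
  f <- ddct_fold(d[!d$is_housekeeping, ], control = "wt")
  expect_equal(f$fold[f$genotype == "wt"], 1)
  expect_error(ddct_fold(d[d$genotype != "wt", ], control = "wt"),
               "control group not found")
})

test_that("Sidak adjustment matches its closed form exactly", {
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3)
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0, 5), 0)
  p <- seq(0, 1, by = 0.05)
  for (m in c(1, 3, 16)) {
    padj <- sidak_adjust(p, m)
    expect_true(all(padj >= p - 1e-12 & padj <= 1 + 1e-12))
    expect_true(all(diff(padj) >= -1e-12))  # monotone in p
  }
})

test_that("per-gene ANOVA p-values match a hand-computed F test", {
  tab <- mk_ct(list(
    list("w1", "wt", "g", 14), list("w2", "wt", "g", 15),
    list("w3", "wt", "g", 16),
    list("m1", "mut", "g", 18), list("m2", "mut", "g", 19),
    list("m3", "mut", "g", 20),
    list("w1", "wt", "hk", 10), list("w2", "wt", "hk", 10),
    list("w3", "wt", "hk", 10), list("m1", "mut", "hk", 10),
    list("m2", "mut", "hk", 10), list("m3", "mut", "hk", 10)))
  d <- delta_ct(tab, "hk")
  got <- anova_dunn_sidak(d, family_size = 1)
  # by hand: group means 5 and 9, SSB = 24, SSW = 4, df = (1, 4), F = 24
  expect_equal(got$p_value, stats::pf(24, 1, 4, lower.tail = FALSE))
  # degenerate cases: zero variance with equal/different means
  same <- d
  same$dct <- rep(5, nrow(same))
  expect_equal(anova_dunn_sidak(same, 1)$p_value, 1)
  diffm <- d
  diffm$dct <- ifelse(diffm$genotype == "wt", 5, 9)
  expect_equal(anova_dunn_sidak(diffm, 1)$p_value, 0)
})

test_that("effect classes follow the fold and significance thresholds", {
  folds <- data.frame(gene = c("a", "b", "c"), genotype = "mut",
                      n = 5, ddct = 0,
                      fold = c(0.01, 0.4, 0.95))
  pv <- data.frame(gene = c("a", "b", "c"),
                   p_value = c(1e-6, 0.001, 0.3),
                   p_adj = c(1e-6, 0.001, 0.3))
  got <- classify_effect(folds, pv, control = "wt")
  expect_identical(got$effect, c("abolished", "reduced", "spared"))
})

test_that("a housekeeping gene self-normalizes to fold 1 exactly without noise", {
  sim <- simulate_qpcr(sigma = 0, tech_sd = 0, sample_sd = 0.8, seed = 221)
  d <- delta_ct(sim$ct, sim$truth$housekeeping)
  f <- ddct_fold(d[d$gene == "Bgus", ], control = "wt")
  expect_equal(f$fold, rep(1, nrow(f)), tolerance = 1e-9)
})

test_that("the noiseless closed loop returns the planted fold exactly", {
  tf <- data.frame(gene = "g1", genotype = "del", fold = 0.5)
  sim <- simulate_qpcr(true_folds = tf, sigma = 0, tech_sd = 0,
                       sample_sd = 0.7, seed = 231)
  res <- qpcr_pipeline(sim$ct, sim$truth$housekeeping, control = "wt")
  expect_equal(res$folds$fold[res$folds$gene == "g1" &
                                res$folds$genotype == "del"],
               0.5, tolerance = 1e-9)
})

test_that("true folds are recovered within 20% (median over replicates)", {
  folds <- c(1, 0.5, 0.1, 0.01)
  tf <- data.frame(gene = paste0("g", seq_along(folds)), genotype = "del",
                   fold = folds)
  est <- matrix(NA_real_, nrow = 200, ncol = length(folds))
  for (r in 1:200) {
    sim <- simulate_qpcr(true_folds = tf, sigma = 0.2, seed = 300 + r)
    d <- delta_ct(sim$ct, sim$truth$housekeeping)
    f <- ddct_fold(d[!d$is_housekeeping, ], control = "wt")
    fd <- f[f$genotype == "del", ]
    est[r, ] <- fd$fold[match(tf$gene, fd$gene)]
  }
  med <- apply(est, 2, stats::median)
  expect_true(all(abs(med / folds - 1) <= 0.2))
})

test_that("the default deletion experiment classifies cluster genes as abolished", {
  sim <- simulate_qpcr(seed = 241)
  res <- qpcr_pipeline(sim$ct, sim$truth$housekeeping, control = "wt")
  truth <- sim$truth$true_folds
  ab <- res$effects$gene[res$effects$effect == "abolished"]
  sp <- res$effects$gene[res$effects$effect == "spared"]
  expect_setequal(ab, truth$gene[truth$fold < 0.05])
  expect_setequal(sp, truth$gene[truth$fold == 1])
})
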