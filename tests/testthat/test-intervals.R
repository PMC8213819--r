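# Coordinate parsing, convention handling, and interval arithmetic.

test_that("printed coordinates reproduce published lengths under their conventions", {
  cases <- list(
    list("chr10: 23,806,234-23,807,226", "one_based_fully_closed", 993L),
    list("chr10: 23,863,677-23,864,656", "one_based_fully_closed", 980L),
    list("chr10: 23,806,230-23,807,225", "one_based_fully_closed", 996L),
    list("chr10: 23,863,677-23,864,655", "one_based_fully_closed", 979L),
    list("chr10: 23,806,280-23,806,978", "one_based_end_exclusive", 698L),
    list("chr10: 23,863,682-23,864,027", "one_based_end_exclusive", 345L)
  )
  for (cs in cases) {
    iv <- parse_interval(cs[[1]], cs[[2]])
    expect_identical(interval_length(iv), cs[[3]])
  }
  # degenerate (empty) interval under the half-open convention
  expect_identical(interval_length(parse_interval("chrX: 100-100",
                                                  "zero_based_half_open")),
                   0L)
})

test_that("malformed or inverted coordinate strings are rejected", {
  expect_error(parse_interval("chr1 100-200", "one_based_fully_closed"),
               "malformed")
  expect_error(parse_interval("chr1: 100..200", "one_based_fully_closed"),
               "malformed")
  expect_error(parse_interval("chr1: 300-200", "one_based_fully_closed"),
               "start > end")
})

test_that("parse/format round-trips are lossless under every convention", {
  set.seed(11)
  for (conv in COORDINATE_CONVENTIONS) {
    for (i in 1:20) {
      s <- sample.int(1e6, 1)
      e <- s + sample.int(5000, 1)
      txt <- sprintf("chr%d: %d-%d", sample.int(20, 1), s, e)
      iv <- parse_interval(txt, conv)
      back <- format_interval(iv, conv, big_mark = "")
      expect_identical(gsub("[ ,]", "", back), gsub("[ ,]", "", txt))
    }
  }
  # thousands separators are stripped on input and re-emitted on output
  iv <- parse_interval("chr10: 23,806,280-23,806,978",
                       "one_based_end_exclusive")
  expect_identical(format_interval(iv, "one_based_end_exclusive"),
                   "chr10: 23,806,280-23,806,978")
})

test_that("intergenic_regions is the set complement of gene footprints", {
  bounds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  genes <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(101, 501), c(200, 600)))
  got <- intergenic_regions(genes, bounds)
  expect_identical(BiocGenerics::start(got), c(1L, 201L, 601L))
  expect_identical(BiocGenerics::end(got), c(100L, 500L, 1000L))

  # no genes within bounds: the bounds come back whole
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000))
  got <- intergenic_regions(far, bounds)
  expect_identical(BiocGenerics::start(got), 1L)
  expect_identical(BiocGenerics::end(got), 1000L)

  # overlapping genes behave as their union
  ovl <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(101, 251), c(300, 600)))
  got <- intergenic_regions(ovl, bounds)
  expect_identical(BiocGenerics::start(got), c(1L, 601L))
  expect_identical(BiocGenerics::end(got), c(100L, 1000L))

  expect_error(
    intergenic_regions(GenomicRanges::GRanges("chr9",
                                              IRanges::IRanges(1, 10)),
                       bounds),
    "chromosome mismatch")
})

test_that("intergenic complement matches a base-wise oracle and partitions the bounds", {
  set.seed(21)
  for (rep in 1:10) {
    bend <- sample(2000:10000, 1)
    bounds <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, bend))
    ng <- sample(0:8, 1)
    gs <- sort(sample.int(bend - 50, ng))
    ge <- pmin(bend, gs + sample.int(400, max(ng, 1))[seq_len(ng)])
    genes <- GenomicRanges::GRanges(rep("chrT", ng),
                                    IRanges::IRanges(gs, ge))
    got <- intergenic_regions(genes, bounds)
    got_bases <- unlist(lapply(seq_along(got), function(i)
      BiocGenerics::start(got)[i]:BiocGenerics::end(got)[i]))
    if (length(got) == 0) got_bases <- integer(0)
    expect_identical(sort(got_bases), oracle_complement(1, bend, gs, ge))
    # partition: intergenic and footprints are disjoint and cover bounds
    fp_bases <- setdiff(1:bend, oracle_complement(1, bend, gs, ge))
    expect_identical(sort(c(got_bases, fp_bases)), 1:bend)
  }
})

test_that("subtract_mask removes exactly the masked bases", {
  r <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(41, 60))
  got <- subtract_mask(r, m)
  expect_identical(BiocGenerics::start(got), c(1L, 61L))
  expect_identical(BiocGenerics::end(got), c(40L, 100L))

  # mask covering the region leaves nothing
  all_mask <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_length(subtract_mask(r, all_mask), 0)

  # abutting masks behave as one merged mask
  two <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(41, 51), c(50, 60)))
  expect_identical(as.data.frame(subtract_mask(r, two)),
                   as.data.frame(got))
})

test_that("subtract_mask matches a base-wise filter on random inputs", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(500:5000, 1)
    rs <- sort(sample.int(n - 20, 3))
    re <- pmin(n, rs + sample.int(300, 3))
    regions <- GenomicRanges::GRanges("chrT", IRanges::IRanges(rs, re))
    ms <- sort(sample.int(n - 10, 4))
    me <- pmin(n, ms + sample.int(150, 4))
    mask <- GenomicRanges::GRanges("chrT", IRanges::IRanges(ms, me))
    got <- subtract_mask(regions, mask)
    got_bases <- unlist(lapply(seq_along(got), function(i)
      BiocGenerics::start(got)[i]:BiocGenerics::end(got)[i]))
    if (length(got) == 0) got_bases <- integer(0)
    region_bases <- unique(unlist(mapply(seq, rs, re, SIMPLIFY = FALSE)))
    mask_bases <- unique(unlist(mapply(seq, ms, me, SIMPLIFY = FALSE)))
    expect_identical(sort(unique(got_bases)),
                     sort(setdiff(region_bases, mask_bases)))
  }
})
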