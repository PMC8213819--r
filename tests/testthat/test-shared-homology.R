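# Shared-block discovery, exact match probabilities, and FDR-controlled
# database scanning.

test_that("a planted exact 30-bp block is recovered with identity 1", {
  set.seed(151)
  block <- rand_dna(30)
  a <- paste0(rand_dna(200), block, rand_dna(270))
  b <- paste0(rand_dna(400), block, rand_dna(70))
  got <- find_shared_blocks(a, b)
  expect_gte(nrow(got), 1L)
  top <- got[1, ]
  expect_equal(top$identity, 1.0)
  expect_gte(top$length, 30L)
  # the reported block contains the planted copy in both sequences
  expect_lte(top$start_a, 201)
  expect_gte(top$end_a, 230)
  expect_lte(top$start_b, 401)
  expect_gte(top$end_b, 430)
})

test_that("identical sequences yield a full-length block", {
  set.seed(161)
  s <- rand_dna(120)
  got <- find_shared_blocks(s, s, min_len = 30)
  expect_true(any(got$start_a == 1 & got$end_a == 120 &
                    got$start_b == 1 & got$strand == "+"))
})

test_that("a reverse-strand planted block is found with forward-b coordinates", {
  set.seed(171)
  block <- rand_dna(40)
  a <- paste0(rand_dna(100), block, rand_dna(100))
  b <- paste0(rand_dna(60), revcomp(block), rand_dna(80))
  got <- find_shared_blocks(a, b)
  hit <- got[got$strand == "-", ][1, ]
  expect_equal(hit$identity, 1.0)
  expect_lte(hit$start_b, 61)
  expect_gte(hit$end_b, 100)
  # reported substrings are reverse complements of each other
  expect_identical(revcomp(hit$seq_b), hit$seq_a)
})

test_that("independent random 500-bp pairs yield no blocks in >= 95% of seeds", {
  clean <- 0L
  for (s in 1:100) {
    set.seed(10000 + s)
    got <- find_shared_blocks(rand_dna(500), rand_dna(500),
                              min_identity = 0.9, min_len = 30)
    if (nrow(got) == 0) clean <- clean + 1L
  }
  expect_gte(clean, 95L)
})

test_that("exact-identity blocks match the all-diagonals oracle on short inputs", {
  set.seed(181)
  for (rep in 1:10) {
    block <- rand_dna(35)
    a <- paste0(rand_dna(60), block, rand_dna(60))
    b <- paste0(rand_dna(90), block, rand_dna(40))
    got <- find_shared_blocks(a, b, min_identity = 1.0, min_len = 30,
                              both_strands = FALSE)
    ora <- oracle_diag_blocks(a, b, 30)
    # every oracle run of length >= 30 must be reported (possibly inside a
    # longer extension), and every reported block must be a true match
    for (i in seq_len(nrow(ora))) {
      expect_true(any(got$start_a <= ora$start_a[i] &
                        got$end_a >= ora$end_a[i]))
    }
    for (i in seq_len(nrow(got))) {
      expect_identical(got$seq_a[i], got$seq_b[i])
    }
  }
})

test_that("IUPAC match probabilities equal closed forms and enumeration", {
  expect_equal(iupac_match_pvalue("ACGT"), 0.25^4)
  expect_equal(iupac_match_pvalue("TAATNN"), 0.25^4)
  expect_equal(iupac_match_pvalue("NNNN"), 1.0)
  # exhaustive enumeration over all hexamers under a uniform background
  hex <- expand.grid(rep(list(c("A", "C", "G", "T")), 6),
                     stringsAsFactors = FALSE)
  n_match <- sum(apply(hex, 1, function(h)
    oracle_window_ok(paste(h, collapse = ""), "TAATNN")))
  expect_equal(iupac_match_pvalue("TAATNN"), n_match / 4^6)
  # non-uniform background, enumeration over trimers
  bg <- c(A = 0.4, C = 0.3, G = 0.2, T = 0.1)
  tri <- expand.grid(rep(list(names(bg)), 3), stringsAsFactors = FALSE)
  pr <- apply(tri, 1, function(h) prod(bg[unlist(h)]))
  ok <- apply(tri, 1, function(h)
    oracle_window_ok(paste(h, collapse = ""), "RYN"))
  expect_equal(iupac_match_pvalue("RYN", bg), sum(pr[ok]))
  expect_error(iupac_match_pvalue("ACGT", c(A = .5, C = .5, G = 0, T = .2)),
               "sum to 1")
})

test_that("a planted query wins the database scan at q < 0.05", {
  set.seed(191)
  query <- rand_dna(25)
  db <- vapply(1:63, function(i) rand_dna(400), character(1))
  names(db) <- paste0("decoy", 1:63)
  db[["island17"]] <- paste0(rand_dna(150), query, rand_dna(225))
  for (mode in c("iupac", "mismatch")) {
    got <- scan_database_with_qvalues(query, db, type = mode)
    expect_identical(got$target[1], "island17")
    expect_lt(got$q_value[1], 0.05)
  }
})

test_that("q-values are BH-monotone and match a hand-computed BH", {
  set.seed(201)
  query <- rand_dna(18)
  db <- vapply(1:5, function(i) rand_dna(300), character(1))
  names(db) <- paste0("t", 1:5)
  got <- scan_database_with_qvalues(query, db, type = "mismatch")
  expect_equal(got$q_value, oracle_bh(got$p_value), tolerance = 1e-12)
  expect_true(all(diff(got$q_value[order(got$p_value)]) >= -1e-12))
  # worked example: p = .01, .02, .03 over three targets -> q all .03
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)),
               stats::p.adjust(c(0.01, 0.02, 0.03), "BH"))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               c(0.03, 0.03, 0.03))
})

test_that("an empty database returns an empty, well-formed result", {
  got <- scan_database_with_qvalues("TAATNN", character(0))
  expect_identical(nrow(got), 0L)
  expect_true(all(c("target", "p_value", "q_value") %in% names(got)))
})

test_that("under the null the minimum q rarely clears 0.05", {
  hits <- 0L
  for (s in 1:150) {
    set.seed(20000 + s)
    query <- rand_dna(20)
    db <- vapply(1:10, function(i) rand_dna(200), character(1))
    names(db) <- paste0("t", 1:10)
    got <- scan_database_with_qvalues(query, db, type = "mismatch")
    if (min(got$q_value) < 0.05) hits <- hits + 1L
  }
  expect_lte(hits / 150, 0.10)
})
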