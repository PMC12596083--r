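test_that("exact substrings are found full-length on both strands", {
  q <- "ACGTTGCAGGTCCATGACCA"
  tgt <- c(chr = paste0(strrep("A", 40), q, strrep("C", 40)))
  h <- localAlign(q, tgt, min_len = 20, min_identity = 0.9)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 41L)
  expect_equal(h$end, 60L)
  expect_equal(h$strand, "+")
  expect_equal(h$length, 20L)
  expect_equal(h$identity, 1)

  tgt_rc <- c(chr = paste0(strrep("A", 40), centrotrace:::.revcomp(q),
                           strrep("C", 40)))
  h2 <- localAlign(q, tgt_rc, min_len = 20, min_identity = 0.9)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$identity, 1)
  expect_equal(h2$query_start, 1L)
  expect_equal(h2$query_end, 20L)
})

test_that("a mutated copy aligns with the planted identity", {
  q <- tiny_genome(100, seed = 3)[[1]]
  seg <- mutate_exact(q, 5, seed = 4) # 5 interior substitutions
  tgt <- c(chr = paste0(tiny_genome(300, seed = 5)[[1]], seg,
                        tiny_genome(300, seed = 6)[[1]]))
  h <- localAlign(q, tgt, min_len = 40, min_identity = 0.9)
  expect_equal(nrow(h), 1L)
  expect_equal(h$aligned_cols, 100L)
  expect_equal(h$identity, 0.95)
  expect_equal(h$start, 301L)
  expect_equal(h$end, 400L)
})

test_that("self-alignment returns one full-length identity hit", {
  q <- tiny_genome(500, seed = 11)[[1]]
  h <- localAlign(q, c(self = q), min_len = 20, min_identity = 0.99)
  expect_equal(nrow(h), 1L)
  expect_equal(h$aligned_cols, 500L)
  expect_equal(h$identity, 1)
})

test_that("degenerate inputs give empty hit tables, not errors", {
  expect_equal(nrow(localAlign("ACGTACGTACGTACGTACGTACGT",
                               character())), 0L)
  tgt <- tiny_genome(500, seed = 2)
  expect_equal(nrow(localAlign(strrep("N", 60), tgt, min_len = 20)), 0L)
  expect_error(localAlign("", tgt), "non-empty")
  expect_error(localAlign("ACGT", tgt, min_len = 4), "at least 20")
})

test_that("soft-masked bases align as uppercase", {
  q <- "acgttgcaggtccatgacca"
  tgt <- c(chr = paste0(strrep("G", 40), toupper(q), strrep("C", 40)))
  h <- localAlign(q, tgt, min_len = 20, min_identity = 0.9)
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1)
})

test_that("binScores reproduces the spec arithmetic on closed-form cases", {
  # no hits: all bins zero
  b0 <- binScores(250, NULL, 100)
  expect_equal(scoreTable(b0)$S, c(0L, 0L, 0L))
  # one full-length hit over 300 bp: three bins of (100, 1, 100)
  h1 <- data.frame(query_id = "q", query_start = 1L, query_end = 300L)
  b1 <- scoreTable(binScores(300, h1, 100))
  expect_equal(b1$L, rep(100L, 3))
  expect_equal(b1$N, rep(1L, 3))
  expect_equal(b1$S, rep(100L, 3))
  # two hits covering [1,80] and [51,100] of a 100-bp query: L=100, N=2
  h2 <- data.frame(query_id = "q", query_start = c(1L, 51L),
                   query_end = c(80L, 100L))
  b2 <- scoreTable(binScores(100, h2, 100))
  expect_equal(b2$L, 100L)
  expect_equal(b2$N, 2L)
  expect_equal(b2$S, 200L)
  # out-of-range hit is a contract violation
  h3 <- data.frame(query_id = "q", query_start = 90L, query_end = 120L)
  expect_error(binScores(100, h3, 100), "contract violation")
})

test_that("binScores is order-invariant and conserves covered bases", {
  centrotrace:::.with_seed(99, {
    for (rep in 1:10) {
      qlen <- sample(200:1000, 1)
      n <- sample(1:15, 1)
      s <- sample(qlen - 20, n, replace = TRUE)
      e <- pmin(qlen, s + sample(10:200, n, replace = TRUE))
      hits <- data.frame(query_id = "q", query_start = s, query_end = e)
      bw <- sample(c(10L, 50L, 100L), 1)
      a <- binScores(qlen, hits, bw)
      b <- binScores(qlen, hits[sample(n), , drop = FALSE], bw)
      expect_identical(scoreTable(a), scoreTable(b))
      covered <- sum(width(reduce(IRanges(s, e))))
      expect_equal(sum(scoreTable(a)$L), covered)
    }
  })
})

test_that("adding a hit never decreases any bin score", {
  centrotrace:::.with_seed(7, {
    qlen <- 600
    s <- sample(500, 8); e <- pmin(qlen, s + sample(20:150, 8, replace = TRUE))
    hits <- data.frame(query_id = "q", query_start = s, query_end = e)
    base <- scoreTable(binScores(qlen, hits[-8, ], 50))$S
    more <- scoreTable(binScores(qlen, hits, 50))$S
    expect_true(all(more >= base))
  })
})
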