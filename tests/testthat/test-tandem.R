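test_that("a perfect array is recovered with exact period and copy number", {
  centrotrace:::.with_seed(2, {
    arr <- strrep("ACGT", 50)
    g <- list(chr1 = paste0(centrotrace:::.random_dna(2000), arr,
                            centrotrace:::.random_dna(2000)))
    tr <- detectTandemRepeats(g, min_period = 2, max_period = 50)
    expect_length(tr, 1L)
    expect_equal(mcols(tr)$period, 4L)
    expect_equal(mcols(tr)$copy_number, 50, tolerance = 0.05)
    # consensus is ACGT up to rotation
    expect_true(mcols(tr)$consensus %in% c("ACGT", "CGTA", "GTAC", "TACG"))
    expect_gte(start(tr), 1995L)
    expect_lte(end(tr), 2206L)
  })
})

test_that("random sequence yields no arrays", {
  for (s in 1:20) {
    g <- tiny_genome(10000, seed = 200 + s)
    expect_length(detectTandemRepeats(g, min_copies = 3,
                                      min_identity = 0.8), 0L)
  }
})

test_that("a mutated 100-bp monomer array is recovered near its truth", {
  centrotrace:::.with_seed(17, {
    monomer <- centrotrace:::.random_dna(100)
    copies <- vapply(1:30, function(i) mutateSequence(monomer, 0.05), "")
    g <- list(chr1 = paste0(centrotrace:::.random_dna(3000),
                            paste(copies, collapse = ""),
                            centrotrace:::.random_dna(3000)))
    tr <- detectTandemRepeats(g, min_period = 2, max_period = 200)
    expect_length(tr, 1L)
    expect_lte(abs(mcols(tr)$period - 100L), 2L)
    expect_lte(abs(mcols(tr)$copy_number - 30), 1)
    expect_gte(mcols(tr)$mean_adjacent_identity, 0.8)
  })
})

test_that("CTR collection filters by centromere overlap and sums lengths", {
  cen <- GRanges("c1", IRanges(1, 1e6))
  arr <- GRanges(c("c1", "c1"), IRanges(c(1001, 2e6), c(11000, 2e6 + 9999)))
  mcols(arr)$period <- c(10L, 10L)
  mcols(arr)$copy_number <- c(1000, 1000)
  mcols(arr)$consensus <- c("A", "A")
  mcols(arr)$mean_adjacent_identity <- c(1, 1)
  ctr <- collectCTRs(arr, cen)
  expect_length(ctr$arrays, 1L) # the outside array is excluded
  expect_equal(ctr$total_bp, 10000L)
  expect_equal(ctr$fraction, 0.01) # 10 kb of a 1-Mb centromere
})

test_that("tracing maps amplified segments back to their source interval", {
  centrotrace:::.with_seed(23, {
    repA <- centrotrace:::.random_dna(600) # carries the amplified segment
    repB <- centrotrace:::.random_dna(600) # unrelated control
    seg <- substr(repA, 201, 300)
    copies <- vapply(1:40, function(i) mutateSequence(seg, 0.02), "")
    arr_seq <- paste(copies, collapse = "")
    g <- list(chr1 = paste0(centrotrace:::.random_dna(5000), arr_seq,
                            centrotrace:::.random_dna(5000)))
    cen <- GRanges("chr1", IRanges(4001, 10000))
    arrays <- detectTandemRepeats(g, min_period = 2, max_period = 200)
    ctr <- collectCTRs(arrays, cen, g)
    tr <- traceOrigin(c(repA = repA, repB = repB), ctr, bin_width = 10)
    # only the source representative reports a high-scoring interval
    expect_true(all(tr$intervals$query_id == "repA"))
    expect_equal(nrow(tr$intervals), 1L)
    iv <- tr$intervals[1, ]
    ov <- min(iv$end, 300) - max(iv$start, 201) + 1
    expect_gte(ov / 100, 0.8) # covers >= 80% of the true source segment
    # the unrelated representative has an all-zero track
    expect_equal(sum(scoreTable(tr$tracks$repB)$S), 0L)
    st <- coverageStats(tr)
    expect_false(st$undefined)
    expect_lte(st$covered_bp, st$alignment_total_bp)
    expect_gte(st$percent, 90)
  })
})

test_that("two representatives sharing a segment report consistent intervals", {
  centrotrace:::.with_seed(29, {
    shared <- centrotrace:::.random_dna(120)
    repA <- paste0(centrotrace:::.random_dna(200), shared,
                   centrotrace:::.random_dna(200))
    repB <- paste0(centrotrace:::.random_dna(80), shared,
                   centrotrace:::.random_dna(300))
    copies <- vapply(1:40, function(i) mutateSequence(shared, 0.02), "")
    g <- list(chr1 = paste0(centrotrace:::.random_dna(4000),
                            paste(copies, collapse = ""),
                            centrotrace:::.random_dna(4000)))
    cen <- GRanges("chr1", IRanges(3001, 10000))
    ctr <- collectCTRs(detectTandemRepeats(g, max_period = 200), cen, g)
    tr <- traceOrigin(c(repA = repA, repB = repB), ctr, bin_width = 10)
    expect_setequal(unique(tr$intervals$query_id), c("repA", "repB"))
    ivA <- tr$intervals[tr$intervals$query_id == "repA", ][1, ]
    ivB <- tr$intervals[tr$intervals$query_id == "repB", ][1, ]
    # homologous query positions: A carries the segment at 201, B at 81
    expect_lt(abs((ivA$start - 200) - (ivB$start - 80)), 25)
  })
})

test_that("empty catalogs and unrelated representatives give null traces", {
  ctr0 <- list(arrays = GRanges(), total_bp = 0L, fraction = NA_real_)
  tr0 <- traceOrigin(c(r = strrep("ACGT", 50)), ctr0)
  expect_equal(nrow(tr0$intervals), 0L)
  expect_equal(tr0$alignment_total_bp, 0L)
  st0 <- coverageStats(tr0)
  expect_true(st0$undefined)
})

test_that("coverage percentages follow half-up rounding at two decimals", {
  st <- coverageStats(120508, 127564)
  expect_equal(st$percent, 94.47)
  expect_equal(coverageStats(100, 100)$percent, 100)
  expect_equal(coverageStats(0, 100)$percent, 0)
  expect_equal(coverageStats(1, 3)$percent, 33.33)
  expect_equal(coverageStats(1, 6)$percent, 16.67)
  expect_error(coverageStats(101, 100), "exceeds")
})

test_that("interval similarity equals local-alignment identity", {
  centrotrace:::.with_seed(37, {
    a <- centrotrace:::.random_dna(100)
    expect_equal(intervalSimilarity(a, a), 1)
    b <- mutate_exact(a, 10, seed = 38)
    expect_equal(intervalSimilarity(a, b), 0.90, tolerance = 0.02)
    # unrelated random sequences stay clearly below related ones
    unrelated <- vapply(1:20, function(i)
      intervalSimilarity(centrotrace:::.random_dna(100),
                         centrotrace:::.random_dna(100)), 1)
    expect_gt(mean(unrelated < 0.6), 0.95)
    expect_error(intervalSimilarity("", a), "empty")
  })
})
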