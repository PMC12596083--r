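# helper: build a hit table with given target intervals and identities
mk_hits <- function(chrom, start, end, identity, qlen = 1000L) {
  n <- length(start)
  data.frame(query_id = "q", query_start = rep(1L, n),
             query_end = rep(qlen, n), chrom = chrom, start = start,
             end = end, strand = "+", aligned_cols = end - start + 1L,
             matches = round((end - start + 1L) * identity),
             length = end - start + 1L, identity = identity,
             score = 0L, stringsAsFactors = FALSE)
}

test_that("CRI follows the identity-weighted mass formula", {
  cen <- GRanges("c1", IRanges(1, 10000))
  # CEN hits (L=100, I=0.9), (L=50, I=0.8); non-CEN hit (L=100, I=0.7)
  hits <- mk_hits("c1", c(101, 301, 20001), c(200, 350, 20100),
                  c(0.9, 0.8, 0.7))
  r <- computeCRI(hits, cen)
  expect_equal(r@cen_mass, 100 * 0.9 + 50 * 0.8)
  expect_equal(r@noncen_mass, 70)
  expect_equal(criValue(r), 130 / 70)
  expect_equal(criStatus(r), "finite")
  expect_equal(r@n_cen_hits, 2L)
  expect_equal(r@n_noncen_hits, 1L)
})

test_that("zero-denominator and empty hit sets are flagged, not numeric", {
  cen <- GRanges("c1", IRanges(1, 10000))
  all_cen <- mk_hits("c1", c(1, 201), c(100, 400), c(1, 0.9))
  r <- computeCRI(all_cen, cen)
  expect_equal(criStatus(r), "infinite")
  expect_true(is.infinite(criValue(r)))
  r0 <- computeCRI(all_cen[0, ], cen)
  expect_equal(criStatus(r0), "undefined")
  expect_true(is.nan(criValue(r0)))
  bad <- all_cen
  bad$identity[1] <- 1.2
  expect_error(computeCRI(bad, cen), "contract violation")
})

test_that("hit classification uses the 50% target-overlap rule", {
  cen <- GRanges("c1", IRanges(1001, 2000))
  # 60% inside vs 40% inside
  hits <- mk_hits("c1", c(961, 1961), c(1060, 2060), c(1, 1))
  r <- computeCRI(hits, cen)
  expect_equal(r@n_cen_hits, 1L)
  expect_equal(r@n_noncen_hits, 1L)
})

test_that("CRI is scale-consistent and unit-consistent", {
  cen <- GRanges("c1", IRanges(1, 50000))
  centrotrace:::.with_seed(5, {
    for (rep in 1:20) {
      n <- sample(3:12, 1)
      s <- sample(c(100, 60000), n, replace = TRUE) + sample(5000, n)
      e <- s + sample(50:400, n, replace = TRUE)
      ident <- runif(n, 0.5, 1)
      hits <- mk_hits("c1", s, e, ident)
      r1 <- criValue(computeCRI(hits, cen))
      # scaling every L by a constant leaves CRI unchanged
      hits10 <- hits
      hits10$length <- hits10$length * 10L
      expect_equal(criValue(computeCRI(hits10, cen)), r1)
      # identities expressed in percent give the same ratio (unit cancels)
      cen_flag <- s <= 50000
      pct <- sum(hits$length[cen_flag] * hits$identity[cen_flag] * 100) /
        sum(hits$length[!cen_flag] * hits$identity[!cen_flag] * 100)
      if (any(cen_flag) && any(!cen_flag)) expect_equal(pct, r1)
    }
  })
})

test_that("CRI is monotone in centromeric and non-centromeric masses", {
  cen <- GRanges("c1", IRanges(1, 50000))
  centrotrace:::.with_seed(9, {
    for (rep in 1:20) {
      s <- c(sample(40000, 3), 60000 + sample(40000, 3))
      e <- s + sample(80:200, 6, replace = TRUE)
      ident <- runif(6, 0.5, 0.95)
      hits <- mk_hits("c1", s, e, ident)
      base <- criValue(computeCRI(hits, cen))
      up <- hits; up$identity[1] <- min(1, up$identity[1] + 0.04)
      expect_gte(criValue(computeCRI(up, cen)), base)
      down <- hits; down$identity[4] <- min(1, down$identity[4] + 0.04)
      expect_lte(criValue(computeCRI(down, cen)), base)
    }
  })
})

test_that("CLTRI aligns the 5' LTR and applies the same formula", {
  centrotrace:::.with_seed(15, {
    ltr <- centrotrace:::.random_dna(400)
    g <- list(chr1 = centrotrace:::.random_dna(40000))
    cen <- GRanges("chr1", IRanges(20001, 32000))
    # equal-geometry copies: 3 centromeric, 1 not (plus the element's own
    # two repeats outside the centromere)
    for (s in c(21001, 24001, 27001)) g <- plant(g, "chr1", s, ltr)
    g <- plant(g, "chr1", 36001, ltr)
    el_seq <- paste0(ltr, centrotrace:::.random_dna(1200), ltr)
    g <- plant(g, "chr1", 2001, el_seq)
    el <- element_row("el_x", "chr1", 2001, 400, 1200)
    r <- computeCLTRI(el, g, cen)
    # masses: 3 cen vs 3 noncen (planted 1 + the element's own 2 LTRs)
    expect_equal(criValue(r), 1)
    expect_equal(r@n_cen_hits, 3L)
    expect_equal(r@n_noncen_hits, 3L)
  })
})

test_that("nCR selection thresholds, ranks and skips undefined entries", {
  mk <- function(id, cri, status) new("EnrichmentResult", element_id = id,
    cen_mass = if (is.finite(cri)) cri else 1, noncen_mass = if (is.finite(cri)) 1 else 0,
    n_cen_hits = 1L, n_noncen_hits = 0L, cri = cri, status = status)
  res <- list(mk("a", 5, "finite"), mk("b", 1.2, "finite"),
              mk("c", Inf, "infinite"))
  expect_equal(selectNCRs(res, 2), c("c", "a"))
  und <- list(mk("u1", NaN, "undefined"), mk("u2", NaN, "undefined"))
  expect_equal(selectNCRs(und, 2), character())
})
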