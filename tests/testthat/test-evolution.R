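test_that("LTR extraction honours strand and recovers planted sequences", {
  centrotrace:::.with_seed(3, {
    ltr5 <- centrotrace:::.random_dna(120)
    ltr3 <- centrotrace:::.random_dna(120)
    internal <- centrotrace:::.random_dna(400)
    fwd <- paste0(ltr5, internal, ltr3)
    g <- list(chr1 = paste0(centrotrace:::.random_dna(200), fwd,
                            centrotrace:::.random_dna(200)),
              chr2 = paste0(centrotrace:::.random_dna(200),
                            centrotrace:::.revcomp(fwd),
                            centrotrace:::.random_dna(200)))
    el <- rbind(element_row("plus", "chr1", 201, 120, 400, strand = "+"),
                element_row("minus", "chr2", 201, 120, 400, strand = "-"))
    ex <- extractLTRs(el, g)
    expect_equal(ex$ltr5[["plus"]], ltr5)
    expect_equal(ex$ltr3[["plus"]], ltr3)
    # minus-strand element: the genomic right-hand repeat, reverse
    # complemented, is the transcription-proximal 5' LTR again
    expect_equal(ex$ltr5[["minus"]], ltr5)
    expect_equal(ex$ltr3[["minus"]], ltr3)
    el_bad <- element_row("off", "chr1", 700, 120, 400)
    expect_error(extractLTRs(el_bad, g), "beyond")
  })
})

test_that("insertion dating is exact at p = 0 and matches the correction", {
  ltr <- tiny_genome(1000, seed = 8)[[1]]
  d0 <- dateInsertion(ltr, ltr)
  expect_equal(d0$p_distance, 0)
  expect_equal(d0$k_jc, 0)
  expect_equal(d0$insertion_time_mya, 0)

  # exactly 1% mismatching sites, no indels: closed-form correction
  ltr_b <- mutate_exact(ltr, 10, seed = 9)
  d1 <- dateInsertion(ltr, ltr_b, mu = 1.3e-8)
  expect_equal(d1$p_distance, 0.01)
  expect_equal(d1$k_jc, -0.75 * log(1 - 0.04 / 3), tolerance = 1e-12)
  expect_equal(d1$k_jc, 0.0100671, tolerance = 1e-4)
  expect_equal(d1$insertion_time_mya, 0.3872, tolerance = 1e-3)

  # symmetry and monotonicity in p
  d1r <- dateInsertion(ltr_b, ltr, mu = 1.3e-8)
  expect_equal(d1$insertion_time_mya, d1r$insertion_time_mya)
  d2 <- dateInsertion(ltr, mutate_exact(ltr, 40, seed = 10))
  expect_gt(d2$insertion_time_mya, d1$insertion_time_mya)
})

test_that("saturated divergence is flagged instead of dated", {
  a <- strrep("A", 300)
  b <- strrep("C", 300) # every aligned column mismatches, gaps never help
  d <- dateInsertion(a, b)
  expect_true(d$saturated)
  expect_true(is.na(d$insertion_time_mya))
})

test_that("simulated LTR pairs date back to their generative age", {
  centrotrace:::.with_seed(20, {
    mu <- 1.3e-8
    for (age in c(0.35, 2.46)) {
      est <- vapply(1:20, function(i) {
        anc <- centrotrace:::.random_dna(800)
        d <- mu * age * 1e6
        dateInsertion(mutateSequence(anc, d), mutateSequence(anc, d),
                      mu = mu)$insertion_time_mya
      }, 1)
      expect_lt(abs(mean(est) - age) / age, 0.15)
    }
  })
})

test_that("greedy clustering collapses identical and separates unrelated", {
  s5 <- tiny_genome(300, seed = 31)[[1]]
  seqs <- stats::setNames(rep(s5, 5), paste0("s", 5:1))
  cl <- clusterGreedy(seqs, 0.70)
  expect_equal(unique(cl$representative_id), "s1") # lexicographic tie-break
  expect_equal(nrow(cl), 5L)
  expect_true(all(cl$identity >= 0.70))

  two <- c(a = tiny_genome(400, seed = 32)[[1]],
           b = tiny_genome(400, seed = 33)[[1]])
  cl2 <- clusterGreedy(two, 0.70)
  expect_equal(length(unique(cl2$representative_id)), 2L)
})

test_that("clustering recovers two planted ancestries perfectly", {
  centrotrace:::.with_seed(41, {
    anc1 <- centrotrace:::.random_dna(500)
    anc2 <- centrotrace:::.random_dna(500)
    seqs <- character()
    truth <- character()
    for (k in 1:10) {
      seqs[sprintf("a%02d", k)] <- mutateSequence(anc1, 0.05)
      seqs[sprintf("b%02d", k)] <- mutateSequence(anc2, 0.05)
      truth[sprintf("a%02d", k)] <- "anc1"
      truth[sprintf("b%02d", k)] <- "anc2"
    }
    cl <- clusterGreedy(seqs, 0.70)
    expect_equal(length(unique(cl$representative_id)), 2L)
    # members of one cluster share one generative ancestor
    for (r in unique(cl$representative_id)) {
      members <- cl$member_id[cl$representative_id == r]
      expect_equal(length(unique(truth[members])), 1L)
    }
    # every member meets the threshold against its representative (direct
    # assertion on the output contract)
    expect_true(all(cl$identity >= 0.70))
    # cluster count is non-increasing in the threshold
    n_low <- length(unique(clusterGreedy(seqs, 0.45)$representative_id))
    n_high <- length(unique(clusterGreedy(seqs, 0.95)$representative_id))
    expect_lte(n_low, 2L)
    expect_gte(n_high, 2L)
  })
})
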