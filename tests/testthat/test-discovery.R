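test_that("family census applies the 50% overlap rule", {
  cen <- GRanges("c1", IRanges(1001, 2000))
  anns <- GRanges("c1", IRanges(c(1100, 951, 2101), c(1200, 1050, 2200)))
  mcols(anns)$family_id <- c("famA", "famA", "famA")
  cs <- censusFamilies(anns, cen)
  expect_equal(cs$genome_count, 3L)
  # copy 2 straddles the boundary 50/50 (951-1050: 50 bases inside)
  expect_equal(cs$centromeric_count, 2L)
  # 60/40 straddle counts as centromeric
  anns2 <- GRanges("c1", IRanges(961, 1060))
  mcols(anns2)$family_id <- "famB"
  expect_equal(censusFamilies(anns2, cen)$centromeric_count, 1L)
  expect_equal(nrow(censusFamilies(GRanges(), cen)), 0L)
})

test_that("census matches brute-force interval intersection on a simulation", {
  sim <- fixture_sims()[[1]]
  cs <- censusFamilies(sim$annotations, sim$centromeres)
  # brute force from the truth table
  cen <- sim$centromeres
  for (k in seq_len(nrow(cs))) {
    fam <- cs$family_id[k]
    idx <- which(mcols(sim$annotations)$family_id == fam)
    n_cen <- 0L
    for (i in idx) {
      a <- sim$annotations[i]
      ov <- 0L
      for (j in seq_along(cen)) {
        if (as.character(seqnames(a)) != as.character(seqnames(cen[j]))) next
        ov <- ov + max(0L, min(end(a), end(cen[j])) -
                         max(start(a), start(cen[j])) + 1L)
      }
      if (ov >= width(a) / 2) n_cen <- n_cen + 1L
    }
    expect_equal(cs$centromeric_count[k], n_cen)
    expect_equal(cs$genome_count[k], length(idx))
  }
})

test_that("candidate selection thresholds counts and resolves containment", {
  census <- data.frame(family_id = c("A", "B"),
                       centromeric_count = c(150L, 99L),
                       genome_count = c(200L, 120L))
  seqs <- c(A = tiny_genome(800, seed = 21)[[1]],
            B = tiny_genome(500, seed = 22)[[1]])
  expect_equal(selectCandidates(census, seqs, min_count = 100), "A")

  # B's consensus verbatim inside A's: only the container A survives
  census2 <- data.frame(family_id = c("A", "B"),
                        centromeric_count = c(150L, 140L),
                        genome_count = c(200L, 150L))
  a <- tiny_genome(1200, seed = 23)[[1]]
  seqs2 <- c(A = a, B = substr(a, 201, 700))
  expect_equal(selectCandidates(census2, seqs2, min_count = 100), "A")

  # chain of containment collapses to the maximal container
  census3 <- data.frame(family_id = c("A", "B", "C"),
                        centromeric_count = c(150L, 140L, 130L),
                        genome_count = c(200L, 150L, 140L))
  seqs3 <- c(A = a, B = substr(a, 201, 900), C = substr(a, 301, 700))
  expect_equal(selectCandidates(census3, seqs3, min_count = 100), "A")

  expect_error(selectCandidates(census, seqs["A"], min_count = 90),
               "no consensus sequence .* B")
})

test_that("CR calling accepts shared structure and rejects small overlap", {
  g <- tiny_genome(30000, seed = 31)
  cand <- substr(g[[1]], 5001, 11000) # a 6-kb candidate from the genome
  # element 1: identical span; element 2: shares only a 300-bp segment
  el <- rbind(element_row("el_a", "chr1", 5001, 800, 4400),
              element_row("el_b", "chr1", 20001, 800, 4400))
  g <- plant(g, "chr1", 20001, paste0(substr(cand, 1, 300),
                                      tiny_genome(5700, seed = 32)[[1]]))
  res <- callCRs(cand, el, g)
  expect_equal(res$cr_ids, "el_a")
  expect_equal(res$representative_id, "el_a")
})

test_that("the representative CR is the element closest in length", {
  # candidate of 12281 bp; CR spans of 11454, 9000 and 13900 bp all match
  centrotrace:::.with_seed(41, {
    cand <- centrotrace:::.random_dna(12281)
    pad <- centrotrace:::.random_dna(13900 - 12281)
    g <- list(chr1 = paste0(
      centrotrace:::.random_dna(500),
      substr(cand, 1, 11454), centrotrace:::.random_dna(500),
      substr(cand, 1, 9000), centrotrace:::.random_dna(500),
      paste0(cand, pad), centrotrace:::.random_dna(500)))
    s1 <- 501L
    s2 <- s1 + 11454L + 500L
    s3 <- s2 + 9000L + 500L
    el <- rbind(
      element_row("el_mid", "chr1", s1, 800, 11454 - 1600),
      element_row("el_small", "chr1", s2, 800, 9000 - 1600),
      element_row("el_big", "chr1", s3, 800, 13900 - 1600))
    res <- callCRs(cand, el, g)
    expect_setequal(res$cr_ids, c("el_mid", "el_small", "el_big"))
    expect_equal(res$representative_id, "el_mid") # |11454 - 12281| smallest
  })
})

test_that("probe copies count gapless matches within the mismatch cap", {
  centrotrace:::.with_seed(51, {
    probe <- centrotrace:::.random_dna(376)
    g <- list(chr1 = centrotrace:::.random_dna(50000),
              chr2 = centrotrace:::.random_dna(30000))
    # 3 copies on chr1 (one with 11 mismatches = the cap, one reverse
    # complement), 1 copy with 12 mismatches (over the cap) on chr2
    g <- plant(g, "chr1", 1001, probe)
    g <- plant(g, "chr1", 5001, mutate_exact(probe, 11, seed = 52))
    g <- plant(g, "chr1", 9001, centrotrace:::.revcomp(probe))
    g <- plant(g, "chr2", 2001, mutate_exact(probe, 12, seed = 53))
    tab <- countProbeCopies(probe, g, mismatch_frac = 0.03)
    expect_equal(tab$copies, c(3L, 0L))
    expect_equal(tab$cumulative_len, c(3L * 376L, 0L))
    m <- attr(tab, "matches")
    expect_setequal(m$start, c(1001L, 5001L, 9001L))
    expect_equal(sort(m$strand), c("+", "+", "-"))
  })
})

test_that("zero-mismatch probe counting equals a naive exact scan", {
  centrotrace:::.with_seed(61, {
    g <- list(chr1 = centrotrace:::.random_dna(20000))
    probe <- centrotrace:::.random_dna(40)
    g <- plant(g, "chr1", 301, probe)
    g <- plant(g, "chr1", 7501, probe)
    g <- plant(g, "chr1", 12001, centrotrace:::.revcomp(probe))
    tab <- countProbeCopies(probe, g, mismatch_frac = 0)
    # naive scan on both strands
    naive <- 0L
    rc <- centrotrace:::.revcomp(probe)
    for (p in 1:(nchar(g$chr1) - 39L)) {
      w <- substr(g$chr1, p, p + 39L)
      if (w == probe || w == rc) naive <- naive + 1L
    }
    expect_equal(tab$copies, naive)
    expect_equal(tab$copies, 3L)
  })
})

test_that("probe design picks the window with the best centromeric excess", {
  centrotrace:::.with_seed(71, {
    ltr <- centrotrace:::.random_dna(500)
    win_true <- substr(ltr, 101, 200) # the window planted in centromeres
    g <- list(chr1 = centrotrace:::.random_dna(60000))
    cen <- GRanges("chr1", IRanges(30001, 50000))
    el_seq <- paste0(ltr, centrotrace:::.random_dna(2000), ltr)
    g <- plant(g, "chr1", 1001, el_seq) # the element itself, outside cen
    for (s in seq(31000, 45000, by = 1500))
      g <- plant(g, "chr1", s, win_true)
    el <- element_row("el_cr", "chr1", 1001, 500, 2000)
    spec <- designProbe(el, g, cen, probe_len = 100, mismatch_frac = 0)
    expect_equal(spec$source$part, "ltr5")
    expect_equal(spec$source$start, 1001L + 100L)
    expect_equal(spec$cen_copies, 10L)
    expect_equal(spec$sequence, win_true)
    # an LTR shorter than the probe is an error
    expect_error(designProbe(el, g, cen, probe_len = 600), "shorter")
  })
})

test_that("element occupancy matches the planted truth table", {
  # clean construction: 10 centromeric + 2 other copies, no solo LTRs or
  # satellite arrays to add extra alignments
  cfg <- simConfig(n_chroms = 1, planted_cr_copies_cen = 10,
                   planted_cr_copies_noncen = 2, background_copies = 5,
                   extra_ltr_solo_copies_cen = 0, tr_copy_number = 0)
  sim <- simulateGenome(cfg, seed = 77)
  rep_el <- sim$elements[sim$elements$true_family == "family_1" &
                         sim$elements$location_class == "cen", ][1, ]
  occ <- elementOccupancy(rep_el, sim$genome, sim$centromeres)
  expect_equal(occ$cen_hits, 10L)
  expect_equal(occ$noncen_hits, 2L)
})

test_that("solo LTR copies push terminal-repeat occupancy above the internal domain", {
  sim <- fixture_sims()[[1]]
  rep_el <- sim$elements[sim$elements$true_family == "family_1" &
                         sim$elements$location_class == "cen", ][1, ]
  occ <- elementOccupancy(rep_el, sim$genome, sim$centromeres)
  mean_s <- function(tr) mean(scoreTable(tr)$S)
  expect_gt(mean_s(occ$part_tracks$ltr5), mean_s(occ$part_tracks$internal))
  expect_gt(mean_s(occ$part_tracks$ltr3), mean_s(occ$part_tracks$internal))
})
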