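# Shared fixtures, generated in code and cached for the session so the
# recovery suites reuse one set of simulated genomes.

.fx <- new.env(parent = emptyenv())

# 20 default-configuration replicates (fixed seeds).
fixture_sims <- function(n = 20L) {
  key <- paste0("sims", n)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- lapply(seq_len(n), function(s)
      simulateGenome(simConfig(), seed = 100L + s))
  .fx[[key]]
}

# Matching negative-control replicates (random satellite monomer).
fixture_neg_sims <- function(n = 20L) {
  key <- paste0("neg", n)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- lapply(seq_len(n), function(s)
      simulateGenome(simConfig(tr_source = "random"), seed = 500L + s))
  .fx[[key]]
}

# A small deterministic random genome as a named character vector.
tiny_genome <- function(lens, seed = 1L) {
  centrotrace:::.with_seed(seed, {
    stats::setNames(lapply(lens, function(n) centrotrace:::.random_dna(n)),
                    paste0("chr", seq_along(lens)))
  })
}

# Plant `seq` at `start` (1-based) on chromosome `chrom` of a genome list.
plant <- function(genome, chrom, start, seq) {
  substr(genome[[chrom]], start, start + nchar(seq) - 1L) <- seq
  genome
}

# Substitute exactly `n_mm` positions of a sequence (interior, spaced).
mutate_exact <- function(seq, n_mm, seed = 1L) {
  centrotrace:::.with_seed(seed, {
    v <- strsplit(seq, "")[[1]]
    pos <- round(seq(5, length(v) - 4, length.out = n_mm))
    for (p in pos)
      v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  })
}

# One-row intact-element table entry for a hand-built element.
element_row <- function(id, chrom, start, ltr_len, internal_len,
                        strand = "+", family = "famX") {
  end <- start + 2L * ltr_len + internal_len - 1L
  data.frame(element_id = id, chrom = chrom, start = start, end = end,
             strand = strand, ltr5_start = start,
             ltr5_end = start + ltr_len - 1L,
             internal_start = start + ltr_len,
             internal_end = end - ltr_len,
             ltr3_start = end - ltr_len + 1L, ltr3_end = end,
             family_id = family, subfamily = NA_character_,
             insertion_time_mya = NA_real_, stringsAsFactors = FALSE)
}
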