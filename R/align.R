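# Deterministic pairwise local alignment and the binned S = L x N score.

#' Local alignment of a query against target sequences
#'
#' Seed-and-extend local alignment on both strands: exact 13-mer seed matches
#' are grouped into diagonal chains and each chain is extended by banded
#' Smith-Waterman (match +1, mismatch -1, gap -2 per gap column). Soft-masked
#' (lowercase) bases align as their uppercase equivalents; `N` never matches.
#' Hits on the same strand whose target intervals overlap by at least 90% of
#' the shorter one are collapsed to the higher-scoring hit, so each locally
#' maximal alignment is reported once.
#'
#' @param query A DNA string (character or `DNAString`).
#' @param targets Named character vector or `DNAStringSet` of target
#'   sequences; an empty set yields an empty result.
#' @param min_len Minimum alignment columns for a reported hit (>= 20).
#' @param min_identity Minimum identity (matches / alignment columns) in
#'   (0, 1].
#' @param query_id Identifier recorded in the output.
#' @param kmer Seed length.
#' @param band_pad Extra band half-width around each seed chain's diagonals.
#' @param max_seed_gap Maximum target gap between consecutive seeds of one
#'   chain.
#' @param diag_slack Maximum diagonal drift within one chain.
#' @return A data.frame of hits sorted by (chrom, start, strand) with 1-based
#'   closed coordinates: `query_id`, `query_start`, `query_end`, `chrom`,
#'   `start`, `end`, `strand`, `aligned_cols`, `matches`, `length`
#'   (= `aligned_cols`), `identity`, `score`.
#' @examples
#' localAlign("ACGTACGTACGTACGTACGT",
#'            c(chr = paste0(strrep("A", 30), "ACGTACGTACGTACGTACGT",
#'                           strrep("C", 30))))
#' @export
localAlign <- function(query, targets, min_len = 20L, min_identity = 0.8,
                       query_id = "query", kmer = 13L, band_pad = 48L,
                       max_seed_gap = 400L, diag_slack = 30L) {
  query <- .seq_chars(query)
  if (nchar(query) == 0L) stop("query must be non-empty")
  if (min_len < 20L) stop("min_len must be at least 20")
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must lie in (0, 1]")
  empty <- data.frame(query_id = character(), query_start = integer(),
                      query_end = integer(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), aligned_cols = integer(),
                      matches = integer(), length = integer(),
                      identity = numeric(), score = integer(),
                      stringsAsFactors = FALSE)
  if (length(targets) == 0L) return(empty)
  tg <- .genome_chars(targets)
  raw <- cpp_local_align(query, unname(tg), as.integer(min_len),
                         min_identity, as.integer(kmer),
                         as.integer(band_pad), as.integer(max_seed_gap),
                         as.integer(diag_slack), 1L, -1L, 2L)
  if (nrow(raw) == 0L) return(empty)
  out <- data.frame(query_id = query_id,
                    query_start = raw$q_start + 1L,
                    query_end = raw$q_end,
                    chrom = names(tg)[raw$chrom_idx],
                    start = raw$t_start + 1L,
                    end = raw$t_end,
                    strand = raw$strand,
                    aligned_cols = raw$cols,
                    matches = raw$matches,
                    length = raw$cols,
                    identity = raw$matches / raw$cols,
                    score = raw$score,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert alignment hits to a GRanges on the target genome
#'
#' @param hits A hit table from [localAlign()].
#' @return GRanges of the hit target intervals with the hit columns as
#'   metadata.
#' @export
hitsAsGRanges <- function(hits) {
  if (nrow(hits) == 0L) return(GRanges())
  gr <- GRanges(hits$chrom, IRanges(hits$start, hits$end),
                strand = hits$strand)
  mcols(gr) <- DataFrame(hits[c("query_id", "query_start", "query_end",
                                "aligned_cols", "matches", "identity",
                                "score")])
  gr
}

#' Binned alignment score S = L x N over a query
#'
#' The query is partitioned into consecutive `bin_width` bins (the last may
#' be partial). For each bin, `N` counts the hits whose query interval
#' intersects the bin, `L` counts the bin positions covered by the union of
#' hit query intervals, and `S = L * N`. The result is invariant to hit
#' ordering, and the per-bin `L` sum equals the number of distinct query
#' bases covered by any hit.
#'
#' @param query_len Query length in bp.
#' @param hits Hit table from [localAlign()] (all rows must refer to the
#'   same query; only `query_start`/`query_end` are used).
#' @param bin_width Bin width in bp (classically 100 bp for element occupancy
#'   profiles, 10 bp for satellite tracing).
#' @param query_id Identifier recorded in the result.
#' @return A [BinnedScoreTrack-class].
#' @export
binScores <- function(query_len, hits, bin_width = 100L,
                      query_id = "query") {
  query_len <- as.integer(query_len)
  bin_width <- as.integer(bin_width)
  stopifnot(query_len > 0L, bin_width > 0L)
  nb <- as.integer(ceiling(query_len / bin_width))
  if (!is.null(hits) && nrow(hits) > 0L) {
    if (length(unique(hits$query_id)) > 1L)
      stop("hits must all refer to the same query")
    if (any(hits$query_start < 1L) || any(hits$query_end > query_len) ||
        any(hits$query_start > hits$query_end))
      stop("hit query interval outside [1, query_len]: contract violation")
    qr <- IRanges(hits$query_start, hits$query_end)
  } else {
    qr <- IRanges()
  }
  bins <- IRanges(start = (seq_len(nb) - 1L) * bin_width + 1L,
                  end = pmin(seq_len(nb) * bin_width, query_len))
  N <- countOverlaps(bins, qr)
  cov <- coverage(qr, width = query_len)
  covered <- as.integer(IRanges::viewSums(IRanges::Views(cov > 0L, bins)))
  new("BinnedScoreTrack", query_id = query_id, query_len = query_len,
      bin_width = bin_width, L = covered, N = as.integer(N),
      S = covered * as.integer(N))
}
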