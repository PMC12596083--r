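# Tandem-repeat detection, the centromeric TR (CTR) catalog, and the
# CLTR -> CTR origin trace with binned scores and high-scoring intervals.

#' Detect tandem repeat arrays by period agreement
#'
#' For each candidate period p, positions i and i + p are compared; maximal
#' runs whose agreement stays at or above `min_identity` and whose implied
#' array spans at least `min_copies * p` bases are reported. Overlapping
#' calls across periods are resolved to the longer array (ties to the
#' shorter period). The consensus is the per-column majority over the phased
#' copies.
#'
#' @param genome Genome sequences (or a single sequence).
#' @param regions Optional GRanges restricting the scan (coordinates are
#'   lifted back to the chromosome); scanning whole chromosomes is the
#'   default.
#' @param min_period,max_period Period range in bp (defaults 2 and 500).
#' @param min_copies Minimum copy number (default 3).
#' @param min_identity Minimum adjacent-copy agreement (default 0.8).
#' @param min_len Minimum array length in bp (default 50). Plays the role of
#'   a score threshold: without it, chance dinucleotide wobble (e.g. a
#'   6-bp `TCTCTC`) formally satisfies a low copy-number cutoff and floods
#'   the catalog.
#' @return A GRanges of arrays with metadata `period`, `copy_number`,
#'   `consensus`, `mean_adjacent_identity`.
#' @export
detectTandemRepeats <- function(genome, regions = NULL, min_period = 2L,
                                max_period = 500L, min_copies = 3,
                                min_identity = 0.8, min_len = 50L) {
  stopifnot(min_period >= 2L, min_period <= max_period, min_copies >= 2)
  g <- .genome_chars(genome)
  scan <- if (is.null(regions)) {
    data.frame(chrom = names(g), start = 1L,
               end = nchar(g), stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = as.character(seqnames(regions)),
               start = start(regions), end = end(regions),
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(scan))) {
    chrom <- scan$chrom[i]
    seg <- substr(g[[chrom]], scan$start[i], scan$end[i])
    tab <- cpp_detect_tandem(seg, as.integer(min_period),
                             as.integer(max_period), min_copies,
                             min_identity, as.integer(min_len))
    if (nrow(tab) == 0L) next
    tab$chrom <- chrom
    tab$gstart <- scan$start[i] + tab$start      # lift to chromosome coords
    tab$gend <- scan$start[i] + tab$end - 1L
    out[[length(out) + 1L]] <- tab
  }
  if (length(out) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(period = integer(), copy_number = numeric(),
                           consensus = character(),
                           mean_adjacent_identity = numeric())
    return(gr)
  }
  tab <- do.call(rbind, out)
  gr <- GRanges(tab$chrom, IRanges(tab$gstart, tab$gend))
  mcols(gr) <- DataFrame(period = tab$period, copy_number = tab$copy_number,
                         consensus = tab$consensus,
                         mean_adjacent_identity = tab$mean_adjacent_identity)
  gr
}

#' Collect the centromeric tandem repeat (CTR) catalog
#'
#' Keeps arrays with at least 50% overlap with a centromere and summarises
#' their total length and the fraction of centromeric sequence they occupy.
#'
#' @param arrays GRanges from [detectTandemRepeats()].
#' @param centromeres GRanges of centromere intervals.
#' @param genome Optional genome; when given, each array's sequence is
#'   attached (needed by [traceOrigin()]).
#' @return A list: `arrays` (filtered GRanges, with `seq` metadata when the
#'   genome is given), `total_bp`, `fraction` (of total centromere length).
#' @export
collectCTRs <- function(arrays, centromeres, genome = NULL) {
  keep <- if (length(arrays)) .is_centromeric(arrays, centromeres)
          else logical()
  ctr <- arrays[keep]
  if (!is.null(genome) && length(ctr)) {
    g <- .genome_chars(genome)
    mcols(ctr)$seq <- vapply(seq_along(ctr), function(i)
      substr(g[[as.character(seqnames(ctr)[i])]], start(ctr)[i],
             end(ctr)[i]), "")
  }
  total <- sum(width(ctr))
  cen_total <- sum(width(reduce(centromeres, ignore.strand = TRUE)))
  list(arrays = ctr, total_bp = total,
       fraction = if (cen_total > 0) total / cen_total else NA_real_)
}

#' Trace centromeric tandem repeats back to LTR representatives
#'
#' Each representative LTR sequence is locally aligned against every CTR
#' array separately (alignments never span two arrays); hit target
#' coordinates are lifted into a concatenated CTR coordinate space. Per
#' representative, [binScores()] with `bin_width` (default 10 bp) profiles
#' the hits along the representative, and maximal runs of bins with
#' `S >= threshold` (and `S > 0`) become high-scoring intervals. The default
#' threshold is half the maximum bin score of that representative
#' (full-width-at-half-maximum delimitation), which adapts to how strongly
#' the homologous segment amplified without assuming most bins are empty.
#'
#' @param representatives Named sequences (cluster representatives).
#' @param ctr_catalog Catalog from [collectCTRs()] with array sequences
#'   attached.
#' @param bin_width Trace bin width (default 10).
#' @param interval_score_threshold Fixed threshold overriding the adaptive
#'   default.
#' @param min_len,min_identity Alignment thresholds (defaults 20 and 0.7).
#' @return A list: `tracks` (per-representative
#'   [BinnedScoreTrack-class]), `intervals` (data.frame `query_id`, `start`,
#'   `end`, `n_bins`, `mean_score`, `covered_ctr_bp`), `hits` (per-rep hit
#'   tables in concatenated CTR space), `alignment_total_bp` (distinct CTR
#'   bases covered by any hit), `ctr_len` (total concatenated length).
#' @export
traceOrigin <- function(representatives, ctr_catalog, bin_width = 10L,
                        interval_score_threshold = NULL, min_len = 20L,
                        min_identity = 0.7) {
  reps <- .genome_chars(representatives)
  if (length(reps) == 0L) stop("no representative sequences given")
  arr <- ctr_catalog$arrays
  empty <- list(tracks = list(), intervals = data.frame(
    query_id = character(), start = integer(), end = integer(),
    n_bins = integer(), mean_score = numeric(), covered_ctr_bp = integer(),
    stringsAsFactors = FALSE), hits = list(), alignment_total_bp = 0L,
    ctr_len = 0L)
  if (length(arr) == 0L) return(empty)
  if (is.null(mcols(arr)$seq))
    stop("ctr_catalog lacks array sequences; call collectCTRs with a genome")
  aseqs <- stats::setNames(as.character(mcols(arr)$seq),
                           paste0("ctr_", seq_along(arr)))
  offsets <- cumsum(c(0L, head(nchar(aseqs), -1L)))
  names(offsets) <- names(aseqs)
  tracks <- list(); hits_out <- list(); intervals <- list()
  all_cov <- IRanges()
  for (rid in names(reps)) {
    hits <- localAlign(reps[[rid]], aseqs, min_len = min_len,
                       min_identity = min_identity, query_id = rid)
    if (nrow(hits)) {
      hits$ctr_start <- hits$start + offsets[hits$chrom]
      hits$ctr_end <- hits$end + offsets[hits$chrom]
      all_cov <- c(all_cov, IRanges(hits$ctr_start, hits$ctr_end))
    }
    track <- binScores(nchar(reps[[rid]]), hits, bin_width, query_id = rid)
    tracks[[rid]] <- track
    hits_out[[rid]] <- hits
    S <- track@S
    thr <- if (!is.null(interval_score_threshold)) interval_score_threshold
           else max(S) / 2
    if (is.na(thr) || thr <= 0) thr <- Inf
    pass <- S >= thr & S > 0
    if (!any(pass)) next
    r <- rle(pass)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      b0 <- starts[k]; b1 <- ends[k]
      istart <- (b0 - 1L) * bin_width + 1L
      iend <- min(b1 * bin_width, nchar(reps[[rid]]))
      cov_bp <- 0L
      if (nrow(hits)) {
        inside <- hits$query_start <= iend & hits$query_end >= istart
        if (any(inside))
          cov_bp <- sum(width(reduce(IRanges(hits$ctr_start[inside],
                                             hits$ctr_end[inside]))))
      }
      intervals[[length(intervals) + 1L]] <- data.frame(
        query_id = rid, start = istart, end = iend, n_bins = b1 - b0 + 1L,
        mean_score = mean(S[b0:b1]), covered_ctr_bp = cov_bp,
        stringsAsFactors = FALSE)
    }
  }
  intervals <- if (length(intervals)) do.call(rbind, intervals)
               else empty$intervals
  list(tracks = tracks, intervals = intervals, hits = hits_out,
       alignment_total_bp = sum(width(reduce(all_cov))),
       ctr_len = sum(nchar(aseqs)))
}

#' Coverage statistics of high-scoring intervals over aligned CTR sequence
#'
#' `covered_bp` counts the distinct CTR bases under hits whose query
#' position falls inside a high-scoring interval; the percentage is taken of
#' the total aligned CTR bases and reported rounded half-up to two decimals.
#'
#' @param x Either the result of [traceOrigin()], or a numeric `covered_bp`.
#' @param alignment_total_bp Total distinct aligned CTR bases (required when
#'   `x` is numeric).
#' @return A list: `covered_bp`, `alignment_total_bp`, `percent` (`NA` with
#'   `undefined = TRUE` when nothing aligned).
#' @export
coverageStats <- function(x, alignment_total_bp = NULL) {
  if (is.numeric(x)) {
    covered <- x
    total <- alignment_total_bp
    stopifnot(!is.null(total))
  } else {
    total <- x$alignment_total_bp
    cov <- IRanges()
    for (rid in names(x$hits)) {
      hits <- x$hits[[rid]]
      iv <- x$intervals[x$intervals$query_id == rid, , drop = FALSE]
      if (is.null(hits) || nrow(hits) == 0L || nrow(iv) == 0L) next
      for (k in seq_len(nrow(iv))) {
        inside <- hits$query_start <= iv$end[k] & hits$query_end >= iv$start[k]
        if (any(inside))
          cov <- c(cov, IRanges(hits$ctr_start[inside], hits$ctr_end[inside]))
      }
    }
    covered <- sum(width(reduce(cov)))
  }
  if (is.null(total) || total == 0) {
    return(list(covered_bp = 0L, alignment_total_bp = 0L, percent = NA_real_,
                undefined = TRUE))
  }
  if (covered > total) stop("covered_bp exceeds alignment_total_bp")
  list(covered_bp = covered, alignment_total_bp = total,
       percent = .round_half_up(100 * covered / total, 2), undefined = FALSE)
}

#' Sequence similarity between two high-scoring interval consensus sequences
#'
#' Identity (matches / alignment columns) of the best alignment placing the
#' shorter interval entirely within the longer one (global in the shorter
#' sequence, local in the longer). Two homologous intervals of different
#' length therefore compare over their shared region, while unrelated
#' sequences are averaged over a full-width alignment rather than one lucky
#' short word.
#'
#' @param a,b Interval sequences (character or `DNAString`).
#' @return Fraction in \[0, 1\].
#' @export
intervalSimilarity <- function(a, b) {
  a <- .seq_chars(a); b <- .seq_chars(b)
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty interval sequence")
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  submat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- pairwiseAlignment(DNAString(a), DNAString(b),
                           type = "global-local",
                           substitutionMatrix = submat, gapOpening = 4,
                           gapExtension = 1)
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  if (cols == 0L) return(0)
  nmatch(aln) / cols
}
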