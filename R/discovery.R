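# CR discovery workflow: family census, candidate selection with containment
# resolution, CR calling against intact elements, occupancy mapping, probe
# design and probe copy counting.

# A feature is "centromeric" when at least half of its length lies inside a
# centromere; one rule shared by the census, CRI and occupancy accounting.
.is_centromeric <- function(gr, centromeres) {
  .overlap_fraction(gr, centromeres) >= 0.5
}

#' Census of repeat families inside and outside centromeres
#'
#' A copy counts as centromeric when at least 50% of its length lies inside
#' a centromere interval.
#'
#' @param annotations GRanges of repeat copies with `mcols()$family_id`.
#' @param centromeres GRanges of centromere intervals.
#' @param consensus_seqs Optional named sequences used to record each
#'   family's consensus length.
#' @return A data.frame with `family_id`, `centromeric_count`,
#'   `genome_count`, `consensus_len`, sorted by decreasing centromeric count.
#' @export
censusFamilies <- function(annotations, centromeres, consensus_seqs = NULL) {
  if (length(annotations) == 0L)
    return(data.frame(family_id = character(), centromeric_count = integer(),
                      genome_count = integer(), consensus_len = integer(),
                      stringsAsFactors = FALSE))
  fam <- as.character(mcols(annotations)$family_id)
  if (is.null(fam)) stop("annotations need a family_id metadata column")
  cen <- .is_centromeric(annotations, centromeres)
  ids <- sort(unique(fam))
  tab <- data.frame(
    family_id = ids,
    centromeric_count = vapply(ids, function(f) sum(cen[fam == f]), 1L),
    genome_count = vapply(ids, function(f) sum(fam == f), 1L),
    stringsAsFactors = FALSE)
  tab$consensus_len <- if (is.null(consensus_seqs)) NA_integer_ else {
    cs <- .genome_chars(consensus_seqs)
    ifelse(tab$family_id %in% names(cs),
           nchar(cs)[match(tab$family_id, names(cs))], NA_integer_)
  }
  tab <- tab[order(-tab$centromeric_count, tab$family_id), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Select candidate centromeric repeat families
#'
#' Families whose centromeric copy count exceeds `min_count` are kept; when
#' one kept family's consensus aligns over at least 90% of its length at 90%
#' identity within another kept family's consensus, the contained family is
#' dropped and the container retained.
#'
#' @param census Census table from [censusFamilies()].
#' @param consensus_seqs Named character vector or `DNAStringSet` of family
#'   consensus sequences (must cover every kept family).
#' @param min_count Census cutoff (strictly exceeded; default 100).
#' @return Character vector of retained family ids (census order).
#' @export
selectCandidates <- function(census, consensus_seqs, min_count = 100L) {
  stopifnot(min_count >= 1L)
  kept <- census$family_id[census$centromeric_count > min_count]
  if (length(kept) == 0L) return(character())
  cs <- .genome_chars(consensus_seqs)
  missing <- setdiff(kept, names(cs))
  if (length(missing))
    .stopf("no consensus sequence for kept family: %s",
           paste(missing, collapse = ", "))
  lens <- nchar(cs[kept])
  ord <- kept[order(-lens, kept)] # longest first; containers checked first
  dropped <- character()
  for (i in seq_along(ord)) {
    for (j in seq_len(i - 1L)) {
      if (ord[j] %in% dropped) next
      res <- .local_identity(cs[[ord[i]]], cs[[ord[j]]])
      if (res$coverage >= 0.9 && res$identity >= 0.9) {
        dropped <- c(dropped, ord[i])
        break
      }
    }
  }
  setdiff(kept, dropped)
}

# Extract the genomic sequence of one element row (forward strand).
.element_seq <- function(el, genome_chars) {
  substr(genome_chars[[el$chrom]], el$start, el$end)
}

.element_part_seq <- function(el, genome_chars, part) {
  s <- el[[paste0(part, "_start")]]
  e <- el[[paste0(part, "_end")]]
  substr(genome_chars[[el$chrom]], s, e)
}

#' Call CR elements against a candidate repeat
#'
#' An intact element is a CR when local-alignment hits of the candidate
#' against the element sequence cover at least `min_cov` of the shorter of
#' the two sequences at identity `min_identity` or better. The
#' representative CR is the one whose span length is closest to the
#' candidate length (ties to the smaller `element_id`).
#'
#' @param candidate Candidate repeat sequence (character or `DNAString`).
#' @param elements Intact element table (see [readLtrElements()]).
#' @param genome Genome sequences.
#' @param min_cov Minimum covered fraction of the shorter sequence (default
#'   0.5).
#' @param min_identity Minimum hit identity (default 0.8).
#' @param align_min_len Minimum per-hit alignment length (default 50).
#' @return A list with `cr_ids` (character) and `representative_id`
#'   (`""` when no CR is found).
#' @export
callCRs <- function(candidate, elements, genome, min_cov = 0.5,
                    min_identity = 0.8, align_min_len = 50L) {
  stopifnot(min_cov > 0, min_cov <= 1)
  candidate <- .seq_chars(candidate)
  g <- .genome_chars(genome)
  cand_len <- nchar(candidate)
  is_cr <- vapply(seq_len(nrow(elements)), function(i) {
    el <- elements[i, ]
    eseq <- .element_seq(el, g)
    hits <- localAlign(candidate, stats::setNames(eseq, "element"),
                       min_len = align_min_len, min_identity = min_identity)
    if (nrow(hits) == 0L) return(FALSE)
    shorter <- min(cand_len, nchar(eseq))
    covered <- if (cand_len <= nchar(eseq)) {
      sum(width(reduce(IRanges(hits$query_start, hits$query_end))))
    } else {
      sum(width(reduce(IRanges(hits$start, hits$end))))
    }
    covered / shorter >= min_cov
  }, logical(1))
  cr_ids <- elements$element_id[is_cr]
  if (length(cr_ids) == 0L) {
    .msg("callCRs: no element passed the coverage/identity thresholds")
    return(list(cr_ids = character(), representative_id = ""))
  }
  spans <- (elements$end - elements$start + 1L)[is_cr]
  d <- abs(spans - cand_len)
  best <- cr_ids[order(d, cr_ids)][1]
  list(cr_ids = cr_ids, representative_id = best)
}

#' Genome-wide occupancy of an element and its parts
#'
#' Aligns the full element sequence genome-wide and splits hits by the
#' shared 50% centromere-overlap rule; additionally aligns the 5' LTR,
#' internal region and 3' LTR separately and returns their
#' [BinnedScoreTrack-class] profiles for comparison (the hallmark of a CR is
#' higher LTR than internal occupancy).
#'
#' @param element One-row element table entry.
#' @param genome Genome sequences.
#' @param centromeres GRanges of centromere intervals.
#' @param min_len,min_identity Alignment thresholds.
#' @param bin_width Score bin width (default 100).
#' @return A list: `cen_hits`, `noncen_hits`, `hits` (full-element hit
#'   table), and `part_tracks` (named list of `BinnedScoreTrack` for ltr5,
#'   internal, ltr3).
#' @export
elementOccupancy <- function(element, genome, centromeres, min_len = 100L,
                             min_identity = 0.8, bin_width = 100L) {
  stopifnot(nrow(element) == 1L)
  g <- .genome_chars(genome)
  full <- .element_seq(element[1, ], g)
  if (nchar(full) == 0L) stop("element sequence is empty: contract violation")
  hits <- localAlign(full, g, min_len = min_len,
                     min_identity = min_identity,
                     query_id = element$element_id[1])
  cen <- if (nrow(hits)) .is_centromeric(hitsAsGRanges(hits), centromeres)
         else logical()
  part_tracks <- list()
  for (part in c("ltr5", "internal", "ltr3")) {
    pseq <- .element_part_seq(element[1, ], g, part)
    if (nchar(pseq) == 0L)
      stop("element part '", part, "' is empty: contract violation")
    phits <- localAlign(pseq, g, min_len = min(min_len, nchar(pseq)),
                        min_identity = min_identity, query_id = part)
    part_tracks[[part]] <- binScores(nchar(pseq), phits, bin_width,
                                     query_id = part)
  }
  list(cen_hits = sum(cen), noncen_hits = sum(!cen), hits = hits,
       part_tracks = part_tracks)
}

#' Count gapless full-length probe copies
#'
#' A copy is a gapless full-length match of the probe on either strand with
#' at most `floor(mismatch_frac * length)` mismatches; overlapping matches
#' are collapsed to the best-scoring start. The per-chromosome cumulative
#' length is `copies * probe length`.
#'
#' @param probe Probe sequence (character or `DNAString`).
#' @param genome Genome sequences.
#' @param centromeres Optional GRanges; when given, each chromosome row also
#'   reports centromeric/non-centromeric copy counts (50% overlap rule).
#' @param mismatch_frac Mismatch tolerance as a fraction of probe length
#'   (default 0.03).
#' @return A data.frame with one row per chromosome: `chrom`, `copies`,
#'   `cumulative_len`, and (with centromeres) `cen_copies`,
#'   `noncen_copies`. An attribute `"matches"` carries the individual match
#'   table.
#' @export
countProbeCopies <- function(probe, genome, centromeres = NULL,
                             mismatch_frac = 0.03) {
  probe <- .seq_chars(probe)
  if (nchar(probe) == 0L) stop("probe must be non-empty")
  if (mismatch_frac < 0 || mismatch_frac > 0.1)
    stop("mismatch_frac must lie in [0, 0.1]")
  g <- .genome_chars(genome)
  m <- cpp_count_gapless(probe, unname(g), mismatch_frac, 13L)[[1]]
  plen <- nchar(probe)
  matches <- data.frame(chrom = names(g)[m$chrom_idx],
                        start = m$start + 1L,
                        end = m$start + plen,
                        strand = m$strand, mismatches = m$mismatches,
                        stringsAsFactors = FALSE)
  out <- data.frame(chrom = names(g),
                    copies = vapply(names(g), function(ch)
                      sum(matches$chrom == ch), 1L),
                    stringsAsFactors = FALSE)
  out$cumulative_len <- out$copies * plen
  if (!is.null(centromeres)) {
    cen <- if (nrow(matches))
      .is_centromeric(GRanges(matches$chrom,
                              IRanges(matches$start, matches$end)),
                      centromeres)
    else logical()
    out$cen_copies <- vapply(names(g), function(ch)
      sum(cen[matches$chrom == ch]), 1L)
    out$noncen_copies <- out$copies - out$cen_copies
    matches$centromeric <- cen
  }
  rownames(out) <- NULL
  attr(out, "matches") <- matches
  out
}

#' Design a centromere-specific FISH probe from a CR's LTRs
#'
#' Scans every `probe_len` window of the element's 5' and 3' LTRs and picks
#' the window maximising (centromeric copies - non-centromeric copies) under
#' the gapless counting rule of [countProbeCopies()]; ties go to the
#' leftmost 5' LTR window.
#'
#' @param cr One-row element table entry (the representative CR).
#' @param genome Genome sequences.
#' @param centromeres GRanges of centromere intervals.
#' @param probe_len Probe length (default 376).
#' @param mismatch_frac Mismatch tolerance (default 0.03).
#' @param step Window stride in bp (default 1 scans every window).
#' @return A list (`probe_spec`): `sequence`, `length`, `mismatch_frac`,
#'   `source` (chrom/start/end/part of the chosen window), `cen_copies`,
#'   `noncen_copies`, `score`.
#' @export
designProbe <- function(cr, genome, centromeres, probe_len = 376L,
                        mismatch_frac = 0.03, step = 1L) {
  stopifnot(nrow(cr) == 1L, step >= 1L)
  g <- .genome_chars(genome)
  windows <- list()
  for (part in c("ltr5", "ltr3")) {
    s0 <- cr[[paste0(part, "_start")]][1]
    e0 <- cr[[paste0(part, "_end")]][1]
    if (e0 - s0 + 1L < probe_len) next
    offs <- seq.int(0L, e0 - s0 + 1L - probe_len, by = step)
    for (o in offs)
      windows[[length(windows) + 1L]] <- list(
        part = part, start = s0 + o, end = s0 + o + probe_len - 1L,
        seq = substr(g[[cr$chrom[1]]], s0 + o, s0 + o + probe_len - 1L))
  }
  if (length(windows) == 0L)
    .stopf("both LTRs are shorter than probe_len = %d", probe_len)
  counts <- cpp_count_gapless(vapply(windows, `[[`, "", "seq"), unname(g),
                              mismatch_frac, 13L)
  score <- vapply(seq_along(windows), function(i) {
    m <- counts[[i]]
    if (nrow(m) == 0L) return(0L)
    gr <- GRanges(names(g)[m$chrom_idx],
                  IRanges(m$start + 1L, m$start + probe_len))
    cen <- .is_centromeric(gr, centromeres)
    sum(cen) - sum(!cen)
  }, 1L)
  best <- which.max(score) # first max: leftmost ltr5 window wins ties
  w <- windows[[best]]
  m <- counts[[best]]
  gr <- GRanges(names(g)[m$chrom_idx], IRanges(m$start + 1L, m$start + probe_len))
  cen <- .is_centromeric(gr, centromeres)
  list(sequence = w$seq, length = probe_len, mismatch_frac = mismatch_frac,
       source = list(chrom = cr$chrom[1], start = w$start, end = w$end,
                     part = w$part),
       cen_copies = sum(cen), noncen_copies = sum(!cen),
       score = score[best])
}

#' Per-chromosome probe report
#'
#' Convenience wrapper mirroring the probe columns of a centromere summary
#' table: copy number of the probe and its cumulative length per chromosome.
#'
#' @param probe_spec Result of [designProbe()] (or any list with `sequence`
#'   and `mismatch_frac`).
#' @param genome Genome sequences.
#' @param centromeres Optional centromere GRanges.
#' @return The [countProbeCopies()] table.
#' @export
probeReport <- function(probe_spec, genome, centromeres = NULL) {
  countProbeCopies(probe_spec$sequence, genome, centromeres,
                   probe_spec$mismatch_frac)
}
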