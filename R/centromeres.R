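# ChIP/Input enrichment, centromere interval calling, and meta-profiles.

#' ChIP/Input ratio track
#'
#' Per-bin enrichment ratio `(chip + pseudocount) / (input + pseudocount)`,
#' reported on the linear scale. The pseudocount keeps coverage deserts
#' finite and neutral (0/0 maps to 1).
#'
#' @param chip,input [SignalTrack-class] objects on the same chromosomes with
#'   the same bin width.
#' @param pseudocount Added to both numerator and denominator (default 1).
#' @return A [SignalTrack-class] of ratios.
#' @export
ratioTrack <- function(chip, input, pseudocount = 1) {
  stopifnot(is(chip, "SignalTrack"), is(input, "SignalTrack"))
  if (binWidth(chip) != binWidth(input))
    stop("chip and input tracks have mismatched bin widths")
  if (!setequal(trackChroms(chip), trackChroms(input)))
    stop("chip and input tracks cover different chromosomes")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  vals <- lapply(stats::setNames(trackChroms(chip), trackChroms(chip)),
    function(chrom) {
      a <- trackValues(chip)[[chrom]]
      b <- trackValues(input)[[chrom]]
      if (length(a) != length(b))
        .stopf("bin count mismatch on %s (%d vs %d)", chrom, length(a),
               length(b))
      (a + pseudocount) / (b + pseudocount)
    })
  SignalTrack(vals, binWidth(chip))
}

#' Call centromere intervals from an enrichment ratio track
#'
#' Bins with ratio at or above `threshold` are marked; marked runs shorter
#' than `min_run` bins are discarded (guarding against isolated count-noise
#' outliers); surviving runs separated by at most `merge_gap` bp are merged;
#' merged intervals shorter than `min_len` bp are dropped; boundary bins
#' below the threshold are trimmed. All surviving intervals are reported and
#' the top-mean interval per chromosome is flagged primary.
#'
#' @param ratio A [SignalTrack-class] of ChIP/Input ratios.
#' @param threshold Ratio call threshold (> 1; default 2).
#' @param merge_gap Maximum gap merged between marked runs (bp).
#' @param min_len Minimum reported interval length (bp).
#' @param min_run Minimum initial run length in bins (default 3).
#' @return A GRanges of centromere calls with metadata `mean_ratio`,
#'   `n_bins`, `primary`.
#' @export
callCentromeres <- function(ratio, threshold = 2, merge_gap = 5e4,
                            min_len = 1e5, min_run = 3L) {
  stopifnot(is(ratio, "SignalTrack"))
  if (threshold <= 1) stop("threshold must exceed 1")
  bw <- binWidth(ratio)
  gap_bins <- as.integer(floor(merge_gap / bw))
  out <- list()
  for (chrom in trackChroms(ratio)) {
    v <- trackValues(ratio)[[chrom]]
    if (length(v) == 0L) next
    marked <- v >= threshold
    # drop isolated short runs before merging
    r <- rle(marked)
    r$values[r$values & r$lengths < min_run] <- FALSE
    marked <- inverse.rle(r)
    if (!any(marked)) next
    # merge across short gaps flanked by marked runs
    r <- rle(marked)
    n <- length(r$values)
    fill <- !r$values & r$lengths <= gap_bins &
      seq_len(n) > 1L & seq_len(n) < n
    r$values[fill] <- TRUE
    marked <- inverse.rle(r)
    r <- rle(marked)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      b0 <- starts[k]; b1 <- ends[k]
      while (b0 <= b1 && v[b0] < threshold) b0 <- b0 + 1L
      while (b1 >= b0 && v[b1] < threshold) b1 <- b1 - 1L
      if (b0 > b1) next
      len_bp <- (b1 - b0 + 1L) * bw
      if (len_bp < min_len) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = (b0 - 1L) * bw + 1L, end = b1 * bw,
        mean_ratio = mean(v[b0:b1]), n_bins = b1 - b0 + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(mean_ratio = numeric(), n_bins = integer(),
                           primary = logical())
    return(gr)
  }
  tab <- do.call(rbind, out)
  primary <- logical(nrow(tab))
  for (chrom in unique(tab$chrom)) {
    idx <- which(tab$chrom == chrom)
    primary[idx[which.max(tab$mean_ratio[idx])]] <- TRUE
  }
  gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
  mcols(gr) <- DataFrame(mean_ratio = tab$mean_ratio, n_bins = tab$n_bins,
                         primary = primary)
  gr
}

# Sample the track bins covering [anchor - flank, anchor + flank) for one
# anchor position; returns NULL when the window leaves the track.
.profile_window <- function(v, anchor, flank, bw) {
  nb <- 2L * flank %/% bw
  pos <- anchor - flank + (seq_len(nb) - 1L) * bw
  bins <- (pos - 1L) %/% bw + 1L
  if (bins[1] < 1L || bins[nb] > length(v)) return(NULL)
  v[bins]
}

#' Meta-profile of signal around element boundaries
#'
#' For each element the signal is sampled in `bin`-bp steps across
#' `[anchor - flank, anchor + flank)` at both anchors (element start and
#' element end). Minus-strand elements are flipped: their transcription-
#' proximal start is the genomic end and their sampled windows are reversed.
#' Elements whose window leaves the track are skipped and counted.
#'
#' @param elements GRanges of elements (strand-aware).
#' @param signal A [SignalTrack-class]; its bin width must equal `bin`.
#' @param flank Flank size in bp (multiple of `bin`).
#' @param bin Sampling bin in bp (defaults to the signal bin width).
#' @return A list with [MetaProfile-class] entries `starts` and `ends`.
#' @export
metaProfile <- function(elements, signal, flank = 1000L,
                        bin = binWidth(signal)) {
  stopifnot(is(signal, "SignalTrack"), length(elements) >= 1L)
  bin <- as.integer(bin); flank <- as.integer(flank)
  if (bin != binWidth(signal))
    stop("sampling bin must equal the signal track bin width")
  if (flank %% bin != 0L) stop("flank must be a multiple of bin")
  nb <- 2L * flank %/% bin
  acc <- list(starts = numeric(nb), ends = numeric(nb))
  n_used <- c(starts = 0L, ends = 0L)
  n_skip <- c(starts = 0L, ends = 0L)
  vals <- trackValues(signal)
  for (i in seq_along(elements)) {
    chrom <- as.character(seqnames(elements)[i])
    v <- vals[[chrom]]
    if (is.null(v)) { n_skip <- n_skip + 1L; next }
    minus <- as.character(strand(elements)[i]) == "-"
    a_start <- if (minus) end(elements)[i] else start(elements)[i]
    a_end <- if (minus) start(elements)[i] else end(elements)[i]
    w_start <- .profile_window(v, a_start, flank, bin)
    w_end <- .profile_window(v, a_end, flank, bin)
    if (minus) { w_start <- rev(w_start); w_end <- rev(w_end) }
    if (is.null(w_start)) n_skip["starts"] <- n_skip["starts"] + 1L
    else { acc$starts <- acc$starts + w_start; n_used["starts"] <- n_used["starts"] + 1L }
    if (is.null(w_end)) n_skip["ends"] <- n_skip["ends"] + 1L
    else { acc$ends <- acc$ends + w_end; n_used["ends"] <- n_used["ends"] + 1L }
  }
  if (any(n_used == 0L))
    stop("no element window fits inside the signal track")
  .msg(sprintf("meta-profile: %d/%d start, %d/%d end windows skipped",
               n_skip["starts"], length(elements), n_skip["ends"],
               length(elements)))
  list(starts = new("MetaProfile", anchor = "element_start", flank = flank,
                    bin = bin, mean_signal = acc$starts / n_used["starts"],
                    n_elements = n_used[["starts"]],
                    n_skipped = n_skip[["starts"]]),
       ends = new("MetaProfile", anchor = "element_end", flank = flank,
                  bin = bin, mean_signal = acc$ends / n_used["ends"],
                  n_elements = n_used[["ends"]],
                  n_skipped = n_skip[["ends"]]))
}
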