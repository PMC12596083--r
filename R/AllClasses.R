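# S4 containers for the pipeline's central value types. Interval data live in
# GRanges and sequences in DNAStringSet; only the types with arithmetic
# invariants worth guarding get their own class.

#' SignalTrack: per-chromosome binned signal values
#'
#' Holds one non-negative value per fixed-width genomic bin for one or more
#' chromosomes, e.g. binned ChIP or Input read counts, or their ratio. The
#' last bin of a chromosome may cover fewer than `bin_width` bases.
#'
#' @slot bin_width Integer bin width in bp.
#' @slot values Named list, one numeric vector of per-bin values per
#'   chromosome.
#' @export
setClass("SignalTrack",
  slots = c(bin_width = "integer", values = "list"))

setValidity("SignalTrack", function(object) {
  msg <- character()
  if (length(object@bin_width) != 1L || is.na(object@bin_width) ||
      object@bin_width < 1L)
    msg <- c(msg, "bin_width must be a single positive integer")
  if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
    msg <- c(msg, "values must be a uniquely named list")
  for (v in object@values) {
    if (!is.numeric(v)) { msg <- c(msg, "values must be numeric"); break }
    if (any(!is.finite(v)) || any(v < 0)) {
      msg <- c(msg, "bin values must be finite and non-negative"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SignalTrack
#'
#' @param values Named list of numeric per-bin vectors (one per chromosome),
#'   or a single numeric vector together with `chrom`.
#' @param bin_width Bin width in bp.
#' @param chrom Chromosome name when `values` is a bare vector.
#' @return A [SignalTrack-class] object.
#' @examples
#' SignalTrack(list(chr1 = c(1, 2, 0.5)), bin_width = 1000)
#' @export
SignalTrack <- function(values, bin_width, chrom = NULL) {
  if (is.numeric(values)) {
    stopifnot(!is.null(chrom))
    values <- stats::setNames(list(as.numeric(values)), chrom)
  }
  new("SignalTrack", bin_width = as.integer(bin_width),
      values = lapply(values, as.numeric))
}

#' BinnedScoreTrack: S = L x N occupancy scores over a query sequence
#'
#' The query is partitioned into consecutive bins (the last may be partial).
#' For each bin, `L` is the number of query positions covered by the union of
#' alignment-hit query intervals (bounded by the bin width), `N` the number of
#' hits intersecting the bin, and `S = L * N` the binned alignment score.
#'
#' @slot query_id Identifier of the query sequence.
#' @slot query_len Query length in bp.
#' @slot bin_width Bin width in bp.
#' @slot L Integer vector of covered bases per bin.
#' @slot N Integer vector of intersecting hit counts per bin.
#' @slot S Integer vector of scores, `S == L * N`.
#' @export
setClass("BinnedScoreTrack",
  slots = c(query_id = "character", query_len = "integer",
            bin_width = "integer", L = "integer", N = "integer",
            S = "integer"))

setValidity("BinnedScoreTrack", function(object) {
  msg <- character()
  n <- length(object@L)
  if (length(object@N) != n || length(object@S) != n)
    msg <- c(msg, "L, N and S must have equal length")
  if (n > 0) {
    if (any(object@L < 0L) || any(object@L > object@bin_width))
      msg <- c(msg, "L must lie in [0, bin_width]")
    if (any(object@N < 0L)) msg <- c(msg, "N must be non-negative")
    if (!identical(object@S, object@L * object@N))
      msg <- c(msg, "S must equal L * N in every bin")
  }
  if (n != ceiling(object@query_len / object@bin_width))
    msg <- c(msg, "number of bins must equal ceiling(query_len / bin_width)")
  if (length(msg)) msg else TRUE
})

#' MetaProfile: mean signal around element anchors
#'
#' Mean binned signal across a set of elements in a window of `+/- flank` bp
#' around one anchor (element start or element end), strand-aware (minus-strand
#' elements are flipped before averaging).
#'
#' @slot anchor Either `"element_start"` or `"element_end"`.
#' @slot flank Flank size in bp on each side of the anchor.
#' @slot bin Bin width in bp.
#' @slot mean_signal Numeric vector of length `2 * flank / bin`.
#' @slot n_elements Number of elements averaged.
#' @slot n_skipped Number of elements skipped because the window ran off the
#'   chromosome (or off the track).
#' @export
setClass("MetaProfile",
  slots = c(anchor = "character", flank = "integer", bin = "integer",
            mean_signal = "numeric", n_elements = "integer",
            n_skipped = "integer"))

setValidity("MetaProfile", function(object) {
  msg <- character()
  if (!object@anchor %in% c("element_start", "element_end"))
    msg <- c(msg, "anchor must be 'element_start' or 'element_end'")
  if (object@flank %% object@bin != 0L)
    msg <- c(msg, "flank must be a multiple of bin")
  if (length(object@mean_signal) != 2L * object@flank %/% object@bin)
    msg <- c(msg, "mean_signal must have 2 * flank / bin entries")
  if (object@n_elements < 1L)
    msg <- c(msg, "profile requires at least one element")
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: CRI/CLTRI for one element
#'
#' The centromeric retrotransposon enrichment index of a query element is the
#' ratio of identity-weighted aligned length inside centromeres to that
#' outside: `CRI = sum(L_i * I_i | cen) / sum(L_j * I_j | non-cen)`. A zero
#' denominator with positive numerator is flagged `"infinite"`; no hits at all
#' is flagged `"undefined"`.
#'
#' @slot element_id Query element identifier.
#' @slot cen_mass Sum of `L * I` over centromeric hits.
#' @slot noncen_mass Sum of `L * I` over non-centromeric hits.
#' @slot n_cen_hits Number of centromeric hits.
#' @slot n_noncen_hits Number of non-centromeric hits.
#' @slot cri The index value; `Inf` when flagged infinite, `NaN` when
#'   undefined.
#' @slot status One of `"finite"`, `"infinite"`, `"undefined"`.
#' @export
setClass("EnrichmentResult",
  slots = c(element_id = "character", cen_mass = "numeric",
            noncen_mass = "numeric", n_cen_hits = "integer",
            n_noncen_hits = "integer", cri = "numeric", status = "character"))

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (object@cen_mass < 0 || object@noncen_mass < 0)
    msg <- c(msg, "masses must be non-negative")
  if (!object@status %in% c("finite", "infinite", "undefined"))
    msg <- c(msg, "status must be finite, infinite or undefined")
  if (object@status == "finite" && object@noncen_mass > 0 &&
      abs(object@cri - object@cen_mass / object@noncen_mass) > 1e-9)
    msg <- c(msg, "cri must equal cen_mass / noncen_mass")
  if (length(msg)) msg else TRUE
})

# ---- generics and accessors -----------------------------------------------

#' @describeIn SignalTrack-class bin width accessor
#' @param x An object with binned values.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @export
setMethod("binWidth", "SignalTrack", function(x) x@bin_width)

#' @export
setMethod("binWidth", "BinnedScoreTrack", function(x) x@bin_width)

#' @describeIn SignalTrack-class named list of per-chromosome bin values
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @describeIn SignalTrack-class chromosome names carried by the track
#' @export
setGeneric("trackChroms", function(x) standardGeneric("trackChroms"))

#' @export
setMethod("trackChroms", "SignalTrack", function(x) names(x@values))

#' @describeIn BinnedScoreTrack-class per-bin score table with bin
#'   coordinates (1-based, closed) and the L, N and S columns
#' @param x A `BinnedScoreTrack`.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @export
setMethod("scoreTable", "BinnedScoreTrack", function(x) {
  n <- length(x@S)
  if (n == 0L)
    return(data.frame(bin = integer(), bin_start = integer(),
                      bin_end = integer(), L = integer(), N = integer(),
                      S = integer()))
  bs <- (seq_len(n) - 1L) * x@bin_width + 1L
  data.frame(bin = seq_len(n), bin_start = bs,
             bin_end = pmin(bs + x@bin_width - 1L, x@query_len),
             L = x@L, N = x@N, S = x@S)
})

#' @describeIn EnrichmentResult-class the index value (may be `Inf`/`NaN`)
#' @param x An `EnrichmentResult`.
#' @export
setGeneric("criValue", function(x) standardGeneric("criValue"))

#' @export
setMethod("criValue", "EnrichmentResult", function(x) x@cri)

#' @describeIn EnrichmentResult-class the flag: finite, infinite or undefined
#' @export
setGeneric("criStatus", function(x) standardGeneric("criStatus"))

#' @export
setMethod("criStatus", "EnrichmentResult", function(x) x@status)

#' Tabulate enrichment results
#'
#' @param results A list of [EnrichmentResult-class] objects (or a single
#'   one).
#' @return A data.frame with one row per element.
#' @export
enrichmentTable <- function(results) {
  if (is(results, "EnrichmentResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(element_id = r@element_id, cri = r@cri, status = r@status,
               cen_mass = r@cen_mass, noncen_mass = r@noncen_mass,
               n_cen_hits = r@n_cen_hits, n_noncen_hits = r@n_noncen_hits,
               stringsAsFactors = FALSE)
  }))
}

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack:", length(object@values), "chromosome(s), bin",
      object@bin_width, "bp\n")
  for (nm in names(object@values))
    cat(" ", nm, ":", length(object@values[[nm]]), "bins\n")
})

setMethod("show", "BinnedScoreTrack", function(object) {
  cat("BinnedScoreTrack for", object@query_id, "(", object@query_len,
      "bp ):", length(object@S), "bins of", object@bin_width, "bp; max S =",
      if (length(object@S)) max(object@S) else 0, "\n")
})

setMethod("show", "MetaProfile", function(object) {
  cat("MetaProfile at", object@anchor, ": +/-", object@flank, "bp in",
      object@bin, "bp bins over", object@n_elements, "elements (",
      object@n_skipped, "skipped )\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult", object@element_id, ": CRI =",
      format(object@cri, digits = 4), "(", object@status, ");",
      object@n_cen_hits, "cen /", object@n_noncen_hits, "non-cen hits\n")
})
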