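# The centromeric retrotransposon enrichment index (CRI/CLTRI) and
# centromere-specific element selection.

#' Compute the centromeric retrotransposon enrichment index (CRI)
#'
#' Each genome-wide hit of a query element is classed centromeric when at
#' least 50% of its target interval overlaps a centromere. The index is the
#' ratio of identity-weighted aligned length inside centromeres to that
#' outside:
#' \deqn{CRI = \frac{\sum_{i \in CEN} L_i I_i}{\sum_{j \notin CEN} L_j I_j}}
#' where \eqn{L} is the alignment length (columns) and \eqn{I} the alignment
#' identity of each hit. A zero denominator with a positive numerator is
#' flagged infinite; no hits at all is flagged undefined.
#'
#' @param hits Hit table from [localAlign()] for a single query element
#'   (columns `length` and `identity` are used; identities must lie in
#'   \[0, 1\]).
#' @param centromeres GRanges of centromere intervals.
#' @param element_id Identifier recorded in the result.
#' @return An [EnrichmentResult-class].
#' @export
computeCRI <- function(hits, centromeres, element_id = "query") {
  if (nrow(hits) > 0 &&
      (any(hits$identity < 0) || any(hits$identity > 1)))
    stop("hit identity outside [0, 1]: contract violation")
  if (nrow(hits) == 0L) {
    return(new("EnrichmentResult", element_id = element_id, cen_mass = 0,
               noncen_mass = 0, n_cen_hits = 0L, n_noncen_hits = 0L,
               cri = NaN, status = "undefined"))
  }
  cen <- .is_centromeric(hitsAsGRanges(hits), centromeres)
  mass <- hits$length * hits$identity
  cen_mass <- sum(mass[cen])
  noncen_mass <- sum(mass[!cen])
  if (noncen_mass > 0) {
    new("EnrichmentResult", element_id = element_id, cen_mass = cen_mass,
        noncen_mass = noncen_mass, n_cen_hits = sum(cen),
        n_noncen_hits = sum(!cen), cri = cen_mass / noncen_mass,
        status = "finite")
  } else if (cen_mass > 0) {
    new("EnrichmentResult", element_id = element_id, cen_mass = cen_mass,
        noncen_mass = 0, n_cen_hits = sum(cen), n_noncen_hits = sum(!cen),
        cri = Inf, status = "infinite")
  } else {
    new("EnrichmentResult", element_id = element_id, cen_mass = 0,
        noncen_mass = 0, n_cen_hits = sum(cen), n_noncen_hits = sum(!cen),
        cri = NaN, status = "undefined")
  }
}

#' Compute the centromeric LTR enrichment index (CLTRI)
#'
#' Aligns an element's 5' LTR sequence genome-wide (falling back to the 3'
#' LTR when the 5' interval is missing or empty) and applies the CRI formula
#' to the resulting hits.
#'
#' @param element One-row element table entry.
#' @param genome Genome sequences.
#' @param centromeres GRanges of centromere intervals.
#' @param min_len,min_identity Alignment thresholds for the genome-wide LTR
#'   alignment.
#' @return An [EnrichmentResult-class].
#' @export
computeCLTRI <- function(element, genome, centromeres, min_len = 100L,
                         min_identity = 0.8) {
  stopifnot(nrow(element) == 1L)
  g <- .genome_chars(genome)
  ltr <- ""
  for (part in c("ltr5", "ltr3")) {
    s <- element[[paste0(part, "_start")]][1]
    e <- element[[paste0(part, "_end")]][1]
    if (!is.na(s) && !is.na(e) && e >= s) {
      ltr <- substr(g[[element$chrom[1]]], s, e)
      if (nchar(ltr) > 0L) break
    }
  }
  if (nchar(ltr) == 0L) stop("element has no usable LTR interval")
  hits <- localAlign(ltr, g, min_len = min(min_len, nchar(ltr)),
                     min_identity = min_identity,
                     query_id = element$element_id[1])
  computeCRI(hits, centromeres, element_id = element$element_id[1])
}

#' Select centromere-specific elements (nCRs) by CRI
#'
#' Elements whose index is at least `threshold`, or flagged infinite, are
#' returned ranked: infinite first (ties by element id), then by decreasing
#' finite CRI (ties by element id). Undefined elements never qualify.
#'
#' @param results List of [EnrichmentResult-class] objects (or the
#'   data.frame from [enrichmentTable()]).
#' @param threshold CRI cutoff (> 0; default 2).
#' @return Character vector of element ids, ranked.
#' @export
selectNCRs <- function(results, threshold = 2) {
  stopifnot(threshold > 0)
  tab <- if (is.data.frame(results)) results else enrichmentTable(results)
  if (is.null(tab) || nrow(tab) == 0L) return(character())
  keep <- tab$status == "infinite" |
    (tab$status == "finite" & tab$cri >= threshold)
  tab <- tab[keep, , drop = FALSE]
  if (nrow(tab) == 0L) return(character())
  inf_first <- tab$status != "infinite"
  tab$element_id[order(inf_first, -ifelse(is.finite(tab$cri), tab$cri, 0),
                       tab$element_id)]
}
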