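# Centromeric LTR extraction, insertion-time dating from 5'/3' LTR
# divergence, and greedy identity clustering to representatives.

#' Extract 5' and 3' LTR sequences of intact elements
#'
#' Strand is applied: minus-strand elements are reverse-complemented so the
#' returned 5' LTR is always the transcription-proximal repeat (the genomic
#' right-hand repeat of a minus-strand element).
#'
#' @param elements Element table (see [readLtrElements()]).
#' @param genome Genome sequences.
#' @return A list with two named character vectors, `ltr5` and `ltr3`
#'   (names are element ids).
#' @export
extractLTRs <- function(elements, genome) {
  g <- .genome_chars(genome)
  n <- nrow(elements)
  ltr5 <- character(n); ltr3 <- character(n)
  for (i in seq_len(n)) {
    el <- elements[i, ]
    if (el$ltr3_end > nchar(g[[el$chrom]]) || el$ltr5_start < 1L)
      .stopf("element %s extends beyond chromosome %s", el$element_id,
             el$chrom)
    a <- .element_part_seq(el, g, "ltr5")
    b <- .element_part_seq(el, g, "ltr3")
    if (identical(el$strand, "-")) {
      tmp <- .revcomp(b); b <- .revcomp(a); a <- tmp
    }
    ltr5[i] <- a; ltr3[i] <- b
  }
  list(ltr5 = stats::setNames(ltr5, elements$element_id),
       ltr3 = stats::setNames(ltr3, elements$element_id))
}

#' Date an LTR retrotransposon insertion from its two LTRs
#'
#' The two terminal repeats are identical at insertion and diverge
#' neutrally afterwards. They are globally aligned; the proportion of
#' mismatched columns among gap-free columns gives the p-distance, corrected
#' with the one-parameter substitution model
#' \eqn{K = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}, and the insertion time is
#' \eqn{T = K / (2\mu)} (both repeats accumulate substitutions
#' independently).
#'
#' @param ltr5,ltr3 The two LTR sequences (character or `DNAString`);
#'   intended for repeats of at least ~100 bp.
#' @param mu Neutral substitution rate in substitutions per site per year
#'   (default 1.3e-8).
#' @param element_id Identifier recorded in the result.
#' @return A one-row data.frame: `element_id`, `p_distance`, `k_jc`,
#'   `insertion_time_mya`, `mu`, `saturated`. At `p >= 0.75` the distance is
#'   saturated: `k_jc` and the time are `NA` and `saturated` is `TRUE`.
#' @export
dateInsertion <- function(ltr5, ltr3, mu = 1.3e-8, element_id = "element") {
  stopifnot(mu > 0)
  a <- DNAString(.seq_chars(ltr5)); b <- DNAString(.seq_chars(ltr3))
  if (length(a) == 0L || length(b) == 0L) stop("empty LTR sequence")
  submat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- pairwiseAlignment(a, b, type = "global",
                           substitutionMatrix = submat, gapOpening = 6,
                           gapExtension = 1)
  sa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  keep <- sa != "-" & sb != "-"
  p <- if (any(keep)) mean(sa[keep] != sb[keep]) else 0
  if (p >= 0.75) {
    return(data.frame(element_id = element_id, p_distance = p, k_jc = NA_real_,
                      insertion_time_mya = NA_real_, mu = mu,
                      saturated = TRUE, stringsAsFactors = FALSE))
  }
  k <- -0.75 * log(1 - 4 * p / 3)
  data.frame(element_id = element_id, p_distance = p, k_jc = k,
             insertion_time_mya = k / (2 * mu) / 1e6, mu = mu,
             saturated = FALSE, stringsAsFactors = FALSE)
}

#' Date every element of a table
#'
#' @param elements Element table.
#' @param genome Genome sequences.
#' @param mu Neutral substitution rate (see [dateInsertion()]).
#' @return A data.frame with one dating row per element.
#' @export
dateElements <- function(elements, genome, mu = 1.3e-8) {
  ltrs <- extractLTRs(elements, genome)
  do.call(rbind, lapply(seq_len(nrow(elements)), function(i)
    dateInsertion(ltrs$ltr5[[i]], ltrs$ltr3[[i]], mu,
                  element_id = elements$element_id[i])))
}

#' Greedy identity clustering to representative sequences
#'
#' Sequences are processed longest-first (ties by id); each sequence joins
#' the first existing cluster whose representative it matches at
#' `identity_threshold` or better (identity = matches / alignment columns of
#' the best local alignment, which must cover at least `min_cov` of the
#' shorter sequence), otherwise it founds a new cluster. Deterministic by
#' construction.
#'
#' @param seqs Named character vector or `DNAStringSet`.
#' @param identity_threshold Identity threshold in (0, 1) (default 0.70).
#' @param min_cov Minimum aligned coverage of the shorter sequence (default
#'   0.8).
#' @return A data.frame with columns `representative_id`, `member_id`,
#'   `identity` (1 for the representative itself).
#' @export
clusterGreedy <- function(seqs, identity_threshold = 0.70, min_cov = 0.8) {
  stopifnot(identity_threshold > 0, identity_threshold < 1)
  s <- .genome_chars(seqs)
  if (length(s) == 0L)
    return(data.frame(representative_id = character(),
                      member_id = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  ord <- names(s)[order(-nchar(s), names(s))]
  reps <- character()
  rows <- list()
  for (id in ord) {
    joined <- FALSE
    for (r in reps) { # founding order
      res <- .local_identity(s[[id]], s[[r]])
      if (res$coverage >= min_cov && res$identity >= identity_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          representative_id = r, member_id = id, identity = res$identity,
          stringsAsFactors = FALSE)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, id)
      rows[[length(rows) + 1L]] <- data.frame(
        representative_id = id, member_id = id, identity = 1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Representative sequences of a greedy clustering
#'
#' @param assignments Output of [clusterGreedy()].
#' @param seqs The clustered sequences.
#' @return Named character vector of representative sequences.
#' @export
clusterRepresentatives <- function(assignments, seqs) {
  s <- .genome_chars(seqs)
  reps <- unique(assignments$representative_id)
  stats::setNames(unname(s[reps]), reps)
}
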