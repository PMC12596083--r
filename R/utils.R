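# internal helpers shared across modules

# Coerce a genome (DNAStringSet or named character vector) to a named
# character vector; names are trimmed at the first whitespace.
.genome_chars <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    x <- as.character(genome)
  } else if (is.list(genome) &&
             all(vapply(genome, is.character, logical(1)))) {
    x <- vapply(genome, `[[`, "", 1L)
  } else if (is.character(genome)) {
    x <- genome
  } else if (is(genome, "DNAString")) {
    x <- stats::setNames(as.character(genome), "seq")
  } else stop("genome must be a DNAStringSet or a named character vector")
  if (is.null(names(x)) || any(names(x) == ""))
    stop("genome sequences must be named")
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop("duplicated chromosome names in genome")
  x
}

.seq_chars <- function(x) {
  if (is(x, "DNAString") || is(x, "DNAStringSet")) as.character(x)
  else as.character(x)
}

.revcomp <- function(x) cpp_revcomp(as.character(x))

# Fraction of each query range covered by the (reduced) subject ranges.
.overlap_fraction <- function(query, subject) {
  if (length(query) == 0L) return(numeric())
  if (length(subject) == 0L) return(rep(0, length(query)))
  subject <- GenomicRanges::reduce(subject, ignore.strand = TRUE)
  hits <- findOverlaps(query, subject, ignore.strand = TRUE)
  ov <- rep(0, length(query))
  if (length(hits)) {
    w <- width(pintersect(query[queryHits(hits)], subject[subjectHits(hits)],
                          ignore.strand = TRUE))
    agg <- tapply(w, queryHits(hits), sum)
    ov[as.integer(names(agg))] <- as.numeric(agg)
  }
  ov / width(query)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random DNA of length n as a character scalar (uses the current RNG stream).
.random_dna <- function(n) {
  rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, n, replace = TRUE)])
}

# Round half away from zero to `digits` decimals (commutes with how
# percentages are conventionally printed; base round() is round-half-even).
.round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Identity and coverage of the best local alignment between two sequences.
# identity = matches / alignment columns (gap columns included);
# coverage = aligned span on the shorter sequence / its length.
.local_identity <- function(a, b) {
  a <- DNAString(.seq_chars(a)); b <- DNAString(.seq_chars(b))
  submat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- pairwiseAlignment(a, b, type = "local", substitutionMatrix = submat,
                           gapOpening = 4, gapExtension = 1)
  pat <- Biostrings::pattern(aln)
  cols <- nchar(as.character(pat)) # alignment columns incl. gap columns
  if (cols == 0L) return(list(identity = 0, coverage = 0, cols = 0L))
  span <- if (length(a) <= length(b)) {
    end(pat) - start(pat) + 1L
  } else {
    sub <- Biostrings::subject(aln)
    end(sub) - start(sub) + 1L
  }
  list(identity = nmatch(aln) / cols,
       coverage = span / min(length(a), length(b)), cols = cols)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.msg <- function(..., verbose = getOption("centrotrace.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
}
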