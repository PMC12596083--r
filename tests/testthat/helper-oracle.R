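# Independent quadratic-time oracles used to verify the seeded aligner and
# the bin scorer. The alignment oracle runs a full (unbanded, unseeded)
# local DP with the same scoring (match +1, mismatch -1, gap -2 per column)
# and enumerates non-overlapping locally maximal alignments by repeatedly
# extracting the best alignment and splitting the target around it.

.enc_oracle <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  match(v, c("A", "C", "G", "T")) # NA for N and friends (never matches)
}

# Full local DP over one target segment; returns the best alignment or NULL.
# Ties resolved like the production code: smallest query end, then smallest
# target end; traceback prefers diagonal, then up (gap in target), then left.
.oracle_best <- function(qv, tv, match = 1, mismatch = -1, gap = 2) {
  m <- length(qv); n <- length(tv)
  if (m == 0 || n == 0) return(NULL)
  H <- matrix(0, m + 1, n + 1)
  jidx <- seq_len(n)
  for (i in seq_len(m)) {
    s <- ifelse(!is.na(qv[i]) & !is.na(tv) & qv[i] == tv, match, mismatch)
    base <- pmax(0, H[i, jidx] + s, H[i, jidx + 1] - gap)
    M <- cummax(base + gap * jidx)
    row <- pmax(base, c(-Inf, M[-n]) - gap * jidx, 0)
    H[i + 1, jidx + 1] <- row
  }
  best <- max(H)
  if (best <= 0) return(NULL)
  hit <- which(H == best, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE][1, ]
  i <- hit[1] - 1L; j <- hit[2] - 1L
  qe <- i; te <- j; cols <- 0L; matches <- 0L
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    s <- if (!is.na(qv[i]) && !is.na(tv[j]) && qv[i] == tv[j]) match else mismatch
    if (H[i + 1, j + 1] == H[i, j] + s) {
      if (s == match) matches <- matches + 1L
      cols <- cols + 1L; i <- i - 1L; j <- j - 1L
    } else if (H[i + 1, j + 1] == H[i, j + 1] - gap) {
      cols <- cols + 1L; i <- i - 1L
    } else if (H[i + 1, j + 1] == H[i + 1, j] - gap) {
      cols <- cols + 1L; j <- j - 1L
    } else break
  }
  list(qs = i, qe = qe, ts = j, te = te, cols = cols, matches = matches,
       score = best)
}

# All non-overlapping local alignments of one oriented query vs one target
# passing (min_len, min_identity); score floor guarantees no passing hit is
# below it: score >= cols * (3 * identity - 2) for linear gap cost 2.
.oracle_one_strand <- function(q, t, min_len, min_identity) {
  qv <- .enc_oracle(q)
  floor_score <- max(1, floor(min_len * (3 * min_identity - 2)))
  segs <- list(c(1L, nchar(t)))
  tv_full <- .enc_oracle(t)
  hits <- list()
  iter <- 0L
  while (length(segs) > 0 && iter < 60L) {
    iter <- iter + 1L
    # best alignment over every remaining target segment
    best <- NULL; best_seg <- NULL
    for (k in seq_along(segs)) {
      sg <- segs[[k]]
      if (sg[2] - sg[1] + 1L < min_len) next
      a <- .oracle_best(qv, tv_full[sg[1]:sg[2]])
      if (is.null(a)) next
      a$ts <- a$ts + sg[1] - 1L; a$te <- a$te + sg[1] - 1L
      if (is.null(best) || a$score > best$score) { best <- a; best_seg <- k }
    }
    if (is.null(best) || best$score < floor_score) break
    if (best$cols >= min_len && best$matches / best$cols >= min_identity - 1e-12)
      hits[[length(hits) + 1L]] <- best
    sg <- segs[[best_seg]]
    segs[[best_seg]] <- NULL
    if (best$ts - sg[1] >= 1L) segs[[length(segs) + 1L]] <- c(sg[1], best$ts)
    if (sg[2] - best$te >= 1L) segs[[length(segs) + 1L]] <- c(best$te + 1L, sg[2])
  }
  hits
}

# Oracle counterpart of localAlign(): both strands, 1-based closed output.
oracle_local_align <- function(query, targets, min_len, min_identity) {
  rows <- list()
  rc <- centrotrace:::.revcomp(query)
  m <- nchar(query)
  for (chrom in names(targets)) {
    for (strand in c("+", "-")) {
      qq <- if (strand == "+") query else rc
      for (h in .oracle_one_strand(qq, targets[[chrom]], min_len,
                                   min_identity)) {
        qs <- if (strand == "+") h$qs + 1L else m - h$qe + 1L
        qe <- if (strand == "+") h$qe else m - h$qs
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = h$ts + 1L, end = h$te, strand = strand,
          query_start = qs, query_end = qe, aligned_cols = h$cols,
          matches = h$matches, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      query_start = integer(), query_end = integer(),
                      aligned_cols = integer(), matches = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force per-position S = L x N: for every bin, count covering hits and
# covered positions by direct position-wise scanning.
oracle_bin_scores <- function(query_len, starts, ends, bin_width) {
  nb <- ceiling(query_len / bin_width)
  L <- integer(nb); N <- integer(nb)
  for (b in seq_len(nb)) {
    lo <- (b - 1L) * bin_width + 1L
    hi <- min(b * bin_width, query_len)
    if (length(starts)) {
      N[b] <- sum(starts <= hi & ends >= lo)
      L[b] <- sum(vapply(lo:hi, function(p) any(starts <= p & ends >= p),
                         logical(1)))
    }
  }
  data.frame(L = L, N = N, S = L * N)
}
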