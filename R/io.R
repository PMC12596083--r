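# Readers/writers for the standard formats the pipeline touches. Interval
# data use GRanges (1-based, closed) internally; BED and bedGraph conversion
# happens at the boundary via rtracklayer.

#' Read a genome from FASTA
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (names trimmed at the first
#'   whitespace); sequence case is preserved.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  if (anyDuplicated(names(g)))
    .stopf("duplicated sequence names in %s", path)
  g
}

#' Write a genome to FASTA
#'
#' @param genome A DNAStringSet or named character vector.
#' @param path Output path.
#' @export
writeGenome <- function(genome, path) {
  g <- .genome_chars(genome)
  writeXStringSet(DNAStringSet(g), path, width = 70L)
  invisible(path)
}

#' Read intervals from a BED file
#'
#' BED3+ (tab-separated, 0-based half-open) is converted to GRanges (1-based,
#' closed). Malformed lines are reported with their line number.
#'
#' @param path Path to a BED file.
#' @return A [GenomicRanges::GRanges]; column 4 (if present) becomes
#'   `mcols(x)$name`, column 6 the strand.
#' @export
readBed <- function(path) {
  if (!file.exists(path)) .stopf("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(GRanges())
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      .stopf("BED line %d: fewer than 3 tab-separated fields", i)
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      .stopf("BED line %d: non-numeric coordinates", i)
    if (s >= e)
      .stopf("BED line %d: start (%s) must be < end (%s)", i, f[2], f[3])
  }
  gr <- rtracklayer::import(path, format = "BED")
  gr
}

#' Write intervals to a BED file
#'
#' @param gr A GRanges; `mcols(gr)$name` (if present) becomes column 4.
#' @param path Output path.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a binned signal track (bedGraph)
#'
#' Records must be aligned to the bin grid: starts on multiples of
#' `bin_width`, spans of at most one bin. Bins without a record are filled
#' with 0; the number of bins per chromosome is inferred from the furthest
#' record unless `seqlengths` is given.
#'
#' @param path Path to a bedGraph file (4 tab- or space-separated columns:
#'   chrom, start, end, value; 0-based half-open).
#' @param bin_width Bin width in bp.
#' @param seqlengths Optional named vector of chromosome lengths used to fix
#'   the bin count per chromosome.
#' @return A [SignalTrack-class].
#' @export
readSignalTrack <- function(path, bin_width, seqlengths = NULL) {
  if (!file.exists(path)) .stopf("signal file not found: %s", path)
  bin_width <- as.integer(bin_width)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  vals <- list()
  nbins <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 4L) .stopf("bedGraph line %d: expected 4 fields", i)
    chrom <- f[1]
    s <- as.numeric(f[2]); e <- as.numeric(f[3]); v <- as.numeric(f[4])
    if (is.na(s) || is.na(e) || is.na(v))
      .stopf("bedGraph line %d: non-numeric fields", i)
    if (s %% bin_width != 0 || e - s > bin_width || e <= s)
      .stopf("bedGraph line %d: interval [%s,%s) not aligned to %d bp bins",
             i, f[2], f[3], bin_width)
    b <- s %/% bin_width + 1L
    if (is.null(vals[[chrom]])) { vals[[chrom]] <- numeric(); nbins[[chrom]] <- 0L }
    cur <- vals[[chrom]]
    if (b > length(cur)) cur <- c(cur, numeric(b - length(cur)))
    cur[b] <- v
    vals[[chrom]] <- cur
  }
  if (!is.null(seqlengths)) {
    for (chrom in names(seqlengths)) {
      nb <- as.integer(ceiling(seqlengths[[chrom]] / bin_width))
      cur <- if (is.null(vals[[chrom]])) numeric() else vals[[chrom]]
      if (nb > length(cur)) cur <- c(cur, numeric(nb - length(cur)))
      vals[[chrom]] <- cur[seq_len(nb)]
    }
  }
  if (length(vals) == 0L)
    return(new("SignalTrack", bin_width = bin_width,
               values = stats::setNames(list(), character())))
  SignalTrack(vals, bin_width)
}

#' Write a binned signal track as bedGraph
#'
#' Only non-zero bins are written (bedGraph is sparse); a write/read
#' round-trip therefore reproduces all non-zero bins exactly.
#'
#' @param track A [SignalTrack-class].
#' @param path Output path.
#' @export
writeSignalTrack <- function(track, path) {
  stopifnot(is(track, "SignalTrack"))
  bw <- binWidth(track)
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in trackChroms(track)) {
    v <- trackValues(track)[[chrom]]
    nz <- which(v != 0)
    if (length(nz))
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, (nz - 1L) * bw, nz * bw,
                         format(v[nz], scientific = FALSE, trim = TRUE)),
                 con)
  }
  invisible(path)
}

#' Read repeat annotations (GFF3 or tabular)
#'
#' Two dialects are supported: GFF3 (1-based inclusive; the repeat family is
#' taken from the `family_id`, `Name` or `Target` attribute) and a
#' RepeatMasker-style TSV with header columns `chrom`, `start`, `end`,
#' `strand`, `family_id` (1-based inclusive).
#'
#' @param path Path to the annotation file.
#' @param dialect `"auto"` (default), `"gff3"` or `"tsv"`.
#' @return A GRanges with `mcols(x)$family_id`.
#' @export
readRepeatAnnotations <- function(path, dialect = c("auto", "gff3", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) .stopf("annotation file not found: %s", path)
  if (dialect == "auto") {
    head1 <- readLines(path, n = 1L)
    dialect <- if (grepl("^##gff", head1)) "gff3"
      else if (grepl("\tfamily_id($|\t)", head1) ||
               grepl("^chrom\t", head1)) "tsv"
      else .stopf(paste("cannot determine annotation dialect of %s;",
                        "supported dialects: gff3, tsv (header columns",
                        "chrom/start/end/strand/family_id)"), path)
  }
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    fam <- mcols(gr)$family_id
    if (is.null(fam)) fam <- mcols(gr)$Name
    if (is.null(fam)) fam <- sub("\\s.*$", "", as.character(mcols(gr)$Target))
    if (is.null(fam) || all(is.na(fam)))
      .stopf("no family_id/Name/Target attribute in %s", path)
    out <- GRanges(seqnames(gr), IRanges::ranges(gr), strand = strand(gr))
    mcols(out)$family_id <- as.character(fam)
    return(out)
  }
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "family_id")
  if (!all(need %in% names(tab)))
    .stopf("TSV annotation %s must have columns %s", path,
           paste(need, collapse = ", "))
  strand <- if ("strand" %in% names(tab)) tab$strand else "*"
  gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end), strand = strand)
  mcols(gr)$family_id <- as.character(tab$family_id)
  gr
}

#' Write repeat annotations as GFF3
#'
#' @param gr GRanges with `mcols(x)$family_id`.
#' @param path Output path.
#' @export
writeRepeatAnnotations <- function(gr, path) {
  out <- gr
  if (is.null(mcols(out)$family_id)) stop("annotations need a family_id column")
  mcols(out)$type <- "dispersed_repeat"
  mcols(out)$source <- "centrotrace"
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

# Columns of the intact LTR-RT element table (coordinates 1-based inclusive).
.ltr_element_cols <- c("element_id", "chrom", "start", "end", "strand",
                       "ltr5_start", "ltr5_end", "internal_start",
                       "internal_end", "ltr3_start", "ltr3_end", "family_id",
                       "subfamily", "insertion_time_mya")

#' Validate an intact LTR-RT element table
#'
#' Checks the structural invariants: 5' LTR, internal region and 3' LTR are
#' ordered, non-overlapping and contained in the element span. Part
#' coordinates are genomic (for minus-strand elements the transcription-
#' proximal "5' LTR" is the genomic right-hand repeat; [extractLTRs()]
#' resolves orientation).
#'
#' @param elements A data.frame of elements.
#' @return The validated data.frame, invisibly usable.
#' @export
validateLtrElements <- function(elements) {
  miss <- setdiff(setdiff(.ltr_element_cols, c("subfamily",
                  "insertion_time_mya")), names(elements))
  if (length(miss))
    .stopf("element table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(elements$element_id)) stop("duplicated element_id")
  with(elements, {
    bad <- !(start <= ltr5_start & ltr5_start <= ltr5_end &
             ltr5_end < internal_start & internal_start <= internal_end &
             internal_end < ltr3_start & ltr3_start <= ltr3_end &
             ltr3_end <= end)
    if (any(bad))
      .stopf("element(s) %s violate 5'LTR <= internal <= 3'LTR ordering",
             paste(element_id[bad], collapse = ", "))
  })
  invisible(elements)
}

#' Read an intact LTR-RT element table (TSV)
#'
#' @param path Path to a tab-separated table with the element columns
#'   (`element_id`, `chrom`, `start`, `end`, `strand`, `ltr5_start`,
#'   `ltr5_end`, `internal_start`, `internal_end`, `ltr3_start`, `ltr3_end`,
#'   `family_id`, optional `subfamily` and `insertion_time_mya`).
#' @return A validated data.frame.
#' @export
readLtrElements <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!"subfamily" %in% names(tab)) tab$subfamily <- NA_character_
  if (!"insertion_time_mya" %in% names(tab)) tab$insertion_time_mya <- NA_real_
  validateLtrElements(tab)
  tab
}

#' Write an intact LTR-RT element table (TSV)
#'
#' @param elements Element data.frame (see [readLtrElements()]).
#' @param path Output path.
#' @export
writeLtrElements <- function(elements, path) {
  validateLtrElements(elements)
  write.table(elements, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the analysis with their defaults: 1-kb
#' signal bins, 100-bp score bins, 10-bp trace bins, a 376-bp probe with a 3%
#' mismatch cap, 70% clustering identity, a family census cutoff of 100
#' centromeric copies, a neutral substitution rate of 1.3e-8 per site per
#' year and a CRI cutoff of 2.
#'
#' @param bin_width_signal,bin_width_score,bin_width_trace Bin widths (bp).
#' @param probe_len Probe length (bp).
#' @param probe_mismatch_frac Probe mismatch tolerance (fraction of length).
#' @param cluster_identity Greedy clustering identity threshold (fraction).
#' @param min_family_count Minimum centromeric copy count in the family
#'   census.
#' @param mutation_rate_mu Neutral substitution rate (substitutions per site
#'   per year) used for LTR dating.
#' @param cri_threshold CRI cutoff for centromere-specific element selection.
#' @param rng_seed Integer seed forwarded to stochastic steps.
#' @return A list of class `pipeline_config`.
#' @export
pipelineConfig <- function(bin_width_signal = 1000L, bin_width_score = 100L,
                           bin_width_trace = 10L, probe_len = 376L,
                           probe_mismatch_frac = 0.03,
                           cluster_identity = 0.70,
                           min_family_count = 100L,
                           mutation_rate_mu = 1.3e-8, cri_threshold = 2.0,
                           rng_seed = 1L) {
  cfg <- list(bin_width_signal = as.integer(bin_width_signal),
              bin_width_score = as.integer(bin_width_score),
              bin_width_trace = as.integer(bin_width_trace),
              probe_len = as.integer(probe_len),
              probe_mismatch_frac = probe_mismatch_frac,
              cluster_identity = cluster_identity,
              min_family_count = as.integer(min_family_count),
              mutation_rate_mu = mutation_rate_mu,
              cri_threshold = cri_threshold,
              rng_seed = as.integer(rng_seed))
  for (f in c("probe_mismatch_frac", "cluster_identity"))
    if (cfg[[f]] <= 0 || cfg[[f]] > 1)
      .stopf("%s must lie in (0, 1]", f)
  for (w in c("bin_width_signal", "bin_width_score", "bin_width_trace",
              "probe_len"))
    if (cfg[[w]] <= 0L) .stopf("%s must be positive", w)
  if (cfg$mutation_rate_mu <= 0) stop("mutation_rate_mu must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`) override the
#' [pipelineConfig()] defaults.
#'
#' @param path Path to the configuration file.
#' @return A `pipeline_config` list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) .stopf("malformed config line: %s", lines[bad][1])
  vals <- stats::setNames(lapply(kv, function(x) {
    v <- utils::type.convert(x[2], as.is = TRUE)
    v
  }), vapply(kv, `[[`, "", 1L))
  unknown <- setdiff(names(vals), names(formals(pipelineConfig)))
  if (length(unknown))
    .stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipelineConfig, vals)
}
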