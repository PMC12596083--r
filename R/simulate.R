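# Synthetic genomes with planted LTR-RT families, solo LTRs, satellite
# arrays and Poisson ChIP/Input tracks, with full truth tables. The defaults
# emulate the study design the rest of the package analyses: one centromere
# per chromosome, a centromere-biased CR family whose LTRs carry extra ChIP
# enrichment, background families with distinct ages, and centromeric tandem
# arrays amplified from a segment of the oldest (CR) family's LTR.

#' Simulation configuration
#'
#' @param n_chroms Number of chromosomes (default 3).
#' @param chrom_len Chromosome length in bp (default 3e6).
#' @param cen_len Centromere length in bp (default 6e5).
#' @param cen_position Centromere start as a fraction of the chromosome
#'   (default 0.45; snapped to the signal bin grid).
#' @param n_families Number of LTR-RT families (default 5; family 1 is the
#'   centromere-biased CR family).
#' @param planted_cr_copies_cen,planted_cr_copies_noncen Intact CR-family
#'   copies inside/outside centromeres (defaults 30 and 3).
#' @param background_copies Intact copies per background family, placed
#'   uniformly (default 40).
#' @param element_len,ltr_len Element and LTR lengths in bp (defaults 6000
#'   and 800).
#' @param extra_ltr_solo_copies_cen Solo copies of the CR family LTR planted
#'   in centromeres (default 20).
#' @param tr_source `"cltr_segment"` (satellite monomer amplified from a
#'   segment of the CR family's LTR) or `"random"` (negative control).
#' @param tr_segment_len Satellite monomer length in bp (default 100).
#' @param tr_copy_number Copies per centromeric array (default 50).
#' @param tr_copy_mut Per-copy substitution probability in the array
#'   (default 0.02).
#' @param tr_source_age_mya Age of the satellite-founding LTR fragment in
#'   Mya (default 2.46): the monomer descends from an ancient insertion of
#'   the CR family even though today's intact CR copies are young.
#' @param ages_mya Insertion ages per family in Mya, recycled to
#'   `n_families`. Defaults to `c(0.35, 2.46, 1.2, 1.8, 0.75)`: the CR
#'   family is young and homogeneous (so a probe window finds most copies
#'   within a small mismatch cap) and families 1 and 2 give a strong
#'   young/old dating contrast.
#' @param chip_fold_cen ChIP enrichment fold over centromeric bins (default
#'   5).
#' @param chip_fold_cr_ltr Fold over bins overlapping planted CR LTRs inside
#'   centromeres (default 7.5).
#' @param input_lambda Poisson mean of the Input track per bin (default 30).
#' @param mu Neutral substitution rate (substitutions/site/year, default
#'   1.3e-8) used to convert ages into LTR divergence.
#' @param bin_width Signal track bin width (default 1000).
#' @return A list of class `sim_config`.
#' @export
simConfig <- function(n_chroms = 3L, chrom_len = 3e6, cen_len = 6e5,
                      cen_position = 0.45, n_families = 5L,
                      planted_cr_copies_cen = 30L,
                      planted_cr_copies_noncen = 3L,
                      background_copies = 40L, element_len = 6000L,
                      ltr_len = 800L, extra_ltr_solo_copies_cen = 20L,
                      tr_source = c("cltr_segment", "random"),
                      tr_segment_len = 100L, tr_copy_number = 50L,
                      tr_copy_mut = 0.02, tr_source_age_mya = 2.46,
                      ages_mya = c(0.35, 2.46, 1.2, 1.8, 0.75),
                      chip_fold_cen = 5, chip_fold_cr_ltr = 7.5,
                      input_lambda = 30, mu = 1.3e-8, bin_width = 1000L) {
  tr_source <- match.arg(tr_source)
  cfg <- list(n_chroms = as.integer(n_chroms), chrom_len = as.integer(chrom_len),
              cen_len = as.integer(cen_len), cen_position = cen_position,
              n_families = as.integer(n_families),
              planted_cr_copies_cen = as.integer(planted_cr_copies_cen),
              planted_cr_copies_noncen = as.integer(planted_cr_copies_noncen),
              background_copies = as.integer(background_copies),
              element_len = as.integer(element_len),
              ltr_len = as.integer(ltr_len),
              extra_ltr_solo_copies_cen = as.integer(extra_ltr_solo_copies_cen),
              tr_source = tr_source,
              tr_segment_len = as.integer(tr_segment_len),
              tr_copy_number = as.integer(tr_copy_number),
              tr_copy_mut = tr_copy_mut,
              tr_source_age_mya = tr_source_age_mya,
              ages_mya = rep_len(ages_mya, n_families),
              chip_fold_cen = chip_fold_cen,
              chip_fold_cr_ltr = chip_fold_cr_ltr,
              input_lambda = input_lambda, mu = mu,
              bin_width = as.integer(bin_width))
  if (cfg$cen_len >= cfg$chrom_len) stop("cen_len must be below chrom_len")
  if (cfg$chip_fold_cen < 1 || cfg$chip_fold_cr_ltr < 1)
    stop("ChIP folds must be at least 1")
  if (cfg$element_len <= 2L * cfg$ltr_len)
    stop("element_len must exceed twice ltr_len")
  class(cfg) <- "sim_config"
  cfg
}

#' Mutate a DNA sequence
#'
#' Independent per-site substitutions to a uniformly chosen different base
#' with probability `sub_prob`; independent 1-bp indels (insertion or
#' deletion, equal odds) with probability `indel_prob`. Deterministic given
#' `seed`. Non-ACGT characters are never substituted.
#'
#' @param seq Input sequence (character scalar or `DNAString`).
#' @param sub_prob Per-site substitution probability in \[0, 0.5).
#' @param indel_prob Per-site 1-bp indel probability in \[0, 0.5).
#' @param seed Optional integer seed (caller RNG state is preserved).
#' @return The mutated sequence as a character scalar.
#' @export
mutateSequence <- function(seq, sub_prob, indel_prob = 0, seed = NULL) {
  stopifnot(sub_prob >= 0, sub_prob < 0.5, indel_prob >= 0, indel_prob < 0.5)
  .with_seed(seed, {
    s <- .seq_chars(seq)
    v <- strsplit(s, "")[[1]]
    n <- length(v)
    bases <- c("A", "C", "G", "T")
    idx <- match(v, bases)
    if (n > 0L && sub_prob > 0) {
      hit <- which(stats::runif(n) < sub_prob & !is.na(idx))
      if (length(hit)) {
        shift <- sample.int(3L, length(hit), replace = TRUE)
        v[hit] <- bases[((idx[hit] - 1L + shift) %% 4L) + 1L]
      }
    }
    if (n > 0L && indel_prob > 0) {
      ind <- which(stats::runif(n) < indel_prob)
      if (length(ind)) {
        del <- stats::runif(length(ind)) < 0.5
        keep <- rep(TRUE, n)
        keep[ind[del]] <- FALSE
        ins_at <- ind[!del]
        pieces <- v
        pieces[ins_at] <- paste0(bases[sample.int(4L, length(ins_at),
                                                  replace = TRUE)],
                                 pieces[ins_at])
        v <- pieces[keep]
      }
    }
    paste(v, collapse = "")
  })
}

# Sample a free start for an interval of width len inside [lo, hi] on one
# chromosome, avoiding current occupancy; NULL when no slot is found.
.place_one <- function(occupied, lo, hi, len, tries = 500L) {
  if (hi - len + 1L < lo) return(NULL)
  for (t in seq_len(tries)) {
    s <- lo + sample.int(hi - len + 2L - lo, 1L) - 1L
    cand <- IRanges(s, s + len - 1L)
    if (countOverlaps(cand, occupied) == 0L) return(s)
  }
  NULL
}

#' Generate a synthetic genome with planted features and truth tables
#'
#' Builds i.i.d. random chromosomes, places one centromere per chromosome
#' (snapped to the signal bin grid), plants intact LTR-RT elements for each
#' family (both LTRs identical at insertion, then independently mutated to
#' per-site divergence `mu * age` so the expected LTR-pair p-distance is
#' about `2 * mu * age`), plants solo copies of the CR family's LTR in
#' centromeres, and builds one tandem array per centromere by amplifying a
#' `tr_segment_len` segment of the CR family's LTR (aged at
#' `tr_source_age_mya`, then 2% per-copy mutation) — or a random monomer
#' under `tr_source = "random"`.
#'
#' @param config A [simConfig()] list.
#' @param seed Integer seed; generation is fully reproducible from
#'   (config, seed).
#' @return A list: `genome` (named character vector), `config`, `seed`,
#'   `centromeres` (GRanges), `elements` (intact-element table with truth
#'   columns `true_family`, `true_age_mya`, `location_class`),
#'   `annotations` (GRanges of every planted repeat copy with `family_id`),
#'   `solo_ltrs` (GRanges), `tr_truth` (per-array truth: location, source
#'   family and source LTR segment), `family_consensus` /
#'   `family_ltr_consensus` (named character vectors).
#' @export
simulateGenome <- function(config = simConfig(), seed = 1L) .with_seed(seed, {
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  # chromosomes are built as raw vectors: slice assignment avoids copying
  # the full sequence at every implant
  genome <- stats::setNames(
    lapply(chroms, function(x)
      as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, cfg$chrom_len,
                                               replace = TRUE)]),
    chroms)
  bw <- cfg$bin_width
  cen_start <- floor(cfg$cen_position * cfg$chrom_len / bw) * bw + 1L
  cen <- GRanges(chroms, IRanges(cen_start, cen_start + cfg$cen_len - 1L))
  fam_ids <- paste0("family_", seq_len(cfg$n_families))
  int_len <- cfg$element_len - 2L * cfg$ltr_len
  ltr_cons <- stats::setNames(
    lapply(fam_ids, function(x) .random_dna(cfg$ltr_len)), fam_ids)
  int_cons <- stats::setNames(
    lapply(fam_ids, function(x) .random_dna(int_len)), fam_ids)
  ages <- stats::setNames(cfg$ages_mya, fam_ids)
  occupied <- stats::setNames(lapply(chroms, function(x) IRanges()), chroms)

  implant <- function(chrom, start, s) {
    genome[[chrom]][start:(start + nchar(s) - 1L)] <<- charToRaw(s)
    occupied[[chrom]] <<- c(occupied[[chrom]],
                            IRanges(start, start + nchar(s) - 1L))
  }

  # reserve satellite array slots first (mid-centromere)
  tr_rows <- list()
  if (cfg$tr_copy_number > 0L && cfg$tr_segment_len > 0L) {
    src_off <- sample.int(cfg$ltr_len - cfg$tr_segment_len + 1L, 1L)
    base_seg <- if (cfg$tr_source == "cltr_segment") {
      substr(ltr_cons[["family_1"]], src_off,
             src_off + cfg$tr_segment_len - 1L)
    } else .random_dna(cfg$tr_segment_len)
    # the founding fragment is an ancient CR insertion, older than the
    # intact copies visible today
    d_src <- cfg$mu * cfg$tr_source_age_mya * 1e6
    aged_seg <- mutateSequence(base_seg, d_src)
    arr_len <- cfg$tr_segment_len * cfg$tr_copy_number
    for (chrom in chroms) {
      copies <- vapply(seq_len(cfg$tr_copy_number), function(k)
        mutateSequence(aged_seg, cfg$tr_copy_mut), "")
      arr <- paste(copies, collapse = "")
      s <- .place_one(occupied[[chrom]],
                      cen_start + (cfg$cen_len - arr_len) %/% 2L - 5000L,
                      cen_start + (cfg$cen_len - arr_len) %/% 2L + 5000L +
                        arr_len, arr_len)
      if (is.null(s))
        s <- .place_one(occupied[[chrom]], cen_start,
                        cen_start + cfg$cen_len - 1L, arr_len)
      if (is.null(s)) stop("no space for tandem array: config error")
      implant(chrom, s, arr)
      tr_rows[[length(tr_rows) + 1L]] <- data.frame(
        chrom = chrom, start = s, end = s + arr_len - 1L,
        period = cfg$tr_segment_len, copies = cfg$tr_copy_number,
        source_family = if (cfg$tr_source == "cltr_segment") "family_1"
                        else NA_character_,
        source_ltr_start = if (cfg$tr_source == "cltr_segment") src_off
                           else NA_integer_,
        source_ltr_end = if (cfg$tr_source == "cltr_segment")
                           src_off + cfg$tr_segment_len - 1L
                         else NA_integer_,
        stringsAsFactors = FALSE)
    }
  }

  make_element <- function(fam) {
    d <- cfg$mu * ages[[fam]] * 1e6
    list(ltr5 = mutateSequence(ltr_cons[[fam]], d),
         ltr3 = mutateSequence(ltr_cons[[fam]], d),
         internal = mutateSequence(int_cons[[fam]], d))
  }

  el_rows <- list()
  anno_rows <- list()
  eid <- 0L
  plant_element <- function(fam, chrom, lo, hi, cls) {
    s <- .place_one(occupied[[chrom]], lo, hi, cfg$element_len)
    if (is.null(s)) return(FALSE)
    parts <- make_element(fam)
    strand <- sample(c("+", "-"), 1L)
    seq <- paste0(parts$ltr5, parts$internal, parts$ltr3)
    if (strand == "-") seq <- .revcomp(seq)
    implant(chrom, s, seq)
    e <- s + cfg$element_len - 1L
    # part coordinates are genomic (ascending); for '-' elements the
    # transcription-proximal 5' LTR is the genomic right-hand repeat and
    # extractLTRs resolves the orientation
    eid <<- eid + 1L
    el_rows[[length(el_rows) + 1L]] <<- data.frame(
      element_id = sprintf("el_%03d", eid), chrom = chrom, start = s,
      end = e, strand = strand, ltr5_start = s, ltr5_end = s + cfg$ltr_len - 1L,
      internal_start = s + cfg$ltr_len, internal_end = e - cfg$ltr_len,
      ltr3_start = e - cfg$ltr_len + 1L, ltr3_end = e, family_id = fam,
      subfamily = NA_character_, insertion_time_mya = NA_real_,
      true_family = fam, true_age_mya = ages[[fam]],
      location_class = cls, stringsAsFactors = FALSE)
    anno_rows[[length(anno_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = s, end = e, strand = strand, family_id = fam,
      type = "intact", stringsAsFactors = FALSE)
    TRUE
  }

  cen_lo <- cen_start
  cen_hi <- cen_start + cfg$cen_len - 1L
  # CR family: centromere-biased intact copies, round-robin over chromosomes
  for (k in seq_len(cfg$planted_cr_copies_cen)) {
    chrom <- chroms[(k - 1L) %% cfg$n_chroms + 1L]
    if (!plant_element("family_1", chrom, cen_lo, cen_hi, "cen"))
      stop("no centromeric space for CR element: config error")
  }
  for (k in seq_len(cfg$planted_cr_copies_noncen)) {
    chrom <- chroms[(k - 1L) %% cfg$n_chroms + 1L]
    side <- sample(2L, 1L)
    ok <- if (side == 1L)
      plant_element("family_1", chrom, 1L, cen_lo - 1L, "noncen")
    else
      plant_element("family_1", chrom, cen_hi + 1L, cfg$chrom_len, "noncen")
    if (!ok) stop("no non-centromeric space for CR element: config error")
  }
  # background families: uniform over the genome
  if (cfg$n_families > 1L) {
    for (fam in fam_ids[-1]) {
      for (k in seq_len(cfg$background_copies)) {
        chrom <- chroms[sample.int(cfg$n_chroms, 1L)]
        s <- .place_one(occupied[[chrom]], 1L, cfg$chrom_len,
                        cfg$element_len)
        if (is.null(s)) stop("no space for background element: config error")
        e <- s + cfg$element_len - 1L
        ov <- max(0L, min(e, cen_hi) - max(s, cen_lo) + 1L)
        cls <- if (ov >= cfg$element_len / 2) "cen" else "noncen"
        ok <- plant_element(fam, chrom, s, e, cls)
        if (!ok) stop("background placement clash: config error")
      }
    }
  }
  # solo LTRs of the CR family inside centromeres
  solo_rows <- list()
  d_cr <- cfg$mu * ages[["family_1"]] * 1e6
  for (k in seq_len(cfg$extra_ltr_solo_copies_cen)) {
    chrom <- chroms[(k - 1L) %% cfg$n_chroms + 1L]
    s <- .place_one(occupied[[chrom]], cen_lo, cen_hi, cfg$ltr_len)
    if (is.null(s)) stop("no centromeric space for solo LTR: config error")
    strand <- sample(c("+", "-"), 1L)
    seq <- mutateSequence(ltr_cons[["family_1"]], d_cr)
    if (strand == "-") seq <- .revcomp(seq)
    implant(chrom, s, seq)
    solo_rows[[length(solo_rows) + 1L]] <- data.frame(
      chrom = chrom, start = s, end = s + cfg$ltr_len - 1L, strand = strand,
      family_id = "family_1", type = "solo_ltr", stringsAsFactors = FALSE)
    anno_rows[[length(anno_rows) + 1L]] <- solo_rows[[length(solo_rows)]]
  }

  elements <- do.call(rbind, el_rows)
  anno <- do.call(rbind, anno_rows)
  annotations <- GRanges(anno$chrom, IRanges(anno$start, anno$end),
                         strand = anno$strand)
  mcols(annotations)$family_id <- anno$family_id
  mcols(annotations)$type <- anno$type
  solo <- if (length(solo_rows)) {
    sr <- do.call(rbind, solo_rows)
    g <- GRanges(sr$chrom, IRanges(sr$start, sr$end), strand = sr$strand)
    mcols(g)$family_id <- sr$family_id
    g
  } else GRanges()
  tr_truth <- if (length(tr_rows)) do.call(rbind, tr_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               period = integer(), copies = integer(),
               source_family = character(), source_ltr_start = integer(),
               source_ltr_end = integer(), stringsAsFactors = FALSE)
  list(genome = vapply(genome, rawToChar, ""), config = cfg, seed = seed,
       centromeres = cen, elements = elements, annotations = annotations,
       solo_ltrs = solo, tr_truth = tr_truth,
       family_consensus = vapply(fam_ids, function(f)
         paste0(ltr_cons[[f]], int_cons[[f]], ltr_cons[[f]]), ""),
       family_ltr_consensus = vapply(fam_ids, function(f) ltr_cons[[f]], ""),
       family_ages_mya = ages)
})

#' Simulate binned ChIP and Input tracks for a synthetic genome
#'
#' Per bin, Input ~ Poisson(`input_lambda`) and ChIP ~ Poisson(
#' `input_lambda * fold`), where the fold is `chip_fold_cr_ltr` on bins
#' overlapping planted CR LTRs (terminal repeats of intact centromeric CR
#' elements, and solo LTRs) inside centromeres, `chip_fold_cen` on other
#' centromeric bins, and 1 elsewhere. Deterministic given `seed`.
#'
#' @param sim Result of [simulateGenome()].
#' @param seed Integer seed.
#' @return A list of [SignalTrack-class] objects: `chip`, `input`, and
#'   `expected_fold` (the noise-free fold per bin).
#' @export
simulateChip <- function(sim, seed = 1L) .with_seed(seed, {
  cfg <- sim$config
  bw <- cfg$bin_width
  el <- sim$elements
  cr_cen <- el[el$true_family == "family_1" & el$location_class == "cen", ,
               drop = FALSE]
  ltr_gr <- GRanges(
    c(cr_cen$chrom, cr_cen$chrom,
      as.character(seqnames(sim$solo_ltrs))),
    IRanges(c(cr_cen$ltr5_start, cr_cen$ltr3_start,
              start(sim$solo_ltrs)),
            c(cr_cen$ltr5_end, cr_cen$ltr3_end, end(sim$solo_ltrs))))
  chip <- list(); input <- list(); foldv <- list()
  for (chrom in names(sim$genome)) {
    nb <- as.integer(ceiling(nchar(sim$genome[[chrom]]) / bw))
    fold <- rep(1, nb)
    bins <- GRanges(chrom, IRanges((seq_len(nb) - 1L) * bw + 1L,
                                   pmin(seq_len(nb) * bw,
                                        nchar(sim$genome[[chrom]]))))
    cen_here <- sim$centromeres[seqnames(sim$centromeres) == chrom]
    fold[countOverlaps(bins, cen_here) > 0L] <- cfg$chip_fold_cen
    in_cen <- countOverlaps(bins, cen_here) > 0L
    hit_ltr <- countOverlaps(bins, ltr_gr[seqnames(ltr_gr) == chrom]) > 0L
    fold[in_cen & hit_ltr] <- cfg$chip_fold_cr_ltr
    input[[chrom]] <- rpois(nb, cfg$input_lambda)
    chip[[chrom]] <- rpois(nb, cfg$input_lambda * fold)
    foldv[[chrom]] <- fold
  }
  list(chip = SignalTrack(chip, bw), input = SignalTrack(input, bw),
       expected_fold = SignalTrack(foldv, bw))
})

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `centromeres.bed`, `elements.tsv`, `repeats.gff3` and,
#' when tracks are given, `chip.bedgraph` / `input.bedgraph`.
#'
#' @param sim Result of [simulateGenome()].
#' @param dir Output directory (created if needed).
#' @param tracks Optional result of [simulateChip()].
#' @return The directory path, invisibly.
#' @export
writeSimulation <- function(sim, dir, tracks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeGenome(sim$genome, file.path(dir, "genome.fa"))
  cen <- sim$centromeres
  mcols(cen)$name <- paste0("cen_", seq_along(cen))
  writeBed(cen, file.path(dir, "centromeres.bed"))
  writeLtrElements(sim$elements, file.path(dir, "elements.tsv"))
  writeRepeatAnnotations(sim$annotations, file.path(dir, "repeats.gff3"))
  if (!is.null(tracks)) {
    writeSignalTrack(tracks$chip, file.path(dir, "chip.bedgraph"))
    writeSignalTrack(tracks$input, file.path(dir, "input.bedgraph"))
  }
  invisible(dir)
}
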