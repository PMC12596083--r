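---
title: "Methods: centromere delineation and centromeric retrotransposon analysis"
author: "centrotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: centromere delineation and centromeric retrotransposon analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrotrace)
library(GenomicRanges)
```

# Scope and model

Many plant centromeres are built not from high-copy satellite arrays but
from *Gypsy*-type LTR retrotransposons. centrotrace implements the
computational workflow for characterising such transposon-dominated
centromeres:

1. **Centromere delineation** from binned CENH3 ChIP/Input read counts.
2. **Centromeric retrotransposon (CR) discovery**: census of repeat
   families inside centromeres, candidate selection with containment
   resolution, calling of intact LTR elements as CRs against a candidate,
   and selection of a representative element.
3. **Occupancy profiling** with the binned alignment score
   \(S_b = L_b \times N_b\), where for each bin \(b\) of the query
   sequence, \(L_b\) is the number of bin positions covered by the union of
   alignment-hit query intervals and \(N_b\) the number of hits
   intersecting the bin.
4. **The centromeric retrotransposon enrichment index**
   \[
   \mathrm{CRI} \;=\; \frac{\sum_{i \in \mathrm{CEN}} L_i I_i}
                           {\sum_{j \notin \mathrm{CEN}} L_j I_j},
   \]
   the ratio of identity-weighted aligned length inside vs outside
   centromeres over all genome-wide hits of an element (CLTRI is the same
   index computed on the element's terminal repeat alone).
5. **Insertion-time dating** from 5'/3' LTR divergence: the two terminal
   repeats are identical on insertion; after global alignment, the
   p-distance over gap-free columns is corrected with the one-parameter
   substitution model \(K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)\) and
   converted to time as \(T = K / 2\mu\).
6. **Greedy identity clustering** of centromeric LTRs to representative
   sequences.
7. **Tandem-repeat detection and the satellite origin trace**: centromeric
   tandem repeats (CTRs) are aligned against the LTR representatives in
   10-bp bins; runs of high \(S_b\) delimit the LTR segment that the
   satellite monomer descends from.

Every step is exercised end to end on a synthetic genome generator that
plants element families, solo LTRs, satellite arrays and Poisson ChIP
counts with a complete truth table.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `bin_width` (signal) | 1000 bp | ChIP/Input summarisation grid |
| `threshold` (calling) | 2.0 | minimum ChIP/Input ratio of a centromeric bin |
| `merge_gap` | 50 kb | marked runs closer than this merge |
| `min_len` (calling) | 100 kb | minimum reported centromere length |
| `min_run` | 3 bins | minimum initial run length (noise guard) |
| `pseudocount` | 1.0 | keeps coverage deserts finite and neutral |
| `min_family_count` | 100 | census cutoff for candidate families |
| `min_cov`, `min_identity` (CR call) | 0.5, 0.8 | coverage of the shorter sequence and hit identity |
| `probe_len`, `mismatch_frac` | 376 bp, 3% | probe window and gapless mismatch cap |
| `cluster_identity` | 0.70 | greedy clustering threshold |
| `mu` | 1.3e-8 /site/yr | neutral substitution rate for dating |
| `cri_threshold` | 2.0 | centromere-specific element cutoff |
| `bin_width` (trace) | 10 bp | satellite origin trace grid |

The census cutoff of 100 centromeric copies matches genome-scale repeat
annotations; on the desk-scale synthetic genomes (about 50 planted CR
copies) the examples pass `min_count = 25`. The CRI cutoff of 2 separates
the planted centromere-biased family (CRI around 10) from uniformly placed
background families (CRI around 0.25) with a wide margin.

# Alignment engine

Genome-wide, multi-hit local alignment is a seed-and-extend design: exact
13-mer seed matches are grouped into diagonal chains and each chain is
extended with a banded Smith–Waterman. Scoring is match +1, mismatch −1,
and a **linear gap cost of 2 per gap column**. A linear cost keeps the
production recurrence identical to a closed-form, vectorisable full-matrix
oracle, so the aligner is verified cell-for-cell against an independent
quadratic implementation; at the substitution-dominated divergences this
pipeline works with (a few percent between family members), linear and
affine schemes select the same hits. `N` never matches anything, lowercase
aligns as uppercase, and hits on one strand whose target intervals overlap
by at least 90% of the shorter are collapsed to the higher-scoring one, so
each locally maximal alignment is reported once.

Two practical consequences of seeding: an alignment is only found if it
contains an exact 13-mer (essentially always true above ~90% identity, and
true by construction for the planted copies the tests use), and single-seed
chains are pre-screened with a cheap gapless X-drop extension before the
banded DP is paid for — a random 13-mer match almost never extends to
26 columns at the identity threshold.

# Numerical choices and tie-breaks

* Intervals are held in `GRanges` (1-based, closed), the Bioconductor
  convention; BED/bedGraph/GFF3 conversion happens in the readers and
  writers only.
* Centromere calling marks bins at `ratio >= threshold`, discards marked
  runs shorter than `min_run` bins, merges across gaps up to `merge_gap`,
  drops intervals below `min_len`, and trims sub-threshold boundary bins.
  The `min_run` guard exists because a single Poisson-outlier bin within
  `merge_gap` of a true block would otherwise be merged in and drag the
  called boundary tens of bins outward.
* The CR representative is the element whose span length is closest to the
  candidate length; ties go to the smaller element id. Probe-design ties go
  to the leftmost 5' LTR window. Cluster membership ties go to the first
  (longest, then lexicographically first) representative.
* The tandem-repeat detector compares positions `i` and `i + p` and keeps
  maximal agreement runs (score `+1 − t` for a match, `−t` otherwise at
  threshold `t`); overlapping candidates across periods are resolved by the
  longest agreement run, which keeps a fundamental period ahead of its
  harmonics (their spans tie within end wobble). A minimum array length of
  50 bp plays the role of an alignment-score threshold; without it, chance
  dinucleotide wobble qualifies everywhere.
* High-scoring trace intervals are delimited at half the maximum bin score
  of each representative (full-width-at-half-maximum). Mean-plus-two-SD
  variants fail exactly in the regime this analysis targets: when the only
  covered bins *are* the homologous segment, the threshold sits above every
  observation and nothing is reported.
* Interval similarity uses an alignment that is global in the shorter
  interval and local in the longer one. The best *local* alignment of two
  unrelated 100-mers is a short near-perfect word (identity ≈ 0.9), which
  would make the null indistinguishable from homology.
* Coverage percentages are rounded half away from zero to two decimals.
* Degenerate inputs: empty target sets and all-`N` queries produce empty
  hit tables; an element with no usable LTR errors; a saturated LTR pair
  (`p >= 0.75`) is flagged undated rather than extrapolated.

# The synthetic study design

`simConfig()` defaults describe the data the pipeline expects: three 3-Mb
chromosomes, one 600-kb centromere each at 45% of the chromosome (snapped
to the signal grid); five element families of 6 kb with 800-bp LTRs; the
CR family planted with strong centromere bias (30 centromeric, 3 outside)
plus 20 centromeric solo LTRs; four background families of 40 copies
placed uniformly. Ages are injected as independent per-site substitutions
at rate \(\mu T\) on each LTR, so the dating estimator is unbiased by
construction: the CR family is young (0.35 Mya — its copies are
homogeneous enough that a 376-bp probe window at a 3% mismatch cap counts
nearly all of them), one background family is old (2.46 Mya) for the
young/old dating contrast, and the satellite-founding fragment is aged
separately at 2.46 Mya: one 100-bp segment of the CR family's LTR,
amplified 50-fold per centromere with 2% per-copy mutation, so the origin
trace has an ancient source to recover. ChIP and Input are bin-level
Poisson counts (Input mean 30 per 1-kb bin; fold 5 over centromeres, 7.5
over centromeric CR-LTR bins, 1 elsewhere).

What the generator deliberately does **not** emulate: GC/isochore
structure, nested and truncated insertions, read-level sequencing noise
and mappability artifacts, recombination between elements, and
higher-order repeat structure in satellites. Passing recovery tests
therefore demonstrates correctness of the computations under the stated
statistical model, not robustness to every artifact of real assemblies.

# Problem sizes used by the test-suite

The recovery suites run 20 seeded replicates of the default configuration
(9 Mb of genome each) for each of: centromere boundary recovery (within
one 1-kb bin), top-1 CRI ranking of the planted family, young/old age
separation (mean ± 3 SD non-overlapping), satellite source-interval
recovery (≥ 80% positional overlap) and the random-monomer negative
control (no interval). Aligner correctness is checked against the
quadratic oracle on 50 randomized instances (queries ≤ 200 bp, targets
≤ 2 kb), and the bin scorer against per-position brute force on 50 random
hit sets. These sizes keep a full run at roughly a quarter hour on one
CPU while leaving the statistical margins of the recovery criteria wide.

# A short worked example

```{r example, eval = FALSE}
cfg <- simConfig()
sim <- simulateGenome(cfg, seed = 1)
tracks <- simulateChip(sim, seed = 2)

calls <- callCentromeres(ratioTrack(tracks$chip, tracks$input))
census <- censusFamilies(sim$annotations, calls, sim$family_consensus)
cand <- selectCandidates(census, sim$family_consensus, min_count = 25)
crs <- callCRs(sim$family_consensus[[cand[1]]], sim$elements, sim$genome)

rep_el <- sim$elements[sim$elements$element_id == crs$representative_id, ]
cltri <- computeCLTRI(rep_el, sim$genome, calls)

arrays <- detectTandemRepeats(sim$genome, regions = calls, max_period = 200)
ctr <- collectCTRs(arrays, calls, sim$genome)
ltrs <- extractLTRs(sim$elements[sim$elements$element_id %in% crs$cr_ids, ],
                    sim$genome)
reps <- clusterRepresentatives(clusterGreedy(ltrs$ltr5), ltrs$ltr5)
trace <- traceOrigin(reps, ctr)
coverageStats(trace)
```

# Known limitations

* The seeded aligner's absolute scores (and hence absolute \(S_b\) values)
  depend on its scoring scheme; profile *shapes* and derived statistics
  (CRI, interval positions, coverage percentages) are the meaningful
  outputs.
* Greedy clustering reproduces the longest-first strategy of the standard
  clustering tools with explicit tie-breaking; it does not guarantee
  optimal cluster count.
* The tandem-repeat detector targets planted-array recovery, not byte
  parity with external detectors; consensus sequences are reported up to
  rotation.
* Dating assumes the one-parameter substitution model and a single rate
  \(\mu\); saturation (`p >= 0.75`) is refused rather than modelled.
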