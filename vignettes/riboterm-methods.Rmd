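---
title: "riboterm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboterm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboterm)
```

This vignette records the models, parameter choices and numerical
conventions behind `riboterm`, in the spirit of a methods supplement: every
choice a user might want to question is stated here with its default and
its rationale.

## The measurement model

Ribosome profiling density at a nucleotide is proportional to ribosome
dwell time there. Around translation termination this licenses three
readouts:

1. **Stop-codon occupancy.** Slow release-factor action prolongs the
   terminating ribosome's dwell on the stop codon, raising footprint
   density there relative to the gene body. We summarise it with
   stop-aligned metagene profiles.
2. **Post-ORF occupancy (RPOR).** Ribosomes that fail to terminate
   continue into the intergenic region, in frame (readthrough) or after a
   ±1 shift, until the next in-frame stop. The ratio of post-ORF to ORF
   density approximates the fraction of ribosomes that read through.
3. **Density drops at post-ORF stops.** A genuine post-ORF translation
   extension ends at a stop codon in *some* frame; density collapses
   across exactly that codon. Post-ORF signal from other sources (RNA
   elements, downstream genes' initiation, unannotated ORFs) does not.

## Coordinates and conventions

* Internally all coordinates are **1-based closed**, the native
  R/Bioconductor convention (GRanges, Biostrings); GFF3 is read natively
  and BED (0-based half-open) is converted on input. One convention
  everywhere keeps strand handling testable: all gene-relative accessors
  return signal in the gene's 5′→3′ direction, so a minus-strand bug
  cannot hide behind a flipped window.
* **Offsets around the stop codon**: offset 0 is the first base of the
  stop codon; the metagene window is [−100, +60].
* **Post-ORF offsets**: offset 0 is the first base *after* the stop codon;
  the RPOR window is half-open [+20, +60) (40 nt), matching the package's
  half-open treatment of derived windows. Starting 20 nt out keeps the
  footprint of a ribosome paused on the stop codon itself out of the
  post-ORF signal.
* **Downstream gap**: the distance from the first base after a gene's
  stop codon to the nearest downstream annotated feature boundary in the
  direction of transcription. By default neighbours on *either* strand
  bound the gap — the conservative reading (smaller gaps, fewer eligible
  genes); `compute_gaps(..., same_strand = TRUE)` restricts to same-strand
  neighbours. Whether opposite-strand neighbours should count is genuinely
  open; both behaviours are exposed and neither is asserted as canonical.

## Density tracks

Reads are filtered to 20–40 nt (inclusive), at most 2 mismatches, unique
alignments. Centre mapping trims 10 nt from each side and spreads unit
weight uniformly over the remaining `length − 20` positions. Two details
are under-determined and resolved as follows:

* **20-mers** have trimmed width 0; annihilating them would silently drop
  an included read class, so they keep weight 1 at their midpoint
  (`discard_20mers` discards them instead).
* **Weighting inside the trimmed interval** is uniform; no alternative
  weighting is claimed.

Each retained read contributes total mass exactly 1, so track mass equals
the retained read count (asserted to 1e−9 in the tests). Per-million
normalization multiplies by 1e6 over the total weighted mass; the raw
depth is kept on the track so raw counts stay recoverable for count
gates. mRNA-seq uses full-read coverage (weight 1/length per covered
nucleotide) rather than centre mapping, since RNA fragments carry no
ribosome geometry.

## Metagene profiles

Each gene's raw window is normalized by its own mean over offsets
[−100, −70] — 31 nt, the symmetric inclusive reading of "70–100 nt
upstream", configurable — and the profile is the per-offset **median**
across genes. A gene enters only if (a) raw counts in the normalization
window reach `min_window_counts` (default 1) and (b) its downstream gap is
at least 50 nt; each filter is individually switchable (the count filter's
window is the normalization window; it can be widened to the full plot
window). A zero normalization-window mean marks the gene ineligible before
any division. Degenerate case: if no gene survives, the error names each
filter's attrition rather than returning an empty profile.

The scalar **stop occupancy** is the maximum of the median profile over
offsets [−2, +4], which captures the centre-mapped stop peak; a windowed
mean over the three stop-codon offsets is available
(`stop_occupancy(method = "mean")`). Which scalarization the field's
fold-change claims correspond to is not fixed; both are provided and the
default is the peak.

Replicates are combined as the per-offset mean of replicate medians with
standard error sd/√n across replicates.

## RPOR

`rpor = post_mean / orf_mean`, with `post_mean` the mean RPM/nt over the
[+20, +60) window and `orf_mean` the masked ORF mean (first and last 5
codons excluded, the same quantity that backs RPKM). Eligibility — gap
≥ 65 nt, footprint and mRNA ORF means ≥ 0.1 RPM/nt (full unmasked ORF,
inclusive bounds), no overlap with the next gene — uses unmasked means
because it gates on overall expression, while the RPOR denominator uses
the masked mean for consistency with gene-level quantification. Genes with
a zero ORF mean are dropped (ratio undefined); zero RPOR values are
removed before distribution comparison because a zero cannot distinguish
perfect termination from missing depth, and zeros inflate the K-S
statistic (with a reference sharing the positive part, D equals exactly
the zero fraction — a property test).

The K-S comparison uses the standard asymptotic two-sided two-sample test
(`stats::ks.test`, `exact = FALSE`), appropriate at the n ≈ 10^2–10^3 of
these analyses; the D statistic is checked against a brute-force
all-breakpoints ECDF scan to 1e−12.

## The recoding detector

The published practice this formalizes was manual annotation; automation
requires explicit cutoffs, so the following are package defaults, all
configurable, chosen to meet the synthetic sensitivity/specificity
targets (≥ 0.95 each at coverage ≥ 1 RPM/nt):

| parameter | default | meaning |
|---|---|---|
| `drop_threshold` | 0.3 | max post/pre density ratio to call a drop |
| `min_pre_density` | 0.2 RPM/nt | candidate pre-window mean required to score |
| `min_region_counts` | 10 raw counts | below this the gene is `unclassifiable` |
| `pre_window`, `post_window` | 30 nt | drop-score windows, clipped to the region |

Candidates are every TAA/TAG/TGA at every offset of the post-ORF sequence;
frame is offset mod 3 (0 → frame 0, 1 → +1, 2 → −1, so a −1 frameshift
lands on offsets ≡ 2 mod 3). The best candidate minimises the drop ratio,
ties broken towards the earliest offset — with a plateau ending cleanly,
every candidate beyond the true stop also scores ~0, and the earliest of
those *is* the true stop. A candidate whose post-window lies entirely
beyond the region is unscorable (NA), not a perfect drop; this prevents a
plateau running into the downstream gene from faking terminations at the
region edge.

Confounder flags: supplied interval sets (REP elements, sRNAs) that
intersect the region; signal abutting the downstream feature (mean over
the last 15 nt ≥ `min_pre_density`); a Shine–Dalgarno-like GGAGG (the
complement of the anti-SD CCUCC) within 15 nt upstream of a downstream
ATG/GTG; and the low-reads gate. A qualifying drop with flags is
`possible` rather than `likely`. A supplied feature covering every
high-signal position reclassifies the gene `misannotation-suspect`.
These flags operationalise annotation categories that were judgement
calls in practice; they are deliberately simple, flag-only heuristics.

Stop-codon enrichment among calls is Pearson's chi-squared (2 df,
two-tailed) against genome-wide stop frequencies, computed by default from
the annotated genes' stop codons (whether "genome-wide" should mean all
annotated genes or the analysis set is ambiguous; the helper takes
whichever table it is given).

## The simulator and its defaults

The generator emulates the features the estimators rely on; its defaults
are the package's study conditions and are fixed here, not tuned per
analysis:

| parameter | default | rationale |
|---|---|---|
| `n_genes` | 200 | desk-scale cohort |
| `orf_length` | 150–1500 nt | brackets typical bacterial ORFs; ≥150 hosts the metagene window |
| `gap_range` | 130–250 nt | hosts the 65-nt eligibility gap and a full planted extension |
| `stop_freqs` | 0.63/0.08/0.29 | E. coli K-12 stop-codon usage |
| `mean_coverage` | 2 RPM/nt | the RPOR-recovery operating point |
| `expr_sdlog` | 1 | ~1 order of magnitude IQR, bacterial dynamic range |
| `dwell_shape` | 4 (gamma, mean 1) | CV 0.5, the scale of codon-level dwell variation |
| `stop_pause` | 2 | a visible wild-type-like stop peak |
| `extension_offset` | 63 nt | a full extension spans the whole [+20, +60) window |
| `count_noise` | Poisson | sequencing-count noise |

Two calibration notes. First, the per-offset **median** is robust but
nonlinear: at stop-codon λ of only a few counts, the median of a Poisson
sits measurably below λ, and unequal pause factors are distorted by
different relative amounts, so fold-change recovery between conditions is
only faithful on well-covered genes. Metagene analyses are accordingly run
on well-expressed cohorts — exactly as the field restricts metagene
analysis to well-expressed genes — and the package's pause-recovery checks
simulate those cohorts at mean coverage 10 RPM/nt (300 genes per
condition). With that cohort the 5-vs-2 pause fold change is recovered
within 10%. Second, extensions plateau at `f × e` (readthrough fraction ×
gene expression) and terminate at the planted stop, which makes median
RPOR ≈ f the designed identity; at 2 RPM/nt and 200 genes it holds within
±20% relative (±0.02 absolute at f = 0), Poisson discreteness being the
limiting factor at f = 0.05.

Problem sizes used by the recovery checks: four 200-gene cohorts (RPOR),
two 300-gene cohorts (metagene), one 100-gene cohort (detector, evaluated
at the ≥ 1 RPM/nt operating point), and a 3600-nt two-ORF locus at
2 RPM/nt (frameshift, recovered within ±3 percentage points).

What the simulator does **not** emulate — and hence what passing tests do
not show about real data: nuclease sequence bias, codon-specific dwell
structure, translational coupling between genes, rho-dependent termination
of readthrough transcripts, RNA contamination peaks, or the genome-scale
situation where recoding calls require human judgement over heterogeneous
confounders. Recovery on synthetic cohorts validates the estimators'
arithmetic and operating points, not their field performance.

## Degenerate inputs and edge rules

* ORFs failing validation (length not a multiple of 3, no genuine stop)
  are excluded with a warning — real annotations contain pseudogenes; a
  feature outside its chromosome is a hard error naming it.
* An ORF too short to mask 10 codons falls back to unmasked RPKM and is
  flagged; the frameshift estimator always uses unmasked sub-ORF RPKMs
  because pre-shift ORFs are typically ~26 codons.
* `normalize_per_million` refuses an already-normalized or empty track.
* The last gene on a chromosome takes its gap to the sequence end.
* Wiggle output (per strand, variableStep span 1, nonzero positions only)
  round-trips exactly at its 15-significant-digit output precision.

## Pipeline determinism

`run_pipeline()` validates its configuration against the full default tree
(unknown keys are errors), stamps every output TSV with the package
version, seed and config MD5, and is byte-reproducible: identical config
and inputs give identical files. All simulator randomness flows from the
single seed.
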