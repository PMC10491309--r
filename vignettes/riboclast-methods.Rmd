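---
title: "riboclast: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboclast: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboclast)
```

# Scope

riboclast models what widespread endonucleolytic mRNA cleavage (RNase
L-like or RNase A-like) does to ribosome profiling and RNA-seq readouts,
and provides the analysis operations needed to recover its signatures:
altORF translation on cleavage fragments, relative-vs-absolute
expression changes under bulk decay, translational-efficiency (TE)
classification, and uORF-mediated initiation shifts. Everything is
validated against simulated ground truth; the same operations apply to
real data loaded from annotation + BED/BAM footprints + count tables.

# Coordinates and annotation

All positions are 0-based half-open in transcript coordinates. A
transcript is `[0, length)` with `utr5 = [0, cds_start)`,
`cds = [cds_start, cds_end)` (stop codon included) and
`utr3 = [cds_end, length)`; the three regions tile the transcript
exactly (`partitionRegions()`). T and U are equivalent everywhere.
Annotation enters via `loadAnnotation()` (transcript table or GTF with
FASTA; one isoform per gene, preferring MANE/RefSeq Select tags) or
`simulateTranscriptome()`. uORFs are intervals in the 5'UTR that may
overlap the CDS (ATF4-like); footprint positions in the overlap are
assigned to the UTR under the default `overlap_to_utr` policy, because
that is the convention for ATF4-style architecture; `overlap_to_cds` is
available. uORF calling itself uses `scanOrfs()` over the 5'UTR with
start codons AUG/CUG/GUG (near-cognate starts are first-class because
ISR-regulated uORFs use them) and a 2-codon minimum, a deliberately
permissive floor since single-codon "ORFs" carry no elongation signal.

# Generative model

`simulationConfig()` holds every parameter with its default; the
defaults are the study conditions, and all randomness flows from the
single `seed`.

## Transcriptome and abundance

`nGenes` genes with log-normal baseline abundance (`meanlog log(50)`,
`sdlog 1`); uniform random sequence with implanted main-ORF start/stop;
5'UTR length 60–300 nt, CDS 100–500 codons, 3'UTR 150–600 nt; 15% of
genes carry an AUG uORF (25% of those overlap the CDS); 1% are "MT-"
mitochondrial-named for the TE-classifier filter.

Per-condition copy numbers are **rounded expectations**, not draws:
`round(baseline)` for control, and
`round(baseline × (1 − globalLossFraction) × induction)` otherwise,
where induced genes (5% by default) get `inductionFactor` (20×) and
TE-shift genes get `teShiftInductionFactor`. Determinism here is what
makes a two-condition null *exchangeable by construction* — the only
differences between null replicates are the per-replicate sampling
noise, so p-value calibration tests are exact. Biological replicate
noise is log-normal per gene (`sd 0.1` log2) applied at read sampling,
fresh per replicate; fragment pools are built once per condition and
shared across its replicates.

## Cleavage and fragmentation

`cleavageModel()` defines motif weights: `rnasel_like` cuts 3' of
UU/UA dinucleotides, `rnasea_like` 3' of U/C. Each copy of each
transcript receives independent Bernoulli cuts at each motif site with
`perSiteProbability × weight / max(weight)`. Cuts partition the copy
into fragments — total fragment length equals transcript length exactly
(mass conservation, tested). Fragments then decay: each survives with
probability `fragmentSurvival` (0.2). `resistantGeneFraction` marks
genes immune to cleavage.

## Footprint emission

Loading units per condition:

- intact copies × TE on the main ORF (share `1 − p_uorf` for
  uORF-bearing genes),
- intact copies × TE × `p_uorf` on each uORF (split equally when a
  transcript has several),
- surviving 3' fragments that contain CDS or 3'UTR sequence
  (`start > 0`, `end > cds_start`) re-initiate with probability
  `pFragmentReinitiation` on their **first available ORF** (first
  AUG/CUG/GUG at/after the fragment start, running to the first in-frame
  stop or the last complete codon before the fragment end).

Each unit's sampling weight carries a factor of its **ORF length**: at
steady state the number of elongating ribosomes (hence footprints) on an
ORF is initiation flux × transit time. This matters: it is why a uORF
(~20 codons) yields far fewer footprints than a main ORF (~300 codons)
at equal initiation rates, and why fragment ORFs in 5'UTRs — short, but
numerous once cleavage is active — can still dominate the 5'UTR signal.

P-sites are placed at in-frame codon positions with frame weights
(0.70, 0.15, 0.15); a `stallFraction` (0.2) of footprints from truncated
fragment ORFs sits at the last complete codon before the cut. Read 5'
ends are `P-site − psiteOffset` (12 nt), read lengths 26–32 centered on
29, plus a 1% positionally uniform background per transcript. RNA-seq
counts are multinomial over CDS nucleotide mass (intact copies
contribute full CDS length; fragments their CDS overlap).

# Analysis operations

- `assignPsites()` shifts read 5' ends by the offset, discarding reads
  whose P-site falls off the transcript; `calibratePsiteOffset()`
  recovers the offset from start-codon meta-profiles (≥100 reads
  required; flat profiles tie-break to 12 with a low-confidence flag).
- `countRegions()` / `toRpm()` produce a `RegionCountMatrix`
  (a `SummarizedExperiment` with utr5/cds/utr3/uorf assays).
- `utrOrfRatio()` computes per-gene or aggregate UTR:ORF ratios; the
  aggregate is Σ UTR / Σ CDS over genes with CDS rpm ≥ `minCdsRpm`
  (default 1), so it is a library-level quantity robust to per-gene
  zeros.
- `metageneProfile()` averages per-gene density normalized by mean CDS
  density with **equal gene weights** (a deep gene cannot dominate the
  profile), anchored at the start codon or at `cds_end − 3` (stop).
- `differentialExpression()` is a transparent stand-in for count-model
  DE: median-of-ratios size factors (`computeSizeFactors()`), Welch t on
  log2(normalized + 0.5), BH adjustment (`bhAdjust()`), flags at
  padj < 0.05 and |log2FC| > 1. `importExternalDE()` adapts tables from
  count-model tools.
- `classifyTEChanges()` applies the stringent gates: considered when
  |log2FC| > 4 and padj < 0.01 in either assay with base mean > 50 in
  both; `te_up`/`te_down` when footprint and RNA fold changes differ by
  >2-fold; mitochondrial (MT-) genes filtered.
- `detectUorfPeaks()` scores 9-nt windows around 5'UTR start codons
  against local background; `utr5MainShift()` computes per-gene
  5'UTR:CDS rpm ratios and the treated/control log2 shift (genes with
  any zero CDS rpm are excluded and reported).
- `runPipeline()` orchestrates everything from one YAML/list config and
  writes TSVs plus a summary JSON; `inst/scripts/riboclast.R` is the CLI.

# Modeling decisions and caveats

- **Literal stringent gates.** The TE gates (log2FC > 4, padj < 0.01,
  base mean > 50) come from the source methodology and are kept literal,
  with the base-mean gate applied in both assays. They are intentionally
  conservative; under them, recovering injected ±2 log2 TE shifts
  requires the shifted genes to also be transcriptionally co-induced
  (the motivating biological case: ~32-fold induced stress genes), which
  `teShiftInductionFactor` provides.
- **TE validation is run cleavage-free.** Active cleavage genuinely
  decouples footprint from RNA counts (fragment translation), so
  apparent TE calls under cleavage are a *modeled confounder*, not an
  estimator bug. The TE-recovery property is therefore tested with
  cleavage disabled; the README shows the confounded case explicitly.
- **uORF shift attenuation is a model consequence, not a tuning.** With
  length-proportional emission, intact uORF initiation at `p_uorf = 0.2`
  produces a tiny 5'UTR:CDS read ratio (~short uORF / long CDS), while
  fragments cut in the 5'UTR initiate on short UTR ORFs whose reads are
  mostly 5'UTR — their ratio is an order of magnitude higher. Enabling
  fragment re-initiation therefore attenuates the negative
  eIF2α-P-style shift for any cleavage probability > 0; tests use a
  moderate probability (0.008) so one simulation resolves the effect
  above replicate noise while intact initiation still dominates.
- **Deterministic abundances + shared pools** trade a source of
  biological realism (Poisson copy-number noise) for exact null
  exchangeability, which the calibration tests require.
- **The DE stand-in is not DESeq2.** Welch t on log2 counts is
  transparent and adequate at simulated depths; real analyses should
  import count-model results via `importExternalDE()`.

# Session info

```{r}
sessionInfo()
```
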