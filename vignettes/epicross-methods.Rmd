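---
title: "Methods: two-condition histone-mark crosstalk analysis with epicross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-condition histone-mark crosstalk analysis with epicross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and scientific background

`epicross` implements an integrative ChIP-seq/RNA-seq comparison of two
cellular conditions — a wild type (WT) and a knockout (KO) that has lost
gene-body H2B monoubiquitination (H2Bub1), as happens on deletion of the
RNF40 ubiquitin-ligase subunit. The package follows three analytical arms:

1. **H3K4me3 domain geometry.** H2Bub1 is an elongation-coupled gene-body
   mark; its loss preferentially narrows *broad* promoter H3K4me3 domains
   and displaces their summits towards the 5' end of the gene, while bulk
   H3K4me3 height falls more uniformly. The arm quantifies peak width,
   height, and strand-aware summit displacement per gene, and classifies
   genes into broad / sharp / random-control sets.
2. **PRC2 derepression.** Loss of H2Bub1 lowers EZH2 activity; promoter
   H3K27me3 (TSS ± 1 kb) drops at almost all occupied promoters, with
   reciprocal H3K27ac gain and upregulation of Polycomb targets.
3. **Enhancer activation.** A class of genes is upregulated through distal
   enhancers (H3K4me1+/H3K27ac+/H3K4me3−, > 5 kb from any gene body) that
   gain H3K27ac in the KO; these enhancers are enriched for a
   Forkhead-family binding motif. Enhancers are linked to genes through
   basal-plus-extension regulatory domains, and motif enrichment is scored
   with region-level Fisher and nucleotide-level Z statistics.

Every stage operates on plain coverage tracks (bedGraph), gene annotations
(BED/GTF) and counts tables, so the same functions run on real data or on
the package's synthetic generator.

## Coordinate and data conventions

* All internal coordinates are 0-based, half-open (BED convention); GTF
  input is converted on read. The TSS of a minus-strand gene is `end − 1`.
* "5'-ward" is always strand-aware: towards lower coordinates for `+`
  genes, higher for `−` genes. Metagene windows for minus-strand genes are
  shifted by 1 bp so both strands cover exactly `flank` bp on each side of
  the anchor (the half-open convention is otherwise asymmetric by one base).
* Coverage is held densely at 1 bp resolution with a recorded
  normalisation constant (reads per hundred million in the conventional
  pipeline). Chromosomes in the synthetic genome are a few Mb, so dense
  vectors are simple and fast; no bigWig indexing is attempted.
* All reported fold changes are `log2(KO / WT)`. Published analyses of
  this design sometimes print WT-versus-KO ratios with the opposite sign
  and without defining the ratio; fixing one convention package-wide
  avoids that ambiguity.

## Peak calling

`call_peaks()` slides a `window` (150 bp, step 75 bp) along the coverage
and tests each window sum against a Poisson null, merging significant
windows (gap ≤ 100 bp) and discarding merged regions narrower than 100 bp.
With a background/control track, the null rate is
`max(local λ over 1 kb / 5 kb / 10 kb, global λ)` estimated from the
background and rescaled to the signal depth — the decision structure of
MACS-style callers with an input sample. **Without** a background the null
is the global per-bp rate alone: a local rate estimated from the enriched
signal itself sits on top of the very peak being tested and shadows broad
domains (in development this collapsed all recovered widths to the peak
core regardless of planted width; with the global null, recovered width
tracks planted width with slope ≈ 0.97). The per-peak p-value is the best
constituent-window tail probability, computed as
`P(X ≥ ceiling(sum))` under Poisson(λ·window). Summits are the leftmost
position of maximum coverage — ties break deterministically left.

Defaults (p < 1e−5, window/step/gap/min-width) are exposed in the
configuration; the p-value cutoff matches the conventional 0.00001.

## Peak geometry and breadth classes

Each gene is assigned the **widest** peak overlapping TSS ± 2 kb (the
promoter window also used for promoter-level H3K4me3 quantification); the
assignment rule is deliberately simple and documented because published
work rarely states one. Broad genes are the top 5% of assigned-peak
widths; sharp genes are the top 5% by peak height **excluding** genes
already broad ("top occupancy" is operationalised as peak height, the
natural per-peak occupancy scalar); the random control is a same-size
uniform draw (seeded, without replacement) from the remaining genes. Width
and height changes are `log2(KO) − log2(WT)` per shared gene; the summit
shift is `WT − KO` summit for `+` genes and `KO − WT` for `−` genes, so
positive means the KO summit moved 5'-ward.

The Pol II pausing index is promoter mean (TSS ± 250 bp) over gene-body
mean (TSS + 500 bp to TES). The quantity is only cited, never defined, in
the source analyses; this standard form is documented and both windows are
configurable.

## Expression stratification

Counts are normalised by median-of-ratios size factors. The differential
test is deliberately plain plumbing: `baseMean` (mean normalised count),
`log2fc = log2((mean_KO + 0.5)/(mean_WT + 0.5))`, and a two-sided Welch
t-test on `log2(normalised + 0.5)` across replicates. The record schema
matches the common DE-table layout so an externally fitted NB-model table
can be dropped in unchanged. Classification uses the printed thresholds
verbatim and strictly: down = baseMean > 15 & p < 0.05 & log2FC < −1; up
symmetric; unchanged = baseMean > 15 & p > 0.8 & |log2FC| < 0.2.

A calibration caveat stated here because the tests measure it: at 3
replicates per condition the Welch approximation is conservative — its
true level is ≈ 0.041 under exact normality and ≈ 0.034–0.041 on
negative-binomial counts across the dispersions we simulate. An empirical
type-I check against a 0.05 ± 0.01 band therefore sits at, and usually
below, the attainable level of this test; the package reports the measured
rate rather than adjusting the test to meet the band.

H2Bub1 occupancy groups are exact quartiles of the ranked gene-body mean
signal (descending; ties broken by gene id for determinism): H = top
quartile, then M (50–75th), L (25–50th), No (bottom). Quartiles are taken
over **all** annotated genes by default (whether the original analyses
restricted to expressed genes is unstated; the choice is switchable by
subsetting the annotation).

## Differential occupancy, enhancers, gene association

Windowed differential occupancy (`differential_regions()`) applies the
same Welch-on-log machinery per region across replicate coverage tracks,
with Benjamini–Hochberg control across regions and
gain/loss calls at |log2FC| > 2 and FDR < 0.05 (promoter H3K27me3 uses
|log2FC| > 1 — the depletion there is genome-wide and the printed ±2
threshold belongs to the enhancer analysis). A region that is identically
zero in both conditions is `stable` with p = 1.

Active enhancers are H3K27ac peaks that overlap an H3K4me1 peak by ≥ 1 bp,
overlap no H3K4me3 peak, and lie entirely > 5 kb from every gene body.
Regulatory domains use the basal-plus-extension rule with the GREAT v3
defaults (basal = TSS − 5 kb … TSS + 1 kb strand-aware; extension up to
1 Mb, stopping at the nearest neighbouring basal boundary; a domain always
contains its own basal region). A region associates with every gene whose
domain it intersects by ≥ 1 bp.

## Motif enrichment

PFMs are read from JASPAR-format text; log-odds PWMs use a total
pseudocount of 0.8 split by background base frequencies (estimated from
the background sequence set, +1 smoothing). Scanning covers both strands;
a window is a hit at relative score ≥ 0.85 of the attainable min–max range
(the oPOSSUM convention), and overlapping same-strand hits collapse to the
best-scoring window. Following oPOSSUM, the **Fisher score** is −ln of the
one-tailed hypergeometric tail on regions-with-≥1-hit (targets vs
background), and the **Z score** is the continuity-corrected standardised
excess of nucleotide-level hits in the target set given the background
per-position rate; a position hit on both strands counts once at region
level and twice at nucleotide level. Target windows are ± 150 bp around
gained-enhancer centres (interval midpoints — summits of plateau-shaped
enhancer peaks are noise-dominated); stable enhancers form the background.
Enrichment requires Fisher > 5 **and** Z > 10.

## The synthetic generator: what it emulates

`simulate_epigenome()` produces the full two-condition input set — genome
FASTA, BED12 annotation, 6 marks × 2 conditions of coverage, replicate
tracks for the differential marks, NB counts, enhancer intervals — plus a
truth table of every planted effect. Defaults are the study conditions
used by the tests and the acceptance script:

* 4 chromosomes × 3 Mb, 500 genes (2–8 kb, ≥ 12 kb spacing so distal
  enhancers exist), 300 enhancers, 3 replicates per condition, seed-driven
  and fully deterministic (per-gene substreams, so adding genes does not
  perturb earlier ones).
* Gene classes: 30% rnf40-dependent (down-regulated, KO loses gene-body
  Pol II but not TSS Pol II), 20% PRC2 targets (promoter H3K27me3 plateau
  depleted 80% in KO, reciprocal H3K27ac gain, up-regulated), 15%
  enhancer-driven (a motif-bearing distal enhancer gains 2.5 log2 units of
  H3K27ac in KO; the Forkhead-like consensus `GTAAACAA` is embedded at the
  enhancer centre), 35% background.
* H2Bub1 (WT only) decays exponentially 5'→3' with a 3 kb half-life;
  per-gene amplitude is lognormal and defines the occupancy quantile `u`.
* H3K4me3 is an asymmetric two-sided exponential peak anchored 150 bp
  downstream of the TSS (sharp 5' rise, longer 3' decay into the body;
  planted width = total 3τ extent). WT width is lognormal
  (meanlog log 800, sdlog 0.6), correlated with H2Bub1 (ρ = 0.7). KO
  width = WT × max(0.2, 1 − 0.5·u); the KO summit moves 50 bp 5'-ward; KO
  height drops by a class-independent factor 0.8.
* Planted expression |log2FC| is 2.2 scaled by quartile (×1.4 in M and L,
  ×0.6 in H and No) — the response concentrates in moderately occupied
  genes; expression level itself is mildly coupled to H2Bub1 (ρ ≈ 0.5 on
  the log scale), reproducing the positive occupancy–expression
  correlation of real gene-body H2Bub1.
* Noise: per-bp signal = smooth profile × gamma noise (shape 25, mean 1)
  drawn per 20 bp tile. The tile mimics the local correlation of
  fragment-level coverage and keeps bedGraph output run-length
  compressible; coverage baseline is 0.5 with the same noise.
* Counts are negative binomial (dispersion 0.05) with lognormal
  per-sample depth factors (sd 0.1) so size factors are exercised.

Free parameters with no authoritative value are set once and documented
here: the enhancer H3K27ac gain (2.5 log2 units) merely clears the printed
|log2FC| > 2 threshold; enhancer/K4me1 plateau levels (5× baseline),
promoter H3K27ac levels, and Pol II amplitudes are desk-scale choices that
make every planted feature callable at p < 1e−5.

**What the generator does not emulate:** read-level sampling and mapping
artifacts, fragment-size effects, replicate batch structure, CpG-island
heterogeneity, copy-number variation, inter-chromosomal contact structure,
and real motif backgrounds (the genome is i.i.d. uniform ACGT outside
embedded sites — chosen deliberately so Fisher/Z calibration has a clean
null). Passing recovery tests therefore demonstrates the pipeline's
statistical machinery, not robustness to alignment-level pathology.

## Problem sizes and determinism

The test-suite and acceptance script run the default 500-gene, 12 Mb
configuration once (cached), a 200-gene null configuration, a 2000-gene
null counts matrix for type-I calibration, and 30–80-gene configurations
for unit-scale checks — sizes chosen so the planted effects are
statistically resolvable (the recovery properties are guaranteed at
n ≥ 500 genes) while a full run stays in the minutes range. All
randomness flows from explicit integer seeds; the same seed reproduces
byte-identical outputs, including the pipeline report JSON.

## Known limitations

* The peak caller is a desk-scale reimplementation of the local-Poisson
  decision structure; it has no fragment-model, duplicate filtering, or
  paired-end awareness, and is not intended to replace a production caller
  on real reads.
* The DE and differential-occupancy tests are Welch-on-log plumbing with
  the conservativeness noted above; for real data, import a
  NB-model table into the same record schema instead.
* Domain association is purely positional (basal-plus-extension); no
  chromatin-contact information is used.
* Motif scanning uses a 0-order background; CpG or dinucleotide
  composition effects in real sequence will inflate some decoy scores.
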