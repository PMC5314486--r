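# epicross

Integrative two-condition ChIP-seq/RNA-seq analysis of histone-mark
crosstalk, centred on the coupling between gene-body H2B
monoubiquitination (H2Bub1) and promoter H3K4me3 domain geometry.

## The problem

Loss of H2Bub1 (e.g. on deletion of the RNF40 ligase subunit) reshapes the
promoter chromatin landscape in three distinguishable ways:

1. **H3K4me3 domains narrow, and their summits shift 5'-ward.** The genes
   most dependent on H2Bub1 carry *broad* H3K4me3 domains (top 5% of peak
   widths); on H2Bub1 loss their width shrinks far more than their height,
   and peak summits move ~50 bp towards the 5' end of the gene.
2. **PRC2 output collapses.** Promoter H3K27me3 (TSS ± 1 kb) falls at
   nearly all occupied promoters, derepressing Polycomb targets.
3. **Distal enhancers activate.** A set of upregulated genes is explained
   not by promoter marks but by distal enhancers
   (H3K4me1⁺/H3K27ac⁺/H3K4me3⁻, > 5 kb from gene bodies) that gain
   H3K27ac and are enriched for a Forkhead-family motif.

`epicross` implements the full pipeline for all three arms — coverage and
annotation I/O; a windowed local-Poisson peak caller; peak
width/height/summit statistics with broad/sharp/random classification and
strand-aware summit-shift estimation (`shift = WT − KO` summit on `+`
genes, `KO − WT` on `−`, positive = KO 5'-ward); median-of-ratios
normalisation and threshold-based DE classification (baseMean > 15,
p < 0.05, |log₂FC| > 1); H2Bub1 occupancy quartiles (H/M/L/No) and
quartile-wise |log₂FC| response with Wilcoxon–Mann–Whitney tests; windowed
differential occupancy with Benjamini–Hochberg control (gain/loss at
|log₂FC| > 2, FDR < 0.05); combinatorial active-enhancer calling;
GREAT-style basal-plus-extension gene association (5 kb/1 kb basal, 1 Mb
extension); and PWM motif scanning with oPOSSUM-style region-level Fisher
(−ln hypergeometric tail) and nucleotide-level Z scores, enriched at
Fisher > 5 ∧ Z > 10. All fold changes are log₂(KO/WT).

Because the corresponding sequencing data are not redistributable, the
package ships a first-class synthetic generator
(`simulate_epigenome()`) that plants every effect above — with a truth
table — so each stage is verifiable offline by parameter recovery. See
`vignettes/epicross-methods.Rmd` for the model and every default.

## Worked example

The numbered drivers under `analysis/` run the three arms on the default
synthetic study (500 genes, 4 × 3 Mb chromosomes, 300 enhancers, 3
replicates per condition, seed 101) and write their tables under
`results/`. `Rscript analysis/03_peak_geometry.R` prints:

```
H3K4me3 peaks: WT=500 KO=500
median summit shift (positive = KO 5'-ward): 50 bp over 500 genes (planted 50 bp)
            label     n mean_d_log2_width mean_d_log2_height
1:          other   429        -0.3401013         -0.3275580
2: random_control    25        -0.2755828         -0.4701276
3:          broad    25        -0.8335273         -0.2681657
4:          sharp    21        -0.2653846         -0.4213906
broad vs sharp width narrowing, one-sided Wilcoxon p = 3.57e-08
median Pol II pausing index on rnf40-dependent genes: WT=2.58 KO=4.4
```

i.e. the planted 50 bp 5'-ward summit shift is recovered exactly at the
median; broad domains narrow ~3× more than sharp or random classes
(mean Δlog₂ width −0.83 vs −0.27) while height changes stay class-uniform
— the breadth-specific signature. `analysis/02_expression_stratify.R`
shows the expression side:

```
DE classes: up=142 down=129 unchanged=33 none=196
median |log2FC| by H2Bub1 quartile: H 1.1, M 2.43, L 2.76, No 1.14
Pearson r, H2Bub1 gene-body signal vs log2 expression: 0.223 (n=500)
planted rnf40-dependent genes recovered as 'down': 86%
```

(moderately occupied M/L genes respond most), and
`analysis/04_differential_occupancy.R` / `05_motif_enrichment.R` close the
enhancer arm: 100/100 occupied promoters lose H3K27me3; 300 active
enhancers, 75 gaining H3K27ac in the KO; 100% of planted enhancer-target
up-genes recovered by domain association; and the planted Forkhead-like
motif tops the 24-motif demo panel (Fisher 86.1, Z 18.3) as the only
enrichment call.

The same stages are exposed as one call over a configuration object:

```r
library(epicross)
report <- run_pipeline(pipeline_config(simulate = sim_config(seed = 101L)))
report$geometry$median_summit_shift   # 50
```

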