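#!/usr/bin/env Rscript

# Differential-occupancy arm: promoter H3K27me3 (TSS +/- 1 kb) loss in the
# KO, combinatorial active-enhancer calling (K27ac+ K4me1+ K4me3-, > 5 kb
# from gene bodies), enhancer H3K27ac differential occupancy (|log2FC| > 2,
# FDR < 0.05), basal-plus-extension gene association, and the Venn-style
# fractions of up/down genes explained by promoter marks or enhancers.

suppressMessages(library(epicross))
library(data.table)

dir.create("results", showWarnings = FALSE)
sim <- simulate_epigenome(sim_config(seed = 101L))
ann <- sim$annotation

## promoter H3K27me3
tsspos <- gene_tss(ann)
prom <- data.frame(chrom = ann$genes$chrom, start = pmax(tsspos - 1000, 0),
                   end = tsspos + 1000, gene_id = ann$genes$gene_id)
wt_m <- sapply(sim$replicate_tracks$H3K27me3$WT, region_signal, regions = prom)
ko_m <- sapply(sim$replicate_tracks$H3K27me3$KO, region_signal, regions = prom)
prom_diff <- differential_regions(wt_m, ko_m, regions = prom,
                                  lfc_threshold = 1)
occupied <- prom_diff$mean_wt > 4
message("H3K27me3-occupied promoters: ", sum(occupied), "; losing in KO: ",
        sum(occupied & prom_diff$status == "loss"), " (",
        round(100 * mean(prom_diff$status[occupied] == "loss"), 1), "%)")
fwrite(prom_diff, "results/promoter_h3k27me3_diff.tsv", sep = "\t")

## active enhancers and H3K27ac differential
k27ac_pk <- call_peaks(sim$tracks$H3K27ac$WT)
k4me1_pk <- call_peaks(sim$tracks$H3K4me1$WT)
k4me3_pk <- call_peaks(sim$tracks$H3K4me3$WT)
enh <- call_active_enhancers(k27ac_pk, k4me1_pk, k4me3_pk, ann)
active <- enh[enh$active, , drop = FALSE]
message("H3K27ac candidates: ", nrow(enh), "; active enhancers: ",
        nrow(active))
wt_e <- sapply(sim$replicate_tracks$H3K27ac$WT, region_signal, regions = active)
ko_e <- sapply(sim$replicate_tracks$H3K27ac$KO, region_signal, regions = active)
enh_diff <- differential_regions(wt_e, ko_e, regions = active)
message("enhancers gaining H3K27ac in KO: ", sum(enh_diff$status == "gain"),
        "; losing: ", sum(enh_diff$status == "loss"))
fwrite(enh_diff, "results/enhancer_h3k27ac_diff.tsv", sep = "\t")

## gene association and fractions
domains <- regulatory_domains(ann)
assoc <- associate_regions(enh_diff[enh_diff$status == "gain", ], domains)
gain_genes <- unique(unlist(assoc$region_to_genes))
de <- classify_genes(differential_expression(sim$counts, sim$condition))
ov <- overlap_summary(de$gene_id[de$class == "up"], gain_genes,
                      "up genes with gained enhancer")
message(ov$label, ": ", ov$n_intersect, "/", ov$n_a, " (",
        round(ov$pct, 1), "%)")
fr <- fraction_report(de, tss_genes <- assign_tss_peak(k4me3_pk, ann)$gene_id,
                      list(gain = gain_genes, loss = character(0)))
jsonlite::write_json(fr, "results/fraction_report.json", auto_unbox = TRUE,
                     pretty = TRUE, digits = 4)

tr <- sim$truth$genes
up_fox <- intersect(de$gene_id[de$class == "up"],
                    tr$gene_id[tr$class == "foxl2_target"])
message("planted enhancer-target up genes recovered via association: ",
        round(100 * length(intersect(up_fox, gain_genes)) /
                max(1, length(up_fox)), 1), "%")
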