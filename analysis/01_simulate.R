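#!/usr/bin/env Rscript

# Generate the two-condition (WT vs KO) synthetic epigenome used throughout
# the analysis: H2Bub1-graded gene bodies, TSS-anchored H3K4me3 domains that
# narrow and shift 5'-ward in the KO, PRC2-target promoters that lose
# H3K27me3, distal enhancers (a subset motif-bearing and H3K27ac-activated),
# and NB expression counts. Writes the ground truth and compact inputs under
# results/; the full coverage bundle of a down-scaled genome goes to
# scratch/ for browsing.

suppressMessages(library(epicross))
library(data.table)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 101L)
message("simulating: ", cfg$n_genes, " genes on ", cfg$n_chroms, " x ",
        cfg$chrom_len / 1e6, " Mb chromosomes, ", cfg$n_enhancers,
        " enhancers, ", cfg$n_replicates, " replicates/condition")
sim <- simulate_epigenome(cfg)

message("gene classes: ",
        paste(names(table(sim$truth$genes$class)),
              table(sim$truth$genes$class), collapse = ", "))
message("motif-bearing enhancers: ", sum(sim$enhancers$has_motif), " of ",
        nrow(sim$enhancers))

fwrite(sim$truth$genes, "results/truth_genes.tsv", sep = "\t")
fwrite(sim$enhancers, "results/enhancers.tsv", sep = "\t")
counts <- data.table(gene_id = rownames(sim$counts))
for (s in colnames(sim$counts)) counts[[s]] <- sim$counts[, s]
fwrite(counts, "results/counts.tsv", sep = "\t")
write_annotation_bed(sim$annotation, "results/genes.bed")

# a small browsable bundle (full bedGraph tracks) from a reduced genome
small <- simulate_epigenome(sim_config(n_chroms = 1L, chrom_len = 8e5,
                                       n_genes = 30L, n_enhancers = 10L,
                                       seed = 101L))
write_bundle(small, "scratch/bundle_small")
message("wrote results/truth_genes.tsv, counts.tsv, enhancers.tsv, ",
        "genes.bed and scratch/bundle_small/")
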