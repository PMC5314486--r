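#' Pipeline configuration
#'
#' Bundles the inputs (either a [sim_config()] to simulate from, or a list
#' of file paths) with every stage threshold. Thresholds default to the
#' conventional printed values: MACS-style peak p-value 1e-5; DE thresholds
#' baseMean > 15, p < 0.05, |log2FC| > 1 (unchanged: p > 0.8, |log2FC| <
#' 0.2); top-5% breadth classes; enhancer differential |log2FC| > 2 at
#' FDR < 0.05; 5 kb distal margin; basal-plus-extension domains 5 kb/1 kb/1
#' Mb; oPOSSUM-style motif scanning at relative score 0.85 with Fisher > 5
#' and Z > 10. All reported fold changes are KO over WT.
#'
#' @param simulate A `sim_config`, or NULL to read `inputs` from disk.
#' @param inputs Named list of paths (`annotation`, `counts`; used when
#'   `simulate` is NULL).
#' @param peak_p_cutoff,tss_window,breadth_top_frac Peak-geometry stage.
#' @param de_base_mean_min,de_p_max,de_lfc_min DE classification.
#' @param promoter_halfwidth,promoter_lfc_threshold Promoter differential
#'   windows (H3K27me3 at TSS +/- 1 kb).
#' @param enhancer_lfc_threshold,fdr_threshold Enhancer differential.
#' @param distal_margin Active-enhancer distal rule (bp).
#' @param basal_up,basal_down,extension_max Regulatory-domain parameters.
#' @param motif_half_width,motif_rel_score,fisher_cutoff,z_cutoff Motif
#'   stage.
#' @param pfm_path JASPAR PFM file; defaults to the bundled synthetic demo
#'   panel.
#' @param seed Seed for the random-control breadth class.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = sim_config(), inputs = NULL,
                            peak_p_cutoff = 1e-5, tss_window = 2000L,
                            breadth_top_frac = 0.05,
                            de_base_mean_min = 15, de_p_max = 0.05,
                            de_lfc_min = 1,
                            promoter_halfwidth = 1000L,
                            promoter_lfc_threshold = 1,
                            enhancer_lfc_threshold = 2,
                            fdr_threshold = 0.05,
                            distal_margin = 5000L,
                            basal_up = 5000L, basal_down = 1000L,
                            extension_max = 1e6,
                            motif_half_width = 150L, motif_rel_score = 0.85,
                            fisher_cutoff = 5, z_cutoff = 10,
                            pfm_path = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$pfm_path))
    cfg$pfm_path <- system.file("extdata", "motifs_demo.jaspar",
                                package = "epicross")
  structure(cfg, class = "pipeline_config")
}

load_pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) return(simulate_epigenome(cfg$simulate))
  inp <- cfg$inputs
  for (need in c("annotation", "counts")) {
    if (is.null(inp[[need]]))
      stop("pipeline input '", need, "' missing and no simulate block present")
    if (!file.exists(inp[[need]]))
      stop("pipeline input '", need, "' not found: ", inp[[need]])
  }
  annotation <- read_annotation(inp$annotation, format = "bed12")
  counts <- read_counts(inp$counts)
  condition <- stats::setNames(
    ifelse(grepl("^KO", colnames(counts)), "KO", "WT"), colnames(counts))
  tracks <- NULL
  if (!is.null(inp$tracks)) {
    tracks <- lapply(inp$tracks, function(by_cond)
      lapply(by_cond, read_coverage,
             chrom_sizes = annotation$chrom_sizes))
  }
  list(config = NULL, annotation = annotation, genome = NULL,
       tracks = tracks, replicate_tracks = NULL, counts = counts,
       condition = condition, enhancers = NULL, truth = NULL)
}

region_replicate_matrix <- function(rep_tracks, regions) {
  do.call(cbind, lapply(rep_tracks, region_signal, regions = regions))
}

#' Run the full integrative pipeline
#'
#' Executes the three analytical arms on simulated (or loaded) inputs:
#' (1) H3K4me3 peak geometry — peak calling in both conditions, TSS
#' assignment, broad/sharp/random classification, summit shift and log2
#' width/height changes — together with expression stratification by H2Bub1
#' occupancy quartile; (2) promoter H3K27me3 differential occupancy;
#' (3) active-enhancer calling, enhancer H3K27ac differential occupancy,
#' regulatory-domain gene association and motif enrichment. Stages that
#' need inputs the path-based mode does not supply (coverage replicates,
#' genome sequence) are reported as skipped.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional directory for `report.json`, `report.txt` and
#'   stage tables.
#' @return The report as a list (also written to `out_dir` when given).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dat <- load_pipeline_inputs(cfg)
  ann <- dat$annotation
  report <- list(parameters = cfg[setdiff(names(cfg), c("simulate", "inputs"))])
  report$parameters$simulated <- !is.null(cfg$simulate)

  ## ---- expression stratification ----------------------------------------
  de <- classify_genes(differential_expression(dat$counts, dat$condition),
                       base_mean_min = cfg$de_base_mean_min,
                       p_max = cfg$de_p_max, lfc_min = cfg$de_lfc_min)
  up_genes <- de$gene_id[de$class == "up"]
  down_genes <- de$gene_id[de$class == "down"]
  report$expression <- list(
    n_genes = nrow(de), n_up = length(up_genes), n_down = length(down_genes),
    n_unchanged = sum(de$class == "unchanged"))
  if (!is.null(dat$tracks$H2Bub1$WT)) {
    groups <- occupancy_groups(dat$tracks$H2Bub1$WT, ann)
    gr <- group_response(groups, de)
    occ <- stats::setNames(groups$signal, groups$gene_id)
    corr <- correlate(occ[de$gene_id], abs(de$log2fc))
    report$stratify <- list(
      group_median_abs_log2fc = stats::setNames(gr$summary$median,
                                                gr$summary$group),
      group_tests = gr$tests,
      occupancy_abs_lfc_pearson_r = corr$r)
  }

  ## ---- H3K4me3 peak geometry ---------------------------------------------
  if (!is.null(dat$tracks$H3K4me3$WT)) {
    pk_wt <- call_peaks(dat$tracks$H3K4me3$WT, p_cutoff = cfg$peak_p_cutoff)
    pk_ko <- call_peaks(dat$tracks$H3K4me3$KO, p_cutoff = cfg$peak_p_cutoff)
    tss_wt <- assign_tss_peak(pk_wt, ann, window = cfg$tss_window)
    tss_ko <- assign_tss_peak(pk_ko, ann, window = cfg$tss_window)
    breadth <- classify_breadth(tss_wt, top_frac = cfg$breadth_top_frac,
                                seed = cfg$seed)
    shift <- summit_shift(tss_wt, tss_ko, ann)
    geom <- geometry_change(tss_wt, tss_ko)
    lab <- stats::setNames(breadth$label, breadth$gene_id)[geom$gene_id]
    by_class <- split(geom, lab)
    report$geometry <- list(
      n_peaks_wt = nrow(pk_wt), n_peaks_ko = nrow(pk_ko),
      n_tss_assigned_wt = nrow(tss_wt),
      median_summit_shift = shift$median,
      n_shift_excluded = shift$n_excluded,
      mean_d_log2_width_by_class =
        vapply(by_class, function(d) mean(d$d_log2_width), numeric(1)),
      mean_d_log2_height_by_class =
        vapply(by_class, function(d) mean(d$d_log2_height), numeric(1)))
    report$breadth_counts <- as.list(table(breadth$label))
  }

  ## ---- promoter H3K27me3 differential ------------------------------------
  if (!is.null(dat$replicate_tracks$H3K27me3)) {
    tsspos <- gene_tss(ann)
    prom <- data.frame(chrom = ann$genes$chrom,
                       start = pmax(tsspos - cfg$promoter_halfwidth, 0),
                       end = tsspos + cfg$promoter_halfwidth,
                       gene_id = ann$genes$gene_id)
    wt_m <- region_replicate_matrix(dat$replicate_tracks$H3K27me3$WT, prom)
    ko_m <- region_replicate_matrix(dat$replicate_tracks$H3K27me3$KO, prom)
    prom_diff <- differential_regions(wt_m, ko_m, regions = prom,
                                      lfc_threshold = cfg$promoter_lfc_threshold,
                                      fdr_threshold = cfg$fdr_threshold)
    # genes with clear promoter H3K27me3 in WT
    occupied <- prom_diff$mean_wt > 4
    k27_frac <- overlap_summary(prom_diff$gene_id[occupied],
                                prom_diff$gene_id[occupied &
                                                    prom_diff$status == "loss"],
                                label = "H3K27me3 loss among occupied promoters")
    report$prc2 <- list(
      n_occupied = sum(occupied),
      n_loss = sum(occupied & prom_diff$status == "loss"),
      pct_loss = k27_frac$pct)
    k27_genes <- prom_diff$gene_id[occupied]
  } else {
    prom_diff <- NULL
    k27_genes <- character(0)
  }

  ## ---- enhancers and motifs ----------------------------------------------
  if (!is.null(dat$replicate_tracks$H3K27ac) && !is.null(dat$tracks$H3K4me1)) {
    k27ac_pk <- call_peaks(dat$tracks$H3K27ac$WT, p_cutoff = cfg$peak_p_cutoff)
    k4me1_pk <- call_peaks(dat$tracks$H3K4me1$WT, p_cutoff = cfg$peak_p_cutoff)
    k4me3_pk <- call_peaks(dat$tracks$H3K4me3$WT, p_cutoff = cfg$peak_p_cutoff)
    enh <- call_active_enhancers(k27ac_pk, k4me1_pk, k4me3_pk, ann,
                                 distal_margin = cfg$distal_margin)
    active <- enh[enh$active, , drop = FALSE]
    wt_m <- region_replicate_matrix(dat$replicate_tracks$H3K27ac$WT, active)
    ko_m <- region_replicate_matrix(dat$replicate_tracks$H3K27ac$KO, active)
    enh_diff <- differential_regions(wt_m, ko_m, regions = active,
                                     lfc_threshold = cfg$enhancer_lfc_threshold,
                                     fdr_threshold = cfg$fdr_threshold)
    domains <- regulatory_domains(ann, basal_up = cfg$basal_up,
                                  basal_down = cfg$basal_down,
                                  extension_max = cfg$extension_max)
    gain <- enh_diff[enh_diff$status == "gain", , drop = FALSE]
    loss <- enh_diff[enh_diff$status == "loss", , drop = FALSE]
    gain_genes <- unique(unlist(associate_regions(gain, domains)$region_to_genes))
    loss_genes <- unique(unlist(associate_regions(loss, domains)$region_to_genes))
    venn_up <- overlap_summary(up_genes, gain_genes,
                               "up genes associated with gained enhancers")
    venn_down <- overlap_summary(down_genes, loss_genes,
                                 "down genes associated with lost enhancers")
    report$enhancers <- list(
      n_candidates = nrow(enh), n_active = nrow(active),
      n_gain = nrow(gain), n_loss = nrow(loss),
      pct_up_genes_gain_associated = venn_up$pct,
      pct_down_genes_loss_associated = venn_down$pct)
    if (!is.null(dat$genome)) {
      tgt <- extract_target_windows(enh_diff, dat$genome,
                                    half_width = cfg$motif_half_width,
                                    status = "gain")
      bg <- extract_target_windows(enh_diff, dat$genome,
                                   half_width = cfg$motif_half_width,
                                   status = "stable")
      if (length(tgt$sequences) && length(bg$sequences)) {
        pfms <- read_jaspar(cfg$pfm_path)
        mot <- enrich_motifs(tgt$sequences, bg$sequences, pfms,
                             rel_score_threshold = cfg$motif_rel_score,
                             fisher_cutoff = cfg$fisher_cutoff,
                             z_cutoff = cfg$z_cutoff)
        report$motifs <- list(
          n_motifs = nrow(mot), n_enriched = sum(mot$enriched),
          top = mot[seq_len(min(5L, nrow(mot))),
                    c("motif_id", "fisher_score", "z_score", "enriched")])
      }
    }
    enhancer_assoc <- list(gain = gain_genes, loss = loss_genes)
  } else {
    enhancer_assoc <- list(gain = character(0), loss = character(0))
  }

  ## ---- Venn-style fraction report ----------------------------------------
  if (!is.null(dat$tracks$H3K4me3$WT)) {
    k4_genes <- tss_wt$gene_id
    report$fractions <- fraction_report(de, union(k4_genes, k27_genes),
                                        enhancer_assoc)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "columns", force = TRUE)
    writeLines(utils::capture.output(utils::str(report, max.level = 3)),
               file.path(out_dir, "report.txt"))
    write_de_table(de, file.path(out_dir, "de_table.tsv"))
  }
  invisible(report)
}

#' Venn-style fractions of regulated genes explained by marks or enhancers
#'
#' For the up- and downregulated gene sets, computes the percentage with
#' promoter mark occupancy (H3K4me3 or H3K27me3), the percentage associated
#' with gained (up) or lost (down) enhancers, and the percentage with
#' neither.
#'
#' @param de Classified DE records ([classify_genes()]).
#' @param marked_genes Genes with significant promoter H3K4me3 or H3K27me3
#'   occupancy.
#' @param enhancer_assoc list with `gain` and `loss` gene-id vectors from
#'   enhancer-domain association.
#' @return Nested list of counts and percentages for `up` and `down`.
#' @export
fraction_report <- function(de, marked_genes, enhancer_assoc) {
  up <- unique(de$gene_id[de$class == "up"])
  down <- unique(de$gene_id[de$class == "down"])
  one_side <- function(set, enh_genes) {
    if (!length(set))
      return(list(n = 0L, pct_promoter_marked = NA_real_,
                  pct_enhancer_associated = NA_real_,
                  pct_neither = NA_real_))
    marked <- overlap_summary(set, marked_genes)
    enh <- overlap_summary(set, enh_genes)
    neither <- setdiff(set, union(marked_genes, enh_genes))
    list(n = length(set),
         n_promoter_marked = marked$n_intersect,
         pct_promoter_marked = marked$pct,
         n_enhancer_associated = enh$n_intersect,
         pct_enhancer_associated = enh$pct,
         n_neither = length(neither),
         pct_neither = 100 * length(neither) / length(set))
  }
  list(up = one_side(up, enhancer_assoc$gain),
       down = one_side(down, enhancer_assoc$loss))
}
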