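#' Mean signal per region
#'
#' @param track A `coverage_track`.
#' @param regions data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @return Numeric vector of per-region means.
#' @export
region_signal <- function(track, regions) {
  vapply(seq_len(nrow(regions)), function(i)
    mean_signal(track, regions$chrom[i], regions$start[i], regions$end[i]),
    numeric(1))
}

#' Windowed differential occupancy between conditions
#'
#' Per region, a two-sided Welch t-test on `log2(signal + pseudocount)`
#' across replicates, with Benjamini-Hochberg correction across regions.
#' `log2fc = log2((mean_KO + pc) / (mean_WT + pc))`. A region is `gain` when
#' `log2fc > lfc_threshold` and `fdr < fdr_threshold`, `loss` when
#' `log2fc < -lfc_threshold` and `fdr < fdr_threshold`, else `stable`.
#' Regions that are identically zero in both conditions are `stable` with
#' p = 1. All fold changes are KO over WT.
#'
#' @param wt,ko Regions x replicates matrices of region mean signal.
#' @param regions Optional data.frame of the regions (carried through).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 2).
#' @param fdr_threshold BH-FDR threshold (default 0.05).
#' @param pseudocount Pseudocount for logs (default 0.5).
#' @return data.frame `mean_wt`, `mean_ko`, `log2fc`, `pvalue`, `fdr`,
#'   `status`, prefixed by the region columns when supplied.
#' @export
differential_regions <- function(wt, ko, regions = NULL, lfc_threshold = 2,
                                 fdr_threshold = 0.05, pseudocount = 0.5) {
  wt <- as.matrix(wt); ko <- as.matrix(ko)
  if (nrow(wt) != nrow(ko)) stop("wt and ko must cover the same regions")
  if (ncol(wt) < 2L || ncol(ko) < 2L)
    stop("need >= 2 replicate values per condition")
  mean_wt <- rowMeans(wt); mean_ko <- rowMeans(ko)
  log2fc <- log2((mean_ko + pseudocount) / (mean_wt + pseudocount))
  pvalue <- welch_rows(log2(wt + pseudocount), log2(ko + pseudocount))
  zero <- mean_wt == 0 & mean_ko == 0
  pvalue[zero] <- 1
  fdr <- stats::p.adjust(pvalue, method = "BH")
  status <- rep("stable", length(pvalue))
  status[log2fc > lfc_threshold & fdr < fdr_threshold] <- "gain"
  status[log2fc < -lfc_threshold & fdr < fdr_threshold] <- "loss"
  res <- data.frame(mean_wt = mean_wt, mean_ko = mean_ko, log2fc = log2fc,
                    pvalue = pvalue, fdr = fdr, status = status,
                    row.names = NULL)
  if (!is.null(regions)) res <- cbind(as.data.frame(regions), res)
  res
}

regions_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(start = regions$start + 1L,
                                          end = regions$end))
}

#' Call active enhancers from combinatorial histone marks
#'
#' Candidates are H3K27ac peaks. A candidate is an active enhancer iff it
#' overlaps at least 1 bp of an H3K4me1 peak, overlaps no H3K4me3 peak, and
#' lies entirely more than `distal_margin` bp away from every gene body.
#'
#' @param k27ac_peaks,k4me1_peaks,k4me3_peaks Peak data.frames (`chrom`,
#'   `start`, `end`, ...).
#' @param annotation A `genome_annotation` (gene bodies for the distal rule).
#' @param distal_margin Minimum distance from gene bodies in bp (default 5000).
#' @return The H3K27ac candidates with logical columns `has_k4me1`,
#'   `has_k4me3`, `distal` and `active`.
#' @export
call_active_enhancers <- function(k27ac_peaks, k4me1_peaks, k4me3_peaks,
                                  annotation, distal_margin = 5000L) {
  cand <- as.data.frame(k27ac_peaks)
  if (!nrow(cand)) {
    cand$has_k4me1 <- logical(0); cand$has_k4me3 <- logical(0)
    cand$distal <- logical(0); cand$active <- logical(0)
    return(cand)
  }
  cand_gr <- regions_granges(cand)
  ov <- function(peaks) {
    if (is.null(peaks) || !nrow(peaks)) return(rep(FALSE, nrow(cand)))
    GenomicRanges::countOverlaps(cand_gr, regions_granges(peaks)) > 0
  }
  g <- annotation$genes
  body_gr <- GenomicRanges::GRanges(
    g$chrom,
    IRanges::IRanges(start = pmax(g$start - distal_margin, 0) + 1L,
                     end = g$end + distal_margin))
  cand$has_k4me1 <- ov(k4me1_peaks)
  cand$has_k4me3 <- ov(k4me3_peaks)
  cand$distal <- GenomicRanges::countOverlaps(cand_gr, body_gr) == 0
  cand$active <- cand$has_k4me1 & !cand$has_k4me3 & cand$distal
  cand
}

#' Basal-plus-extension regulatory domains
#'
#' Each gene's basal region is `TSS - basal_up .. TSS + basal_down`
#' (strand-aware: upstream is 5' of the TSS). The basal region is extended
#' in both directions up to `extension_max` bp, stopping at the nearest
#' neighbouring gene's basal boundary, and clipped to the chromosome. A
#' domain always contains its own basal region in full.
#'
#' @param annotation A `genome_annotation`.
#' @param basal_up,basal_down Basal window in bp (defaults 5000/1000).
#' @param extension_max Maximum extension in bp (default 1e6).
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (domain),
#'   `basal_start`, `basal_end`.
#' @export
regulatory_domains <- function(annotation, basal_up = 5000L,
                               basal_down = 1000L, extension_max = 1e6) {
  g <- annotation$genes
  tss <- gene_tss(annotation)
  basal_start <- ifelse(g$strand == "+", tss - basal_up, tss - basal_down + 1L)
  basal_end <- ifelse(g$strand == "+", tss + basal_down, tss + basal_up + 1L)
  basal_start <- pmax(basal_start, 0L)
  basal_end <- pmin(basal_end, annotation$chrom_sizes[g$chrom])
  dom_start <- integer(nrow(g)); dom_end <- integer(nrow(g))
  for (chrom in unique(g$chrom)) {
    idx <- which(g$chrom == chrom)
    clen <- annotation$chrom_sizes[[chrom]]
    bs <- basal_start[idx]; be <- basal_end[idx]
    ord <- order(bs, be)
    n <- length(idx)
    # nearest basal boundary to the left/right of each gene's own basal,
    # capped so a domain never loses its own basal region
    left_lim <- numeric(n); right_lim <- numeric(n)
    be_sorted <- be[ord]; bs_sorted <- bs[ord]
    prev_max_end <- cummax(c(-Inf, be_sorted[-n]))
    nxt <- rev(cummin(rev(c(bs_sorted[-1], Inf))))
    for (k in seq_len(n)) {
      i <- ord[k]
      left_lim[i] <- min(prev_max_end[k], bs_sorted[k])
      right_lim[i] <- max(nxt[k], be_sorted[k])
    }
    dom_start[idx] <- pmax(0, pmax(bs - extension_max, left_lim))
    dom_end[idx] <- pmin(clen, pmin(be + extension_max, right_lim))
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             start = as.integer(dom_start), end = as.integer(dom_end),
             basal_start = as.integer(basal_start),
             basal_end = as.integer(basal_end), row.names = NULL)
}

#' Associate regions with genes via regulatory domains
#'
#' A region is associated with every gene whose regulatory domain it
#' intersects by at least 1 bp.
#'
#' @param regions data.frame `chrom`, `start`, `end`.
#' @param domains data.frame from [regulatory_domains()].
#' @return list with `region_to_genes` (list, one character vector per
#'   region row) and `gene_to_regions` (named list gene_id -> region row
#'   indices).
#' @export
associate_regions <- function(regions, domains) {
  n <- nrow(regions)
  if (!n) return(list(region_to_genes = list(),
                      gene_to_regions = structure(list(), names = character(0))))
  hits <- GenomicRanges::findOverlaps(regions_granges(regions),
                                      regions_granges(domains))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  region_to_genes <- lapply(seq_len(n), function(i) character(0))
  for (i in seq_along(qh))
    region_to_genes[[qh[i]]] <- c(region_to_genes[[qh[i]]],
                                  domains$gene_id[sh[i]])
  gene_to_regions <- split(qh, domains$gene_id[sh])
  list(region_to_genes = region_to_genes, gene_to_regions = gene_to_regions)
}

#' Overlap summary of two gene sets
#'
#' @param setA,setB Character vectors of gene ids.
#' @param label Optional label carried through.
#' @return list `label`, `n_a`, `n_b`, `n_intersect`, `pct`
#'   (`100 * |A intersect B| / |A|`; NA when A is empty).
#' @export
overlap_summary <- function(setA, setB, label = "") {
  setA <- unique(setA); setB <- unique(setB)
  ni <- length(intersect(setA, setB))
  list(label = label, n_a = length(setA), n_b = length(setB),
       n_intersect = ni,
       pct = if (length(setA)) 100 * ni / length(setA) else NA_real_)
}
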