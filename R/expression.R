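#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes (restricted to
#' genes with nonzero counts in every sample) of the ratio of the sample's
#' count to the gene's geometric mean across samples.
#'
#' @param counts Integer matrix, genes x samples (rownames = gene ids).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep))
    stop("no gene has nonzero counts in all samples; size factors undefined")
  lc <- log(counts[keep, , drop = FALSE])
  geo <- rowMeans(lc)
  apply(lc, 2, function(col) exp(stats::median(col - geo)))
}

#' Differential expression by Welch test on log normalized counts
#'
#' Counts are normalized by [size_factors()]. Per gene: `baseMean` is the
#' mean normalized count over all samples; `log2fc = log2((mean_KO + pc) /
#' (mean_WT + pc))` on normalized condition means; the p-value is a
#' two-sided Welch t-test on `log2(normalized + pc)` across replicates. The
#' record schema (baseMean, log2fc, pvalue) matches the common DE-table
#' layout, so an externally produced table can be substituted downstream.
#'
#' @param counts Genes x samples count matrix with rownames.
#' @param condition Character vector (`"WT"`/`"KO"`) per sample, or a named
#'   vector matched against colnames.
#' @param pseudocount Pseudocount for fold changes and logs (default 0.5).
#' @return data.frame `gene_id`, `baseMean`, `log2fc`, `pvalue`, `class`
#'   (all `"none"`; see [classify_genes()]).
#' @export
differential_expression <- function(counts, condition, pseudocount = 0.5) {
  counts <- as.matrix(counts)
  if (!is.null(names(condition)) && !is.null(colnames(counts)))
    condition <- condition[colnames(counts)]
  condition <- as.character(condition)
  if (length(condition) != ncol(counts))
    stop("`condition` length must match the number of samples")
  if (!all(condition %in% c("WT", "KO")))
    stop("condition labels must be 'WT' or 'KO'")
  n_wt <- sum(condition == "WT"); n_ko <- sum(condition == "KO")
  if (n_wt < 2L || n_ko < 2L)
    stop("each condition needs >= 2 replicates (got WT=", n_wt, ", KO=", n_ko, ")")
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  wt <- norm[, condition == "WT", drop = FALSE]
  ko <- norm[, condition == "KO", drop = FALSE]
  base_mean <- rowMeans(norm)
  log2fc <- log2((rowMeans(ko) + pseudocount) / (rowMeans(wt) + pseudocount))
  pvalue <- welch_rows(log2(wt + pseudocount), log2(ko + pseudocount))
  data.frame(gene_id = rownames(counts), baseMean = base_mean,
             log2fc = log2fc, pvalue = pvalue, class = "none",
             row.names = NULL)
}

# Vectorized two-sided Welch t-test across rows of two matrices.
# Degenerate rows (both groups constant): p = 1 if the means agree, else 0.
welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  p[degen] <- ifelse(ma[degen] == mb[degen], 1, 0)
  p
}

#' Classify differential-expression records
#'
#' Applies the standard thresholding: `down` if baseMean > 15, p < 0.05 and
#' log2FC < -1; `up` if baseMean > 15, p < 0.05 and log2FC > 1; `unchanged`
#' if baseMean > 15, p > 0.8 and -0.2 < log2FC < 0.2; otherwise `none`. All
#' inequalities are strict.
#'
#' @param records data.frame from [differential_expression()].
#' @param base_mean_min,p_max,lfc_min Thresholds for up/down calls.
#' @param unch_p_min,unch_lfc_max Thresholds for the unchanged class.
#' @return The records with `class` set.
#' @export
classify_genes <- function(records, base_mean_min = 15, p_max = 0.05,
                           lfc_min = 1, unch_p_min = 0.8, unch_lfc_max = 0.2) {
  cl <- rep("none", nrow(records))
  expr_ok <- records$baseMean > base_mean_min
  cl[expr_ok & records$pvalue < p_max & records$log2fc > lfc_min] <- "up"
  cl[expr_ok & records$pvalue < p_max & records$log2fc < -lfc_min] <- "down"
  cl[expr_ok & records$pvalue > unch_p_min &
       records$log2fc > -unch_lfc_max & records$log2fc < unch_lfc_max] <- "unchanged"
  records$class <- cl
  records
}

#' H2Bub1 occupancy quartile groups
#'
#' Ranks genes by mean gene-body signal (descending, ties broken by gene id)
#' and cuts at ranks n/4, n/2, 3n/4 into `H` (upper quartile), `M`
#' (50th-75th percentile), `L` (25th-50th) and `No` (lowest quartile).
#'
#' @param track H2Bub1 `coverage_track`.
#' @param annotation A `genome_annotation` (>= 4 genes).
#' @return data.frame `gene_id`, `signal`, `group`.
#' @export
occupancy_groups <- function(track, annotation) {
  g <- annotation$genes
  n <- nrow(g)
  if (n < 4L) stop("need >= 4 genes for quartile groups")
  sig <- vapply(seq_len(n), function(i)
    mean_signal(track, g$chrom[i], g$start[i], g$end[i]), numeric(1))
  ord <- order(-sig, g$gene_id)
  cuts <- floor(n * (1:3) / 4)
  grp <- character(n)
  grp[ord[seq_len(cuts[1])]] <- "H"
  grp[ord[(cuts[1] + 1):cuts[2]]] <- "M"
  grp[ord[(cuts[2] + 1):cuts[3]]] <- "L"
  grp[ord[(cuts[3] + 1):n]] <- "No"
  data.frame(gene_id = g$gene_id, signal = sig,
             group = factor(grp, levels = c("H", "M", "L", "No")),
             row.names = NULL)
}

#' Pearson correlation of two per-gene vectors
#'
#' @param x,y Numeric vectors of equal length; pairs with non-finite values
#'   are dropped.
#' @return list with `r` (Pearson r, or NA when undefined), `n` (pairs
#'   used) and `defined` (FALSE when either vector has zero variance).
#' @export
correlate <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, n = length(x), defined = FALSE))
  list(r = stats::cor(x, y, method = "pearson"), n = length(x), defined = TRUE)
}

#' Expression response by occupancy group
#'
#' Summarises `|log2fc|` per occupancy group (median and quartiles) and runs
#' an unpaired Wilcoxon-Mann-Whitney test for every pair of groups. Pairs
#' where either group has fewer than 2 members are skipped.
#'
#' @param groups data.frame from [occupancy_groups()].
#' @param records data.frame from [differential_expression()].
#' @return list with `summary` (per-group median/q25/q75/n) and `tests`
#'   (data.frame `group1`, `group2`, `pvalue`).
#' @export
group_response <- function(groups, records) {
  lfc <- stats::setNames(abs(records$log2fc), records$gene_id)
  groups <- groups[groups$gene_id %in% names(lfc), ]
  if (!nrow(groups)) stop("no shared genes between groups and records")
  vals <- split(lfc[groups$gene_id], groups$group)
  summ <- do.call(rbind, lapply(names(vals), function(gname) {
    v <- vals[[gname]]
    data.frame(group = gname, n = length(v),
               median = stats::median(v),
               q25 = unname(stats::quantile(v, 0.25)),
               q75 = unname(stats::quantile(v, 0.75)))
  }))
  pairs <- utils::combn(names(vals), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    if (length(vals[[g1]]) < 2L || length(vals[[g2]]) < 2L)
      return(data.frame(group1 = g1, group2 = g2, pvalue = NA_real_))
    p <- suppressWarnings(
      stats::wilcox.test(vals[[g1]], vals[[g2]], exact = FALSE)$p.value)
    data.frame(group1 = g1, group2 = g2, pvalue = p)
  }))
  list(summary = summ, tests = tests)
}

#' Read a counts matrix from TSV
#'
#' First column = gene_id, remaining columns = samples.
#'
#' @param path TSV file.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "integer"
  m
}

#' Write a differential-expression table as TSV
#' @param records DE data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(records, path) {
  data.table::fwrite(records, path, sep = "\t")
  invisible(path)
}
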