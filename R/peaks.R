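#' Call peaks on a coverage track with a windowed local-Poisson test
#'
#' Slides a window of `window` bp (step `window/2`) along each chromosome and
#' tests the window sum against a Poisson null whose rate is the maximum of
#' the local background estimated at several scales (1/5/10 kb by default)
#' and the global per-bp rate. Significant overlapping windows are merged,
#' and merged regions closer than `merge_gap` are joined. Each peak carries
#' the best (smallest) window p-value among its constituent windows, plus
#' summit/height/width metrics. The summit is the leftmost position of
#' maximum signal.
#'
#' When a `background` track is supplied, the local rates are estimated from
#' it and rescaled by total-signal ratio so the null is on the signal scale.
#' Without a background the null is the signal's global per-bp rate alone:
#' local rates estimated from the enriched signal itself would sit on top of
#' the very peaks being tested and shadow broad domains, so the uniform
#' global rate is the honest input-free null.
#'
#' @param track Signal `coverage_track`.
#' @param background Optional background/control `coverage_track`.
#' @param p_cutoff Poisson upper-tail p-value cutoff (default 1e-5).
#' @param window Sliding window width in bp.
#' @param step Window step; defaults to `window / 2`.
#' @param local_scales Scales (bp) for the local background rate.
#' @param merge_gap Merge significant regions separated by <= this many bp.
#' @param min_width Discard merged peaks narrower than this.
#' @return data.frame with columns `chrom`, `start`, `end`, `summit`,
#'   `height`, `width`, `pvalue`, sorted and non-overlapping.
#' @export
call_peaks <- function(track, background = NULL, p_cutoff = 1e-5,
                       window = 150L, step = NULL,
                       local_scales = c(1000L, 5000L, 10000L),
                       merge_gap = 100L, min_width = 100L) {
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff >= 1)
    stop("p_cutoff must be in (0, 1)")
  if (is.null(step)) step <- as.integer(window / 2)
  if (!is.null(background) &&
      !identical(names(track$values), names(background$values)))
    stop("signal and background tracks cover different chromosomes")
  out <- list()
  for (chrom in names(track$values)) {
    x <- track$values[[chrom]]
    len <- length(x)
    if (len < window) next
    if (sum(x) == 0) next
    starts0 <- seq.int(0L, len - window, by = step)   # 0-based window starts
    cx <- c(0, cumsum(x))
    wsum <- cx[starts0 + window + 1L] - cx[starts0 + 1L]
    if (is.null(background)) {
      rate <- rep(mean(x), length(starts0))
    } else {
      bg <- background$values[[chrom]]
      tot_bg <- sum(bg)
      bg_scale <- if (tot_bg == 0) 1 else sum(x) / tot_bg
      cb <- c(0, cumsum(bg))
      centers <- starts0 + window / 2
      rate <- rep(mean(bg) * bg_scale, length(starts0))
      for (L in local_scales) {
        lo <- pmax(0L, as.integer(centers - L / 2))
        hi <- pmin(len, as.integer(centers + L / 2))
        loc <- (cb[hi + 1L] - cb[lo + 1L]) / (hi - lo) * bg_scale
        rate <- pmax(rate, loc)
      }
    }
    lambda <- rate * window
    pv <- stats::ppois(ceiling(wsum) - 1, lambda, lower.tail = FALSE)
    sig <- which(pv < p_cutoff & wsum > 0)
    if (!length(sig)) next
    s <- starts0[sig]; e <- s + window
    # merge overlapping/nearby significant windows, tracking best p per region
    ord <- order(s)
    s <- s[ord]; e <- e[ord]; p <- pv[sig][ord]
    rs <- s[1]; re <- e[1]; rp <- p[1]
    regions <- list()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= re + merge_gap) {
        re <- max(re, e[i]); rp <- min(rp, p[i])
      } else {
        regions[[length(regions) + 1L]] <- c(rs, re, rp)
        rs <- s[i]; re <- e[i]; rp <- p[i]
      }
    }
    regions[[length(regions) + 1L]] <- c(rs, re, rp)
    m <- do.call(rbind, regions)
    keep <- (m[, 2] - m[, 1]) >= min_width
    if (!any(keep)) next
    m <- m[keep, , drop = FALSE]
    df <- data.frame(chrom = chrom, start = as.integer(m[, 1]),
                     end = as.integer(m[, 2]), pvalue = m[, 3])
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) {
    empty <- data.frame(chrom = character(), start = integer(),
                        end = integer(), summit = integer(),
                        height = numeric(), width = integer(),
                        pvalue = numeric())
    return(empty)
  }
  peaks <- do.call(rbind, out)
  rownames(peaks) <- NULL
  peak_metrics(track, peaks)
}

#' Populate width/height/summit metrics on peak intervals
#'
#' @param track The `coverage_track` the peaks were called on.
#' @param peaks data.frame with `chrom`, `start`, `end` (and optionally
#'   `pvalue`).
#' @return The peaks with `summit` (absolute 0-based position of the maximum
#'   signal, leftmost on ties), `height` (that maximum) and `width`
#'   (`end - start`) columns set.
#' @export
peak_metrics <- function(track, peaks) {
  n <- nrow(peaks)
  summit <- integer(n); height <- numeric(n)
  for (i in seq_len(n)) {
    chrom <- peaks$chrom[i]
    check_interval(track, chrom, peaks$start[i], peaks$end[i])
    v <- track$values[[chrom]][(peaks$start[i] + 1L):peaks$end[i]]
    k <- which.max(v)                      # leftmost max by which.max
    summit[i] <- peaks$start[i] + k - 1L
    height[i] <- v[k]
  }
  peaks$summit <- summit
  peaks$height <- height
  peaks$width <- peaks$end - peaks$start
  if (is.null(peaks$pvalue)) peaks$pvalue <- NA_real_
  peaks[c("chrom", "start", "end", "summit", "height", "width", "pvalue")]
}

#' Assign each gene the widest peak overlapping its TSS window
#'
#' A gene is assigned the single peak that overlaps `TSS +/- window` by at
#' least 1 bp and has the greatest width (ties broken by leftmost start).
#' Genes with no overlapping peak are absent from the result.
#'
#' @param peaks Peak data.frame (from [call_peaks()]).
#' @param annotation A `genome_annotation`.
#' @param window Half-width of the TSS window in bp (default 2000).
#' @return data.frame keyed by `gene_id` with the assigned peak's columns.
#' @export
assign_tss_peak <- function(peaks, annotation, window = 2000L) {
  if (window <= 0) stop("window must be positive")
  if (!nrow(peaks)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), summit = integer(),
                      height = numeric(), width = integer(), pvalue = numeric()))
  }
  tss <- gene_tss(annotation)
  g <- annotation$genes
  tss_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(start = pmax(tss - window, 0) + 1L,
                              end = tss + window))
  pk_gr <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
  hits <- GenomicRanges::findOverlaps(tss_gr, pk_gr)
  if (!length(hits)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), summit = integer(),
                      height = numeric(), width = integer(), pvalue = numeric()))
  }
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  # widest peak per gene; ties -> leftmost start
  ord <- order(qh, -peaks$width[sh], peaks$start[sh])
  first <- !duplicated(qh[ord])
  gi <- qh[ord][first]; pi <- sh[ord][first]
  res <- peaks[pi, , drop = FALSE]
  res <- cbind(gene_id = g$gene_id[gi], res)
  rownames(res) <- NULL
  res
}

#' Classify genes into broad / sharp / random-control H3K4me3 classes
#'
#' Broad genes carry the top 5% widest TSS peaks; sharp genes the top 5% by
#' peak height among genes not already broad; a random control set of the
#' same size as the broad set is drawn (without replacement, deterministic
#' given `seed`) from the remaining genes; everything else is `other`.
#'
#' @param tss_peaks Gene-to-peak table from [assign_tss_peak()].
#' @param top_frac Fraction defining the broad/sharp classes (default 0.05).
#' @param seed Integer seed for the random-control draw.
#' @return data.frame `gene_id`, `label` plus the backing peak columns.
#' @export
classify_breadth <- function(tss_peaks, top_frac = 0.05, seed = 1L) {
  n <- nrow(tss_peaks)
  if (n < 40L) stop("need >= 40 assigned genes to classify breadth (got ", n, ")")
  k <- as.integer(ceiling(top_frac * n))
  ord_w <- order(-tss_peaks$width, tss_peaks$gene_id)
  broad <- tss_peaks$gene_id[ord_w[seq_len(k)]]
  ord_h <- order(-tss_peaks$height, tss_peaks$gene_id)
  top_height <- tss_peaks$gene_id[ord_h[seq_len(k)]]
  sharp <- setdiff(top_height, broad)
  rest <- setdiff(tss_peaks$gene_id, c(broad, sharp))
  random_control <- with_local_seed(seed, sample(rest, size = min(k, length(rest))))
  label <- rep("other", n)
  label[tss_peaks$gene_id %in% broad] <- "broad"
  label[tss_peaks$gene_id %in% sharp] <- "sharp"
  label[tss_peaks$gene_id %in% random_control] <- "random_control"
  cbind(tss_peaks["gene_id"], label = label,
        tss_peaks[setdiff(names(tss_peaks), "gene_id")])
}

#' Strand-aware summit shift between conditions
#'
#' The shift is `WT summit - KO summit` for plus-strand genes and
#' `KO summit - WT summit` for minus-strand genes, so a positive value means
#' the KO summit lies 5'-ward (towards the TSS-upstream direction) of the WT
#' summit.
#'
#' @param wt,ko Gene-to-peak tables from [assign_tss_peak()] for the two
#'   conditions.
#' @param annotation A `genome_annotation`.
#' @return list with `per_gene` (data.frame `gene_id`, `shift`), `median`,
#'   and `n_excluded` (genes present in only one condition).
#' @export
summit_shift <- function(wt, ko, annotation) {
  shared <- intersect(wt$gene_id, ko$gene_id)
  n_excluded <- length(union(wt$gene_id, ko$gene_id)) - length(shared)
  g <- annotation$genes
  strand <- stats::setNames(g$strand, g$gene_id)[shared]
  s_wt <- stats::setNames(wt$summit, wt$gene_id)[shared]
  s_ko <- stats::setNames(ko$summit, ko$gene_id)[shared]
  shift <- ifelse(strand == "+", s_wt - s_ko, s_ko - s_wt)
  list(per_gene = data.frame(gene_id = shared, shift = as.integer(shift),
                             row.names = NULL),
       median = if (length(shift)) stats::median(shift) else NA_real_,
       n_excluded = n_excluded)
}

#' Per-gene log2 changes in peak width and height
#'
#' `d_log2_width = log2(width_KO) - log2(width_WT)`, and analogously for
#' height, over genes with a peak in both conditions.
#'
#' @param wt,ko Gene-to-peak tables for the two conditions.
#' @return data.frame `gene_id`, `d_log2_width`, `d_log2_height`.
#' @export
geometry_change <- function(wt, ko) {
  shared <- intersect(wt$gene_id, ko$gene_id)
  w_wt <- stats::setNames(wt$width, wt$gene_id)[shared]
  w_ko <- stats::setNames(ko$width, ko$gene_id)[shared]
  h_wt <- stats::setNames(wt$height, wt$gene_id)[shared]
  h_ko <- stats::setNames(ko$height, ko$gene_id)[shared]
  if (any(c(w_wt, w_ko) <= 0)) stop("zero or negative peak width")
  if (any(c(h_wt, h_ko) <= 0)) stop("zero or negative peak height")
  data.frame(gene_id = shared,
             d_log2_width = log2(w_ko) - log2(w_wt),
             d_log2_height = log2(h_ko) - log2(h_wt),
             row.names = NULL)
}

#' Metagene matrix around TSS/TES or over scaled gene bodies
#'
#' For `anchor = "TSS"` or `"TES"` each gene contributes the binned signal
#' over `anchor +/- flank`; for `anchor = "body"` each gene body is resampled
#' to `body_bins` bins. Rows are strand-aware: bin 1 is always 5'-most.
#' Genes whose window exceeds the chromosome are dropped and counted.
#'
#' @param track A `coverage_track`.
#' @param annotation A `genome_annotation`.
#' @param anchor `"TSS"`, `"TES"` or `"body"`.
#' @param flank Flank in bp for TSS/TES anchors.
#' @param binsize Bin width in bp for TSS/TES anchors.
#' @param body_bins Number of bins for `anchor = "body"`.
#' @return list with `matrix` (genes x bins), `profile` (column means) and
#'   `n_dropped`.
#' @export
metagene_matrix <- function(track, annotation, anchor = c("TSS", "TES", "body"),
                            flank = 2000L, binsize = 50L, body_bins = 100L) {
  anchor <- match.arg(anchor)
  if (flank <= 0 || binsize <= 0) stop("flank and binsize must be positive")
  g <- annotation$genes
  if (anchor == "body") {
    nbins <- body_bins
  } else {
    nbins <- as.integer(2 * flank / binsize)
  }
  rows <- list(); dropped <- 0L
  for (i in seq_len(nrow(g))) {
    chrom <- g$chrom[i]
    len <- length(track$values[[chrom]])
    if (anchor == "body") {
      s <- g$start[i]; e <- g$end[i]
      if (e - s < nbins) { dropped <- dropped + 1L; next }
    } else {
      pos <- if (anchor == "TSS") {
        if (g$strand[i] == "+") g$start[i] else g$end[i] - 1L
      } else {
        if (g$strand[i] == "+") g$end[i] - 1L else g$start[i]
      }
      # half-open windows are strand-symmetric: a minus-strand window is
      # shifted by 1 so both strands span flank bp on each side of the TSS
      if (g$strand[i] == "+") {
        s <- pos - flank; e <- pos + flank
      } else {
        s <- pos - flank + 1L; e <- pos + flank + 1L
      }
      if (s < 0 || e > len) { dropped <- dropped + 1L; next }
    }
    rows[[g$gene_id[i]]] <-
      bin_signal(track, chrom, s, e, nbins, strand = g$strand[i],
                 flip_if_minus = TRUE)
  }
  mat <- do.call(rbind, rows)
  list(matrix = mat,
       profile = if (is.null(mat)) numeric(nbins) else colMeans(mat),
       n_dropped = dropped)
}

#' RNA polymerase II pausing index
#'
#' Ratio of mean signal over `TSS +/- tss_window` to mean signal over the
#' gene body from `TSS + body_offset` to the TES (strand-aware). Genes too
#' short for the body window (or with windows outside the chromosome) are
#' excluded. A gene with zero body signal and positive TSS signal gets
#' `Inf`.
#'
#' @param track Pol II `coverage_track`.
#' @param annotation A `genome_annotation`.
#' @param tss_window Promoter half-window in bp (default 250).
#' @param body_offset Distance from TSS to the body window start (default 500).
#' @return data.frame `gene_id`, `pausing_index`.
#' @export
pausing_index <- function(track, annotation, tss_window = 250L,
                          body_offset = 500L) {
  g <- annotation$genes
  out_id <- character(0); out_pi <- numeric(0)
  for (i in seq_len(nrow(g))) {
    chrom <- g$chrom[i]
    len <- length(track$values[[chrom]])
    glen <- g$end[i] - g$start[i]
    if (glen <= body_offset) next
    if (g$strand[i] == "+") {
      tss <- g$start[i]
      body <- c(tss + body_offset, g$end[i])
    } else {
      tss <- g$end[i] - 1L
      body <- c(g$start[i], tss - body_offset + 1L)
    }
    prom <- c(tss - tss_window, tss + tss_window)
    if (prom[1] < 0 || prom[2] > len || body[1] >= body[2]) next
    m_tss <- mean_signal(track, chrom, prom[1], prom[2])
    m_body <- mean_signal(track, chrom, body[1], body[2])
    out_id <- c(out_id, g$gene_id[i])
    out_pi <- c(out_pi, if (m_body == 0) {
      if (m_tss > 0) Inf else NA_real_
    } else m_tss / m_body)
  }
  data.frame(gene_id = out_id, pausing_index = out_pi, row.names = NULL)
}

#' Write peaks as BED6+3
#'
#' Columns: chrom, start, end, name, score (`-log10` p-value), strand (`.`),
#' summit offset from start, height, width.
#'
#' @param peaks Peak data.frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- ifelse(is.na(peaks$pvalue), 0, pmin(1000, -log10(peaks$pvalue)))
  dt <- data.table::data.table(
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    name = sprintf("peak_%d", seq_len(nrow(peaks))),
    score = round(score, 3), strand = ".",
    summit_offset = peaks$summit - peaks$start,
    height = signif(peaks$height, 6), width = peaks$width)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
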