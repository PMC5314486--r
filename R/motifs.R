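#' Read position frequency matrices in JASPAR text format
#'
#' Each record is a `>motif_id [name]` header followed by four rows (A, C,
#' G, T). Both the plain four-row layout and the bracketed JASPAR layout
#' (`A [ 1 2 3 ]`) are accepted.
#'
#' @param path JASPAR-format text file.
#' @return Named list of PFMs; each PFM is a 4 x L numeric matrix with
#'   rownames A, C, G, T.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' headers in ", path)
  pfms <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1L
    to <- if (i < length(heads)) heads[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L)
      stop("motif block with fewer than 4 rows in ", path)
    id <- strsplit(sub("^>\\s*", "", lines[heads[i]]), "\\s+")[[1]][1]
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(vapply(rows, length, integer(1)))
    if (length(L) != 1L) stop("ragged PFM rows for motif ", id, " in ", path)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    if (any(m < 0) || any(colSums(m) <= 0))
      stop("invalid PFM counts for motif ", id)
    if (L < 4L) stop("motif ", id, " shorter than 4 bp")
    pfms[[id]] <- m
  }
  pfms
}

#' Convert a PFM to a log-odds PWM
#'
#' Column probabilities use a total pseudocount split by the background base
#' frequencies: `p = (count + pseudocount * bg) / (colsum + pseudocount)`;
#' the PWM entry is `log2(p / bg)`.
#'
#' @param pfm 4 x L count matrix (rows A, C, G, T).
#' @param bg Background base frequencies (A, C, G, T); default uniform.
#' @param pseudocount Total pseudocount per column (default 0.8).
#' @return 4 x L log-odds matrix with attributes `min_score`/`max_score`.
#' @export
pfm_to_pwm <- function(pfm, bg = rep(0.25, 4), pseudocount = 0.8) {
  bg <- bg / sum(bg)
  cs <- colSums(pfm)
  probs <- sweep(pfm, 2, cs + pseudocount, "/") +
    outer(bg * pseudocount, cs + pseudocount, "/")
  pwm <- log2(probs / bg)
  attr(pwm, "min_score") <- sum(apply(pwm, 2, min))
  attr(pwm, "max_score") <- sum(apply(pwm, 2, max))
  pwm
}

DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

encode_seq <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  unname(DNA_CODE[chars])  # non-ACGT -> NA
}

revcomp_pwm <- function(pwm) {
  out <- pwm[4:1, ncol(pwm):1, drop = FALSE]
  rownames(out) <- c("A", "C", "G", "T")
  attr(out, "min_score") <- attr(pwm, "min_score")
  attr(out, "max_score") <- attr(pwm, "max_score")
  out
}

score_windows <- function(code, pwm) {
  L <- ncol(pwm)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(L)) {
    v <- pwm[, j][code[j:(j + n - 1L)]]
    sc <- sc + v
  }
  sc  # windows containing non-ACGT characters score NA
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands with the log-odds PWM derived from
#' `pfm`. A window is a hit when its score reaches
#' `min + rel_score_threshold * (max - min)`, where min/max are the PWM's
#' attainable extremes. Overlapping hits on the same strand are collapsed to
#' the best-scoring one (leftmost on ties).
#'
#' @param seq Character DNA sequence.
#' @param pfm 4 x L PFM (or a PWM from [pfm_to_pwm()] with score attributes).
#' @param rel_score_threshold Relative score threshold in (0, 1] (default
#'   0.85).
#' @param bg Background base frequencies used for the log-odds conversion.
#' @param pseudocount PFM pseudocount.
#' @return data.frame `pos` (1-based window start on the forward strand),
#'   `strand`, `score`, `rel_score`.
#' @export
pwm_scan <- function(seq, pfm, rel_score_threshold = 0.85,
                     bg = rep(0.25, 4), pseudocount = 0.8) {
  if (rel_score_threshold <= 0 || rel_score_threshold > 1)
    stop("rel_score_threshold must be in (0, 1]")
  pwm <- if (is.null(attr(pfm, "min_score")))
    pfm_to_pwm(pfm, bg = bg, pseudocount = pseudocount) else pfm
  lo <- attr(pwm, "min_score"); hi <- attr(pwm, "max_score")
  thr <- lo + rel_score_threshold * (hi - lo)
  code <- encode_seq(seq)
  hits <- list()
  for (strand in c("+", "-")) {
    mat <- if (strand == "+") pwm else revcomp_pwm(pwm)
    sc <- score_windows(code, mat)
    idx <- which(!is.na(sc) & sc >= thr)
    if (!length(idx)) next
    # collapse overlapping same-strand hits to the best-scoring window
    keep <- integer(0)
    ord <- idx[order(-sc[idx], idx)]
    taken <- logical(length(sc))
    L <- ncol(pwm)
    for (i in ord) {
      span <- max(1L, i - L + 1L):min(length(sc), i + L - 1L)
      if (!any(taken[span])) { keep <- c(keep, i); taken[i] <- TRUE }
    }
    keep <- sort(keep)
    hits[[strand]] <- data.frame(pos = keep, strand = strand,
                                 score = sc[keep],
                                 rel_score = (sc[keep] - lo) / (hi - lo))
  }
  if (!length(hits))
    return(data.frame(pos = integer(), strand = character(),
                      score = numeric(), rel_score = numeric()))
  res <- do.call(rbind, hits)
  rownames(res) <- NULL
  res[order(res$pos, res$strand), , drop = FALSE]
}

#' Fisher score for region-level motif enrichment
#'
#' One-tailed Fisher exact test (hypergeometric upper tail) on the 2 x 2
#' table of regions with >= 1 motif hit versus without, in targets versus
#' background. Returns `-ln p`.
#'
#' @param t_hit,t_tot Target regions with a hit / total target regions.
#' @param b_hit,b_tot Background regions with a hit / total background.
#' @return list `score` (`-ln p`) and `pvalue`.
#' @export
fisher_score <- function(t_hit, t_tot, b_hit, b_tot) {
  if (t_tot < 1 || b_tot < 1) stop("empty target or background set")
  if (t_hit > t_tot || b_hit > b_tot) stop("hits exceed totals")
  p <- stats::phyper(t_hit - 1, t_hit + b_hit,
                     (t_tot - t_hit) + (b_tot - b_hit), t_tot,
                     lower.tail = FALSE)
  list(score = -log(p), pvalue = p)
}

#' Z score for nucleotide-level motif enrichment
#'
#' Standardised, continuity-corrected excess of motif hits in the target
#' sequences given the background hit rate:
#' `z = (t_hits - p * t_nt - 0.5) / sqrt(t_nt * p * (1 - p))` with
#' `p = b_hits / b_nt`.
#'
#' @param t_nt_hits,t_nt Hits and scanned positions in targets.
#' @param b_nt_hits,b_nt Hits and scanned positions in background.
#' @return list `z` (NA when the background rate is 0 or 1) and `defined`.
#' @export
motif_z_score <- function(t_nt_hits, t_nt, b_nt_hits, b_nt) {
  if (b_nt <= 0 || t_nt <= 0) stop("need positive scanned-position totals")
  p <- b_nt_hits / b_nt
  if (p <= 0 || p >= 1) return(list(z = NA_real_, defined = FALSE))
  mu <- p * t_nt
  sigma <- sqrt(t_nt * p * (1 - p))
  list(z = (t_nt_hits - mu - 0.5) / sigma, defined = TRUE)
}

count_hits <- function(seqs, pwm, rel_score_threshold) {
  L <- ncol(pwm)
  region_hits <- 0L; nt_hits <- 0L; nt_scanned <- 0
  for (s in seqs) {
    h <- pwm_scan(s, pwm, rel_score_threshold = rel_score_threshold)
    if (nrow(h)) region_hits <- region_hits + 1L
    nt_hits <- nt_hits + nrow(h)
    nt_scanned <- nt_scanned + 2 * max(0L, nchar(s) - L + 1L)
  }
  list(region_hits = region_hits, nt_hits = nt_hits, nt_scanned = nt_scanned)
}

#' Motif enrichment of target versus background sequences
#'
#' Scans both sequence sets with every PFM and reports, per motif, the
#' region-level Fisher score and the nucleotide-level Z score, flagged
#' `enriched` when Fisher > `fisher_cutoff` and Z > `z_cutoff` (defaults 5
#' and 10). Background base frequencies for the log-odds conversion are
#' estimated from the background sequences. A position hit on both strands
#' counts once at region level and twice at nucleotide level.
#'
#' @param targets,background Character vectors of DNA sequences.
#' @param pfms Named list of PFMs (see [read_jaspar()]).
#' @param rel_score_threshold PWM relative score threshold (default 0.85).
#' @param fisher_cutoff,z_cutoff Enrichment cutoffs.
#' @return data.frame sorted by decreasing `fisher_score` with the hit
#'   counts, both scores and the `enriched` flag.
#' @export
enrich_motifs <- function(targets, background, pfms,
                          rel_score_threshold = 0.85,
                          fisher_cutoff = 5, z_cutoff = 10) {
  if (!length(targets) || !length(background))
    stop("need non-empty target and background sequence sets")
  bg_freq <- background_frequencies(background)
  rows <- lapply(names(pfms), function(id) {
    pwm <- pfm_to_pwm(pfms[[id]], bg = bg_freq)
    t <- count_hits(targets, pwm, rel_score_threshold)
    b <- count_hits(background, pwm, rel_score_threshold)
    fs <- fisher_score(t$region_hits, length(targets),
                       b$region_hits, length(background))
    z <- motif_z_score(t$nt_hits, t$nt_scanned, b$nt_hits, b$nt_scanned)
    data.frame(motif_id = id,
               target_regions_hit = t$region_hits,
               target_regions_total = length(targets),
               bg_regions_hit = b$region_hits,
               bg_regions_total = length(background),
               target_nt_hits = t$nt_hits, bg_nt_hits = b$nt_hits,
               fisher_score = fs$score,
               z_score = if (z$defined) z$z else NA_real_,
               enriched = fs$score > fisher_cutoff &
                 (!is.na(z$z) && z$z > z_cutoff))
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$fisher_score, res$motif_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

background_frequencies <- function(seqs) {
  tab <- table(factor(unlist(strsplit(toupper(paste(seqs, collapse = "")), "")),
                      levels = c("A", "C", "G", "T")))
  freq <- as.numeric(tab)
  if (sum(freq) == 0) return(rep(0.25, 4))
  freq <- freq + 1  # avoid zero frequencies
  freq / sum(freq)
}

#' Extract fixed-width sequence windows around differential-region centres
#'
#' For each region with the requested status (default `gain`), takes the
#' `+/- half_width` window around the region centre — the interval midpoint
#' by default, or the peak summit with `center = "summit"` — clips it to
#' the chromosome, and extracts the sequence. Windows shorter than
#' `min_width` after clipping are dropped and counted.
#'
#' @param records Differential-region data.frame with `chrom`, `start`,
#'   `end`, optionally `summit` and `status`.
#' @param genome Named `Biostrings::DNAStringSet` (or named character
#'   vector) of chromosome sequences.
#' @param half_width Half window width in bp (default 150).
#' @param status Status to select, or NULL for all rows.
#' @param center `"midpoint"` (peak centre, default) or `"summit"`.
#' @param min_width Minimum clipped window width (default 50).
#' @return list `sequences` (character, named by region index) and
#'   `n_dropped`.
#' @export
extract_target_windows <- function(records, genome, half_width = 150L,
                                   status = "gain",
                                   center = c("midpoint", "summit"),
                                   min_width = 50L) {
  center_mode <- match.arg(center)
  if (!is.null(status) && "status" %in% names(records))
    records <- records[records$status == status, , drop = FALSE]
  chars <- if (methods::is(genome, "DNAStringSet"))
    stats::setNames(as.character(genome), names(genome)) else genome
  seqs <- character(0); dropped <- 0L
  for (i in seq_len(nrow(records))) {
    chrom <- records$chrom[i]
    center <- if (center_mode == "summit" && !is.null(records$summit) &&
                  !is.na(records$summit[i]))
      records$summit[i] else floor((records$start[i] + records$end[i]) / 2)
    clen <- nchar(chars[[chrom]])
    s <- max(0, center - half_width); e <- min(clen, center + half_width)
    if (e - s < min_width) { dropped <- dropped + 1L; next }
    seqs[length(seqs) + 1L] <- substr(chars[[chrom]], s + 1L, e)
    names(seqs)[length(seqs)] <- rownames(records)[i]
  }
  list(sequences = seqs, n_dropped = dropped)
}
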