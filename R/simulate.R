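#' Simulation configuration for the two-condition synthetic epigenome
#'
#' The generator emulates a wild-type (WT) versus knockout (KO) comparison in
#' which the KO loses gene-body H2Bub1. Planted structure:
#' * H2Bub1 (WT) decays exponentially 5'->3' over each gene body with the
#'   configured half-life; the KO retains only background.
#' * H3K4me3 is a TSS-anchored asymmetric peak (sharp 5' rise, longer 3'
#'   decay into the gene body). The KO width is the WT width times
#'   `1 - ko_width_shrink_slope * u`, floored at 0.2x, where `u` is the
#'   gene's H2Bub1 occupancy quantile; the KO summit moves `summit_shift_bp`
#'   5'-ward; the KO height drops by the (class-independent)
#'   `k4_ko_height_factor`.
#' * PRC2-target genes carry an H3K27me3 plateau over TSS +/- 1 kb that the
#'   KO depletes by `k27me3_ko_depletion_factor`, with reciprocal promoter
#'   H3K27ac gain and a positive expression fold change.
#' * rnf40-dependent genes are downregulated and lose gene-body (not TSS)
#'   Pol II signal in the KO.
#' * Enhancers are distal H3K4me1+/H3K27ac+ intervals without H3K4me3;
#'   motif-bearing enhancers (assigned to foxl2-target genes) carry an
#'   embedded Forkhead-like consensus and gain H3K27ac by
#'   `enhancer_gain_log2fc` in the KO.
#' * Expression counts are negative binomial; the planted log2 fold-change
#'   magnitude is scaled by H2Bub1 quartile (largest in the M and L
#'   quartiles).
#' * Per-bp signal is a smooth profile times gamma-distributed multiplicative
#'   noise drawn per `noise_tile` bp (mean 1, shape `noise_shape`).
#'
#' @param n_chroms,chrom_len Number and length (bp) of chromosomes.
#' @param n_genes Total number of genes (>= 4).
#' @param gene_len_range Min/max gene length in bp.
#' @param n_enhancers Number of distal enhancers to place.
#' @param frac_rnf40_dependent,frac_prc2_target,frac_foxl2_enhancer_target
#'   Fractions of genes in each (mutually exclusive) planted class.
#' @param h2bub1_decay_halflife 5'->3' decay half-life in bp.
#' @param k4_width_meanlog,k4_width_sdlog Lognormal parameters of the WT
#'   H3K4me3 width distribution (bp).
#' @param ko_width_shrink_slope Narrowing per unit H2Bub1 occupancy quantile.
#' @param summit_shift_bp Planted 5'-ward KO summit displacement (bp).
#' @param k4_ko_height_factor KO/WT H3K4me3 height ratio (class-independent).
#' @param k27me3_ko_depletion_factor Fractional KO loss of H3K27me3 at
#'   PRC2-target promoters.
#' @param enhancer_gain_log2fc Planted KO H3K27ac log2 gain at motif
#'   enhancers.
#' @param expr_effect_log2fc Base magnitude of planted expression fold
#'   changes (scaled by quartile).
#' @param nb_dispersion Negative-binomial dispersion of the counts.
#' @param n_replicates Replicates per condition (>= 2).
#' @param noise_shape Gamma shape of the multiplicative coverage noise.
#' @param noise_tile Tile size (bp) at which noise is drawn.
#' @param baseline Background coverage level (per bp).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 4L, chrom_len = 3e6, n_genes = 500L,
                       gene_len_range = c(2000L, 8000L), n_enhancers = 300L,
                       frac_rnf40_dependent = 0.30, frac_prc2_target = 0.20,
                       frac_foxl2_enhancer_target = 0.15,
                       h2bub1_decay_halflife = 3000,
                       k4_width_meanlog = log(800), k4_width_sdlog = 0.6,
                       ko_width_shrink_slope = 0.5, summit_shift_bp = 50,
                       k4_ko_height_factor = 0.8,
                       k27me3_ko_depletion_factor = 0.8,
                       enhancer_gain_log2fc = 2.5,
                       expr_effect_log2fc = 2.2,
                       nb_dispersion = 0.05, n_replicates = 3L,
                       noise_shape = 25, noise_tile = 20L, baseline = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_rnf40_dependent, frac_prc2_target, frac_foxl2_enhancer_target)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stop("class fractions must be in [0,1] and sum to <= 1")
  if (k27me3_ko_depletion_factor < 0 || k27me3_ko_depletion_factor > 1)
    stop("k27me3_ko_depletion_factor must be in [0,1]")
  if (n_replicates < 2L) stop("n_replicates must be >= 2")
  if (gene_len_range[1] <= 0 || gene_len_range[2] < gene_len_range[1])
    stop("invalid gene_len_range")
  if (n_genes < 4L) stop("n_genes must be >= 4")
  structure(cfg, class = "sim_config")
}

#' Read a simulation configuration from YAML
#'
#' Field names mirror the [sim_config()] arguments.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, vals)
}

FOX_CONSENSUS <- "GTAAACAA"

# quartile of the H2Bub1 occupancy quantile u (H = top quartile)
u_quartile <- function(u) {
  cut(u, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf),
      labels = c("No", "L", "M", "H"))
}

QUARTILE_EFFECT_MULT <- c(H = 0.6, M = 1.4, L = 1.4, No = 0.6)

# add a two-sided exponential-decay peak into `v` (1-indexed vector)
add_exp_peak <- function(v, apex0, tau_left, tau_right, height) {
  len <- length(v)
  lo <- max(0L, as.integer(apex0 - 3 * tau_left))
  hi <- min(len - 1L, as.integer(apex0 + 3 * tau_right))
  if (lo > hi) return(v)
  pos <- lo:hi
  d <- pos - apex0
  prof <- ifelse(d < 0, height * exp(d / tau_left),
                 height * exp(-d / tau_right))
  v[pos + 1L] <- v[pos + 1L] + prof
  v
}

add_plateau <- function(v, start0, end0, height) {
  len <- length(v)
  s <- max(0L, as.integer(start0)); e <- min(len, as.integer(end0))
  if (s >= e) return(v)
  v[(s + 1L):e] <- v[(s + 1L):e] + height
  v
}

tile_noise <- function(len, tile, shape, seed) {
  ntile <- ceiling(len / tile)
  g <- with_local_seed(seed, stats::rgamma(ntile, shape = shape,
                                           rate = shape))
  rep(g, each = tile)[seq_len(len)]
}

#' Simulate a two-condition synthetic epigenome
#'
#' Deterministic given `config$seed` (a hierarchical substream scheme keeps
#' early genes stable when more are added). See [sim_config()] for the
#' planted structure.
#'
#' @param config A `sim_config`.
#' @return list with `config`, `annotation` (a `genome_annotation`),
#'   `genome` (named character vector of chromosome sequences), `tracks`
#'   (`tracks[[mark]][[cond]]`, a `coverage_track` per mark in H2Bub1,
#'   H3K4me3, H3K27me3, H3K27ac, H3K4me1, PolII and condition WT/KO),
#'   `replicate_tracks` (`[[mark]][[cond]][[rep]]` for H3K27me3 and
#'   H3K27ac), `counts` (genes x samples), `condition` (named sample ->
#'   WT/KO), `enhancers` (data.frame) and `truth` (list `genes`,
#'   `enhancers`).
#' @export
simulate_epigenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(as.integer(cfg$chrom_len),
                                     cfg$n_chroms), chroms)
  margin <- 25000L
  min_gap <- 12000L; max_gap <- 18000L

  ## ---- gene placement -----------------------------------------------------
  n_per <- diff(floor(cfg$n_genes * (0:cfg$n_chroms) / cfg$n_chroms))
  genes <- list()
  gidx <- 0L
  for (ci in seq_along(chroms)) {
    placed <- with_local_seed(derive_seed(cfg$seed, 1L, ci), {
      pos <- margin
      rows <- vector("list", n_per[ci])
      for (k in seq_len(n_per[ci])) {
        gap <- round(stats::runif(1, min_gap, max_gap))
        len <- round(stats::runif(1, cfg$gene_len_range[1],
                                  cfg$gene_len_range[2]))
        start <- pos + gap
        if (start + len > cfg$chrom_len - margin)
          stop("chromosome ", chroms[ci], " too short for the requested ",
               "gene count; increase chrom_len or reduce n_genes")
        rows[[k]] <- data.frame(start = start, end = start + len,
                                strand = sample(c("+", "-"), 1))
        pos <- start + len
      }
      do.call(rbind, rows)
    })
    if (is.null(placed)) next
    placed$chrom <- chroms[ci]
    placed$gene_id <- sprintf("gene_%04d", gidx + seq_len(nrow(placed)))
    gidx <- gidx + nrow(placed)
    genes[[ci]] <- placed
  }
  genes <- do.call(rbind, genes)
  annotation <- genome_annotation(genes, chrom_sizes)
  n <- nrow(genes)

  ## ---- gene classes -------------------------------------------------------
  n_rnf40 <- round(cfg$frac_rnf40_dependent * n)
  n_prc2 <- round(cfg$frac_prc2_target * n)
  n_fox <- round(cfg$frac_foxl2_enhancer_target * n)
  class <- rep("background", n)
  picked <- with_local_seed(derive_seed(cfg$seed, 2L),
                            sample.int(n, n_rnf40 + n_prc2 + n_fox))
  if (n_rnf40) class[picked[seq_len(n_rnf40)]] <- "rnf40_dependent"
  if (n_prc2) class[picked[n_rnf40 + seq_len(n_prc2)]] <- "prc2_target"
  if (n_fox) class[picked[n_rnf40 + n_prc2 + seq_len(n_fox)]] <- "foxl2_target"

  ## ---- per-gene parameters ------------------------------------------------
  rho <- 0.7   # H2Bub1 <-> H3K4me3 width coupling
  par <- lapply(seq_len(n), function(i) with_local_seed(
    derive_seed(cfg$seed, 3L, i), {
      z <- stats::rnorm(1)
      eps <- stats::rnorm(1)
      u <- stats::pnorm(z)
      width_wt <- exp(cfg$k4_width_meanlog +
                        cfg$k4_width_sdlog * (rho * z + sqrt(1 - rho^2) * eps))
      width_wt <- min(max(width_wt, 250), 6000)
      shrink <- max(0.2, 1 - cfg$ko_width_shrink_slope * u)
      list(u = u,
           h2bub1_amp = 2 * exp(0.8 * z),
           width_wt = width_wt,
           width_ko = width_wt * shrink,
           k4_height = stats::rlnorm(1, log(15), 0.4),
           k4_height_ko_jitter = exp(stats::rnorm(1, 0, 0.05)),
           k27me3_amp = stats::rlnorm(1, log(8), 0.3),
           polii_tss = stats::rlnorm(1, log(10), 0.3),
           polii_body = stats::rlnorm(1, log(2), 0.3),
           # expression level mildly coupled to H2Bub1 occupancy
           expr_mu = stats::rlnorm(1, log(120) + 0.5 * z, 0.8))
    }))
  u <- vapply(par, `[[`, numeric(1), "u")
  quart <- as.character(u_quartile(u))
  eff_mult <- QUARTILE_EFFECT_MULT[quart]
  lfc <- numeric(n)
  lfc[class == "rnf40_dependent"] <-
    -cfg$expr_effect_log2fc * eff_mult[class == "rnf40_dependent"]
  lfc[class == "prc2_target"] <-
    cfg$expr_effect_log2fc * eff_mult[class == "prc2_target"]
  lfc[class == "foxl2_target"] <-
    cfg$expr_effect_log2fc * eff_mult[class == "foxl2_target"]

  tss <- gene_tss(annotation)

  ## ---- enhancer placement -------------------------------------------------
  enh_width <- 800L
  gaps <- list()
  for (ci in seq_along(chroms)) {
    gc <- genes[genes$chrom == chroms[ci], ]
    gc <- gc[order(gc$start), ]
    if (nrow(gc) < 2L) next
    gap_start <- gc$end[-nrow(gc)]
    gap_end <- gc$start[-1]
    keep <- (gap_end - gap_start) >= min_gap
    if (!any(keep)) next
    gaps[[ci]] <- data.frame(
      chrom = chroms[ci], gap_start = gap_start[keep], gap_end = gap_end[keep],
      left_gene = gc$gene_id[-nrow(gc)][keep], right_gene = gc$gene_id[-1][keep])
  }
  gaps <- do.call(rbind, gaps)
  gaps$center <- floor((gaps$gap_start + gaps$gap_end) / 2)
  fox_ids <- genes$gene_id[class == "foxl2_target"]
  claimed <- rep(NA_character_, nrow(gaps))  # gap -> assigned gene
  has_motif_gap <- rep(FALSE, nrow(gaps))
  for (gid in fox_ids) {
    cand <- which(is.na(claimed) &
                    (gaps$left_gene == gid | gaps$right_gene == gid))
    if (!length(cand)) next   # no free flanking gap (rare)
    claimed[cand[1]] <- gid
    has_motif_gap[cand[1]] <- TRUE
  }
  free <- which(is.na(claimed))
  n_extra <- max(0L, cfg$n_enhancers - sum(!is.na(claimed)))
  extra <- with_local_seed(derive_seed(cfg$seed, 4L),
                           free[sample.int(length(free),
                                           min(n_extra, length(free)))])
  # assign background enhancers to the nearer flanking gene (by TSS)
  for (i in extra) {
    dl <- abs(gaps$center[i] - tss[[gaps$left_gene[i]]])
    dr <- abs(gaps$center[i] - tss[[gaps$right_gene[i]]])
    claimed[i] <- if (dl <= dr) gaps$left_gene[i] else gaps$right_gene[i]
  }
  sel <- which(!is.na(claimed))
  sel <- sel[order(gaps$chrom[sel], gaps$center[sel])]
  enhancers <- data.frame(
    enhancer_id = sprintf("enh_%04d", seq_along(sel)),
    chrom = gaps$chrom[sel],
    start = as.integer(gaps$center[sel] - enh_width / 2),
    end = as.integer(gaps$center[sel] + enh_width / 2),
    has_motif = has_motif_gap[sel],
    assigned_gene = claimed[sel],
    planted_k27ac_log2fc = ifelse(has_motif_gap[sel],
                                  cfg$enhancer_gain_log2fc, 0),
    row.names = NULL)

  ## ---- genome sequence ----------------------------------------------------
  bases <- c("A", "C", "G", "T")
  genome <- stats::setNames(vector("list", length(chroms)), chroms)
  for (ci in seq_along(chroms)) {
    chars <- with_local_seed(derive_seed(cfg$seed, 5L, ci),
                             bases[sample.int(4, chrom_sizes[ci],
                                              replace = TRUE)])
    motif_enh <- enhancers[enhancers$chrom == chroms[ci] & enhancers$has_motif, ]
    mchars <- strsplit(FOX_CONSENSUS, "")[[1]]
    for (k in seq_len(nrow(motif_enh))) {
      center <- floor((motif_enh$start[k] + motif_enh$end[k]) / 2)
      pos0 <- center - floor(length(mchars) / 2)   # 0-based embed start
      chars[pos0 + seq_along(mchars)] <- mchars
    }
    genome[[ci]] <- paste(chars, collapse = "")
  }
  genome <- unlist(genome)

  ## ---- coverage profiles and tracks ---------------------------------------
  marks <- c("H2Bub1", "H3K4me3", "H3K27me3", "H3K27ac", "H3K4me1", "PolII")
  conds <- c("WT", "KO")
  rep_marks <- c("H3K27me3", "H3K27ac")
  tracks <- lapply(marks, function(m)
    stats::setNames(vector("list", 2), conds))
  names(tracks) <- marks
  replicate_tracks <- lapply(rep_marks, function(m)
    stats::setNames(list(vector("list", cfg$n_replicates),
                         vector("list", cfg$n_replicates)), conds))
  names(replicate_tracks) <- rep_marks
  vals <- lapply(marks, function(m)
    stats::setNames(list(list(), list()), conds))
  names(vals) <- marks
  rep_vals <- lapply(rep_marks, function(m)
    stats::setNames(list(lapply(seq_len(cfg$n_replicates), function(r) list()),
                         lapply(seq_len(cfg$n_replicates), function(r) list())),
                    conds))
  names(rep_vals) <- rep_marks

  summit_off <- 150   # WT summit sits this far 3' of the TSS
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    len <- chrom_sizes[[chrom]]
    gc_idx <- which(genes$chrom == chrom)
    prof <- lapply(marks, function(m)
      stats::setNames(list(rep(cfg$baseline, len), rep(cfg$baseline, len)),
                      conds))
    names(prof) <- marks
    for (i in gc_idx) {
      p <- par[[i]]
      s <- genes$start[i]; e <- genes$end[i]
      plus <- genes$strand[i] == "+"
      t0 <- tss[[genes$gene_id[i]]]
      dirn <- if (plus) 1 else -1
      ## H2Bub1: WT gene-body 5'->3' exponential decay
      body <- s:(e - 1L)
      d <- if (plus) body - s else (e - 1L) - body
      prof$H2Bub1$WT[body + 1L] <- prof$H2Bub1$WT[body + 1L] +
        p$h2bub1_amp * exp(-log(2) * d / cfg$h2bub1_decay_halflife)
      ## H3K4me3: asymmetric TSS-anchored peak, KO narrowed + 5'-shifted
      for (cond in conds) {
        w <- if (cond == "WT") p$width_wt else p$width_ko
        h <- if (cond == "WT") p$k4_height else
          p$k4_height * cfg$k4_ko_height_factor * p$k4_height_ko_jitter
        apex <- if (cond == "WT") t0 + dirn * summit_off else
          t0 + dirn * (summit_off - cfg$summit_shift_bp)
        tau5 <- 0.1 * w; tau3 <- w / 3 - tau5   # 3*(tau5+tau3) = w
        tl <- if (plus) tau5 else tau3
        tr <- if (plus) tau3 else tau5
        prof$H3K4me3[[cond]] <- add_exp_peak(prof$H3K4me3[[cond]], apex,
                                             tl, tr, h)
      }
      ## promoter H3K27me3 / H3K27ac
      if (class[i] == "prc2_target") {
        prof$H3K27me3$WT <- add_plateau(prof$H3K27me3$WT, t0 - 1000, t0 + 1000,
                                        p$k27me3_amp)
        prof$H3K27me3$KO <- add_plateau(prof$H3K27me3$KO, t0 - 1000, t0 + 1000,
                                        p$k27me3_amp *
                                          (1 - cfg$k27me3_ko_depletion_factor))
        prof$H3K27ac$WT <- add_plateau(prof$H3K27ac$WT, t0 - 1000, t0 + 1000, 0.5)
        prof$H3K27ac$KO <- add_plateau(prof$H3K27ac$KO, t0 - 1000, t0 + 1000,
                                       0.5 + 5.5 * cfg$k27me3_ko_depletion_factor)
      } else {
        for (cond in conds)
          prof$H3K27ac[[cond]] <- add_plateau(prof$H3K27ac[[cond]],
                                              t0 - 1000, t0 + 1000, 3)
      }
      ## Pol II: TSS peak + gene-body plateau (body lost in KO for
      ## rnf40-dependent genes)
      for (cond in conds) {
        prof$PolII[[cond]] <- add_exp_peak(prof$PolII[[cond]], t0, 150, 150,
                                           p$polii_tss)
        body_level <- if (cond == "KO" && class[i] == "rnf40_dependent")
          0.4 * p$polii_body else p$polii_body
        prof$PolII[[cond]] <- add_plateau(prof$PolII[[cond]], s, e, body_level)
      }
    }
    ## enhancer marks
    ec <- enhancers[enhancers$chrom == chrom, ]
    for (k in seq_len(nrow(ec))) {
      for (cond in conds) {
        prof$H3K4me1[[cond]] <- add_plateau(prof$H3K4me1[[cond]],
                                            ec$start[k] - 200, ec$end[k] + 200, 5)
        lev <- if (cond == "KO" && ec$has_motif[k])
          5 * 2^cfg$enhancer_gain_log2fc else 5
        prof$H3K27ac[[cond]] <- add_plateau(prof$H3K27ac[[cond]],
                                            ec$start[k], ec$end[k], lev)
      }
    }
    ## noise layers
    for (mi in seq_along(marks)) {
      m <- marks[mi]
      for (cj in seq_along(conds)) {
        cond <- conds[cj]
        if (m %in% rep_marks) {
          acc <- numeric(len)
          for (r in seq_len(cfg$n_replicates)) {
            nz <- tile_noise(len, cfg$noise_tile, cfg$noise_shape,
                             derive_seed(cfg$seed, 6L, mi, cj, r, ci))
            v <- prof[[m]][[cond]] * nz
            rep_vals[[m]][[cond]][[r]][[chrom]] <- v
            acc <- acc + v
          }
          vals[[m]][[cond]][[chrom]] <- acc / cfg$n_replicates
        } else {
          nz <- tile_noise(len, cfg$noise_tile, cfg$noise_shape,
                           derive_seed(cfg$seed, 6L, mi, cj, 1L, ci))
          vals[[m]][[cond]][[chrom]] <- prof[[m]][[cond]] * nz
        }
      }
    }
    # bound transient garbage from the per-layer noise expansions
    rm(prof); invisible(gc(verbose = FALSE))
  }
  for (m in marks) for (cond in conds)
    tracks[[m]][[cond]] <- coverage_track(vals[[m]][[cond]])
  for (m in rep_marks) for (cond in conds)
    for (r in seq_len(cfg$n_replicates))
      replicate_tracks[[m]][[cond]][[r]] <-
        coverage_track(rep_vals[[m]][[cond]][[r]])

  ## ---- expression counts --------------------------------------------------
  sample_ids <- c(paste0("WT_", seq_len(cfg$n_replicates)),
                  paste0("KO_", seq_len(cfg$n_replicates)))
  condition <- stats::setNames(rep(conds, each = cfg$n_replicates), sample_ids)
  depth <- with_local_seed(derive_seed(cfg$seed, 7L),
                           exp(stats::rnorm(length(sample_ids), 0, 0.1)))
  counts <- matrix(0L, nrow = n, ncol = length(sample_ids),
                   dimnames = list(genes$gene_id, sample_ids))
  size <- 1 / cfg$nb_dispersion
  for (i in seq_len(n)) {
    mu <- par[[i]]$expr_mu * ifelse(condition == "KO", 2^lfc[i], 1) * depth
    counts[i, ] <- with_local_seed(derive_seed(cfg$seed, 8L, i),
                                   stats::rnbinom(length(mu), mu = mu,
                                                  size = size))
  }

  truth_genes <- data.frame(
    gene_id = genes$gene_id, class = class,
    h2bub1_quantile = u,
    h2bub1_quartile = quart,
    planted_width_wt = vapply(par, `[[`, numeric(1), "width_wt"),
    planted_width_ko = vapply(par, `[[`, numeric(1), "width_ko"),
    planted_summit_shift = cfg$summit_shift_bp,
    planted_expression_log2fc = lfc,
    row.names = NULL)

  list(config = cfg, annotation = annotation, genome = genome,
       tracks = tracks, replicate_tracks = replicate_tracks,
       counts = counts, condition = condition, enhancers = enhancers,
       truth = list(genes = truth_genes,
                    enhancers = enhancers[c("enhancer_id", "has_motif",
                                            "planted_k27ac_log2fc",
                                            "assigned_gene")]))
}

#' Null configuration: no planted effects
#'
#' Convenience wrapper for [sim_config()] with all class fractions, the
#' width shrink, the summit shift, the height drop, the H3K27me3 depletion
#' and the enhancer gain set to zero (or one), so WT and KO differ only by
#' noise.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_sim_config <- function(...) {
  args <- list(frac_rnf40_dependent = 0, frac_prc2_target = 0,
               frac_foxl2_enhancer_target = 0, ko_width_shrink_slope = 0,
               summit_shift_bp = 0, k4_ko_height_factor = 1,
               k27me3_ko_depletion_factor = 0, enhancer_gain_log2fc = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

#' Write a simulation bundle to disk
#'
#' Writes `genome.fa`, `genes.bed` (BED12), one `{mark}_{cond}.bedGraph`
#' per mark and condition (the replicate-mean tracks; 12 files),
#' `counts.tsv`, `enhancers.bed`, `truth.json` and a `manifest.json`
#' listing every file with its MD5 checksum.
#'
#' @param sim Result of [simulate_epigenome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a named list file -> checksum.
#' @export
write_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), fa)
  files <- c(files, fa)
  g <- sim$annotation$genes
  bed12 <- data.table::data.table(
    chrom = g$chrom, start = g$start, end = g$end, name = g$gene_id,
    score = 0L, strand = g$strand, thickStart = g$start, thickEnd = g$end,
    rgb = "0,0,0", blockCount = 1L, blockSizes = g$end - g$start,
    blockStarts = 0L)
  genes_bed <- file.path(dir, "genes.bed")
  data.table::fwrite(bed12, genes_bed, sep = "\t", col.names = FALSE)
  files <- c(files, genes_bed)
  for (m in names(sim$tracks)) for (cond in names(sim$tracks[[m]])) {
    f <- file.path(dir, sprintf("%s_%s.bedGraph", m, cond))
    write_coverage(sim$tracks[[m]][[cond]], f)
    files <- c(files, f)
  }
  counts_f <- file.path(dir, "counts.tsv")
  dt <- data.table::data.table(gene_id = rownames(sim$counts))
  for (s in colnames(sim$counts)) dt[[s]] <- sim$counts[, s]
  data.table::fwrite(dt, counts_f, sep = "\t")
  files <- c(files, counts_f)
  enh_f <- file.path(dir, "enhancers.bed")
  data.table::fwrite(
    data.table::data.table(chrom = sim$enhancers$chrom,
                           start = sim$enhancers$start,
                           end = sim$enhancers$end,
                           name = sim$enhancers$enhancer_id,
                           score = 0L, strand = "."),
    enh_f, sep = "\t", col.names = FALSE)
  files <- c(files, enh_f)
  truth_f <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, truth_f, dataframe = "columns",
                       digits = NA, pretty = TRUE)
  files <- c(files, truth_f)
  sums <- tools::md5sum(files)
  manifest <- stats::setNames(as.list(unname(sums)), basename(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a truth table back from JSON
#' @param path `truth.json` written by [write_bundle()].
#' @return list with `genes` and `enhancers` data.frames.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(genes = as.data.frame(x$genes), enhancers = as.data.frame(x$enhancers))
}
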