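consensus_of <- function(pfm) {
  paste(rownames(pfm)[apply(pfm, 2, which.max)], collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# independent oracle: score one window naively against the log-odds matrix
naive_score <- function(seq, pwm, pos) {
  chars <- strsplit(substr(seq, pos, pos + ncol(pwm) - 1), "")[[1]]
  sum(vapply(seq_along(chars), function(j) pwm[chars[j], j], numeric(1)))
}

test_that("JASPAR panels parse into 4 x L count matrices", {
  pfms <- demo_pfms()
  expect_gte(length(pfms), 20L)
  expect_true(all(vapply(pfms, nrow, integer(1)) == 4L))
  expect_true(all(vapply(pfms, ncol, integer(1)) >= 4L))
  expect_equal(rownames(pfms[[1]]), c("A", "C", "G", "T"))
  expect_equal(consensus_of(pfms$FOXL2_like), "GTAAACAA")
})

test_that("a planted consensus is found at the right position and strand", {
  pfm <- fox_pfm()
  cons <- consensus_of(pfm)
  seq <- paste0(strrep("C", 50), cons, strrep("A", 42))
  hits <- pwm_scan(seq, pfm, rel_score_threshold = 0.85)
  fwd <- hits[hits$strand == "+", ]
  expect_equal(fwd$pos, 51L)
  expect_equal(fwd$rel_score, 1, tolerance = 1e-12)
  # reverse complement: one hit on the minus strand at the same window
  seq_rc <- paste0(strrep("C", 30), revcomp(cons), strrep("G", 30))
  hits_rc <- pwm_scan(seq_rc, pfm, rel_score_threshold = 0.95)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$pos, 31L)
  # sequences shorter than the motif give no hits
  expect_equal(nrow(pwm_scan("ACG", pfm)), 0L)
})

test_that("pwm_scan agrees with exhaustive brute-force window scoring", {
  set.seed(15)
  pfm <- fox_pfm()
  pwm <- pfm_to_pwm(pfm)
  lo <- attr(pwm, "min_score"); hi <- attr(pwm, "max_score")
  thr <- lo + 0.8 * (hi - lo)
  seq <- paste0(random_dna(1, 600), consensus_of(pfm), random_dna(1, 400))
  hits <- pwm_scan(seq, pfm, rel_score_threshold = 0.8)
  L <- ncol(pfm)
  # every reported + strand hit's score equals the naive rescoring
  for (i in which(hits$strand == "+"))
    expect_equal(hits$score[i], naive_score(seq, pwm, hits$pos[i]))
  # exhaustive scan: every above-threshold window is represented by a
  # reported hit within L-1 bp scoring at least as high
  nwin <- nchar(seq) - L + 1L
  fwd_scores <- vapply(seq_len(nwin), function(p) naive_score(seq, pwm, p),
                       numeric(1))
  above <- which(fwd_scores >= thr)
  fwd_hits <- hits[hits$strand == "+", ]
  expect_true(all(fwd_hits$score >= thr))
  for (p in above) {
    near <- fwd_hits[abs(fwd_hits$pos - p) < L, ]
    expect_gte(nrow(near), 1L)
    expect_gte(max(near$score) + 1e-9, fwd_scores[p])
  }
})

test_that("fisher score is the exact hypergeometric upper tail", {
  # equal proportions: no enrichment, p >= 0.5
  eq <- fisher_score(10, 100, 10, 100)
  expect_gte(eq$pvalue, 0.5)
  expect_lte(eq$score, log(2))
  # 10/20 vs 10/100 against a direct dhyper enumeration
  fs <- fisher_score(10, 20, 10, 100)
  p_oracle <- sum(dhyper(10:20, 20, 100, 20))
  expect_equal(fs$pvalue, p_oracle, tolerance = 1e-12)
  # fully unbalanced table: closed-form tail
  fs2 <- fisher_score(20, 20, 0, 100)
  expect_equal(fs2$pvalue, dhyper(20, 20, 100, 20), tolerance = 1e-12)
  expect_equal(fs2$score, -log(dhyper(20, 20, 100, 20)))
  # agreement with fisher.test and monotonicity in t_hit
  ft <- fisher.test(matrix(c(15, 5, 10, 90), 2, byrow = TRUE),
                    alternative = "greater")$p.value
  expect_equal(fisher_score(15, 20, 10, 100)$pvalue, ft, tolerance = 1e-9)
  scores <- vapply(5:20, function(k) fisher_score(k, 20, 10, 100)$score,
                   numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_error(fisher_score(5, 0, 1, 10), "empty")
})

test_that("motif z score is the continuity-corrected standardised excess", {
  z <- motif_z_score(300, 10000, 100, 10000)
  expect_equal(z$z, (300 - 100 - 0.5) / sqrt(10000 * 0.01 * 0.99),
               tolerance = 1e-12)
  expect_equal(z$z, 20.05, tolerance = 1e-3)
  # equal rates: |z| small (continuity correction only)
  z0 <- motif_z_score(100, 10000, 100, 10000)
  expect_lt(abs(z0$z), 0.1)
  # doubling hits and positions at fixed rates scales z by ~sqrt(2)
  z1 <- motif_z_score(300, 10000, 100, 10000)
  z2 <- motif_z_score(600, 20000, 200, 20000)
  expect_equal(z2$z / z1$z, sqrt(2), tolerance = 0.01)
  expect_false(motif_z_score(0, 100, 0, 100)$defined)
})

test_that("enrich_motifs flags planted motifs and not null panels", {
  set.seed(16)
  pfm <- fox_pfm()
  cons <- consensus_of(pfm)
  embed <- function(s) {
    at <- sample(nchar(s) - nchar(cons), 1)
    paste0(substr(s, 1, at - 1), cons,
           substr(s, at + nchar(cons), nchar(s)))
  }
  targets <- random_dna(50, 200)
  targets[1:40] <- vapply(targets[1:40], embed, character(1))
  background <- random_dna(100, 200)
  background[1:5] <- vapply(background[1:5], embed, character(1))
  res <- enrich_motifs(targets, background, list(FOX = pfm))
  expect_true(res$enriched[1])
  expect_gt(res$fisher_score[1], 5)
  expect_gt(res$z_score[1], 10)
  # motif absent everywhere: near-zero score, not enriched
  gcpoor <- vapply(seq_len(30), function(i)
    paste(sample(c("C", "G"), 100, replace = TRUE), collapse = ""),
    character(1))
  res0 <- enrich_motifs(gcpoor[1:15], gcpoor[16:30], list(FOX = pfm))
  expect_false(res0$enriched[1])
  expect_equal(res0$target_regions_hit, 0L)
  expect_equal(res0$fisher_score, 0, tolerance = 1e-9)
  # identical target and background sets: nothing enriched
  same <- random_dna(40, 200)
  res1 <- enrich_motifs(same, same, demo_pfms())
  expect_false(any(res1$enriched))
})

test_that("target windows are peak-centred, clipped, and filtered", {
  genome <- c(chr1 = paste(rep("ACGT", 500), collapse = ""))  # 2 kb
  rec <- data.frame(chrom = "chr1", start = c(850, 0, 1970),
                    end = c(1150, 200, 2000),
                    status = c("gain", "gain", "gain"))
  got <- extract_target_windows(rec, genome, half_width = 150,
                                min_width = 260)
  # centre 1000 -> [850, 1150); centre 100 -> clipped to [0, 250)... which
  # falls below min_width and is dropped, as is the chromosome-end window
  expect_equal(length(got$sequences), 1L)
  expect_equal(unname(nchar(got$sequences[1])), 300L)
  expect_equal(unname(got$sequences[1]), unname(substr(genome, 851, 1150)))
  expect_equal(got$n_dropped, 2L)
  all3 <- extract_target_windows(rec, genome, half_width = 150)
  expect_equal(unname(nchar(all3$sequences[2])), 250L)
  expect_equal(unname(all3$sequences[2]), unname(substr(genome, 1, 250)))
  expect_equal(all3$n_dropped, 0L)
  # status filter selects the background set
  rec$status <- c("gain", "stable", "stable")
  bg <- extract_target_windows(rec, genome, half_width = 100,
                               status = "stable")
  expect_equal(length(bg$sequences), 2L)
})
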