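uniform_track <- function(level, len, chrom = "chr1")
  coverage_track(setNames(list(rep(level, len)), chrom))

test_that("a flat track equal to background yields no peaks", {
  sig <- uniform_track(1, 10000)
  bg <- uniform_track(1, 10000)
  expect_equal(nrow(call_peaks(sig, background = bg)), 0L)
  expect_equal(nrow(call_peaks(uniform_track(0, 10000))), 0L)
  expect_error(call_peaks(sig, p_cutoff = 0), "p_cutoff")
})

test_that("an enriched block over uniform background is one peak with the
          closed-form Poisson tail", {
  v <- rep(1, 10000)
  v[5001:5200] <- 10            # 0-based [5000, 5200)
  sig <- track1(v)
  bg <- uniform_track(1, 10000)
  pk <- call_peaks(sig, background = bg, p_cutoff = 1e-5)
  expect_equal(nrow(pk), 1L)
  expect_lte(pk$start, 5000)
  expect_gte(pk$end, 5200)
  # independent oracle: best window is fully inside the block
  lambda <- 1 * 150
  p_oracle <- ppois(ceiling(10 * 150) - 1, lambda, lower.tail = FALSE)
  expect_equal(pk$pvalue, p_oracle)
  expect_lt(pk$pvalue, 1e-5)
  expect_equal(pk$height, 10)
})

test_that("merge gap separates or joins nearby enriched regions", {
  mk <- function(sep) {
    v <- rep(1, 20000)
    v[5001:5300] <- 10
    v[(5300 + sep + 1):(5300 + sep + 300)] <- 10
    call_peaks(track1(v), background = uniform_track(1, 20000))
  }
  expect_equal(nrow(mk(150)), 1L)   # closer than extended-window gap: joined
  expect_equal(nrow(mk(700)), 2L)   # well separated: two peaks
})

test_that("called peaks are sorted, non-overlapping, and significant", {
  sim <- tiny_sim()
  pk <- call_peaks(sim$tracks$H3K4me3$WT)
  expect_true(all(diff(pk$start) > 0))
  expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
  expect_true(all(pk$pvalue < 1e-5))
  expect_true(all(pk$width >= 100))
  expect_true(all(pk$start <= pk$summit & pk$summit < pk$end))
})

test_that("peak metrics report width, height, leftmost-max summit", {
  v <- rep(0, 300)
  v[101:200] <- c(seq(0.14, 7, length.out = 50), seq(7, 0.14, length.out = 50))
  tr <- track1(v)
  pk <- peak_metrics(tr, data.frame(chrom = "chr1", start = 100L, end = 200L))
  expect_equal(pk$width, 100L)
  expect_equal(pk$height, 7)
  expect_equal(pk$summit, 149L)  # leftmost of the two tied maxima
  # plateau: summit is the leftmost maximum
  v2 <- rep(0, 100); v2[41:60] <- 5
  pk2 <- peak_metrics(track1(v2), data.frame(chrom = "chr1", start = 0L,
                                             end = 100L))
  expect_equal(pk2$summit, 40L)
  # random profile: brute-force scan oracle
  set.seed(3)
  v3 <- runif(400)
  pk3 <- peak_metrics(track1(v3), data.frame(chrom = "chr1", start = 50L,
                                             end = 350L))
  seg <- v3[51:350]
  expect_equal(pk3$height, max(seg))
  expect_equal(pk3$summit, 50L + which.max(seg) - 1L)
})

test_that("TSS peak assignment picks the widest overlapping peak", {
  ann <- ann1(data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                         end = 15000, strand = "+"))
  peaks <- data.frame(chrom = "chr1", start = c(9500, 9000, 20000),
                      end = c(9800, 9800, 21000),
                      summit = c(9600, 9400, 20500),
                      height = c(5, 4, 9), width = c(300, 800, 1000),
                      pvalue = 1e-9)
  got <- assign_tss_peak(peaks, ann, window = 2000)
  expect_equal(nrow(got), 1L)
  expect_equal(got$width, 800)   # widest wins; 20 kb peak is out of window
  # peak 3 kb away with a 2 kb window -> unassigned
  far <- data.frame(chrom = "chr1", start = 13000, end = 13500,
                    summit = 13200, height = 5, width = 500, pvalue = 1e-9)
  ann2 <- ann1(data.frame(gene_id = "g2", chrom = "chr1", start = 10000,
                          end = 20000, strand = "+"))
  expect_equal(nrow(assign_tss_peak(far, ann2, window = 2000)), 0L)
})

test_that("breadth classes honour the top-5% rules and cardinalities", {
  n <- 100
  tss <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                    start = 0L, end = 100L, summit = 50L,
                    height = runif(n, 1, 2), width = 1:n, pvalue = 1e-9)
  cls <- classify_breadth(tss, seed = 5)
  expect_setequal(cls$gene_id[cls$label == "broad"], sprintf("g%03d", 96:100))
  expect_equal(sum(cls$label == "broad"), ceiling(0.05 * n))
  expect_equal(sum(cls$label == "random_control"), ceiling(0.05 * n))
  # a gene in the top 5% of both width and height is broad, not sharp
  tss$height <- as.numeric(1:n)   # same ordering as width
  cls2 <- classify_breadth(tss, seed = 5)
  expect_true(all(cls2$label[cls2$gene_id %in% sprintf("g%03d", 96:100)] ==
                    "broad"))
  expect_equal(sum(cls2$label == "sharp"), 0L)
  # determinism of the random control draw
  cls3 <- classify_breadth(tss, seed = 5)
  expect_identical(cls2$label, cls3$label)
  expect_error(classify_breadth(tss[1:30, ], seed = 1), ">= 40")
})

test_that("summit shift follows the strand-aware 5'-ward sign convention", {
  ann <- ann1(data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                         start = c(1000, 5000), end = c(3000, 7000),
                         strand = c("+", "-")))
  mk <- function(ids, summits)
    data.frame(gene_id = ids, chrom = "chr1", start = 0L, end = 10000L,
               summit = summits, height = 5, width = 100L, pvalue = 1e-9)
  # identical peaks -> zero shift
  s0 <- summit_shift(mk(c("gp", "gm"), c(1100, 6900)),
                     mk(c("gp", "gm"), c(1100, 6900)), ann)
  expect_equal(s0$per_gene$shift, c(0L, 0L))
  expect_equal(s0$median, 0)
  # + strand: WT 1050, KO 1000 -> +50 (KO 5'-ward)
  # - strand: WT 1000, KO 1050 -> +50
  s1 <- summit_shift(mk(c("gp", "gm"), c(1050, 1000)),
                     mk(c("gp", "gm"), c(1000, 1050)), ann)
  expect_equal(s1$per_gene$shift, c(50L, 50L))
  # a gene missing in one condition is excluded and counted
  s2 <- summit_shift(mk("gp", 1050), mk(c("gp", "gm"), c(1000, 1050)), ann)
  expect_equal(s2$n_excluded, 1L)
})

test_that("geometry change is the log2 KO/WT ratio of width and height", {
  mk <- function(w, h)
    data.frame(gene_id = "g", chrom = "chr1", start = 0L, end = w,
               summit = 1L, height = h, width = w, pvalue = 1e-9)
  expect_equal(geometry_change(mk(1000, 10), mk(500, 10))$d_log2_width, -1)
  same <- geometry_change(mk(1000, 10), mk(1000, 10))
  expect_equal(same$d_log2_width, 0)
  expect_equal(same$d_log2_height, 0)
  gc <- geometry_change(mk(1000, 10), mk(800, 9))
  expect_equal(gc$d_log2_width, -0.321928, tolerance = 1e-5)
  expect_equal(gc$d_log2_height, -0.152003, tolerance = 1e-5)
  expect_error(geometry_change(mk(1000, 0), mk(800, 9)), "height")
})

test_that("metagene profiles are strand-aware and match brute-force bins", {
  len <- 20000
  v <- rep(2, len)
  tr <- track1(v)
  ann <- ann1(data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                         end = 14000, strand = "+"), chrom_len = len)
  mg <- metagene_matrix(tr, ann, anchor = "TSS", flank = 1000, binsize = 50)
  expect_equal(unname(mg$profile), rep(2, 40))
  # mirrored ramps on opposite strands give identical rows
  ramp <- numeric(len)
  ramp[9001:11000] <- 1:2000
  ramp[13001:15000] <- 2000:1
  tr2 <- track1(ramp)
  ann2 <- ann1(data.frame(gene_id = c("p", "m"), chrom = "chr1",
                          start = c(10000, 10000), end = c(14000, 14000),
                          strand = c("+", "-")), chrom_len = len)
  mg2 <- metagene_matrix(tr2, ann2, anchor = "TSS", flank = 1000, binsize = 100)
  expect_equal(unname(mg2$matrix["p", ]), unname(mg2$matrix["m", ]))
  # brute-force oracle on a random track
  set.seed(4)
  v3 <- runif(len)
  mg3 <- metagene_matrix(track1(v3), ann, anchor = "TSS", flank = 200,
                         binsize = 100)
  tss <- 10000
  expect_equal(unname(mg3$matrix[1, ]),
               c(mean(v3[(tss - 200 + 1):(tss - 100)]),
                 mean(v3[(tss - 100 + 1):tss]),
                 mean(v3[(tss + 1):(tss + 100)]),
                 mean(v3[(tss + 101):(tss + 200)])))
  # genes whose window leaves the chromosome are dropped and counted
  ann3 <- ann1(data.frame(gene_id = "edge", chrom = "chr1", start = 100,
                          end = 3000, strand = "+"), chrom_len = len)
  mg4 <- metagene_matrix(track1(v3), ann3, anchor = "TSS", flank = 1000)
  expect_equal(mg4$n_dropped, 1L)
})

test_that("pausing index is promoter over gene-body mean signal", {
  len <- 10000
  v <- rep(0, len)
  v[751:1250] <- 10                      # TSS +/- 250 around TSS = 1000
  v[1501:3000] <- 2                      # body from TSS + 500 to TES
  ann <- ann1(data.frame(gene_id = "g1", chrom = "chr1", start = 1000,
                         end = 3000, strand = "+"), chrom_len = len)
  pi1 <- pausing_index(track1(v), ann)
  expect_equal(pi1$pausing_index, 5)
  # uniform coverage -> ratio 1
  pi2 <- pausing_index(track1(rep(3, len)), ann)
  expect_equal(pi2$pausing_index, 1)
  # genes shorter than the body offset are excluded
  ann3 <- ann1(data.frame(gene_id = "tiny", chrom = "chr1", start = 1000,
                          end = 1400, strand = "+"), chrom_len = len)
  expect_equal(nrow(pausing_index(track1(v), ann3)), 0L)
})

test_that("KO pausing index exceeds WT on rnf40-dependent genes", {
  sim <- tiny_sim()
  rnf <- sim$truth$genes$gene_id[sim$truth$genes$class == "rnf40_dependent"]
  pw <- pausing_index(sim$tracks$PolII$WT, sim$annotation)
  pk <- pausing_index(sim$tracks$PolII$KO, sim$annotation)
  wt <- setNames(pw$pausing_index, pw$gene_id)[rnf]
  ko <- setNames(pk$pausing_index, pk$gene_id)[rnf]
  expect_gt(median(ko / wt), 1.5)
})
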