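test_that("size factors are medians of ratios to the geometric mean", {
  counts <- matrix(c(10, 20, 30, 40, 50), ncol = 1)
  counts <- cbind(s1 = counts[, 1], s2 = 2 * counts[, 1])
  rownames(counts) <- paste0("g", 1:5)
  sf <- size_factors(counts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # identical samples -> all factors 1
  same <- cbind(a = counts[, 1], b = counts[, 1], c = counts[, 1])
  expect_equal(unname(size_factors(same)), rep(1, 3))
  # 5-gene fixture against hand-computed medians of ratios
  set.seed(8)
  m <- matrix(rpois(15, 60) + 1, nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  geo <- exp(rowMeans(log(m)))
  manual <- apply(m / geo, 2, median)
  expect_equal(size_factors(m), manual)
  expect_error(size_factors(matrix(0, 3, 2)), "nonzero")
})

test_that("size factors agree with the DESeq2 median-of-ratios oracle", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  m <- matrix(rnbinom(600, mu = 80, size = 10) + 1, nrow = 100)
  colnames(m) <- paste0("s", 1:6); rownames(m) <- paste0("g", 1:100)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("differential expression computes baseMean, log2fc and Welch p", {
  base <- matrix(rpois(40, 100), nrow = 10,
                 dimnames = list(paste0("g", 1:10), NULL))
  counts <- cbind(base, base)
  colnames(counts) <- c(paste0("WT_", 1:4), paste0("KO_", 1:4))
  cond <- setNames(rep(c("WT", "KO"), each = 4), colnames(counts))
  de <- differential_expression(counts, cond)
  expect_equal(de$log2fc, rep(0, 10))
  expect_equal(de$pvalue, rep(1, 10))
  # a gene whose KO mean is 4x its WT mean, on a stable background of
  # unchanged genes (so size factors stay ~1) -> log2fc ~= 2
  set.seed(77)
  stable <- matrix(rpois(80, 100), nrow = 20)
  counts2 <- rbind(stable, c(98L, 102L, 398L, 402L))
  dimnames(counts2) <- list(paste0("g", 1:21),
                            c("WT_1", "WT_2", "KO_1", "KO_2"))
  de2 <- differential_expression(counts2,
                                 setNames(c("WT", "WT", "KO", "KO"),
                                          colnames(counts2)))
  expect_equal(de2$log2fc[21], 2, tolerance = 0.1)
  expect_error(
    differential_expression(counts2[, 1:3],
                            setNames(c("WT", "WT", "KO"),
                                     colnames(counts2)[1:3])),
    "replicates")
})

test_that("gene classification applies the printed thresholds strictly", {
  rec <- data.frame(
    gene_id = paste0("g", 1:5),
    baseMean = c(20, 14, 20, 20, 20),
    log2fc = c(1.5, -3, 0.1, -1.5, 0.5),
    pvalue = c(0.01, 0.001, 0.9, 0.01, 0.01),
    class = "none")
  got <- classify_genes(rec)$class
  expect_equal(got, c("up", "none", "unchanged", "down", "none"))
  # partition: every record gets exactly one label
  set.seed(10)
  rnd <- data.frame(gene_id = paste0("r", 1:500),
                    baseMean = runif(500, 0, 60),
                    log2fc = rnorm(500, 0, 2),
                    pvalue = runif(500), class = "none")
  cl <- classify_genes(rnd)$class
  expect_true(all(cl %in% c("up", "down", "unchanged", "none")))
  up <- rnd$baseMean > 15 & rnd$pvalue < 0.05 & rnd$log2fc > 1
  expect_equal(cl == "up", up)
})

test_that("occupancy quartiles rank genes H/M/L/No with deterministic ties", {
  len <- 8000
  v <- numeric(len)
  genes <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr1",
                      start = seq(0, 7000, by = 1000),
                      end = seq(500, 7500, by = 1000), strand = "+")
  for (i in 1:8) v[(genes$start[i] + 1):genes$end[i]] <- 9 - i  # signals 8..1
  ann <- ann1(genes, chrom_len = len)
  og <- occupancy_groups(track1(v), ann)
  expect_equal(as.character(og$group), rep(c("H", "M", "L", "No"), each = 2))
  # all-equal signals: groups follow gene-id order, sizes 2/2/2/2
  og2 <- occupancy_groups(track1(rep(1, len)), ann)
  expect_equal(as.character(og2$group), rep(c("H", "M", "L", "No"), each = 2))
  # permutation invariance of input order
  perm <- sample(1:8)
  og3 <- occupancy_groups(track1(v), ann1(genes[perm, ], chrom_len = len))
  expect_equal(og3$group[match(og$gene_id, og3$gene_id)], og$group)
})

test_that("quartile group sizes differ by at most one for any n", {
  for (n in c(4, 5, 6, 7, 9, 11, 13, 25, 50, 99)) {
    len <- n * 100
    genes <- data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                        start = seq(0, by = 100, length.out = n),
                        end = seq(50, by = 100, length.out = n), strand = "+")
    og <- occupancy_groups(track1(runif(len)), ann1(genes, chrom_len = len))
    sizes <- table(og$group)
    expect_lte(max(sizes) - min(sizes), 1)
  }
})

test_that("Pearson correlation matches the hand formula and flags degeneracy", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  set.seed(11)
  a <- rnorm(10); b <- rnorm(10)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlate(a, b)$r, manual)
  z <- correlate(rep(1, 5), rnorm(5))
  expect_false(z$defined)
  expect_error(correlate(1:2, 1:2), ">= 3")
})

test_that("group response summarises |log2fc| and runs rank-sum tests", {
  groups <- data.frame(gene_id = paste0("g", 1:40), signal = 40:1,
                       group = factor(rep(c("H", "M", "L", "No"), each = 10),
                                      levels = c("H", "M", "L", "No")))
  set.seed(12)
  shared <- rnorm(40, 1, 0.3)
  rec <- data.frame(gene_id = paste0("g", 1:40), baseMean = 50,
                    log2fc = shared, pvalue = 0.5, class = "none")
  gr <- group_response(groups, rec)
  expect_equal(nrow(gr$tests), 6L)
  # identical distributions: no pair strongly significant
  rec2 <- rec; rec2$log2fc <- rep(shared[1:10], 4)
  gr2 <- group_response(groups, rec2)
  expect_true(all(gr2$tests$pvalue > 0.9))
  expect_equal(max(gr2$summary$median) - min(gr2$summary$median), 0)
  # fully separated groups: p below the exact enumeration bound
  rec3 <- rec
  rec3$log2fc <- ifelse(groups$group == "H", 2, 0)
  gr3 <- group_response(groups, rec3)
  hm <- gr3$tests$pvalue[gr3$tests$group1 == "H" & gr3$tests$group2 == "M"]
  p_exact <- 2 / choose(20, 10)   # both extreme orderings of 10 vs 10
  expect_lt(p_exact, 1e-4)
  expect_lt(hm, 0.001)
  s <- gr3$summary
  expect_equal(s$median[s$group == "H"], 2)
  expect_equal(s$median[s$group == "M"], 0)
})
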