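# Shared fixtures. Simulations are cached in the session so the suite pays
# for each configuration once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# tiny genome: fast unit-scale simulation (one chromosome)
tiny_sim <- function(seed = 7L, ...) {
  key <- paste0("tiny_", seed, "_", paste(deparse(substitute(list(...))),
                                          collapse = ""))
  cached(key, simulate_epigenome(
    sim_config(n_chroms = 1L, chrom_len = 1.2e6, n_genes = 50L,
               n_enhancers = 25L, seed = seed, ...)))
}

# the default study conditions used by the acceptance checks
default_sim <- function() {
  cached("default", simulate_epigenome(sim_config(seed = 101L)))
}

default_k4_geometry <- function() {
  cached("default_k4", {
    sim <- default_sim()
    pk_wt <- call_peaks(sim$tracks$H3K4me3$WT)
    pk_ko <- call_peaks(sim$tracks$H3K4me3$KO)
    tss_wt <- assign_tss_peak(pk_wt, sim$annotation)
    tss_ko <- assign_tss_peak(pk_ko, sim$annotation)
    list(tss_wt = tss_wt, tss_ko = tss_ko,
         shift = summit_shift(tss_wt, tss_ko, sim$annotation),
         geom = geometry_change(tss_wt, tss_ko),
         breadth = classify_breadth(tss_wt, seed = 1L))
  })
}

null_sim <- function() {
  cached("null", simulate_epigenome(
    null_sim_config(n_chroms = 1L, chrom_len = 4.5e6, n_genes = 200L,
                    n_enhancers = 60L, seed = 33L)))
}

# single-chromosome coverage track from a numeric vector
track1 <- function(v, chrom = "chr1") coverage_track(setNames(list(v), chrom))

# annotation with one chromosome and explicit gene rows
ann1 <- function(genes, chrom_len = 1e6) {
  genome_annotation(genes, setNames(chrom_len, unique(genes$chrom)))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

fox_pfm <- function() {
  cached("pfms", read_jaspar(system.file("extdata", "motifs_demo.jaspar",
                                         package = "epicross")))[["FOXL2_like"]]
}

demo_pfms <- function() {
  cached("pfms", read_jaspar(system.file("extdata", "motifs_demo.jaspar",
                                         package = "epicross")))
}

# independent Benjamini-Hochberg step-up oracle
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
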