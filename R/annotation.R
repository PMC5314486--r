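#' Genome annotation
#'
#' A genome annotation is a table of strand-aware gene coordinates plus the
#' chromosome lengths. Coordinates are 0-based half-open. The transcription
#' start site (TSS) of a plus-strand gene is `start`; for a minus-strand gene
#' it is `end - 1`. The transcription end site (TES) is the opposite end.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+` or `-`).
#' @param chrom_sizes Named vector of chromosome lengths in bp.
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes, chrom_sizes) {
  req <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(req %in% names(genes)))
    stop("`genes` must have columns: ", paste(req, collapse = ", "))
  genes <- as.data.frame(genes)[req]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[anyDuplicated(genes$gene_id)])
  if (any(!genes$strand %in% c("+", "-")))
    stop("unknown strand symbol: ",
         genes$strand[which(!genes$strand %in% c("+", "-"))[1]])
  if (any(genes$start < 0 | genes$start >= genes$end))
    stop("gene with start >= end or negative start")
  missing_chrom <- setdiff(genes$chrom, names(chrom_sizes))
  if (length(missing_chrom))
    stop("gene on chromosome absent from chrom_sizes: ", missing_chrom[1])
  over <- genes$end > chrom_sizes[genes$chrom]
  if (any(over))
    stop("gene beyond chromosome end: ", genes$gene_id[which(over)[1]])
  structure(list(genes = genes,
                 chrom_sizes = stats::setNames(as.integer(chrom_sizes),
                                               names(chrom_sizes))),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes on",
      length(x$chrom_sizes), "chromosome(s)\n")
  invisible(x)
}

#' Strand-aware TSS and TES positions
#'
#' @param annotation A `genome_annotation`.
#' @return Integer vector of 0-based positions, named by gene_id.
#' @export
gene_tss <- function(annotation) {
  g <- annotation$genes
  stats::setNames(ifelse(g$strand == "+", g$start, g$end - 1L), g$gene_id)
}

#' @rdname gene_tss
#' @export
gene_tes <- function(annotation) {
  g <- annotation$genes
  stats::setNames(ifelse(g$strand == "+", g$end - 1L, g$start), g$gene_id)
}

#' Read a gene annotation from BED12/BED6 or GTF
#'
#' BED coordinates are used as-is (already 0-based half-open); GTF
#' coordinates (1-based closed) are converted on read. For GTF, rows with
#' feature type `gene` are used when present, otherwise `transcript`; the
#' `gene_id` attribute names the record.
#'
#' @param path File path.
#' @param format `"bed12"` (also accepts BED6) or `"gtf"`.
#' @param chrom_sizes Optional named vector of chromosome lengths; when
#'   omitted, each chromosome's length is taken as the maximum gene end.
#' @return A `genome_annotation`.
#' @export
read_annotation <- function(path, format = c("bed12", "gtf"),
                            chrom_sizes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "bed12") {
    dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                            colClasses = list(character = 1))
    if (ncol(dt) < 6L)
      stop("BED file needs at least 6 columns (BED6/BED12): ", path)
    genes <- data.frame(gene_id = as.character(dt[[4]]),
                        chrom = as.character(dt[[1]]),
                        start = suppressWarnings(as.integer(dt[[2]])),
                        end = suppressWarnings(as.integer(dt[[3]])),
                        strand = as.character(dt[[6]]),
                        stringsAsFactors = FALSE)
    bad <- which(is.na(genes$start) | is.na(genes$end) |
                   genes$start < 0 | genes$start >= genes$end)
    if (length(bad))
      stop("malformed BED row at line ", bad[1], " of ", path)
    badstrand <- which(!genes$strand %in% c("+", "-"))
    if (length(badstrand))
      stop("unknown strand symbol at line ", badstrand[1], " of ", path)
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    type <- as.character(gr$type)
    keep <- if (any(type == "gene")) type == "gene" else type == "transcript"
    gr <- gr[keep]
    if (!length(gr)) stop("no gene/transcript rows in GTF: ", path)
    ids <- gr$gene_id
    if (is.null(ids)) stop("GTF lacks gene_id attribute: ", path)
    strand <- as.character(GenomicRanges::strand(gr))
    if (any(!strand %in% c("+", "-")))
      stop("unknown strand symbol in GTF: ", path)
    genes <- data.frame(gene_id = as.character(ids),
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,  # 1-based -> 0-based
                        end = GenomicRanges::end(gr),
                        strand = strand,
                        stringsAsFactors = FALSE)
  }
  if (is.null(chrom_sizes))
    chrom_sizes <- tapply(genes$end, genes$chrom, max)
  genome_annotation(genes, chrom_sizes)
}

#' Write an annotation as BED6
#'
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  g <- annotation$genes
  dt <- data.table::data.table(chrom = g$chrom, start = g$start, end = g$end,
                               name = g$gene_id, score = 0L, strand = g$strand)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA as a named character vector
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()`; sequence names are
#' truncated at the first whitespace, matching chromosome naming in the
#' other formats.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(dss))
  stats::setNames(as.character(dss), nm)
}

# GRanges view of the gene table (1-based, as GenomicRanges expects)
annotation_granges <- function(annotation) {
  g <- annotation$genes
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, gene_id = g$gene_id)
}
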