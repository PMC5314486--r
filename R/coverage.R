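#' Coverage track
#'
#' A coverage track holds per-base-pair, non-negative signal for a set of
#' chromosomes at 1 bp resolution, together with the normalisation constant
#' that was applied to the underlying read counts (reads per hundred million
#' in the conventional pipeline). All genomic coordinates in this package are
#' 0-based, half-open (BED convention): position `p` of chromosome `chrom`
#' corresponds to `values[[chrom]][p + 1]`.
#'
#' @param values Named list of non-negative numeric vectors, one per
#'   chromosome; the vector length is the chromosome length in bp.
#' @param norm_constant Positive scale factor already applied to the values.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(values, norm_constant = 1) {
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values))))
    stop("`values` must be a named list of per-chromosome numeric vectors")
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (!is.numeric(v)) stop("coverage for ", chrom, " is not numeric")
    if (anyNA(v)) stop("coverage for ", chrom, " contains NA")
    if (any(v < 0)) stop("negative coverage value on ", chrom)
  }
  if (!is.numeric(norm_constant) || length(norm_constant) != 1L || norm_constant <= 0)
    stop("`norm_constant` must be a single positive number")
  structure(list(values = values, norm_constant = norm_constant),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  lens <- vapply(x$values, length, integer(1))
  cat("coverage_track:", length(lens), "chromosome(s),",
      format(sum(as.numeric(lens)), big.mark = ","), "bp total, norm_constant =",
      x$norm_constant, "\n")
  invisible(x)
}

#' Chromosome lengths of a coverage track
#' @param track A `coverage_track`.
#' @return Named integer vector of chromosome lengths.
#' @export
track_chrom_sizes <- function(track) {
  vapply(track$values, length, integer(1))
}

#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length in bp.
#'
#' @param path File path.
#' @return Named integer vector chrom -> length.
#' @export
read_chrom_sizes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "size"))
  if (ncol(dt) < 2L) stop("chrom.sizes file must have two columns: ", path)
  sizes <- as.integer(dt$size)
  if (anyNA(sizes) || any(sizes <= 0)) stop("invalid chromosome length in ", path)
  stats::setNames(sizes, as.character(dt$chrom))
}

#' Read a bedGraph file into a dense coverage track
#'
#' Intervals must be non-overlapping within each chromosome; positions not
#' covered by any interval are zero. An empty file yields an all-zero track
#' (over `chrom_sizes` when given, otherwise an empty track).
#'
#' @param path bedGraph file (chrom, start, end, value; 0-based half-open).
#' @param chrom_sizes Optional named vector of chromosome lengths. When
#'   omitted, each chromosome's length is the maximum interval end seen.
#' @param norm_constant Normalisation constant recorded on the track.
#' @return A `coverage_track`.
#' @export
read_coverage <- function(path, chrom_sizes = NULL, norm_constant = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t",
                        colClasses = list(character = 1),
                        col.names = c("chrom", "start", "end", "value")[1:4])),
    error = function(e) {
      # empty file (or only blank lines)
      data.table::data.table(chrom = character(), start = integer(),
                             end = integer(), value = numeric())
    })
  if (nrow(dt) > 0 && ncol(dt) < 4L)
    stop("bedGraph needs 4 columns (chrom, start, end, value): ", path)
  if (nrow(dt) > 0) {
    bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start < 0 |
                   dt$end <= dt$start | !is.finite(dt$value))
    if (length(bad))
      stop("malformed bedGraph row at line ", bad[1], " of ", path)
    if (any(dt$value < 0))
      stop("negative coverage value at line ", which(dt$value < 0)[1], " of ", path)
  }
  chroms <- if (is.null(chrom_sizes)) unique(dt$chrom) else names(chrom_sizes)
  values <- vector("list", length(chroms))
  names(values) <- chroms
  for (chrom in chroms) {
    sub <- dt[dt$chrom == chrom, ]
    len <- if (is.null(chrom_sizes)) {
      if (nrow(sub)) max(sub$end) else 0L
    } else as.integer(chrom_sizes[[chrom]])
    v <- numeric(len)
    if (nrow(sub)) {
      o <- order(sub$start)
      s <- sub$start[o]; e <- sub$end[o]; val <- sub$value[o]
      if (any(s[-1] < e[-length(e)]))
        stop("overlapping bedGraph intervals on ", chrom, " in ", path)
      if (max(e) > len)
        stop("interval beyond chromosome end on ", chrom, " in ", path)
      for (i in seq_along(s)) if (val[i] != 0) v[(s[i] + 1L):e[i]] <- val[i]
    }
    values[[chrom]] <- v
  }
  coverage_track(values, norm_constant = norm_constant)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are merged into single intervals; zero runs are
#' omitted, so `read_coverage(write_coverage(x))` reproduces the dense
#' vectors exactly (given the chromosome sizes).
#'
#' @param track A `coverage_track`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(track, path) {
  pieces <- vector("list", length(track$values))
  for (i in seq_along(track$values)) {
    chrom <- names(track$values)[i]
    r <- rle(track$values[[i]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    pieces[[i]] <- data.table::data.table(
      chrom = chrom, start = starts[keep], end = ends[keep],
      value = r$values[keep])
  }
  dt <- data.table::rbindlist(pieces)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

check_interval <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$values)) stop("unknown chromosome: ", chrom)
  len <- length(track$values[[chrom]])
  if (start < 0 || end > len || start >= end)
    stop("interval [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", len, ")")
  invisible(len)
}

#' Mean signal over an interval
#'
#' Arithmetic mean of the per-bp values over the 0-based half-open interval
#' `[start, end)`.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @return Non-negative scalar.
#' @export
mean_signal <- function(track, chrom, start, end) {
  check_interval(track, chrom, start, end)
  mean(track$values[[chrom]][(start + 1L):end])
}

#' Binned signal over an interval
#'
#' Splits `[start, end)` into `nbins` near-equal-width bins and returns the
#' mean signal per bin. With `flip_if_minus = TRUE` and `strand == "-"` the
#' bin order is reversed, so bin 1 is always the 5'-most bin of the feature.
#'
#' @param track A `coverage_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval bounds.
#' @param nbins Number of bins; must not exceed the interval length.
#' @param strand `"+"` or `"-"`.
#' @param flip_if_minus Reverse bins for minus-strand features.
#' @return Numeric vector of length `nbins`.
#' @export
bin_signal <- function(track, chrom, start, end, nbins, strand = "+",
                       flip_if_minus = TRUE) {
  check_interval(track, chrom, start, end)
  len <- end - start
  if (nbins < 1L || nbins > len)
    stop("nbins (", nbins, ") must be in 1..interval length (", len, ")")
  v <- track$values[[chrom]][(start + 1L):end]
  # equal-width bin boundaries; widths differ by at most 1 bp
  edges <- round(seq(0, len, length.out = nbins + 1L))
  out <- numeric(nbins)
  for (b in seq_len(nbins)) out[b] <- mean(v[(edges[b] + 1L):edges[b + 1L]])
  if (flip_if_minus && identical(strand, "-")) out <- rev(out)
  out
}
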