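#' Binned signal tracks
#'
#' A signal track stores one numeric vector of per-bin values per chromosome
#' at a fixed bin width, covering each chromosome exactly
#' (`ceiling(length / bin_width)` bins).
#'
#' @param values named list, chromosome -> numeric vector of bin values.
#' @param bin_width bin width in bp.
#' @param chromsizes a [chrom_sizes()]; bin counts are checked against it.
#' @return a `signal_track` object.
#' @export
signal_track <- function(values, bin_width, chromsizes) {
  stopifnot(is.list(values), bin_width > 0)
  for (chrom in names(chromsizes)) {
    nb <- ceiling(chromsizes[[chrom]] / bin_width)
    v <- values[[chrom]] %||% numeric(nb)
    if (length(v) != nb)
      stop(sprintf("track for %s has %d bins, expected %d", chrom,
                   length(v), nb), call. = FALSE)
    values[[chrom]] <- as.numeric(v)
  }
  structure(list(values = values[names(chromsizes)], bin_width = bin_width,
                 chromsizes = chromsizes), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("signal_track:", length(x$values), "chromosomes at", x$bin_width,
      "bp bins\n")
  invisible(x)
}

#' Read a bedGraph file into a binned signal track
#'
#' Intervals (0-based half-open) are rasterized to fixed-width bins by
#' length-weighted mean; uncovered parts of a bin count as 0. Overlapping
#' intervals are rejected as ambiguous.
#'
#' @param path bedGraph file.
#' @inheritParams signal_track
#' @return a [signal_track()].
#' @export
read_signal_track <- function(path, chromsizes, bin_width) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(names(chromsizes), function(chrom) {
    nb <- ceiling(chromsizes[[chrom]] / bin_width)
    v <- numeric(nb)
    sel <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    if (!length(sel)) return(v)
    sel <- sort(sel)
    s <- GenomicRanges::start(sel) - 1L   # back to 0-based
    e <- GenomicRanges::end(sel)
    if (any(s[-1] < e[-length(e)]))
      stop("overlapping bedGraph intervals on ", chrom, call. = FALSE)
    sc <- S4Vectors::mcols(sel)$score
    for (i in seq_along(sel)) {
      b0 <- s[i] %/% bin_width
      b1 <- (e[i] - 1L) %/% bin_width
      for (b in b0:b1) {
        lo <- max(s[i], b * bin_width)
        hi <- min(e[i], (b + 1) * bin_width)
        v[b + 1L] <- v[b + 1L] + sc[i] * (hi - lo) / bin_width
      }
    }
    v
  })
  names(values) <- names(chromsizes)
  signal_track(values, bin_width, chromsizes)
}

#' Write a signal track as bedGraph
#'
#' Zero bins are omitted.
#'
#' @param track a [signal_track()].
#' @param path output file.
#' @export
write_signal_track <- function(track, path) {
  rows <- rbindlist(lapply(names(track$values), function(chrom) {
    v <- track$values[[chrom]]
    nz <- which(v != 0)
    if (!length(nz)) return(NULL)
    data.table(chrom = chrom,
               start = (nz - 1L) * track$bin_width,
               end = pmin(nz * track$bin_width,
                          as.integer(track$chromsizes[[chrom]])),
               value = v[nz])
  }))
  if (is.null(rows) || !nrow(rows))
    rows <- data.table(chrom = character(), start = integer(),
                       end = integer(), value = numeric())
  fwrite(rows, path, sep = "\t", col.names = FALSE, scipen = 50)
  invisible(path)
}

#' Mean track signal over intervals
#'
#' Length-weighted mean of bin values over each 0-based half-open interval.
#'
#' @param track a [signal_track()].
#' @param chrom,start,end interval vectors.
#' @return numeric vector of means.
#' @export
track_interval_mean <- function(track, chrom, start, end) {
  bw <- track$bin_width
  vapply(seq_along(chrom), function(i) {
    v <- track$values[[chrom[i]]]
    if (is.null(v) || end[i] <= start[i]) return(NA_real_)
    b0 <- start[i] %/% bw
    b1 <- (end[i] - 1L) %/% bw
    bins <- b0:b1
    lo <- pmax(start[i], bins * bw)
    hi <- pmin(end[i], (bins + 1) * bw)
    sum(v[bins + 1L] * (hi - lo)) / (end[i] - start[i])
  }, numeric(1))
}
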