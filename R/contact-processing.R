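#' Split a chimeric read at the bridge linker
#'
#' A read is a valid chromatin contact when the bridge linker occurs inside
#' it with enough flanking sequence on both sides. Returns the flanks
#' around the first linker occurrence, or `NULL` when the linker is absent
#' or either flank is shorter than `min_flank`. Matching is exact by
#' default; `max_mismatch = 1` tolerates one substitution.
#'
#' @param read_seq read sequence (character scalar).
#' @param linker_seq linker search string; default is the bridge-linker
#'   F-oligo sequence with chemistry tags stripped.
#' @param min_flank minimum flank length (nt).
#' @param max_mismatch allowed substitutions in the linker match (0 or 1).
#' @return `list(flank1, flank2)` or `NULL`.
#' @export
split_linker_read <- function(read_seq, linker_seq = "GTCAGAAAGATATCGCGT",
                              min_flank = 20L, max_mismatch = 0L) {
  if (!nchar(linker_seq)) stop("empty linker", call. = FALSE)
  if (max_mismatch == 0L) {
    at <- regexpr(linker_seq, read_seq, fixed = TRUE)[1]
  } else {
    m <- Biostrings::matchPattern(linker_seq, Biostrings::DNAString(read_seq),
                                  max.mismatch = as.integer(max_mismatch))
    at <- if (length(m)) IRanges::start(m)[1] else -1L
  }
  if (at < 0) return(NULL)
  flank1 <- substr(read_seq, 1L, at - 1L)
  flank2 <- substr(read_seq, at + nchar(linker_seq), nchar(read_seq))
  if (nchar(flank1) < min_flank || nchar(flank2) < min_flank) return(NULL)
  list(flank1 = flank1, flank2 = flank2)
}

#' Split a whole read table at the bridge linker
#'
#' Vectorized form of [split_linker_read()] over a read table; returns the
#' subset of reads that are valid contacts.
#'
#' @param reads `data.table` with `name` and `seq`.
#' @inheritParams split_linker_read
#' @return `data.table` `name, flank1, flank2` for valid reads.
#' @export
split_linker_reads <- function(reads, linker_seq = "GTCAGAAAGATATCGCGT",
                               min_flank = 20L) {
  if (!nchar(linker_seq)) stop("empty linker", call. = FALSE)
  at <- regexpr(linker_seq, reads$seq, fixed = TRUE)
  at <- as.integer(at)
  f1 <- substr(reads$seq, 1L, at - 1L)
  f2 <- substr(reads$seq, at + nchar(linker_seq), nchar(reads$seq))
  ok <- at > 0L & nchar(f1) >= min_flank & nchar(f2) >= min_flank
  data.table(name = reads$name[ok], flank1 = f1[ok], flank2 = f2[ok])
}

#' Filter contact pairs
#'
#' Applies, in order: the mapping-quality filter (`min(mapq1, mapq2) >=
#' mapq_min`), a self-ligation guard dropping intra-chromosomal pairs
#' closer than `min_distance`, and exact-duplicate collapsing (identical on
#' both coordinates and both strands).
#'
#' @param pairs canonical contact pair table.
#' @param mapq_min minimum per-end mapping quality (default 10).
#' @param min_distance minimum intra-chromosomal separation in bp; default
#'   2 bins at `resolution`.
#' @param resolution bin width used for the `min_distance` default.
#' @param dedup collapse exact duplicates.
#' @return `list(pairs, report)`; the report counts pairs removed by each
#'   filter (`n_input = n_output + mapq + min_distance + duplicates`).
#' @export
filter_pairs <- function(pairs, mapq_min = 10L, min_distance = NULL,
                         resolution = 200L, dedup = TRUE) {
  min_distance <- min_distance %||% (2L * resolution)
  n_in <- nrow(pairs)
  keep <- pmin(pairs$mapq1, pairs$mapq2) >= mapq_min
  n_mapq <- sum(!keep)
  pairs <- pairs[keep]
  near <- pairs$chrom1 == pairs$chrom2 &
    (pairs$pos2 - pairs$pos1) < min_distance
  n_near <- sum(near)
  pairs <- pairs[!near]
  n_dup <- 0L
  if (dedup) {
    before <- nrow(pairs)
    pairs <- unique(pairs, by = c("chrom1", "pos1", "strand1",
                                  "chrom2", "pos2", "strand2"))
    n_dup <- before - nrow(pairs)
  }
  list(pairs = pairs[],
       report = list(n_input = n_in, n_output = nrow(pairs),
                     mapq = n_mapq, min_distance = n_near,
                     duplicates = n_dup,
                     mapq_min = mapq_min, min_distance_bp = min_distance))
}

#' Bin contact pairs into a sparse contact matrix
#'
#' Bin index is `floor(pos / resolution)`; intra-chromosomal bin pairs are
#' stored with `bin1 <= bin2`. The matrix total `N` equals the number of
#' input pairs.
#'
#' @param pairs canonical contact pair table.
#' @param resolution bin width in bp (> 0).
#' @param chromsizes a [chrom_sizes()].
#' @return a `contact_matrix`: list with `counts` (`chrom1, bin1, chrom2,
#'   bin2, count`), `resolution`, `chromsizes`, `N`.
#' @export
bin_contacts <- function(pairs, resolution = 200L, chromsizes) {
  if (resolution <= 0) stop("resolution must be positive", call. = FALSE)
  b <- data.table(chrom1 = pairs$chrom1,
                  bin1 = pairs$pos1 %/% as.integer(resolution),
                  chrom2 = pairs$chrom2,
                  bin2 = pairs$pos2 %/% as.integer(resolution))
  swap <- b$chrom1 == b$chrom2 & b$bin2 < b$bin1
  if (any(swap)) b[swap, `:=`(bin1 = bin2, bin2 = bin1)]
  counts <- b[, .(count = .N), by = .(chrom1, bin1, chrom2, bin2)]
  setorder(counts, chrom1, chrom2, bin1, bin2)
  structure(list(counts = counts[], resolution = as.integer(resolution),
                 chromsizes = chromsizes, N = nrow(pairs)),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$N, "contacts in", nrow(x$counts),
      "bin pairs at", x$resolution, "bp\n")
  invisible(x)
}

#' Write / read a contact matrix as COO TSV
#'
#' Columns: `chrom1 bin1 chrom2 bin2 count`.
#'
#' @param matrix a `contact_matrix`.
#' @param path output TSV.
#' @export
write_contact_matrix <- function(matrix, path) {
  fwrite(matrix$counts, path, sep = "\t")
  invisible(path)
}

#' @rdname write_contact_matrix
#' @inheritParams bin_contacts
#' @export
read_contact_matrix <- function(path, resolution, chromsizes) {
  counts <- fread(path, sep = "\t",
                  colClasses = list(character = c("chrom1", "chrom2")))
  structure(list(counts = counts, resolution = as.integer(resolution),
                 chromsizes = chromsizes, N = sum(counts$count)),
            class = "contact_matrix")
}

#' Vanilla-coverage normalization
#'
#' Divides each entry by the product of its two bin coverages (row sums of
#' the full symmetric per-chromosome-pair matrix) and rescales so the total
#' mass equals the input total. Zero-coverage bins stay zero.
#'
#' @param matrix a `contact_matrix` with raw counts.
#' @return a `contact_matrix` with normalized (non-integer) counts.
#' @export
vc_normalize <- function(matrix) {
  cnt <- copy(matrix$counts)
  tot_in <- sum(cnt$count)
  if (tot_in == 0) {
    warning("all-zero contact matrix; returned unchanged")
    return(matrix)
  }
  cnt[, count := as.numeric(count)]
  cnt <- cnt[, {
    if (chrom1[1] == chrom2[1]) {
      # full-symmetric row sums: off-diagonal entries hit two rows,
      # diagonal entries one
      off <- bin1 != bin2
      cov <- data.table(bin = c(bin1, bin2[off]),
                        w = c(count, count[off]))[, .(cov = sum(w)),
                                                  by = bin]
      c1 <- cov$cov[match(bin1, cov$bin)]
      c2 <- cov$cov[match(bin2, cov$bin)]
    } else {
      a <- data.table(bin = bin1, w = count)[, .(cov = sum(w)), by = bin]
      b <- data.table(bin = bin2, w = count)[, .(cov = sum(w)), by = bin]
      c1 <- a$cov[match(bin1, a$bin)]
      c2 <- b$cov[match(bin2, b$bin)]
    }
    list(bin1 = bin1, bin2 = bin2, count = count / (c1 * c2))
  }, by = .(chrom1, chrom2)]
  cnt[, count := count * tot_in / sum(count)]
  setorder(cnt, chrom1, chrom2, bin1, bin2)
  structure(list(counts = cnt[, .(chrom1, bin1, chrom2, bin2, count)],
                 resolution = matrix$resolution,
                 chromsizes = matrix$chromsizes, N = matrix$N),
            class = "contact_matrix")
}

#' Distance-decay curve and fitted exponent
#'
#' Depth-normalized contact density versus genomic separation in log-spaced
#' distance bins, with the power-law exponent `alpha` fitted by least
#' squares on log density versus log distance over occupied bins.
#'
#' @param pairs canonical contact pair table (intra-chromosomal pairs are
#'   used).
#' @param d_min,d_max distance range in bp (defaults 1 kb to 10 Mb).
#' @param n_bins number of log-spaced distance bins.
#' @return a `decay_curve`: `data.table` of bins (`d_lo, d_hi, mid, count,
#'   density`) plus `alpha`, `alpha_se` and `N` attributes.
#' @export
decay_curve <- function(pairs, d_min = 1e3, d_max = 1e7, n_bins = 40L) {
  intra <- pairs[chrom1 == chrom2]
  s <- intra$pos2 - intra$pos1
  s <- s[s >= d_min & s <= d_max]
  if (!length(s)) stop("no intra-chromosomal contacts in distance range",
                       call. = FALSE)
  edges <- exp(seq(log(d_min), log(min(d_max, max(s) + 1)),
                   length.out = n_bins + 1L))
  idx <- findInterval(s, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
  cnt <- tabulate(idx, nbins = n_bins)
  width <- diff(edges)
  N <- length(s)
  bins <- data.table(d_lo = edges[-length(edges)], d_hi = edges[-1],
                     mid = sqrt(edges[-length(edges)] * edges[-1]),
                     count = cnt, density = cnt / (N * width))
  occ <- bins[count > 0]
  if (nrow(occ) < 3L)
    stop("fewer than 3 occupied distance bins; decay fit refused",
         call. = FALSE)
  fit <- lm(log(density) ~ log(mid), data = occ)
  structure(bins[], class = c("decay_curve", class(bins)),
            alpha = -unname(coef(fit)[2]),
            alpha_se = unname(sqrt(diag(stats::vcov(fit))[2])), N = N)
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("decay_curve: alpha = %.3f (se %.3f) over %d contacts\n",
              attr(x, "alpha"), attr(x, "alpha_se"), attr(x, "N")))
  invisible(x)
}

#' Replicate reproducibility of two contact matrices
#'
#' Pearson correlation of `log1p(count)` over the union of occupied bin
#' pairs, overall and within distance strata.
#'
#' @param matrix_a,matrix_b `contact_matrix` objects at the same resolution
#'   over the same genome.
#' @param strata distance stratum edges in bp (intra-chromosomal); pairs
#'   beyond the last edge and inter-chromosomal pairs form their own strata.
#' @return list with `overall` correlation and a per-stratum `data.table`.
#' @export
replicate_correlation <- function(matrix_a, matrix_b,
                                  strata = c(0, 2e3, 2e4, 2e5)) {
  if (matrix_a$resolution != matrix_b$resolution)
    stop("resolution mismatch", call. = FALSE)
  key <- c("chrom1", "bin1", "chrom2", "bin2")
  m <- merge(matrix_a$counts, matrix_b$counts, by = key, all = TRUE,
             suffixes = c(".a", ".b"))
  if (!nrow(m)) stop("no occupied bin pairs", call. = FALSE)
  if (!any(!is.na(m$count.a) & !is.na(m$count.b)))
    stop("disjoint occupancy; correlation undefined", call. = FALSE)
  xa <- log1p(fifelse(is.na(m$count.a), 0, as.numeric(m$count.a)))
  xb <- log1p(fifelse(is.na(m$count.b), 0, as.numeric(m$count.b)))
  if (sd(xa) == 0 || sd(xb) == 0)
    stop("degenerate occupancy; correlation undefined", call. = FALSE)
  res <- matrix_a$resolution
  d <- fifelse(m$chrom1 == m$chrom2,
               abs(m$bin2 - m$bin1) * res, NA_integer_)
  stratum <- fifelse(is.na(d), "trans",
                     paste0(">=", strata[findInterval(d, strata)]))
  per <- data.table(stratum = stratum, xa = xa, xb = xb)[
    , .(n = .N, r = if (.N > 2 && sd(xa) > 0 && sd(xb) > 0)
      cor(xa, xb) else NA_real_), by = stratum]
  list(overall = cor(xa, xb), strata = per[])
}
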