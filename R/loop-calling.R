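#' Weighted pool-adjacent-violators, non-increasing
#'
#' Monotone (non-increasing) least-squares smoothing used on the raw
#' expected contact probabilities across distance bins.
#'
#' @param y values in distance order (near to far).
#' @param w positive weights.
#' @return smoothed vector, `length(y)`, non-increasing.
#' @export
pava_nonincreasing <- function(y, w = rep(1, length(y))) {
  stopifnot(length(y) == length(w), all(w > 0))
  n <- length(y)
  if (n <= 1L) return(y)
  # pool on -y to reuse the standard non-decreasing algorithm
  vals <- -y; wts <- w; sizes <- rep(1L, n)
  i <- 1L
  while (i < length(vals)) {
    if (vals[i] > vals[i + 1L] + 1e-15) {
      new_w <- wts[i] + wts[i + 1L]
      new_v <- (vals[i] * wts[i] + vals[i + 1L] * wts[i + 1L]) / new_w
      vals <- c(vals[seq_len(i - 1L)], new_v,
                vals[-seq_len(i + 1L)])
      wts <- c(wts[seq_len(i - 1L)], new_w, wts[-seq_len(i + 1L)])
      sizes <- c(sizes[seq_len(i - 1L)], sizes[i] + sizes[i + 1L],
                 sizes[-seq_len(i + 1L)])
      if (i > 1L) i <- i - 1L
    } else i <- i + 1L
  }
  -rep(vals, sizes)
}

# possible intra-chromosomal bin pairs at each bin distance d, summed over
# chromosomes
n_locus_pairs <- function(d_bins, chromsizes, resolution) {
  B <- floor(as.numeric(chromsizes) / resolution)
  vapply(d_bins, function(d) sum(pmax(B - d, 0)), numeric(1))
}

#' Fit the distance-decay expected model
#'
#' Re-implementation of the equal-occupancy binomial expected model used
#' for stable-contact calling: intra-chromosomal contacts are partitioned
#' into distance bins carrying approximately equal contact counts; each
#' bin's raw contact probability is its contact share divided by the
#' number of possible locus pairs at those distances, then smoothed to be
#' monotone non-increasing by weighted pool-adjacent-violators.
#'
#' @param matrix a `contact_matrix` of raw counts.
#' @param n_distance_bins target number of equal-occupancy bins
#'   (default 100).
#' @param min_distance,max_distance tested distance range in bp; pairs
#'   outside it are not modeled. Defaults: 2 bins to half the longest
#'   chromosome — beyond that the expectation is dominated by the shrinking
#'   number of available locus pairs rather than by distance decay, and a
#'   distance-binned model is no longer reliable.
#' @param max_span_ratio upper bound on `d_hi / d_lo` within one distance
#'   bin (default 1.25); bounds the decay-rate variation a single expected
#'   probability has to cover. `Inf` disables the guard, giving pure
#'   equal-occupancy bins.
#' @return an `expected_model`: `data.table` of distance bins
#'   (`d_lo, d_hi` in bins, `n_contacts, n_pairs, p_raw, p`) with
#'   attributes `N` (binomial total) and `resolution`.
#' @export
fit_expected <- function(matrix, n_distance_bins = 100L,
                         min_distance = NULL, max_distance = NULL,
                         max_span_ratio = 1.25) {
  res <- matrix$resolution
  min_distance <- min_distance %||% (2L * res)
  max_distance <- max_distance %||% (max(as.numeric(matrix$chromsizes)) / 2)
  intra <- matrix$counts[chrom1 == chrom2]
  intra[, distance := (bin2 - bin1)]
  d_min_b <- ceiling(min_distance / res)
  d_max_b <- floor(max_distance / res)
  intra <- intra[distance >= d_min_b & distance <= d_max_b]
  if (!nrow(intra)) stop("no contacts in modeled distance range",
                         call. = FALSE)
  byd <- intra[, .(n = sum(count)), by = distance]
  setorder(byd, distance)
  N <- sum(matrix$counts$count)
  total <- sum(byd$n)
  n_bins <- min(n_distance_bins, nrow(byd))
  if (n_bins < n_distance_bins)
    warning("fewer occupied distances than requested bins; using ", n_bins)
  # greedy equal-occupancy: accumulate distances until the per-bin target.
  # Two splitting guards keep within-bin rate variation small: a distance
  # carrying a full bin's worth of contacts gets its own bin, and no bin
  # spans more than a quarter-octave of distances.
  target <- total / n_bins
  grp <- integer(nrow(byd)); g <- 1L; acc <- 0; d_start <- byd$distance[1]
  for (i in seq_len(nrow(byd))) {
    if (acc > 0 && (byd$n[i] >= target ||
                    byd$distance[i] > max_span_ratio * d_start)) {
      g <- g + 1L; acc <- 0; d_start <- byd$distance[i]
    }
    grp[i] <- g
    acc <- acc + byd$n[i]
    if (acc >= target && i < nrow(byd)) {
      g <- g + 1L
      acc <- 0
      d_start <- if (i < nrow(byd)) byd$distance[i + 1L] else d_start
    }
  }
  byd[, d_bin := grp]
  bins <- byd[, .(d_lo = min(distance), d_hi = max(distance),
                  n_contacts = sum(n)), by = d_bin]
  # possible pairs over every distance in each bin's range, including
  # unoccupied distances
  bins[, n_pairs := vapply(seq_len(.N), function(i)
    sum(n_locus_pairs(seq(d_lo[i], d_hi[i]), matrix$chromsizes, res)),
    numeric(1))]
  bins[, p_raw := n_contacts / (N * n_pairs)]
  bins[, p := pava_nonincreasing(p_raw, w = n_pairs)]
  structure(bins[], class = c("expected_model", class(bins)),
            N = N, resolution = res,
            d_range_bins = c(d_min_b, d_max_b))
}

#' @export
print.expected_model <- function(x, ...) {
  cat("expected_model:", nrow(x), "distance bins, N =", attr(x, "N"), "\n")
  invisible(x)
}

# expected probability per bin distance (NA outside modeled range)
expected_p <- function(model, d_bins) {
  idx <- findInterval(d_bins, c(model$d_lo, utils::tail(model$d_hi, 1) + 1))
  p <- model$p[idx]
  p[d_bins < model$d_lo[1] | d_bins > utils::tail(model$d_hi, 1)] <- NA_real_
  p
}

#' Upper-tail binomial p-value
#'
#' `P(X >= k)` for `X ~ Binomial(N, p)`, evaluated with the stable
#' survival-function path.
#'
#' @param k observed count (vectorized).
#' @param N binomial total.
#' @param p success probability in (0, 1).
#' @return p-values in `[0, 1]`.
#' @export
binom_pvalue <- function(k, N, p) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)", call. = FALSE)
  if (any(k < 0 | k > N)) stop("k must be in [0, N]", call. = FALSE)
  pbinom(k - 1, N, p, lower.tail = FALSE)
}

#' Call stable chromatin contacts
#'
#' Tests every occupied intra-chromosomal bin pair within the model's
#' distance range against the expected model with an upper-tail binomial
#' test, applies Benjamini-Hochberg over all tested pairs, and returns
#' pairs with `q <= q_threshold`, sorted by q then distance.
#'
#' @param matrix a `contact_matrix` of raw counts.
#' @param model the [fit_expected()] model fitted on the same matrix.
#' @param q_threshold FDR threshold (default 0.01).
#' @return `data.table` of calls: `chrom1, bin1, chrom2, bin2, start1,
#'   end1, start2, end2, count, p_exp, pvalue, qvalue`, with attribute
#'   `n_tested`.
#' @export
call_stable_contacts <- function(matrix, model, q_threshold = 0.01) {
  res <- matrix$resolution
  rng <- attr(model, "d_range_bins")
  tested <- matrix$counts[chrom1 == chrom2]
  empty <- data.table(chrom1 = character(), bin1 = integer(),
                      chrom2 = character(), bin2 = integer(),
                      start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer(),
                      count = integer(), p_exp = numeric(),
                      pvalue = numeric(), qvalue = numeric())
  if (!nrow(tested)) return(structure(empty, n_tested = 0L,
                                      q_threshold = q_threshold))
  tested[, distance := bin2 - bin1]
  tested <- tested[distance >= rng[1] & distance <= rng[2]]
  if (!nrow(tested)) return(structure(empty, n_tested = 0L,
                                      q_threshold = q_threshold))
  tested[, p_exp := expected_p(model, distance)]
  tested <- tested[!is.na(p_exp)]
  tested[, pvalue := binom_pvalue(count, attr(model, "N"), p_exp)]
  tested[, qvalue := p.adjust(pvalue, method = "BH")]
  n_tested <- nrow(tested)
  calls <- tested[qvalue <= q_threshold]
  setorder(calls, qvalue, distance)
  calls[, `:=`(start1 = bin1 * res, end1 = (bin1 + 1L) * res,
               start2 = bin2 * res, end2 = (bin2 + 1L) * res)]
  out <- calls[, .(chrom1, bin1, chrom2, bin2, start1, end1, start2, end2,
                   count, p_exp, pvalue, qvalue)]
  structure(out, n_tested = n_tested, q_threshold = q_threshold)
}

#' Write stable-contact calls as BEDPE-like TSV
#'
#' @param calls a [call_stable_contacts()] result.
#' @param path output file.
#' @export
write_loop_calls <- function(calls, path) {
  fwrite(calls[, .(chrom1, start1, end1, chrom2, start2, end2, count,
                   p_exp, pvalue, qvalue)], path, sep = "\t")
  invisible(path)
}

#' Intersect stable contacts across conditions
#'
#' Bin pairs present in every condition ("primed" contacts). Matching is
#' exact on anchors by default; `slack` allows +/- that many bins on each
#' anchor.
#'
#' @param calls_by_condition named list of [call_stable_contacts()]
#'   results (>= 2), same resolution.
#' @param slack anchor slack in bins (0 = exact).
#' @return `data.table` of bin pairs present everywhere, with per-condition
#'   supporting counts and the condition names in attribute `conditions`.
#' @export
intersect_conditions <- function(calls_by_condition, slack = 0L) {
  stopifnot(length(calls_by_condition) >= 2)
  key <- c("chrom1", "bin1", "chrom2", "bin2")
  base <- copy(calls_by_condition[[1]])[, ..key]
  for (i in seq_along(calls_by_condition)[-1]) {
    other <- calls_by_condition[[i]][, ..key]
    if (slack > 0L) {
      shifts <- expand.grid(d1 = -slack:slack, d2 = -slack:slack)
      other <- rbindlist(lapply(seq_len(nrow(shifts)), function(j)
        copy(other)[, `:=`(bin1 = bin1 + shifts$d1[j],
                           bin2 = bin2 + shifts$d2[j])]))
    }
    base <- unique(base[unique(other), on = key, nomatch = NULL])
  }
  unique(structure(base, conditions = names(calls_by_condition)))
}
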