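#' Normalized chromatin contact density per gene
#'
#' Counts contacts with both ends inside the gene body and normalizes to
#' contacts per kb of gene length per million library contacts.
#'
#' @param pairs filtered canonical contact pair table.
#' @param annotation a [gene_annotation()].
#' @param library_total library size used for depth normalization
#'   (default: `nrow(pairs)`).
#' @return `data.table` with `gene_id, n_contacts, length_bp, density`.
#' @export
gene_contact_density <- function(pairs, annotation,
                                 library_total = nrow(pairs)) {
  if (is.null(library_total) || library_total == 0)
    stop("library_total must be positive", call. = FALSE)
  g <- copy(annotation$genes)
  intra <- pairs[chrom1 == chrom2, .(chrom = chrom1, start = pos1,
                                     end = pos2 + 1L)]
  setkey(g, chrom, start, end)
  if (nrow(intra)) {
    ov <- foverlaps(intra, g[, .(chrom, start, end, gene_id)],
                    type = "within", nomatch = NULL)
    cnt <- ov[, .(n_contacts = .N), by = gene_id]
  } else {
    cnt <- data.table(gene_id = character(), n_contacts = integer())
  }
  out <- cnt[annotation$genes[, .(gene_id, length_bp = end - start)],
             on = "gene_id"]
  out[is.na(n_contacts), n_contacts := 0L]
  out[, density := n_contacts / (length_bp / 1e3) / (library_total / 1e6)]
  setorder(out, gene_id)
  out[]
}

#' Top and bottom percentile gene sets
#'
#' Deterministic stratification: ties broken by gene id; set sizes are
#' `ceiling(pct/100 * n)`.
#'
#' @param values named numeric vector (names = gene ids) or a two-column
#'   data.frame `gene_id, value`.
#' @param pct percentile in (0, 50].
#' @return list with `top`, `bottom` (character vectors of gene ids) and
#'   `n` per set.
#' @export
stratify_by_percentile <- function(values, pct = 10) {
  if (is.data.frame(values))
    values <- setNames(values[[2]], values[[1]])
  if (pct <= 0 || pct > 50) stop("pct must be in (0, 50]", call. = FALSE)
  n <- length(values)
  k <- ceiling(pct / 100 * n)
  if (length(unique(values)) == 1L)
    warning("all values equal; stratification is by gene id only")
  ord_desc <- order(-values, names(values))
  ord_asc <- order(values, names(values))
  list(top = names(values)[ord_desc[seq_len(k)]],
       bottom = names(values)[ord_asc[seq_len(k)]], n = k)
}

#' Scaled metagene contact profile
#'
#' Rescales every gene body to `n_body_bins` positions (minus-strand genes
#' reversed so the profile runs TSS to TTS), adds fixed-width flanks, and
#' averages depth-normalized contact-end coverage per bin within each gene
#' group. Each contact contributes both ends.
#'
#' @param pairs filtered canonical contact pair table.
#' @param annotation a [gene_annotation()].
#' @param groups named list of gene-id character vectors (e.g. top/bottom
#'   strata).
#' @param n_body_bins scaled gene-body bins (default 100).
#' @param flank_bp flank extent in bp on both sides.
#' @param n_flank_bins bins per flank.
#' @param library_total depth normalization denominator.
#' @return `data.table` with `group, bin, region, mean_density, n_genes`;
#'   `bin` runs 1..(2*n_flank_bins + n_body_bins).
#' @export
metagene_profile <- function(pairs, annotation, groups, n_body_bins = 100L,
                             flank_bp = 500L, n_flank_bins = 20L,
                             library_total = nrow(pairs)) {
  stopifnot(is.list(groups), length(groups) > 0)
  if (any(lengths(groups) == 0)) stop("empty gene group", call. = FALSE)
  g <- annotation$genes
  ends <- rbind(pairs[, .(chrom = chrom1, pos = pos1)],
                pairs[, .(chrom = chrom2, pos = pos2)])
  setkey(ends, chrom, pos)
  pos_by_chrom <- split(ends$pos, ends$chrom)  # sorted within chromosome
  depth <- library_total / 1e6
  total_bins <- 2L * n_flank_bins + n_body_bins
  rows <- lapply(names(groups), function(grp) {
    ids <- groups[[grp]]
    sel <- g[gene_id %in% ids]
    sel <- sel[(end - start) >= n_body_bins]
    if (!nrow(sel))
      stop("no usable genes in group ", grp, call. = FALSE)
    acc <- numeric(total_bins)
    for (i in seq_len(nrow(sel))) {
      gs <- sel$start[i]; ge <- sel$end[i]; len <- ge - gs
      w0 <- gs - flank_bp; w1 <- ge + flank_bp
      pv <- pos_by_chrom[[sel$chrom[i]]]
      if (is.null(pv)) next
      lo <- findInterval(w0 - 0.5, pv) + 1L
      hi <- findInterval(w1 - 0.5, pv)
      if (hi < lo) next
      p <- pv[lo:hi]
      b <- integer(length(p))
      inb <- p >= gs & p < ge
      b[inb] <- n_flank_bins + 1L +
        as.integer(floor((p[inb] - gs) / len * n_body_bins))
      upb <- p < gs
      b[upb] <- as.integer(floor((p[upb] - w0) / flank_bp * n_flank_bins)) +
        1L
      dnb <- p >= ge
      b[dnb] <- n_flank_bins + n_body_bins +
        as.integer(floor((p[dnb] - ge) / flank_bp * n_flank_bins)) + 1L
      b[b > total_bins] <- total_bins
      if (sel$strand[i] == "-") b <- total_bins + 1L - b
      acc <- acc + tabulate(b, nbins = total_bins)
    }
    data.table(group = grp, bin = seq_len(total_bins),
               region = rep(c("upstream", "body", "downstream"),
                            c(n_flank_bins, n_body_bins, n_flank_bins)),
               mean_density = acc / nrow(sel) / depth,
               n_genes = nrow(sel))
  })
  rbindlist(rows)
}

#' Contact profile around 5' splice sites
#'
#' Per-bp contact-end density over a window around (first) 5' splice
#' sites, strand-aware (positive offsets run downstream in transcription
#' direction), optionally per condition with per-condition Z-score
#' normalization over the window (population standard deviation), the
#' device used to compare libraries of different depths.
#'
#' @param pairs_by_condition named list of canonical contact pair tables
#'   (one per condition), or a single table (condition `all`).
#' @param annotation a [gene_annotation()].
#' @param window `c(upstream, downstream)` in bp, default `c(-100, 200)`.
#' @param first_only use only each gene's first 5'SS (default TRUE).
#' @param zscore apply per-condition Z-scoring over the window.
#' @return `data.table` with `condition, offset, density, z` (and
#'   attribute `n_sites`).
#' @export
splice_site_profile <- function(pairs_by_condition, annotation,
                                window = c(-100L, 200L), first_only = TRUE,
                                zscore = TRUE) {
  if (is.data.frame(pairs_by_condition))
    pairs_by_condition <- list(all = pairs_by_condition)
  ss <- splice_sites_5p(annotation, first_only = first_only)
  if (!nrow(ss)) stop("no multi-exon genes", call. = FALSE)
  offs <- seq(window[1], window[2])
  rows <- lapply(names(pairs_by_condition), function(cond) {
    pairs <- pairs_by_condition[[cond]]
    ends <- rbind(pairs[, .(chrom = chrom1, pos = pos1)],
                  pairs[, .(chrom = chrom2, pos = pos2)])
    depth <- nrow(pairs) / 1e6
    acc <- numeric(length(offs))
    for (ci in unique(ss$chrom)) {
      e <- ends[chrom == ci]
      if (!nrow(e)) next
      cnt <- tabulate(e$pos + 1L,
                      nbins = max(e$pos) + 1L)
      sel <- ss[chrom == ci]
      for (i in seq_len(nrow(sel))) {
        gpos <- if (sel$strand[i] == "+") sel$pos[i] + offs else
          sel$pos[i] - offs
        ok <- gpos >= 0L & gpos < length(cnt)
        acc[ok] <- acc[ok] + cnt[gpos[ok] + 1L]
      }
    }
    density <- acc / nrow(ss) / depth
    data.table(condition = cond, offset = offs, density = density)
  })
  out <- rbindlist(rows)
  if (zscore) {
    out[, z := (density - mean(density)) / sd_pop(density), by = condition]
  } else out[, z := NA_real_]
  structure(out[], n_sites = nrow(ss))
}

#' Spearman rank correlation
#'
#' Midrank-tied Spearman correlation with a two-sided p-value: exact
#' permutation enumeration for `n <= 9`, t-approximation otherwise.
#'
#' @param x,y paired numeric vectors, `n >= 4`, not constant.
#' @return list with `rho` and `p_value`.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 paired values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector; correlation undefined", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- permutations_of(n)
    ry_c <- ry - mean(ry)
    rx_c <- rx - mean(rx)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    stats_all <- as.vector((matrix(rx_c[perms], nrow = nrow(perms)) %*%
                              ry_c)) / denom
    p <- mean(abs(stats_all) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p_value = min(p, 1))
}

# all permutations of 1..n as a matrix (n! rows); n <= 9
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}
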