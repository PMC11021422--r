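#' Pearson correlation of expression per gene pair
#'
#' Pearson r across the expression sample vector (conditions x
#' replicates) for each gene pair. Pairs involving a constant expression
#' vector are excluded (reported in the `n_constant` attribute).
#'
#' @param expr expression matrix from [expression_matrix()] (genes x
#'   samples) or a long table.
#' @param gene_pairs `data.table` with `geneA, geneB`.
#' @return `data.table` `geneA, geneB, r` with attribute `n_constant`.
#' @export
pair_expression_correlation <- function(expr, gene_pairs) {
  if (!is.matrix(expr)) expr <- expression_matrix(expr)
  if (ncol(expr) < 3) stop("need >= 3 expression samples", call. = FALSE)
  gene_pairs <- as.data.table(gene_pairs)
  missing <- setdiff(unique(c(gene_pairs$geneA, gene_pairs$geneB)),
                     rownames(expr))
  if (length(missing))
    stop("genes absent from expression: ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  z <- standardize_rows(expr)
  const <- is.na(z[, 1])
  keep <- !(const[gene_pairs$geneA] | const[gene_pairs$geneB])
  gp <- gene_pairs[keep]
  r <- rowSums(z[gp$geneA, , drop = FALSE] * z[gp$geneB, , drop = FALSE]) /
    (ncol(expr) - 1)
  structure(data.table(geneA = gp$geneA, geneB = gp$geneB, r = r),
            n_constant = sum(!keep))
}

# rows scaled to mean 0, sd 1 (sample sd); constant rows become NA
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  z <- (m - mu) / s
  z[s == 0, ] <- NA_real_
  z
}

#' Sample random control gene pairs
#'
#' Model A draws `n` distinct gene pairs uniformly. Model B draws, for each
#' observed PPI pair, a random same-chromosome gene pair whose TSS
#' separation falls in the same log2 distance bin (trans PPI pairs are
#' matched by random trans pairs); empty bins fall back to the nearest
#' non-empty bin with a warning.
#'
#' @param annotation a [gene_annotation()] (candidate genes and TSS
#'   coordinates).
#' @param n number of pairs (model A).
#' @param model `"A"` or `"B"`.
#' @param ppi_distances for model B: `data.table` with `distance` (bp, NA
#'   for trans) of the observed PPI pairs.
#' @param log2_bin_width log2 distance bin width (default 0.25).
#' @param seed integer seed.
#' @param candidates optional precomputed candidate cis-pair table (from
#'   repeated model-B sampling); computed from the annotation when NULL.
#' @return `data.table` `geneA, geneB, distance` (NA distance = trans pair).
#' @export
sample_random_pairs <- function(annotation, n = NULL, model = c("A", "B"),
                                ppi_distances = NULL, log2_bin_width = 0.25,
                                seed = NULL, candidates = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  tsst <- tss_table(annotation)
  ng <- nrow(tsst)
  if (model == "A") {
    stopifnot(!is.null(n))
    got <- data.table(i = integer(), j = integer())
    while (nrow(got) < n) {
      i <- sample(ng, 2 * (n - nrow(got)) + 4, replace = TRUE)
      j <- sample(ng, length(i), replace = TRUE)
      ok <- i != j
      cand <- data.table(i = pmin(i, j)[ok], j = pmax(i, j)[ok])
      got <- unique(rbind(got, cand))
    }
    got <- got[seq_len(n)]
    d <- fifelse(tsst$chrom[got$i] == tsst$chrom[got$j],
                 abs(tsst$tss[got$j] - tsst$tss[got$i]), NA_integer_)
    return(data.table(geneA = pmin(tsst$gene_id[got$i], tsst$gene_id[got$j]),
                      geneB = pmax(tsst$gene_id[got$i], tsst$gene_id[got$j]),
                      distance = d))
  }
  stopifnot(!is.null(ppi_distances))
  dist_obs <- as.data.table(ppi_distances)$distance
  cand <- candidates %||% candidate_cis_pairs(tsst)
  if (!"d_bin" %in% names(cand))
    cand[, d_bin := floor(log2(pmax(distance, 1)) / log2_bin_width)]
  cis_d <- dist_obs[!is.na(dist_obs)]
  rows <- list()
  if (length(cis_d)) {
    want <- floor(log2(pmax(cis_d, 1)) / log2_bin_width)
    # per-bin index pools, pre-shuffled; popped without replacement
    pools <- lapply(split(seq_len(nrow(cand)), cand$d_bin),
                    function(ix) if (length(ix) > 1) sample(ix) else ix)
    bins_avail <- as.numeric(names(pools))
    ptr <- setNames(rep(1L, length(pools)), names(pools))
    fell_back <- FALSE
    pick <- integer(length(want))
    for (k in seq_along(want)) {
      b <- as.character(want[k])
      if (is.null(pools[[b]]) || ptr[[b]] > length(pools[[b]])) {
        # empty or exhausted bin: nearest non-empty bin
        fell_back <- TRUE
        left <- vapply(names(pools), function(nm)
          ptr[[nm]] <= length(pools[[nm]]), logical(1))
        if (!any(left)) stop("candidate pairs exhausted", call. = FALSE)
        b <- names(pools)[left][
          which.min(abs(bins_avail[left] - want[k]))]
      }
      pick[k] <- pools[[b]][ptr[[b]]]
      ptr[[b]] <- ptr[[b]] + 1L
    }
    if (fell_back)
      warning("distance bin(s) without candidate pairs; ",
              "resampled from nearest non-empty bin")
    rows$cis <- cand[pick, .(geneA, geneB, distance)]
  }
  n_trans <- sum(is.na(dist_obs))
  if (n_trans > 0) {
    got <- data.table(i = integer(), j = integer())
    while (nrow(got) < n_trans) {
      i <- sample(ng, 2 * (n_trans - nrow(got)) + 4, replace = TRUE)
      j <- sample(ng, length(i), replace = TRUE)
      ok <- tsst$chrom[i] != tsst$chrom[j]
      cand_t <- data.table(i = pmin(i, j)[ok], j = pmax(i, j)[ok])
      got <- unique(rbind(got, cand_t))
    }
    got <- got[seq_len(n_trans)]
    rows$trans <- data.table(
      geneA = pmin(tsst$gene_id[got$i], tsst$gene_id[got$j]),
      geneB = pmax(tsst$gene_id[got$i], tsst$gene_id[got$j]),
      distance = NA_integer_)
  }
  unique(rbindlist(rows))
}

# all unordered same-chromosome gene pairs with TSS separations
candidate_cis_pairs <- function(tsst) {
  rbindlist(lapply(split(tsst, tsst$chrom), function(tc) {
    ng <- nrow(tc)
    if (ng < 2) return(NULL)
    idx <- CJ(i = seq_len(ng), j = seq_len(ng))[i < j]
    data.table(geneA = pmin(tc$gene_id[idx$i], tc$gene_id[idx$j]),
               geneB = pmax(tc$gene_id[idx$i], tc$gene_id[idx$j]),
               distance = abs(tc$tss[idx$j] - tc$tss[idx$i]))
  }))
}

#' Permutation test of PPI co-expression against matched nulls
#'
#' Compares the mean pairwise expression Pearson r of PPI-connected gene
#' pairs with `n_reps` replicates of two null models: A (same number of
#' random pairs) and B (random pairs with a matched distance
#' distribution). Empirical one-sided p uses the add-one estimator
#' `p = (1 + #{null >= observed}) / (1 + n_reps)` and can never be 0.
#'
#' @param expr expression matrix or long table.
#' @param annotation a [gene_annotation()].
#' @param ppi_pairs observed PPI gene pairs (`geneA, geneB`), used both for
#'   the observed statistic and the model-B distance multiset.
#' @param n_reps null replicates (default 1000; < 100 warns).
#' @param seed integer seed.
#' @param models which null models to run.
#' @return a `coexpression_result` list: `observed_mean`,
#'   `observed_median`, `n_pairs`, and per model the null replicate means
#'   and the empirical `p`.
#' @export
compare_to_null <- function(expr, annotation, ppi_pairs, n_reps = 1000L,
                            seed = 1L, models = c("A", "B")) {
  if (n_reps < 100) warning("fewer than 100 replicates; p is unstable")
  if (!is.matrix(expr)) expr <- expression_matrix(expr)
  ppi_pairs <- as.data.table(ppi_pairs)
  tsst <- tss_table(annotation)
  obs <- pair_expression_correlation(expr, ppi_pairs)
  observed_mean <- mean(obs$r)
  d <- data.table(
    distance = fifelse(
      tsst$chrom[match(ppi_pairs$geneA, tsst$gene_id)] ==
        tsst$chrom[match(ppi_pairs$geneB, tsst$gene_id)],
      abs(tsst$tss[match(ppi_pairs$geneB, tsst$gene_id)] -
            tsst$tss[match(ppi_pairs$geneA, tsst$gene_id)]),
      NA_integer_))
  z <- standardize_rows(expr)
  mean_r <- function(gp) {
    keep <- !(is.na(z[gp$geneA, 1]) | is.na(z[gp$geneB, 1]))
    gp <- gp[keep]
    mean(rowSums(z[gp$geneA, , drop = FALSE] *
                   z[gp$geneB, , drop = FALSE]) / (ncol(z) - 1))
  }
  out <- list(observed_mean = observed_mean,
              observed_median = stats::median(obs$r),
              n_pairs = nrow(obs), n_reps = n_reps, seed = seed)
  cand <- if ("B" %in% models) {
    cc <- candidate_cis_pairs(tsst)
    cc[, d_bin := floor(log2(pmax(distance, 1)) / 0.25)]
    cc
  } else NULL
  for (m in models) {
    nulls <- vapply(seq_len(n_reps), function(r) {
      gp <- suppressWarnings(sample_random_pairs(
        annotation, n = nrow(ppi_pairs), model = m, ppi_distances = d,
        seed = derive_seed(seed, paste0("null", m, ".", r)),
        candidates = cand))
      mean_r(gp)
    }, numeric(1))
    out[[paste0("null_", m)]] <- list(
      means = nulls, mean = mean(nulls), sd = sd(nulls),
      p = (1 + sum(nulls >= observed_mean)) / (1 + n_reps))
  }
  class(out) <- "coexpression_result"
  out
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat(sprintf("coexpression: observed mean r = %.3f over %d pairs\n",
              x$observed_mean, x$n_pairs))
  for (m in c("A", "B")) {
    nm <- paste0("null_", m)
    if (!is.null(x[[nm]]))
      cat(sprintf("  null %s: mean %.3f (sd %.3f), p = %.4g\n", m,
                  x[[nm]]$mean, x[[nm]]$sd, x[[nm]]$p))
  }
  invisible(x)
}
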