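#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package: a 3 Mb genome in 5 chromosomes, 500 genes, a power-law
#' (exponent `alpha`) intra-chromosomal contact background truncated to
#' `[decay_min, chromosome length)`, 200 planted loops at 8-fold enrichment
#' with anchor separations log-uniform on `loop_sep_range`, gene-body
#' contacts concentrated in a window downstream of each gene's first 5'
#' splice site with condition weights `22C > cold12h > cold3h` (sharp drop
#' at 3 h cold, partial recovery by 12 h), and three-condition expression
#' with correlation `rho` for loop-connected gene pairs.
#'
#' @param seed mandatory integer seed; all stage seeds derive from it.
#' @param n_chroms,chrom_length genome shape (bp per chromosome).
#' @param n_genes total genes; `tight_pair_fraction` of them are placed as
#'   close divergent/tandem promoter pairs usable as loop anchors.
#' @param multiexon_fraction fraction of genes with >= 2 exons.
#' @param resolution contact matrix bin width (bp).
#' @param alpha distance-decay exponent of the background (> 0).
#' @param n_background_pairs total background contact pairs per condition.
#' @param trans_fraction fraction of background pairs that are
#'   inter-chromosomal.
#' @param decay_min lower truncation of the background distance law (bp).
#' @param n_loops planted loops; `loop_fold` their fold-enrichment over the
#'   local background expectation (>= 1; 1 plants nothing).
#' @param loop_sep_range anchor separation range (bp), sampled log-uniform.
#' @param tight_pair_fraction fraction of genes arranged as close pairs.
#' @param pp_loop_fraction fraction of the tight pairs that are planted as
#'   promoter-promoter loops; the rest stay unconnected so distance-matched
#'   null models have genuine candidates at loop-like separations.
#' @param n_enhancers free (non-loop) enhancer intervals.
#' @param fivess_window window downstream of the first 5'SS (bp offsets)
#'   receiving pausing-like gene-body contacts.
#' @param fivess_rate expected pausing-window contacts per gene at 22C
#'   before the per-gene activity factor.
#' @param condition_weights named multipliers of `fivess_rate` per
#'   condition.
#' @param activity_coupling target Spearman correlation between per-gene
#'   activity signal and planted gene-body contact intensity.
#' @param rho expression correlation for loop-connected gene pairs
#'   (in (-1, 1)).
#' @param n_replicates expression replicates per condition.
#' @param n_hotspots,hotspot_spokes network-level hub promoters added to the
#'   ground-truth PPI pair set (not planted as extra contacts).
#' @param mapq_low_fraction fraction of read ends with MAPQ < 10.
#' @param duplicate_fraction fraction of pairs re-emitted as exact
#'   duplicates.
#' @param linker bridge-linker search string planted in simulated reads.
#' @param read_len maximum simulated read length (bp).
#' @param decoy_fraction probability that a simulated read is a linker-free
#'   decoy.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_chroms = 5L, chrom_length = 6e5, n_genes = 500L,
                       multiexon_fraction = 0.8, resolution = 200L,
                       alpha = 1.0, n_background_pairs = 2e6,
                       trans_fraction = 0.05, decay_min = 1000,
                       n_loops = 200L, loop_fold = 8,
                       loop_sep_range = c(1000, 2000),
                       tight_pair_fraction = 0.4, pp_loop_fraction = 0.5,
                       n_enhancers = 60L,
                       fivess_window = c(0, 50), fivess_rate = 80,
                       condition_weights = c("22C" = 1, "cold3h" = 0.3,
                                             "cold12h" = 0.7),
                       activity_coupling = 0.4, rho = 0.5,
                       n_replicates = 3L, n_hotspots = 2L,
                       hotspot_spokes = 60L,
                       mapq_low_fraction = 0.05, duplicate_fraction = 0.01,
                       linker = "GTCAGAAAGATATCGCGT", read_len = 418L,
                       decoy_fraction = 0.2) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(alpha > 0, loop_fold >= 1, n_chroms >= 1, chrom_length > 0)
  if (rho <= -1 || rho >= 1) stop("rho must be in (-1, 1)", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

conditions_of <- function(config) names(config$condition_weights)

# truncated power-law sampler, density ~ s^-alpha on [smin, smax]
r_powerlaw <- function(n, alpha, smin, smax) {
  u <- runif(n)
  if (abs(alpha - 1) < 1e-12) {
    smin * (smax / smin)^u
  } else {
    a1 <- 1 - alpha
    (smin^a1 + u * (smax^a1 - smin^a1))^(1 / a1)
  }
}

# analytic density of the truncated power law at s
d_powerlaw <- function(s, alpha, smin, smax) {
  if (abs(alpha - 1) < 1e-12) {
    1 / (log(smax / smin) * s)
  } else {
    a1 <- 1 - alpha
    a1 / (smax^a1 - smin^a1) * s^(-alpha)
  }
}

#' Generate a toy genome with planted loop anchors
#'
#' Places non-overlapping genes (a configurable fraction as close
#' divergent/tandem promoter pairs whose TSS separation falls in
#' `loop_sep_range`), enhancers in intergenic space, and derives the ground
#' truth: planted loop anchors with folds, loop-connected gene pairs, hub
#' promoters, and per-gene activity factors.
#'
#' @param config a [sim_config()].
#' @return list with `chromsizes`, `annotation`, `enhancers`
#'   (`data.table`), `truth` (loops, PPI pairs, hubs, activity factors) and
#'   the `config`; class `fc_genome`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  n_chroms <- config$n_chroms
  L <- config$chrom_length
  chromsizes <- chrom_sizes(paste0("chr", seq_len(n_chroms)),
                            rep(L, n_chroms))

  n_pairs <- floor(config$tight_pair_fraction * config$n_genes / 2)
  n_single <- config$n_genes - 2L * n_pairs
  sep_rng <- config$loop_sep_range

  rlen <- function(n) pmin(pmax(round(exp(rnorm(n, log(2000), 0.35))), 800),
                           6000)
  units <- vector("list", n_pairs + n_single)
  for (i in seq_len(n_pairs)) {
    sep <- round(r_powerlaw(1, 1, sep_rng[1], sep_rng[2]))  # log-uniform
    if (runif(1) < 0.5) {
      # divergent: <-L  R->, TSSs sep apart, bodies extend outwards
      lenL <- rlen(1); lenR <- rlen(1)
      units[[i]] <- list(kind = "pair", sep = sep, lenL = lenL, lenR = lenR,
                         strandL = "-", strandR = "+",
                         span = lenL + sep + lenR)
    } else if (runif(1) < 0.5) {
      # tandem + +: left gene must end before the right TSS
      lenL <- min(rlen(1), sep - 100L); lenR <- rlen(1)
      units[[i]] <- list(kind = "pair", sep = sep, lenL = lenL, lenR = lenR,
                         strandL = "+", strandR = "+",
                         span = sep + lenR)
    } else {
      # tandem - -: right gene must start after the left TSS
      lenL <- rlen(1); lenR <- min(rlen(1), sep - 100L)
      units[[i]] <- list(kind = "pair", sep = sep, lenL = lenL, lenR = lenR,
                         strandL = "-", strandR = "-",
                         span = lenL + sep)
    }
  }
  for (i in seq_len(n_single)) {
    len <- rlen(1)
    units[[n_pairs + i]] <- list(kind = "single", len = len,
                                 strand = sample(c("+", "-"), 1), span = len)
  }

  margin <- 5000
  min_gap <- 400
  chrom_of <- rep(seq_len(n_chroms), length.out = length(units))
  # exact multi-exon count (gene lengths are all >= 800, so no fallback)
  multi_flag <- logical(config$n_genes)
  multi_flag[sample(config$n_genes,
                    round(config$multiexon_fraction * config$n_genes))] <- TRUE
  genes <- list(); exons <- list(); pair_ids <- list()
  gid <- 0L
  mk_gene <- function(chrom, start, len, strand) {
    gid <<- gid + 1L
    id <- sprintf("G%04d", gid)
    genes[[length(genes) + 1L]] <<- data.table(
      gene_id = id, chrom = chrom, start = start, end = start + len,
      strand = strand)
    exons[[length(exons) + 1L]] <<- mk_exons(id, start, len, strand,
                                             multi_flag[gid])
    id
  }
  mk_exons <- function(id, start, len, strand, multi) {
    if (!multi || len < 700L)
      return(data.table(gene_id = id, start = start, end = start + len))
    n_ex <- max(2L, min(4L, len %/% 600L))
    n_seg <- 2L * n_ex - 1L
    min_seg <- 120L
    # transcription-order segments: exon1 100-400 bp, later segments >= 120
    e1 <- round(runif(1, 100, min(400, len - (n_seg - 1L) * min_seg)))
    w <- runif(n_seg - 1L, 0.5, 1.5)
    raw <- min_seg + (len - e1 - (n_seg - 1L) * min_seg) * w / sum(w)
    seg <- c(e1, floor(raw))
    seg[n_seg] <- len - sum(seg[-n_seg])
    if (strand == "-") seg <- rev(seg)  # genomic order
    edges <- start + cumsum(c(0, seg))
    ex_i <- seq(1, n_seg, by = 2)
    data.table(gene_id = id, start = as.integer(edges[ex_i]),
               end = as.integer(edges[ex_i + 1]))
  }

  for (c_i in seq_len(n_chroms)) {
    u_idx <- which(chrom_of == c_i)
    if (!length(u_idx)) next
    spans <- vapply(units[u_idx], `[[`, numeric(1), "span")
    avail <- L - 2 * margin - sum(spans) - (length(u_idx) + 1) * min_gap
    if (avail < 0)
      stop("genome too small for requested genes", call. = FALSE)
    raw <- stats::rexp(length(u_idx) + 1)
    gaps <- min_gap + raw / sum(raw) * avail
    pos <- margin
    for (j in seq_along(u_idx)) {
      pos <- pos + gaps[j]
      u <- units[[u_idx[j]]]
      at <- as.integer(round(pos))
      chrom <- names(chromsizes)[c_i]
      if (u$kind == "single") {
        mk_gene(chrom, at, u$len, u$strand)
      } else {
        # lay out by TSS positions tssL = p, tssR = p + sep
        if (u$strandL == "-") {
          p <- at + u$lenL - 1L
          idL <- mk_gene(chrom, at, u$lenL, "-")
        } else {
          p <- at
          idL <- mk_gene(chrom, at, u$lenL, "+")
        }
        tssR <- p + u$sep
        if (u$strandR == "+") {
          idR <- mk_gene(chrom, tssR, u$lenR, "+")
        } else {
          idR <- mk_gene(chrom, tssR - u$lenR + 1L, u$lenR, "-")
        }
        pair_ids[[length(pair_ids) + 1L]] <- data.table(
          geneA = idL, geneB = idR, chrom = chrom,
          tssA = p, tssB = tssR, sep = u$sep)
      }
      pos <- pos + u$span
    }
  }
  genes <- rbindlist(genes)
  exons <- rbindlist(exons)
  annotation <- gene_annotation(genes, exons)
  tight_pairs <- if (length(pair_ids)) rbindlist(pair_ids) else
    data.table(geneA = character(), geneB = character(), chrom = character(),
               tssA = integer(), tssB = integer(), sep = integer())

  tsst <- tss_table(annotation)
  prom_guard <- promoter_windows(annotation, 600L, 600L, chromsizes)

  overlaps_any <- function(chrom_val, start, end) {
    g <- annotation$genes[annotation$genes$chrom == chrom_val]
    p <- prom_guard[prom_guard$chrom == chrom_val]
    any(g$start < end & g$end > start) || any(p$start < end & p$end > start)
  }

  # planted loops: all tight promoter pairs first (P-P), then E-P, then
  # intergenic anchor pairs to fill up to n_loops
  loops <- list()
  n_pp <- min(round((config$pp_loop_fraction %||% 1) * nrow(tight_pairs)),
              config$n_loops)
  if (n_pp > 0) {
    tp <- tight_pairs[seq_len(n_pp)]
    loops[[1]] <- data.table(chrom = tp$chrom, pos1 = pmin(tp$tssA, tp$tssB),
                             pos2 = pmax(tp$tssA, tp$tssB),
                             kind = "PP", geneA = tp$geneA, geneB = tp$geneB,
                             enhancer_id = NA_character_)
  }
  enh <- list(); enh_n <- 0L
  mk_enhancer <- function(chrom, mid) {
    enh_n <<- enh_n + 1L
    id <- sprintf("E%03d", enh_n)
    enh[[enh_n]] <<- data.table(enhancer_id = id, chrom = chrom,
                                start = as.integer(mid - 150L),
                                end = as.integer(mid + 150L))
    id
  }
  n_ep <- config$n_loops - n_pp
  ep_rows <- list()
  tries <- 0L
  while (length(ep_rows) < n_ep && tries < n_ep * 60L) {
    tries <- tries + 1L
    g <- tsst[sample(nrow(tsst), 1)]
    d <- round(r_powerlaw(1, 1, sep_rng[1], sep_rng[2]))
    side <- sample(c(-1L, 1L), 1)
    mid <- g$tss + side * d
    if (mid - 150L < margin || mid + 150L > L - margin) next
    if (overlaps_any(g$chrom, mid - 150L, mid + 150L)) next
    eid <- mk_enhancer(g$chrom, mid)
    ep_rows[[length(ep_rows) + 1L]] <- data.table(
      chrom = g$chrom, pos1 = min(g$tss, mid), pos2 = max(g$tss, mid),
      kind = "EP", geneA = g$gene_id, geneB = NA_character_,
      enhancer_id = eid)
  }
  if (length(ep_rows)) loops[[length(loops) + 1L]] <- rbindlist(ep_rows)
  short <- config$n_loops - n_pp - length(ep_rows)
  if (short > 0) {
    ot_rows <- list(); tries <- 0L
    while (length(ot_rows) < short && tries < short * 200L) {
      tries <- tries + 1L
      chrom <- sample(names(chromsizes), 1)
      a <- round(runif(1, margin, L - margin - sep_rng[2]))
      d <- round(r_powerlaw(1, 1, sep_rng[1], sep_rng[2]))
      if (overlaps_any(chrom, a - 100L, a + 100L) ||
          overlaps_any(chrom, a + d - 100L, a + d + 100L)) next
      ot_rows[[length(ot_rows) + 1L]] <- data.table(
        chrom = chrom, pos1 = a, pos2 = a + d, kind = "other",
        geneA = NA_character_, geneB = NA_character_,
        enhancer_id = NA_character_)
    }
    if (length(ot_rows)) loops[[length(loops) + 1L]] <- rbindlist(ot_rows)
  }
  loops <- rbindlist(loops)
  if (!nrow(loops))
    loops <- data.table(chrom = character(), pos1 = integer(),
                        pos2 = integer(), kind = character(),
                        geneA = character(), geneB = character(),
                        enhancer_id = character())
  loops[, `:=`(pos1 = as.integer(pos1), pos2 = as.integer(pos2),
               sep = as.integer(pos2 - pos1), fold = config$loop_fold)]

  # free enhancers (not loop-anchored)
  tries <- 0L
  want <- config$n_enhancers
  while (enh_n < want + sum(loops$kind == "EP") && tries < want * 60L) {
    tries <- tries + 1L
    chrom <- sample(names(chromsizes), 1)
    mid <- round(runif(1, margin, L - margin))
    if (overlaps_any(chrom, mid - 150L, mid + 150L)) next
    mk_enhancer(chrom, mid)
  }
  enhancers <- if (enh_n) rbindlist(enh) else
    data.table(enhancer_id = character(), chrom = character(),
               start = integer(), end = integer())

  # per-gene activity factor driving pausing-window contact intensity
  act <- exp(rnorm(nrow(genes), 0, 0.6))
  activity <- data.table(gene_id = genes$gene_id, factor = act)

  # hub promoters: network-level ground truth (primed PPIs to many genes)
  hubs <- list()
  if (config$n_hotspots > 0 && nrow(genes) > config$hotspot_spokes + 1) {
    hub_genes <- sample(genes$gene_id, config$n_hotspots)
    for (h in hub_genes) {
      spokes <- sample(setdiff(genes$gene_id, h), config$hotspot_spokes)
      hubs[[h]] <- spokes
    }
  }
  ppi_pairs <- loops[kind == "PP", .(geneA, geneB)]
  if (length(hubs)) {
    hub_edges <- rbindlist(lapply(names(hubs), function(h)
      data.table(geneA = h, geneB = hubs[[h]])))
    ppi_pairs <- unique(rbind(ppi_pairs, hub_edges))
  }
  ppi_pairs[, `:=`(geneA0 = pmin(geneA, geneB), geneB0 = pmax(geneA, geneB))]
  ppi_pairs <- unique(ppi_pairs[, .(geneA = geneA0, geneB = geneB0)])

  truth <- list(loops = loops[], tight_pairs = tight_pairs,
                ppi_pairs = ppi_pairs[], hubs = hubs,
                activity_factor = activity,
                condition_weights = config$condition_weights)
  structure(list(chromsizes = chromsizes, annotation = annotation,
                 enhancers = enhancers, truth = truth, config = config),
            class = "fc_genome")
}

#' @export
print.fc_genome <- function(x, ...) {
  cat("fc_genome:", length(x$chromsizes), "chromosomes,",
      nrow(x$annotation$genes), "genes,", nrow(x$truth$loops),
      "planted loops\n")
  invisible(x)
}

# pausing anchor per gene: first 5'SS for multi-exon genes, a fixed offset
# downstream of the TSS otherwise
pausing_anchors <- function(genome) {
  ss <- splice_sites_5p(genome$annotation, first_only = TRUE)
  g <- genome$annotation$genes
  single <- g[!gene_id %in% ss$gene_id]
  extra <- data.table(gene_id = single$gene_id, chrom = single$chrom,
                      pos = fifelse(single$strand == "+",
                                    single$start + 150L, single$end - 151L),
                      strand = single$strand, intron_rank = NA_integer_)
  rbind(ss, extra)
}

#' Simulate contact pairs for one condition
#'
#' Background intra-chromosomal distances follow the truncated power law
#' `s^-alpha` on `[decay_min, chrom_length)`; planted loops add
#' `Poisson((fold - 1) x expected)` extra pairs in their anchor bin pair;
#' pausing-like gene-body contacts join the window downstream of each
#' gene's first 5'SS to a random position in the gene body, scaled by the
#' per-gene activity factor and the condition weight; a low rate of
#' inter-chromosomal background and exact duplicates is added, and a small
#' fraction of read ends carries MAPQ < 10.
#'
#' @param genome a [generate_genome()] result.
#' @param condition one of the configured condition names.
#' @param config optional override of `genome$config`.
#' @return canonical contact pair `data.table`.
#' @export
simulate_contacts <- function(genome, condition, config = genome$config) {
  w <- config$condition_weights
  if (!condition %in% names(w))
    stop("unknown condition: ", condition, call. = FALSE)
  set.seed(derive_seed(config$seed, paste0("contacts.", condition)))
  cs <- genome$chromsizes
  res <- config$resolution
  n_bg <- config$n_background_pairs
  n_trans <- rbinom(1, n_bg, config$trans_fraction)
  n_intra <- n_bg - n_trans

  # intra background
  chrom_i <- sample(seq_along(cs), n_intra, replace = TRUE,
                    prob = as.numeric(cs))
  L <- as.numeric(cs)[chrom_i]
  s <- r_powerlaw(n_intra, config$alpha, config$decay_min, L - 1)
  s <- pmin(round(s), L - 1)
  p1 <- floor(runif(n_intra) * (L - s))
  bg <- data.table(chrom1 = names(cs)[chrom_i], pos1 = as.integer(p1),
                   chrom2 = names(cs)[chrom_i], pos2 = as.integer(p1 + s))

  # trans background
  if (n_trans > 0) {
    ci <- sample(seq_along(cs), n_trans, replace = TRUE,
                 prob = as.numeric(cs))
    cj <- sample(seq_along(cs), n_trans, replace = TRUE,
                 prob = as.numeric(cs))
    same <- ci == cj
    while (any(same)) {
      cj[same] <- sample(seq_along(cs), sum(same), replace = TRUE)
      same <- ci == cj
    }
    tr <- data.table(
      chrom1 = names(cs)[ci],
      pos1 = as.integer(floor(runif(n_trans) * as.numeric(cs)[ci])),
      chrom2 = names(cs)[cj],
      pos2 = as.integer(floor(runif(n_trans) * as.numeric(cs)[cj])))
  } else tr <- NULL

  # planted loops at fold x expected background rate for their bin pair
  lp <- genome$truth$loops
  loop_rows <- NULL
  if (nrow(lp) && config$loop_fold > 1) {
    n_c <- as.numeric(table(factor(names(cs)[chrom_i], levels = names(cs))))
    names(n_c) <- names(cs)
    B <- floor(as.numeric(cs) / res); names(B) <- names(cs)
    d_bins <- abs(floor(lp$pos2 / res) - floor(lp$pos1 / res))
    lam <- n_c[lp$chrom] * d_powerlaw(lp$sep, config$alpha, config$decay_min,
                                      as.numeric(cs[lp$chrom]) - 1) * res /
      (B[lp$chrom] - d_bins)
    extra <- rpois(nrow(lp), (lp$fold - 1) * lam)
    if (sum(extra) > 0) {
      idx <- rep(seq_len(nrow(lp)), extra)
      b1 <- floor(lp$pos1[idx] / res)
      b2 <- floor(lp$pos2[idx] / res)
      loop_rows <- data.table(
        chrom1 = lp$chrom[idx],
        pos1 = as.integer(b1 * res + floor(runif(length(idx)) * res)),
        chrom2 = lp$chrom[idx],
        pos2 = as.integer(b2 * res + floor(runif(length(idx)) * res)))
    }
  }

  # pausing-window gene-body contacts
  anchors <- pausing_anchors(genome)
  af <- genome$truth$activity_factor
  anchors <- anchors[af, on = "gene_id", nomatch = NULL]
  g <- genome$annotation$genes
  anchors <- anchors[g[, .(gene_id, gstart = start, gend = end)],
                     on = "gene_id", nomatch = NULL]
  counts <- rpois(nrow(anchors), config$fivess_rate * anchors$factor *
                    w[[condition]])
  gb_rows <- NULL
  if (sum(counts) > 0) {
    idx <- rep(seq_len(nrow(anchors)), counts)
    a <- anchors[idx]
    off <- floor(runif(length(idx), config$fivess_window[1],
                       config$fivess_window[2] + 1))
    e1 <- fifelse(a$strand == "+", a$pos + off, a$pos - off)
    e2 <- floor(a$gstart + runif(length(idx)) * (a$gend - a$gstart))
    gb_rows <- data.table(chrom1 = a$chrom, pos1 = as.integer(e1),
                          chrom2 = a$chrom, pos2 = as.integer(e2))
  }

  all_rows <- rbindlist(list(bg, tr, loop_rows, gb_rows), use.names = TRUE)
  n <- nrow(all_rows)
  mq <- function(n) fifelse(runif(n) < config$mapq_low_fraction,
                            as.integer(floor(runif(n, 0, 10))),
                            as.integer(floor(runif(n, 10, 61))))
  all_rows[, `:=`(strand1 = sample(c("+", "-"), n, replace = TRUE),
                  strand2 = sample(c("+", "-"), n, replace = TRUE),
                  mapq1 = mq(n), mapq2 = mq(n))]
  n_dup <- rbinom(1, n, config$duplicate_fraction)
  if (n_dup > 0)
    all_rows <- rbind(all_rows, all_rows[sample(n, n_dup, replace = TRUE)])
  canonicalize_pairs(all_rows[, .(chrom1, pos1, strand1, chrom2, pos2,
                                  strand2, mapq1, mapq2)], cs)
}

#' Simulate activity tracks and an expression matrix
#'
#' Per-condition activity tracks paint each gene body with a positive value
#' rank-coupled (target Spearman `activity_coupling`) to the gene's planted
#' pausing-contact intensity, scaled by the condition weight. Expression for
#' loop-connected gene pairs is drawn from a shared-factor Gaussian model
#' giving pairwise correlation `rho` across conditions x replicates;
#' unconnected genes are independent.
#'
#' @inheritParams simulate_contacts
#' @return list with `tracks` (named list of [signal_track()] per
#'   condition), `expression` (long table) and `activity` (per-gene values).
#' @export
simulate_activity_and_expression <- function(genome, config = genome$config) {
  if (config$rho <= -1 || config$rho >= 1)
    stop("rho must be in (-1, 1)", call. = FALSE)
  set.seed(derive_seed(config$seed, "activity"))
  g <- genome$annotation$genes
  af <- genome$truth$activity_factor
  stopifnot(identical(af$gene_id, g$gene_id))
  n <- nrow(g)

  # normal-score coupling; Pearson on scores chosen so the rank (Spearman)
  # correlation matches the configured target for bivariate Gaussian scores
  rs <- config$activity_coupling
  rp <- 2 * sin(pi * rs / 6)
  z_contact <- scale(log(af$factor))[, 1]
  z_act <- rp * z_contact + sqrt(1 - rp^2) * rnorm(n)
  act_value <- exp(z_act)

  res <- config$resolution
  tracks <- lapply(conditions_of(config), function(cond) {
    wc <- config$condition_weights[[cond]]
    vals <- lapply(names(genome$chromsizes), function(chrom) {
      nb <- ceiling(genome$chromsizes[[chrom]] / res)
      v <- numeric(nb)
      sel <- which(g$chrom == chrom)
      for (i in sel) {
        b0 <- g$start[i] %/% res + 1L
        b1 <- (g$end[i] - 1L) %/% res + 1L
        v[b0:b1] <- v[b0:b1] + act_value[i] * wc
      }
      v
    })
    names(vals) <- names(genome$chromsizes)
    signal_track(vals, res, genome$chromsizes)
  })
  names(tracks) <- conditions_of(config)

  # expression: shared latent factor per connected PPI component
  comp <- ppi_components(g$gene_id, genome$truth$ppi_pairs)
  conds <- conditions_of(config)
  reps <- seq_len(config$n_replicates)
  n_samp <- length(conds) * length(reps)
  f <- matrix(rnorm(max(comp) * n_samp), nrow = max(comp))
  eps <- matrix(rnorm(n * n_samp), nrow = n)
  connected <- g$gene_id %in% unique(unlist(genome$truth$ppi_pairs))
  x <- matrix(0, n, n_samp)
  sr <- sqrt(config$rho)
  x[connected, ] <- sr * f[comp[connected], , drop = FALSE] +
    sqrt(1 - config$rho) * eps[connected, , drop = FALSE]
  x[!connected, ] <- eps[!connected, , drop = FALSE]
  x <- x + rnorm(n, 8, 1)  # per-gene baseline
  grid <- expand.grid(replicate = reps, condition = conds,
                      stringsAsFactors = FALSE)
  expr <- rbindlist(lapply(seq_len(n_samp), function(j)
    data.table(gene_id = g$gene_id, condition = grid$condition[j],
               replicate = grid$replicate[j], value = x[, j])))
  list(tracks = tracks, expression = expression_table(expr),
       activity = data.table(gene_id = g$gene_id, value = act_value))
}

# connected components over gene ids; returns component index per gene
ppi_components <- function(gene_ids, ppi_pairs) {
  idx <- seq_along(gene_ids)
  names(idx) <- gene_ids
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(ppi_pairs)) {
    for (r in seq_len(nrow(ppi_pairs))) {
      a <- find(idx[[ppi_pairs$geneA[r]]])
      b <- find(idx[[ppi_pairs$geneB[r]]])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(idx, find, integer(1))
  match(roots, unique(roots))
}

#' Simulate bridge-linker reads from contact pairs
#'
#' Each non-decoy read is `flank1 + linker + flank2` with flank lengths
#' drawn uniform on 50-200 bp (DNaseI-fragment scale) and random base
#' content; the true pair coordinates are encoded in the read name as
#' `pair<i>|chrom1:pos1|chrom2:pos2`. A `decoy_fraction` of reads is
#' replaced by linker-free random sequence (invalid contacts).
#'
#' @param pairs canonical contact pair table.
#' @param config a [sim_config()]; uses `linker`, `read_len`,
#'   `decoy_fraction` and `seed`.
#' @return `data.table` with `name`, `seq` and `is_decoy`.
#' @export
simulate_linker_reads <- function(pairs, config) {
  linker <- config$linker
  if (config$read_len < nchar(linker))
    stop("read_len shorter than linker", call. = FALSE)
  if (!nchar(linker)) stop("empty linker", call. = FALSE)
  set.seed(derive_seed(config$seed, "reads"))
  n <- nrow(pairs)
  rand_seq <- function(len) {
    vapply(len, function(l)
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
      character(1))
  }
  f1 <- floor(runif(n, 50, 201))
  f2 <- floor(runif(n, 50, 201))
  over <- f1 + f2 + nchar(linker) - config$read_len
  f2 <- as.integer(f2 - pmax(over, 0))
  decoy <- runif(n) < config$decoy_fraction
  seqs <- character(n)
  seqs[!decoy] <- paste0(rand_seq(f1[!decoy]), linker, rand_seq(f2[!decoy]))
  if (any(decoy)) {
    d <- rand_seq(f1[decoy] + f2[decoy] + nchar(linker))
    while (any(grepl(linker, d, fixed = TRUE)))
      d[grepl(linker, d, fixed = TRUE)] <-
        rand_seq(nchar(d[grepl(linker, d, fixed = TRUE)]))
    seqs[decoy] <- d
  }
  name <- ifelse(decoy, sprintf("decoy%d", seq_len(n)),
                 sprintf("pair%d|%s:%d|%s:%d", seq_len(n), pairs$chrom1,
                         pairs$pos1, pairs$chrom2, pairs$pos2))
  data.table(name = name, seq = seqs, is_decoy = decoy)
}

#' Parse true pair coordinates back out of simulated read names
#'
#' @param names read names from [simulate_linker_reads()].
#' @return `data.table` with `chrom1, pos1, chrom2, pos2` (decoys dropped).
#' @export
parse_read_names <- function(names) {
  keep <- startsWith(names, "pair")
  parts <- strsplit(names[keep], "|", fixed = TRUE)
  loc <- function(x) {
    s <- strsplit(x, ":", fixed = TRUE)
    list(chrom = vapply(s, `[[`, character(1), 1),
         pos = as.integer(vapply(s, `[[`, character(1), 2)))
  }
  l1 <- loc(vapply(parts, `[[`, character(1), 2))
  l2 <- loc(vapply(parts, `[[`, character(1), 3))
  data.table(chrom1 = l1$chrom, pos1 = l1$pos,
             chrom2 = l2$chrom, pos2 = l2$pos)
}

#' Write / read simulated reads as FASTQ
#'
#' @param reads table from [simulate_linker_reads()].
#' @param path FASTQ file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$name
  q <- Biostrings::BStringSet(vapply(nchar(reads$seq), function(l)
    paste(rep("I", l), collapse = ""), character(1)))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(
      x, Biostrings::PhredQuality(q)), path)
  invisible(path)
}

#' @rdname write_fastq
#' @return for `read_fastq`, `data.table` with `name` and `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.table(name = names(x), seq = as.character(x))
}
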