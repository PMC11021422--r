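#' Build the primed promoter-promoter interaction network
#'
#' Collapses classified primed P-P contacts to one edge per unique gene
#' pair (lexicographic order), counting supporting loops, and tabulates
#' node degrees.
#'
#' @param classified [classify_contacts()] rows (P-P rows are used; others
#'   ignored).
#' @param annotation a [gene_annotation()] supplying node coordinates.
#' @param conditions character vector of condition names the contacts were
#'   intersected over (stored per edge).
#' @return a `ppi_network`: list with `edges` (`geneA, geneB, class_kind,
#'   orientation, n_conditions, conditions, support`), `nodes`
#'   (`gene_id, chrom, tss, degree`).
#' @export
build_ppi_network <- function(classified, annotation,
                              conditions = character(0)) {
  pp <- as.data.table(classified)[kind %in% c("PP_cis", "PP_trans")]
  if (nrow(pp)) {
    edges <- pp[, .(support = .N, class_kind = kind[1],
                    orientation = orientation[1]),
                by = .(geneA = pmin(geneA, geneB),
                       geneB = pmax(geneA, geneB))]
  } else {
    edges <- data.table(geneA = character(), geneB = character(),
                        support = integer(), class_kind = character(),
                        orientation = character())
  }
  edges[, `:=`(n_conditions = length(conditions),
               conditions = replicate(.N, conditions, simplify = FALSE))]
  setorder(edges, geneA, geneB)
  tsst <- tss_table(annotation)
  deg <- rbind(edges[, .(gene_id = geneA)], edges[, .(gene_id = geneB)])
  degtab <- deg[, .(degree = .N), by = gene_id]
  nodes <- tsst[gene_id %in% c(edges$geneA, edges$geneB)]
  nodes <- degtab[nodes, on = "gene_id"]
  setorder(nodes, -degree, gene_id)
  structure(list(edges = edges[, .(geneA, geneB, class_kind, orientation,
                                   n_conditions, conditions, support)],
                 nodes = nodes[, .(gene_id, chrom, tss, degree)]),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", nrow(x$nodes), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Detect network hotspots
#'
#' Hotspots are promoters whose PPI degree exceeds either the given degree
#' percentile of the network's degree distribution (default 99.9) or an
#' absolute degree cutoff.
#'
#' @param network a [build_ppi_network()] result.
#' @param threshold percentile in (0, 100) of the degree distribution.
#' @param min_degree optional absolute cutoff; when given, the percentile
#'   rule is ignored.
#' @return `data.table` of hotspot genes (`gene_id, chrom, tss, degree`),
#'   degree-descending; empty when no node exceeds the rule.
#' @export
detect_hotspots <- function(network, threshold = 99.9, min_degree = NULL) {
  nodes <- network$nodes
  if (!nrow(nodes)) return(nodes)
  cut <- if (!is.null(min_degree)) min_degree else
    as.numeric(quantile(nodes$degree, threshold / 100, type = 1))
  hot <- nodes[degree > cut]
  if (!is.null(min_degree)) hot <- nodes[degree >= min_degree]
  setorder(hot, -degree, gene_id)
  hot[]
}

#' Degree table export
#'
#' @param network a [build_ppi_network()] result.
#' @param path output TSV.
#' @export
write_degree_table <- function(network, path) {
  fwrite(network$nodes, path, sep = "\t")
  invisible(path)
}

#' Contact enrichment over site intervals
#'
#' Mean contact-end density per offset around site centers, against a
#' background obtained by placing the same-length sites uniformly at
#' random on their own chromosome (`n_shuffles` draws, seeded).
#'
#' @param pairs canonical contact pair table (contact evidence; both ends
#'   of each pair contribute).
#' @param sites `data.table` with `chrom, start, end` site intervals.
#' @param chromsizes a [chrom_sizes()].
#' @param window half-window in bp around site centers.
#' @param bin_width profile bin width in bp.
#' @param n_shuffles background draws (default 100).
#' @param seed seed for the shuffle null.
#' @return `data.table` with `offset, density, background`; profile length
#'   is `2 * window / bin_width + 1`.
#' @export
signal_over_sites <- function(pairs, sites, chromsizes, window = 2000L,
                              bin_width = 200L, n_shuffles = 100L,
                              seed = 1L) {
  sites <- as.data.table(sites)
  if (!nrow(sites)) stop("no sites", call. = FALSE)
  ends <- rbind(pairs[, .(chrom = chrom1, pos = pos1)],
                pairs[, .(chrom = chrom2, pos = pos2)])
  n_bins <- 2L * as.integer(window %/% bin_width) + 1L
  half <- (n_bins - 1L) %/% 2L
  offsets <- (seq_len(n_bins) - 1L - half) * bin_width
  # pre-binned contact-end coverage per chromosome
  cov <- lapply(names(chromsizes), function(ci) {
    nb <- ceiling(chromsizes[[ci]] / bin_width)
    e <- ends[chrom == ci]
    if (!nrow(e)) return(numeric(nb))
    tabulate(e$pos %/% bin_width + 1L, nbins = nb)
  })
  names(cov) <- names(chromsizes)
  profile_of <- function(centers, chroms) {
    acc <- numeric(n_bins)
    cb <- centers %/% bin_width + 1L
    for (i in seq_along(centers)) {
      v <- cov[[chroms[i]]]
      idx <- cb[i] + (-half:half)
      ok <- idx >= 1L & idx <= length(v)
      acc[ok] <- acc[ok] + v[idx[ok]]
    }
    acc / length(centers)
  }
  centers <- as.integer((sites$start + sites$end) / 2)
  obs <- profile_of(centers, sites$chrom)
  set.seed(seed)
  widths <- sites$end - sites$start
  bg <- matrix(0, n_shuffles, n_bins)
  for (r in seq_len(n_shuffles)) {
    L <- as.numeric(chromsizes[chrom_index(sites$chrom, chromsizes)])
    rc <- as.integer(floor(runif(nrow(sites), window,
                                 L - widths - window)) + widths %/% 2L)
    bg[r, ] <- profile_of(rc, sites$chrom)
  }
  data.table(offset = offsets, density = obs,
             background = colMeans(bg))
}
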