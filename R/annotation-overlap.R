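#' Annotate loop anchors with genomic features
#'
#' Reports every promoter, enhancer and gene-body overlap of each anchor
#' interval and assigns one primary label with precedence
#' promoter > enhancer > gene body > intergenic. Promoter windows are
#' strand-aware ([promoter_windows()]).
#'
#' @param anchors `data.table` with `chrom, start, end` (0-based half-open
#'   anchor intervals, e.g. loop-call bins).
#' @param annotation a [gene_annotation()].
#' @param enhancers `data.table` with `enhancer_id, chrom, start, end`.
#' @param chromsizes a [chrom_sizes()]; anchors must lie inside.
#' @param promoter_upstream,promoter_downstream promoter window (bp around
#'   the TSS, strand-aware).
#' @return `data.table`: one row per anchor with list-columns
#'   `promoter_genes`, `enhancer_ids`, `body_genes` and `label`.
#' @export
annotate_anchors <- function(anchors, annotation, enhancers, chromsizes,
                             promoter_upstream = 500L,
                             promoter_downstream = 100L) {
  anchors <- as.data.table(anchors)
  i <- chrom_index(anchors$chrom, chromsizes)
  if (any(anchors$start < 0 | anchors$end > chromsizes[i]))
    stop("anchor outside genome", call. = FALSE)
  prom <- promoter_windows(annotation, promoter_upstream,
                           promoter_downstream, chromsizes)
  sinfo <- GenomeInfoDb::Seqinfo(names(chromsizes),
                                 as.integer(chromsizes))
  gr_anchor <- GenomicRanges::GRanges(
    anchors$chrom, IRanges::IRanges(anchors$start + 1L, anchors$end),
    seqinfo = sinfo)
  ov_ids <- function(feat_chrom, feat_start, feat_end, feat_id) {
    if (!length(feat_chrom))
      return(replicate(nrow(anchors), character(0), simplify = FALSE))
    gr_feat <- GenomicRanges::GRanges(
      feat_chrom, IRanges::IRanges(feat_start + 1L, feat_end),
      seqinfo = sinfo)
    hits <- GenomicRanges::findOverlaps(gr_anchor, gr_feat,
                                        ignore.strand = TRUE)
    out <- replicate(nrow(anchors), character(0), simplify = FALSE)
    if (length(hits)) {
      sp <- split(feat_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
      out[as.integer(names(sp))] <- lapply(sp, unique)
    }
    out
  }
  g <- annotation$genes
  promoter_genes <- ov_ids(prom$chrom, prom$start, prom$end, prom$gene_id)
  enhancer_ids <- ov_ids(enhancers$chrom, enhancers$start, enhancers$end,
                         enhancers$enhancer_id)
  body_genes <- ov_ids(g$chrom, g$start, g$end, g$gene_id)
  label <- fifelse(lengths(promoter_genes) > 0, "promoter",
                   fifelse(lengths(enhancer_ids) > 0, "enhancer",
                           fifelse(lengths(body_genes) > 0, "gene_body",
                                   "intergenic")))
  out <- copy(anchors)
  out[, `:=`(promoter_genes = promoter_genes, enhancer_ids = enhancer_ids,
             body_genes = body_genes, label = label)]
  out[]
}

#' Classify an enhancer-promoter contact
#'
#' `range` is proximal when the anchor midpoints are separated by at most
#' `proximal_max_bp`, else distal; `side` says whether the enhancer lies
#' upstream or downstream of the interacting promoter's TSS in
#' transcription direction (strand-aware).
#'
#' @param enhancer_mid,promoter_tss anchor midpoint and TSS positions (bp,
#'   same chromosome).
#' @param promoter_strand `+` or `-`.
#' @param proximal_max_bp proximal/distal cutoff (default 2000 bp).
#' @return list with `kind = "EP"`, `range` and `side`.
#' @export
classify_ep <- function(enhancer_mid, promoter_tss, promoter_strand,
                        proximal_max_bp = 2000L) {
  sep <- abs(enhancer_mid - promoter_tss)
  delta <- enhancer_mid - promoter_tss
  upstream <- (promoter_strand == "+" & delta < 0) |
    (promoter_strand == "-" & delta > 0)
  list(kind = "EP",
       range = ifelse(sep <= proximal_max_bp, "proximal", "distal"),
       side = ifelse(upstream, "upstream", "downstream"))
}

#' Classify a promoter-promoter contact
#'
#' Trans when the genes sit on different chromosomes. For cis pairs, with A
#' the left (smaller TSS) gene: `(+,+)` and `(-,-)` are tandem, `(-,+)`
#' divergent (transcription pointing apart), `(+,-)` convergent (pointing
#' together). Invariant to the order the two genes are supplied in.
#'
#' @param chromA,tssA,strandA,chromB,tssB,strandB gene coordinates
#'   (vectorized).
#' @param geneA,geneB gene ids (used only to reject self-loops).
#' @return `data.table` with `kind` (`PP_cis`/`PP_trans`) and `orientation`
#'   (`tandem`/`divergent`/`convergent`, NA for trans).
#' @export
classify_ppi <- function(chromA, tssA, strandA, chromB, tssB, strandB,
                         geneA = NULL, geneB = NULL) {
  if (!is.null(geneA) && any(geneA == geneB))
    stop("self-loop: both anchors map to the same gene", call. = FALSE)
  trans <- chromA != chromB
  swap <- !trans & tssB < tssA
  ls <- fifelse(swap, strandB, strandA)  # left gene strand
  rs <- fifelse(swap, strandA, strandB)
  orientation <- fifelse(trans, NA_character_,
                         fifelse(ls == rs, "tandem",
                                 fifelse(ls == "-", "divergent",
                                         "convergent")))
  data.table(kind = fifelse(trans, "PP_trans", "PP_cis"),
             orientation = orientation)
}

#' Classify called loops against annotated anchors
#'
#' Pairs each loop's two annotated anchors and produces one classified
#' contact per gene/feature combination: `PP_cis`/`PP_trans` (with
#' orientation) for promoter-promoter, `EP` (with range and side) for
#' enhancer-promoter, `other` otherwise. Anchors hitting several promoters
#' yield one row per gene pair (deduplicated).
#'
#' @param loops `data.table` with `chrom1, bin1, chrom2, bin2` (or
#'   `start1/start2`) as produced by [call_stable_contacts()].
#' @param annotation a [gene_annotation()].
#' @param enhancers enhancer table (`enhancer_id, chrom, start, end`).
#' @param chromsizes a [chrom_sizes()].
#' @param resolution bin width used to expand bins to intervals.
#' @param proximal_max_bp cutoff for [classify_ep()].
#' @param promoter_upstream,promoter_downstream promoter window (bp).
#' @return `data.table` of classified contacts with columns `chrom1, mid1,
#'   chrom2, mid2, kind, orientation, range, side, geneA, geneB,
#'   enhancer_id`.
#' @export
classify_contacts <- function(loops, annotation, enhancers, chromsizes,
                              resolution = 200L, proximal_max_bp = 2000L,
                              promoter_upstream = 500L,
                              promoter_downstream = 100L) {
  loops <- as.data.table(loops)
  if (!nrow(loops))
    return(data.table(chrom1 = character(), mid1 = integer(),
                      chrom2 = character(), mid2 = integer(),
                      kind = character(), orientation = character(),
                      range = character(), side = character(),
                      geneA = character(), geneB = character(),
                      enhancer_id = character()))
  if (!"start1" %in% names(loops))
    loops[, `:=`(start1 = bin1 * resolution, end1 = (bin1 + 1L) * resolution,
                 start2 = bin2 * resolution, end2 = (bin2 + 1L) * resolution)]
  a1 <- annotate_anchors(loops[, .(chrom = chrom1, start = start1,
                                   end = end1)],
                         annotation, enhancers, chromsizes,
                         promoter_upstream, promoter_downstream)
  a2 <- annotate_anchors(loops[, .(chrom = chrom2, start = start2,
                                   end = end2)],
                         annotation, enhancers, chromsizes,
                         promoter_upstream, promoter_downstream)
  tsst <- tss_table(annotation)
  rows <- lapply(seq_len(nrow(loops)), function(i) {
    l1 <- a1$label[i]; l2 <- a2$label[i]
    mid1 <- as.integer((a1$start[i] + a1$end[i]) / 2)
    mid2 <- as.integer((a2$start[i] + a2$end[i]) / 2)
    base <- data.table(chrom1 = a1$chrom[i], mid1 = mid1,
                       chrom2 = a2$chrom[i], mid2 = mid2,
                       kind = "other", orientation = NA_character_,
                       range = NA_character_, side = NA_character_,
                       geneA = NA_character_, geneB = NA_character_,
                       enhancer_id = NA_character_)
    if (l1 == "promoter" && l2 == "promoter") {
      combos <- CJ(gA = a1$promoter_genes[[i]], gB = a2$promoter_genes[[i]])
      combos <- combos[gA != gB]
      if (!nrow(combos)) return(base)
      tA <- tsst[match(combos$gA, gene_id)]
      tB <- tsst[match(combos$gB, gene_id)]
      cl <- classify_ppi(tA$chrom, tA$tss, tA$strand,
                         tB$chrom, tB$tss, tB$strand)
      out <- base[rep(1L, nrow(combos))]
      out[, `:=`(kind = cl$kind, orientation = cl$orientation,
                 geneA = pmin(combos$gA, combos$gB),
                 geneB = pmax(combos$gA, combos$gB))]
      return(unique(out))
    }
    ep <- NULL
    if (l1 == "enhancer" && l2 == "promoter")
      ep <- list(emid = mid1, eids = a1$enhancer_ids[[i]],
                 genes = a2$promoter_genes[[i]])
    if (l1 == "promoter" && l2 == "enhancer")
      ep <- list(emid = mid2, eids = a2$enhancer_ids[[i]],
                 genes = a1$promoter_genes[[i]])
    if (!is.null(ep)) {
      combos <- CJ(eid = ep$eids, g = ep$genes)
      if (!nrow(combos)) return(base)
      tG <- tsst[match(combos$g, gene_id)]
      cl <- classify_ep(ep$emid, tG$tss, tG$strand, proximal_max_bp)
      out <- base[rep(1L, nrow(combos))]
      out[, `:=`(kind = "EP", range = cl$range, side = cl$side,
                 geneA = combos$g, enhancer_id = combos$eid)]
      return(unique(out))
    }
    base
  })
  rbindlist(rows)
}

#' Fraction table over contact classes
#'
#' Fractions within each classification family: cis/trans over P-P
#' contacts, tandem/divergent/convergent over cis P-P, proximal/distal over
#' E-P, upstream/downstream over E-P (per range). Fractions within a family
#' sum to 1.
#'
#' @param classified result of [classify_contacts()].
#' @return `data.table` with `family, level, n, fraction` (empty input
#'   gives an empty table).
#' @export
classification_summary <- function(classified) {
  out <- list()
  frac <- function(family, x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NULL)
    t <- table(x)
    data.table(family = family, level = names(t), n = as.integer(t),
               fraction = as.numeric(t) / length(x))
  }
  pp <- classified[kind %in% c("PP_cis", "PP_trans")]
  out$cis_trans <- frac("pp_cis_trans",
                        fifelse(pp$kind == "PP_cis", "cis", "trans"))
  out$orient <- frac("pp_orientation",
                     classified[kind == "PP_cis"]$orientation)
  ep <- classified[kind == "EP"]
  out$range <- frac("ep_range", ep$range)
  if (nrow(ep)) {
    out$side_prox <- frac("ep_side_proximal", ep[range == "proximal"]$side)
    out$side_dist <- frac("ep_side_distal", ep[range == "distal"]$side)
  }
  res <- rbindlist(out[!vapply(out, is.null, logical(1))])
  if (is.null(res) || !nrow(res))
    return(data.table(family = character(), level = character(),
                      n = integer(), fraction = numeric()))
  res
}
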