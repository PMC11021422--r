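#' Gene annotation tables
#'
#' A gene annotation holds two `data.table`s in 0-based half-open
#' coordinates: `genes` (`gene_id, chrom, start, end, strand`) and `exons`
#' (`gene_id, start, end, exon_rank` with exons in genomic order,
#' non-overlapping within a gene). The TSS of a `+` gene is `start`, of a `-`
#' gene `end - 1`.
#'
#' @param genes,exons data.frames as described above.
#' @return a `gene_annotation` object.
#' @export
gene_annotation <- function(genes, exons) {
  genes <- as.data.table(genes)[, .(gene_id = as.character(gene_id),
                                    chrom = as.character(chrom),
                                    start = as.integer(start),
                                    end = as.integer(end),
                                    strand = as.character(strand))]
  exons <- as.data.table(exons)[, .(gene_id = as.character(gene_id),
                                    start = as.integer(start),
                                    end = as.integer(end))]
  stopifnot(all(genes$end > genes$start), all(genes$strand %in% c("+", "-")),
            !anyDuplicated(genes$gene_id))
  setorder(exons, gene_id, start)
  exons[, exon_rank := seq_len(.N), by = gene_id]
  chk <- exons[genes, on = "gene_id"]
  if (nrow(chk) && any(chk$start < chk$i.start | chk$end > chk$i.end,
                       na.rm = TRUE))
    stop("exon outside its gene body", call. = FALSE)
  structure(list(genes = genes[], exons = exons[]), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat("gene_annotation:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Transcription start sites
#'
#' @param annotation a [gene_annotation()].
#' @return `data.table` with `gene_id, chrom, tss, strand` (0-based bp).
#' @export
tss_table <- function(annotation) {
  g <- annotation$genes
  data.table(gene_id = g$gene_id, chrom = g$chrom,
             tss = fifelse(g$strand == "+", g$start, g$end - 1L),
             strand = g$strand)
}

#' Strand-aware promoter windows
#'
#' Default window: `upstream` bp upstream through `downstream` bp downstream
#' of the TSS (both strand-aware), clipped to the chromosome.
#'
#' @inheritParams tss_table
#' @param upstream,downstream window extent in bp around the TSS.
#' @param chromsizes a [chrom_sizes()] used for clipping.
#' @return `data.table` with `gene_id, chrom, start, end, strand, tss`
#'   (0-based half-open).
#' @export
promoter_windows <- function(annotation, upstream = 500L, downstream = 100L,
                             chromsizes) {
  t <- tss_table(annotation)
  start <- fifelse(t$strand == "+", t$tss - upstream, t$tss - downstream + 1L)
  end <- fifelse(t$strand == "+", t$tss + downstream + 1L, t$tss + upstream + 1L)
  L <- as.integer(chromsizes[chrom_index(t$chrom, chromsizes)])
  t[, `:=`(start = pmax(as.integer(start), 0L),
           end = pmin(as.integer(end), L))]
  t[, .(gene_id, chrom, start, end, strand, tss)]
}

#' First (and later) 5' splice sites
#'
#' The 5' splice site of an intron is reported as the genomic coordinate of
#' the first intron base in transcription direction. `first_only` keeps each
#' gene's first 5'SS (the junction closest to the TSS). Single-exon genes
#' yield no sites.
#'
#' @inheritParams tss_table
#' @param first_only keep only each gene's first 5'SS.
#' @return `data.table` with `gene_id, chrom, pos, strand, intron_rank`.
#' @export
splice_sites_5p <- function(annotation, first_only = TRUE) {
  ex <- annotation$exons[annotation$genes, on = "gene_id",
                         nomatch = NULL][, .(gene_id, start, end, exon_rank,
                                             chrom, strand)]
  n_ex <- ex[, .N, by = gene_id]
  ex <- ex[gene_id %in% n_ex[N >= 2L]$gene_id]
  if (!nrow(ex))
    return(data.table(gene_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      intron_rank = integer()))
  plus <- ex[strand == "+"][, {
    if (.N >= 2L) list(pos = end[-.N], intron_rank = seq_len(.N - 1L),
                       chrom = chrom[1], strand = "+") else NULL
  }, by = gene_id]
  minus <- ex[strand == "-"][, {
    if (.N >= 2L) list(pos = rev(start[-1L]) - 1L,
                       intron_rank = seq_len(.N - 1L),
                       chrom = chrom[1], strand = "-") else NULL
  }, by = gene_id]
  out <- rbindlist(list(plus, minus), use.names = TRUE, fill = TRUE)
  if (!nrow(out))
    return(data.table(gene_id = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      intron_rank = integer()))
  if (first_only) out <- out[intron_rank == 1L]
  out[, .(gene_id, chrom, pos = as.integer(pos), strand, intron_rank)]
}

as_granges_genes <- function(annotation) {
  g <- annotation$genes
  GenomicRanges::GRanges(g$chrom,
                         IRanges::IRanges(g$start + 1L, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}

#' Read gene models from GFF3 or BED12
#'
#' GFF3 `gene`/`exon` (optionally via `mRNA`) features or BED12 blocks are
#' converted to 0-based half-open gene models. A gene without exon records
#' becomes a single-exon model spanning the gene body (with a warning).
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED12 (`.bed`) file.
#' @return a [gene_annotation()].
#' @export
read_annotation <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE))
    read_annotation_bed12(path) else read_annotation_gff3(path)
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  type <- as.character(m$type)
  ids <- if ("ID" %in% names(m)) as.character(m$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(m))
    vapply(m$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))
  gi <- which(type == "gene")
  if (!length(gi)) stop("no gene features in ", path, call. = FALSE)
  genes <- data.table(
    gene_id = ids[gi],
    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
    start = GenomicRanges::start(gr)[gi] - 1L,
    end = GenomicRanges::end(gr)[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi])
  # map any feature id to its gene id (follow one mRNA level)
  to_gene <- setNames(ids[gi], ids[gi])
  ti <- which(type %in% c("mRNA", "transcript"))
  if (length(ti)) to_gene[ids[ti]] <- to_gene[parent[ti]]
  ei <- which(type == "exon")
  exons <- data.table(
    gene_id = unname(to_gene[parent[ei]]),
    start = GenomicRanges::start(gr)[ei] - 1L,
    end = GenomicRanges::end(gr)[ei])
  exons <- exons[!is.na(gene_id)]
  missing <- setdiff(genes$gene_id, exons$gene_id)
  if (length(missing)) {
    warning(length(missing),
            " gene(s) without exons; using single-exon models")
    exons <- rbind(exons, genes[gene_id %in% missing,
                                .(gene_id, start, end)])
  }
  gene_annotation(genes, exons)
}

read_annotation_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  m <- S4Vectors::mcols(gr)
  genes <- data.table(
    gene_id = as.character(m$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)))
  if (!is.null(m$blocks)) {
    bl <- m$blocks
    exons <- rbindlist(lapply(seq_along(gr), function(i) {
      b <- bl[[i]]  # 1-based, relative to feature start
      data.table(gene_id = genes$gene_id[i],
                 start = genes$start[i] + IRanges::start(b) - 1L,
                 end = genes$start[i] + IRanges::end(b))
    }))
  } else {
    warning("BED file without blocks; using single-exon models")
    exons <- genes[, .(gene_id, start, end)]
  }
  gene_annotation(genes, exons)
}

#' Write a gene annotation as GFF3
#'
#' @inheritParams tss_table
#' @param path output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  gene_gr <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Parent = NA_character_)
  exon_gr <- GenomicRanges::GRanges(
    g$chrom[match(e$gene_id, g$gene_id)],
    IRanges::IRanges(e$start + 1L, e$end),
    strand = g$strand[match(e$gene_id, g$gene_id)],
    type = "exon", ID = paste0(e$gene_id, ".exon", e$exon_rank),
    Parent = e$gene_id)
  all_gr <- c(gene_gr, exon_gr)
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}
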