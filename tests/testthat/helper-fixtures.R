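library(data.table)

# tiny two-chromosome genome used across IO tests
tiny_chromsizes <- function() chrom_sizes(c("chr1", "chr2"), c(5e6, 3e6))

# hand-built annotation: two genes on chr1 (one per strand), one on chr2
tiny_annotation <- function() {
  genes <- data.table(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 8000L, 2000L),
    end = c(4000L, 11000L, 5000L),
    strand = c("+", "-", "+"))
  exons <- data.table(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    start = c(1000L, 2500L, 8000L, 9500L, 2000L),
    end = c(2000L, 4000L, 9000L, 11000L, 5000L))
  gene_annotation(genes, exons)
}

# small memoised synthetic genome for medium tests
small_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 71, n_chroms = 2, chrom_length = 3e5,
                        n_genes = 120, n_background_pairs = 1e5,
                        n_loops = 30, n_enhancers = 15, n_hotspots = 0)
      cache <<- generate_genome(cfg)
    }
    cache
  }
})

# minimal annotation covering whatever gene ids an edge table mentions
tiny_annotation_for <- function(cls) {
  ids <- sort(unique(c(cls$geneA, cls$geneB)))
  genes <- data.table(gene_id = ids, chrom = "chr1",
                      start = seq_along(ids) * 10000L,
                      end = seq_along(ids) * 10000L + 2000L, strand = "+")
  gene_annotation(genes, genes[, .(gene_id, start, end)])
}

write_lines <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
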