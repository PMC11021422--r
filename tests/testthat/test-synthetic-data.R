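test_that("fixed seed gives byte-identical genomes and contacts", {
  cfg <- sim_config(seed = 3, n_chroms = 2, chrom_length = 2e5,
                    n_genes = 60, n_background_pairs = 2e4, n_loops = 10,
                    n_enhancers = 8)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$annotation, g2$annotation)
  expect_identical(g1$truth$loops, g2$truth$loops)
  p1 <- simulate_contacts(g1, "22C")
  p2 <- simulate_contacts(g2, "22C")
  expect_identical(p1, p2)
  # and stays deterministic through file round-trip
  f <- tempfile(); write_pairs(p1, f)
  expect_identical(read_pairs(f, g1$chromsizes), p1)
})

test_that("genome construction honors gene quotas and bounds", {
  cfg <- sim_config(seed = 4, n_chroms = 2, chrom_length = 3e5,
                    n_genes = 100, multiexon_fraction = 0.8,
                    n_background_pairs = 1e3, n_loops = 5, n_enhancers = 5)
  g <- generate_genome(cfg)
  genes <- g$annotation$genes
  expect_equal(nrow(genes), 100L)
  # non-overlapping within a chromosome
  for (ci in unique(genes$chrom)) {
    gc <- genes[chrom == ci][order(start)]
    expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  # multi-exon quota gives first-5'SS anchors for at least 80 genes
  expect_gte(nrow(splice_sites_5p(g$annotation)), 80L)
  # planted anchors inside the genome
  expect_true(all(g$truth$loops$pos2 < g$chromsizes[g$truth$loops$chrom]))
  # genome too small for the requested genes
  expect_error(generate_genome(
    sim_config(seed = 1, n_chroms = 1, chrom_length = 5e4, n_genes = 100)),
    "too small")
})

test_that("background distances follow the configured power law", {
  cfg <- sim_config(seed = 9, n_chroms = 1, chrom_length = 6e5,
                    n_genes = 50, n_background_pairs = 2e5, n_loops = 0,
                    fivess_rate = 0, trans_fraction = 0, n_enhancers = 0,
                    n_hotspots = 0, duplicate_fraction = 0)
  g <- generate_genome(cfg)
  p <- simulate_contacts(g, "22C")
  dc <- decay_curve(p, d_max = 6e5)
  expect_lt(abs(attr(dc, "alpha") - 1.0), 0.1)
  # doubling the table leaves the depth-normalized curve unchanged
  dc2 <- decay_curve(rbind(p, p), d_max = 6e5)
  expect_equal(dc2$density, dc$density)
})

test_that("condition weights scale the pausing-window contacts", {
  g <- small_genome()
  p22 <- simulate_contacts(g, "22C")
  p3 <- simulate_contacts(g, "cold3h")
  ss <- splice_sites_5p(g$annotation)
  count_window <- function(p) {
    ends <- rbind(p[, .(chrom = chrom1, pos = pos1)],
                  p[, .(chrom = chrom2, pos = pos2)])
    n <- 0L
    for (i in seq_len(nrow(ss))) {
      w <- if (ss$strand[i] == "+") c(ss$pos[i], ss$pos[i] + 50L) else
        c(ss$pos[i] - 50L, ss$pos[i])
      n <- n + ends[chrom == ss$chrom[i] & pos >= w[1] & pos <= w[2], .N]
    }
    n
  }
  expect_gt(count_window(p22), 1.5 * count_window(p3))
  expect_error(simulate_contacts(g, "hot42"), "unknown condition")
})

test_that("expression carries the configured pair correlation", {
  cfg <- sim_config(seed = 21, n_chroms = 2, chrom_length = 3e5,
                    n_genes = 200, tight_pair_fraction = 0.5,
                    pp_loop_fraction = 1, n_loops = 50, n_hotspots = 0,
                    rho = 0.9, n_background_pairs = 1e3, n_enhancers = 0)
  g <- generate_genome(cfg)
  ax <- simulate_activity_and_expression(g)
  rs <- pair_expression_correlation(ax$expression, g$truth$ppi_pairs)
  expect_gte(nrow(rs), 50L)
  expect_lt(abs(mean(rs$r) - 0.9), 0.1)
  # rho = 0: connected pairs are as uncorrelated as anyone else
  cfg0 <- sim_config(seed = 22, n_chroms = 2, chrom_length = 3e5,
                     n_genes = 200, tight_pair_fraction = 0.5,
                     pp_loop_fraction = 1, n_loops = 50, n_hotspots = 0,
                     rho = 0, n_background_pairs = 1e3, n_enhancers = 0)
  g0 <- generate_genome(cfg0)
  ax0 <- simulate_activity_and_expression(g0)
  rs0 <- pair_expression_correlation(ax0$expression, g0$truth$ppi_pairs)
  expect_lt(abs(mean(rs0$r)), 0.15)
  expect_error(simulate_activity_and_expression(
    g0, modifyList(cfg0, list(rho = 1.2))), "rho")
})

test_that("activity coupling targets the configured rank correlation", {
  # zero coupling: activity is independent of the planted intensity
  cfg <- sim_config(seed = 31, n_chroms = 2, chrom_length = 6e5,
                    n_genes = 300, activity_coupling = 0,
                    n_background_pairs = 1e3, n_loops = 0, n_enhancers = 0,
                    n_hotspots = 0)
  g <- generate_genome(cfg)
  ax <- simulate_activity_and_expression(g)
  s <- spearman(g$truth$activity_factor$factor, ax$activity$value)
  expect_lt(abs(s$rho), 0.15)
})

test_that("linker reads embed recoverable pairs and binomial decoys", {
  g <- small_genome()
  p <- simulate_contacts(g, "22C")[1:1000]
  cfg <- g$config
  cfg$decoy_fraction <- 0.3
  reads <- simulate_linker_reads(p, cfg)
  n_decoy <- sum(reads$is_decoy)
  expect_lt(abs(n_decoy - 300), 60)  # ~4 sd of Binomial(1000, 0.3)
  has_linker <- grepl(cfg$linker, reads$seq, fixed = TRUE)
  expect_identical(has_linker, !reads$is_decoy)
  # exactly one occurrence in valid reads
  expect_true(all(lengths(gregexpr(cfg$linker, reads$seq[!reads$is_decoy],
                                   fixed = TRUE)) == 1L))
  # read names parse back to the emitting pairs
  got <- parse_read_names(reads$name)
  expect_equal(got, p[!reads$is_decoy, .(chrom1, pos1, chrom2, pos2)])
  # FASTQ round trip preserves names and sequences
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back$name, reads$name)
  expect_equal(back$seq, reads$seq)
  cfg$read_len <- 10
  expect_error(simulate_linker_reads(p, cfg), "linker")
})
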