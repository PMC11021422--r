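test_that("linker splitting honors presence, position and flank rules", {
  linker <- "GTCAGAAAGATATCGCGT"
  f1 <- "ACGTACGTACGTACGTACGT"
  f2 <- "TTTTCCCCTTTTCCCCTTTT"
  out <- split_linker_read(paste0(f1, linker, f2))
  expect_equal(out, list(flank1 = f1, flank2 = f2))
  expect_null(split_linker_read(paste0(f1, f2)))
  # flank shorter than the minimum
  expect_null(split_linker_read(paste0("ACGTA", linker, f2)))
  expect_error(split_linker_read("ACGT", linker_seq = ""), "empty")
  # one-mismatch tolerance behind its flag
  mm <- sub("GTCAGA", "GTCTGA", linker)
  expect_null(split_linker_read(paste0(f1, mm, f2)))
  expect_equal(split_linker_read(paste0(f1, mm, f2), max_mismatch = 1),
               list(flank1 = f1, flank2 = f2))
  # vectorized splitter agrees
  reads <- data.table(name = c("a", "b"),
                      seq = c(paste0(f1, linker, f2), paste0(f1, f2)))
  sp <- split_linker_reads(reads)
  expect_equal(sp$name, "a")
  expect_equal(sp$flank2, f2)
})

test_that("pair filtering applies MAPQ, self-ligation and duplicate rules", {
  cs <- tiny_chromsizes()
  p <- contact_pairs(
    chrom1 = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    pos1 = c(1000L, 1000L, 5000L, 5000L, 7000L),
    strand1 = c("+", "+", "-", "-", "+"),
    chrom2 = c("chr1", "chr1", "chr1", "chr1", "chr1"),
    pos2 = c(9000L, 9000L, 5150L, 5150L, 9000L),
    strand2 = c("+", "+", "+", "+", "-"),
    mapq1 = c(30L, 30L, 30L, 30L, 9L),
    mapq2 = c(30L, 30L, 30L, 60L, 30L), chromsizes = cs)
  out <- filter_pairs(p, mapq_min = 10, resolution = 200)
  # mapq 9/30 dropped; 150 bp separation dropped twice; exact dup collapsed
  expect_equal(out$report$mapq, 1L)
  expect_equal(out$report$min_distance, 2L)
  expect_equal(out$report$duplicates, 1L)
  expect_equal(out$report$n_output, 1L)
  expect_equal(out$report$n_input - out$report$n_output,
               out$report$mapq + out$report$min_distance +
                 out$report$duplicates)
  # strand-aware duplicates: same coordinates, different strands survive
  q <- contact_pairs("chr1", 100L, c("+", "-"), "chr1", 9000L, "+",
                     30L, 30L, chromsizes = cs)
  expect_equal(filter_pairs(q)$report$duplicates, 0L)
})

test_that("binning conserves pairs and is symmetric", {
  cs <- tiny_chromsizes()
  p <- contact_pairs("chr1", c(150L, 450L), "+", "chr1", c(450L, 150L),
                     "+", 30L, 30L, chromsizes = cs)
  m <- bin_contacts(p, 200, cs)
  expect_equal(m$counts$bin1, 0L)
  expect_equal(m$counts$bin2, 2L)
  expect_equal(m$counts$count, 2L)  # pre-canonical order maps to same pair
  expect_equal(m$N, 2L)
  expect_error(bin_contacts(p, 0, cs), "resolution")
  g <- small_genome()
  pr <- simulate_contacts(g, "22C")
  mm <- bin_contacts(pr, 200, g$chromsizes)
  expect_equal(sum(mm$counts$count), nrow(pr))
  expect_true(all(mm$counts[chrom1 == chrom2, bin1 <= bin2]))
})

test_that("VC normalization matches the hand-computed case and conserves mass", {
  cs <- chrom_sizes("chr1", 1000)
  # matrix [[0,2],[2,6]] over bins 0,1: row sums 2 and 8
  m <- structure(list(
    counts = data.table(chrom1 = "chr1", bin1 = c(0L, 1L), chrom2 = "chr1",
                        bin2 = c(1L, 1L), count = c(2L, 6L)),
    resolution = 200L, chromsizes = cs, N = 8L), class = "contact_matrix")
  vc <- vc_normalize(m)
  pre <- c(2 / (2 * 8), 6 / (8 * 8))       # before rescaling
  expect_equal(vc$counts$count / sum(vc$counts$count) * sum(pre), pre)
  expect_equal(sum(vc$counts$count), 8, tolerance = 1e-9)
  # uniform-coverage matrix is unchanged up to a global scale
  u <- structure(list(
    counts = data.table(chrom1 = "chr1", bin1 = c(0L, 1L, 0L),
                        chrom2 = "chr1", bin2 = c(1L, 2L, 2L),
                        count = c(3L, 3L, 3L)),
    resolution = 200L, chromsizes = cs, N = 9L), class = "contact_matrix")
  vu <- vc_normalize(u)
  expect_equal(vu$counts$count, u$counts$count)
  # uniform-coverage matrices are the fixed points: re-applying VC to one
  # changes nothing, and mass is conserved through repeated application
  expect_equal(vc_normalize(vu)$counts$count, vu$counts$count)
  expect_equal(sum(vc_normalize(vc)$counts$count), sum(vc$counts$count),
               tolerance = 1e-9)
  z <- structure(list(counts = m$counts[0], resolution = 200L,
                      chromsizes = cs, N = 0L), class = "contact_matrix")
  expect_warning(vc_normalize(z), "all-zero")
})

test_that("decay curve refuses degenerate input", {
  cs <- tiny_chromsizes()
  p <- contact_pairs("chr1", rep(1000L, 50), "+", "chr1", rep(51000L, 50),
                     "+", 30L, 30L, chromsizes = cs)
  expect_error(decay_curve(p), "3 occupied")
  trans <- contact_pairs("chr1", 1000L, "+", "chr2", 1000L, "+", 30L, 30L,
                         chromsizes = cs)
  expect_error(decay_curve(trans), "no intra")
})

test_that("replicate correlation behaves at its anchors", {
  cfg <- sim_config(seed = 81, n_chroms = 2, chrom_length = 1e5,
                    n_genes = 30, n_background_pairs = 4e5, n_loops = 0,
                    n_enhancers = 0, n_hotspots = 0)
  g <- generate_genome(cfg)
  p <- simulate_contacts(g, "22C")
  m <- bin_contacts(p, 2000, g$chromsizes)
  self <- replicate_correlation(m, m)
  expect_equal(self$overall, 1.0)
  # a second sampling draw of the same genome at deep per-bin coverage
  cfg2 <- cfg; cfg2$seed <- 82
  g2 <- g; g2$config <- cfg2
  m2 <- bin_contacts(simulate_contacts(g2, "22C"), 2000, g$chromsizes)
  rep_cor <- replicate_correlation(m, m2)
  expect_gt(rep_cor$overall, 0.9)
  # independent Poisson matrices over the same bins decorrelate
  cs <- chrom_sizes("chr1", 2e6)
  set.seed(1)
  rnd <- function() structure(list(
    counts = data.table(chrom1 = "chr1", bin1 = 0:2999,
                        chrom2 = "chr1", bin2 = 10000L,
                        count = rpois(3000, 5)),
    resolution = 200L, chromsizes = cs, N = 3000L),
    class = "contact_matrix")
  ra <- rnd(); rb <- rnd()
  expect_lt(abs(replicate_correlation(ra, rb)$overall), 0.1)
  # disjoint occupancy is undefined
  rc <- rnd(); rc$counts[, bin2 := 10001L]
  expect_error(replicate_correlation(ra, rc), "disjoint")
})
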