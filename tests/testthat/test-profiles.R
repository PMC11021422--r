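test_that("gene contact density applies the stated normalization", {
  cs <- tiny_chromsizes()
  genes <- data.table(gene_id = "g1", chrom = "chr1", start = 10000L,
                      end = 12000L, strand = "+")
  ann <- gene_annotation(genes, genes[, .(gene_id, start, end)])
  inside <- contact_pairs("chr1", sample(10000:11000, 10), "+",
                          "chr1", sample(11001:11999, 10), "+", 30L, 30L,
                          chromsizes = cs)
  outside <- contact_pairs("chr1", 500L, "+", "chr1", 11000L, "+", 30L, 30L,
                           chromsizes = cs)
  p <- rbind(inside, outside)
  d <- gene_contact_density(p, ann, library_total = 1e6)
  # 10 contacts fully inside a 2 kb gene at 1e6 library: 10 / 2 / 1 = 5
  expect_equal(d$density, 5)
  expect_equal(d$n_contacts, 10L)
  # doubling the library halves density
  d2 <- gene_contact_density(p, ann, library_total = 2e6)
  expect_equal(d2$density, 2.5)
  expect_error(gene_contact_density(p, ann, library_total = 0), "positive")
  # gene with no internal contacts reports 0
  ann0 <- gene_annotation(
    rbind(genes, data.table(gene_id = "g2", chrom = "chr2", start = 1000L,
                            end = 3000L, strand = "+")),
    rbind(genes[, .(gene_id, start, end)],
          data.table(gene_id = "g2", start = 1000L, end = 3000L)))
  expect_equal(gene_contact_density(p, ann0, 1e6)[gene_id == "g2"]$density, 0)
})

test_that("percentile stratification is deterministic and disjoint", {
  set.seed(2)
  v <- setNames(runif(100), sprintf("g%03d", 1:100))
  s <- stratify_by_percentile(v, 10)
  expect_equal(length(s$top), 10L)
  expect_equal(length(s$bottom), 10L)
  expect_length(intersect(s$top, s$bottom), 0L)
  expect_setequal(s$top, names(sort(v, decreasing = TRUE))[1:10])
  expect_error(stratify_by_percentile(v, 60), "pct")
  expect_warning(s2 <- stratify_by_percentile(setNames(rep(1, 10),
                                                       letters[1:10]), 20),
                 "equal")
  expect_equal(s2$top, c("a", "b"))  # tie-broken by gene id
})

test_that("metagene profiles separate planted groups and respect strand", {
  cs <- tiny_chromsizes()
  genes <- data.table(gene_id = c("hi", "lo", "neg"), chrom = "chr1",
                      start = c(10000L, 30000L, 50000L),
                      end = c(14000L, 34000L, 54000L),
                      strand = c("+", "+", "-"))
  ann <- gene_annotation(genes, genes[, .(gene_id, start, end)])
  set.seed(8)
  mk <- function(n, lo, hi) contact_pairs(
    "chr1", sample(lo:hi, n, TRUE), "+", "chr1", sample(lo:hi, n, TRUE),
    "+", 30L, 30L, chromsizes = cs)
  # heavy uniform coverage in "hi", light in "lo", TSS-proximal in "neg"
  # (minus strand: TSS at end - 1)
  p <- rbind(mk(400, 10000, 13999), mk(60, 30000, 33999),
             mk(120, 53200, 53999))
  prof <- metagene_profile(p, ann, groups = list(top = "hi", bottom = "lo"),
                           n_body_bins = 50, flank_bp = 500,
                           n_flank_bins = 5)
  top <- prof[group == "top" & region == "body"]$mean_density
  bot <- prof[group == "bottom" & region == "body"]$mean_density
  expect_true(all(top > bot))
  # minus-strand TSS-proximal signal lands at the profile start
  pn <- metagene_profile(p, ann, groups = list(g = "neg"), n_body_bins = 50,
                         flank_bp = 500, n_flank_bins = 5)
  body <- pn[region == "body"]$mean_density
  expect_gt(mean(body[1:10]), mean(body[41:50]) + 1)
  expect_error(metagene_profile(p, ann, groups = list(empty = character())),
               "empty")
})

test_that("splice-site profiles peak downstream and Z-score per condition", {
  g <- small_genome()
  conds <- c("22C", "cold3h", "cold12h")
  pbc <- lapply(conds, function(cd)
    filter_pairs(simulate_contacts(g, cd))$pairs)
  names(pbc) <- conds
  prof <- splice_site_profile(pbc, g$annotation)
  # Z-score contract: mean 0, population sd 1 per condition
  for (cd in conds) {
    z <- prof[condition == cd]$z
    expect_lt(abs(mean(z)), 1e-9)
    expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-9)
  }
  # planted enrichment within 0..+50 bp downstream of the first 5'SS
  z22 <- prof[condition == "22C"]
  expect_gt(mean(z22[offset >= 0 & offset <= 50]$z),
            mean(z22[offset < 0 | offset > 50]$z) + 0.5)
  # condition ordering of the pausing signal: 22C > cold12h > cold3h
  zbar <- prof[offset >= 0 & offset <= 50, .(z = mean(z)), by = condition]
  zv <- setNames(zbar$z, zbar$condition)
  expect_true(zv[["22C"]] > zv[["cold12h"]])
  expect_true(zv[["cold12h"]] > zv[["cold3h"]])
  # first_only anchors are a subset of all 5'SS anchors
  expect_lte(attr(splice_site_profile(pbc["22C"], g$annotation,
                                      first_only = TRUE), "n_sites"),
             attr(splice_site_profile(pbc["22C"], g$annotation,
                                      first_only = FALSE), "n_sites"))
  single_exon <- gene_annotation(
    data.table(gene_id = "s", chrom = "chr1", start = 1000L, end = 3000L,
               strand = "+"),
    data.table(gene_id = "s", start = 1000L, end = 3000L))
  expect_error(splice_site_profile(pbc["22C"], single_exon), "multi-exon")
})

test_that("spearman matches independent midrank and exact references", {
  expect_equal(spearman(c(1, 2, 3, 5), c(3, 6, 9, 30))$rho, 1.0)
  expect_equal(spearman(c(1, 2, 3, 4), c(9, 6, 3, 1))$rho, -1.0)
  # tie-heavy vectors against a hand-rolled midrank computation
  set.seed(13)
  for (i in 1:20) {
    x <- sample(1:4, 12, TRUE); y <- sample(1:3, 12, TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    midrank <- function(v) {
      sapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2)
    }
    want <- cor(midrank(x), midrank(y))
    expect_equal(spearman(x, y)$rho, want)
  }
  # exact small-n p-value against cor.test's exact method (no ties)
  set.seed(14)
  for (i in 1:10) {
    x <- sample(1:8); y <- sample(1:8)
    got <- spearman(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # t-approximation for larger n agrees with cor.test's asymptotic path
  set.seed(15)
  x <- rnorm(40); y <- rnorm(40)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(spearman(x, y)$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(spearman(c(1, 1, 1, 1), 1:4), "constant")
  expect_error(spearman(1:3, 1:3), "at least 4")
})

test_that("activity-contact coupling is recovered from simulated data", {
  cfg <- sim_config(seed = 61, n_chroms = 2, chrom_length = 6e5,
                    n_genes = 300, n_background_pairs = 4e5,
                    n_loops = 0, n_enhancers = 0, n_hotspots = 0,
                    activity_coupling = 0.4)
  g <- generate_genome(cfg)
  ax <- simulate_activity_and_expression(g)
  p <- filter_pairs(simulate_contacts(g, "22C"))$pairs
  dens <- gene_contact_density(p, g$annotation)
  genes <- g$annotation$genes
  actv <- track_interval_mean(ax$tracks[["22C"]], genes$chrom, genes$start,
                              genes$end)
  s <- spearman(dens$density, actv)
  expect_lt(abs(s$rho - 0.4), 0.1)
})
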