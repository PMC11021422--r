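test_that("anchor annotation reports overlaps with promoter precedence", {
  cs <- tiny_chromsizes()
  ann <- tiny_annotation()
  enh <- data.table(enhancer_id = c("e1", "e2"), chrom = "chr1",
                    start = c(700L, 6000L), end = c(1000L, 6300L))
  # gA is + with TSS 1000: promoter window [500, 1101)
  anchors <- data.table(chrom = "chr1",
                        start = c(600L, 800L, 6000L, 2200L, 4900L),
                        end = c(800L, 1000L, 6200L, 2400L, 5100L))
  out <- annotate_anchors(anchors, ann, enh, cs)
  expect_equal(out$label,
               c("promoter", "promoter", "enhancer", "gene_body",
                 "intergenic"))
  # promoter AND enhancer hit resolves to promoter by precedence
  expect_equal(out$promoter_genes[[2]], "gA")
  expect_equal(out$enhancer_ids[[2]], "e1")
  expect_equal(out$body_genes[[4]], "gA")
  expect_error(annotate_anchors(
    data.table(chrom = "chr1", start = -5L, end = 10L), ann, enh, cs),
    "outside")
})

# independent oracle: exhaustive case analysis of cis orientations written
# out by hand (left/right gene by TSS, four strand combinations x two
# supply orders)
test_that("PPI orientation matches exhaustive enumeration", {
  config_grid <- expand.grid(sL = c("+", "-"), sR = c("+", "-"),
                             swap = c(FALSE, TRUE),
                             stringsAsFactors = FALSE)
  hand_rule <- function(sL, sR) {
    if (sL == sR) "tandem" else if (sL == "-") "divergent" else "convergent"
  }
  for (i in seq_len(nrow(config_grid))) {
    sL <- config_grid$sL[i]; sR <- config_grid$sR[i]
    tL <- 1000L; tR <- 9000L
    args <- list(chromA = "chr1", tssA = tL, strandA = sL,
                 chromB = "chr1", tssB = tR, strandB = sR)
    if (config_grid$swap[i])
      args <- list(chromA = "chr1", tssA = tR, strandA = sR,
                   chromB = "chr1", tssB = tL, strandB = sL)
    got <- do.call(classify_ppi, args)
    expect_equal(got$kind, "PP_cis")
    expect_equal(got$orientation, hand_rule(sL, sR),
                 info = paste(sL, sR, config_grid$swap[i]))
  }
  trans <- classify_ppi("chr1", 100L, "+", "chr3", 100L, "-")
  expect_equal(trans$kind, "PP_trans")
  expect_true(is.na(trans$orientation))
  expect_error(classify_ppi("chr1", 1L, "+", "chr1", 2L, "+",
                            geneA = "g", geneB = "g"), "self-loop")
})

test_that("E-P classification is strand-aware and distance-cut", {
  # enhancer 1 kb 5' of a plus-strand TSS
  out <- classify_ep(enhancer_mid = 4000L, promoter_tss = 5000L,
                     promoter_strand = "+", proximal_max_bp = 2000L)
  expect_equal(c(out$range, out$side), c("proximal", "upstream"))
  # mirrored geometry on a minus-strand gene is still upstream
  out2 <- classify_ep(6000L, 5000L, "-", 2000L)
  expect_equal(c(out2$range, out2$side), c("proximal", "upstream"))
  out3 <- classify_ep(55000L, 5000L, "+", 2000L)
  expect_equal(out3$range, "distal")
  out4 <- classify_ep(5500L, 5000L, "+", 2000L)
  expect_equal(out4$side, "downstream")
})

test_that("classification summary gives family-wise fractions summing to 1", {
  cls <- data.table(
    kind = c(rep("PP_cis", 4), "PP_trans", "EP", "EP"),
    orientation = c("tandem", "tandem", "tandem", "divergent", NA, NA, NA),
    range = c(rep(NA, 5), "proximal", "distal"),
    side = c(rep(NA, 5), "upstream", "downstream"),
    geneA = letters[1:7], geneB = LETTERS[1:7],
    enhancer_id = NA_character_)
  s <- classification_summary(cls)
  ori <- s[family == "pp_orientation"]
  expect_equal(ori[level == "tandem"]$fraction, 0.75)
  expect_equal(ori[level == "divergent"]$fraction, 0.25)
  expect_equal(nrow(ori[level == "convergent"]), 0L)
  for (fam in unique(s$family))
    expect_equal(sum(s[family == fam]$fraction), 1)
  expect_equal(nrow(classification_summary(cls[0])), 0L)
})

test_that("classify_contacts pairs annotated anchors into typed contacts", {
  cs <- tiny_chromsizes()
  ann <- tiny_annotation()
  enh <- data.table(enhancer_id = "e1", chrom = "chr1",
                    start = 6000L, end = 6300L)
  # gA TSS 1000 (+), gB TSS 10999 (-): promoter-promoter loop
  loops <- data.table(chrom1 = "chr1", bin1 = 4L, chrom2 = "chr1",
                      bin2 = 54L)
  cls <- classify_contacts(loops, ann, enh, cs, resolution = 200L)
  expect_equal(cls$kind, "PP_cis")
  expect_equal(cls$orientation, "convergent")  # + gene left, - gene right
  expect_equal(c(cls$geneA, cls$geneB), c("gA", "gB"))
  # enhancer-promoter loop: anchor on e1, anchor on gB promoter
  loops2 <- data.table(chrom1 = "chr1", bin1 = 30L, chrom2 = "chr1",
                       bin2 = 55L)
  cls2 <- classify_contacts(loops2, ann, enh, cs, resolution = 200L)
  expect_equal(cls2$kind, "EP")
  expect_equal(cls2$side, "downstream")  # enhancer 3' of the minus TSS
  # intergenic-intergenic falls through to "other"
  loops3 <- data.table(chrom1 = "chr2", bin1 = 60L, chrom2 = "chr2",
                       bin2 = 100L)
  expect_equal(classify_contacts(loops3, ann, enh, cs)$kind, "other")
})
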