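# independent brute-force BH used as the q-value oracle
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

test_that("binomial p-values match direct pmf summation and closed forms", {
  expect_equal(binom_pvalue(0, 100, 0.3), 1.0)
  expect_equal(binom_pvalue(10, 10, 0.5), 2^-10)
  brute <- sum(dbinom(2:100, 100, 0.02))
  expect_lt(abs(binom_pvalue(2, 100, 0.02) - brute), 1e-12)
  expect_error(binom_pvalue(2, 100, 0), "p must")
  expect_error(binom_pvalue(-1, 100, 0.5), "k must")
  # monotone decreasing in k, increasing in p
  ks <- 0:50
  expect_true(all(diff(binom_pvalue(ks, 50, 0.1)) <= 0))
  ps <- seq(0.01, 0.9, by = 0.01)
  expect_true(all(diff(binom_pvalue(5, 50, ps)) >= 0))
})

test_that("BH q-values agree with an independent brute-force BH", {
  set.seed(42)
  for (i in 1:50) {
    p <- runif(sample(5:400, 1))^sample(1:3, 1)
    expect_equal(p.adjust(p, "BH"), brute_bh(p))
  }
})

test_that("pool-adjacent-violators produces the monotone least-squares fit", {
  y <- c(5, 6, 3, 3, 4, 1)
  out <- pava_nonincreasing(y)
  expect_true(all(diff(out) <= 1e-12))
  # pooled blocks are weighted means of their members
  expect_equal(out[1:2], rep(5.5, 2))
  expect_equal(out[3:5], rep(10 / 3, 3))
  # weights shift pooled values
  outw <- pava_nonincreasing(c(2, 4), w = c(1, 3))
  expect_equal(outw, rep(3.5, 2))
  # already monotone input is untouched
  expect_equal(pava_nonincreasing(c(9, 4, 1)), c(9, 4, 1))
})

test_that("expected model is flat on a uniform matrix and decays on a power law", {
  cs <- chrom_sizes("chr1", 2e4)  # 100 bins
  grid <- CJ(bin1 = 0:99, bin2 = 0:99)[bin2 > bin1 + 1]
  m <- structure(list(
    counts = data.table(chrom1 = "chr1", grid[, .(bin1)], chrom2 = "chr1",
                        grid[, .(bin2)], count = 4L),
    resolution = 200L, chromsizes = cs, N = nrow(grid) * 4L),
    class = "contact_matrix")
  mod <- fit_expected(m, n_distance_bins = 10, max_distance = 2e4)
  expect_lt(diff(range(mod$p)) / mean(mod$p), 1e-9)
  # alpha = 1 background: log-log slope of p(s) near -1
  g <- small_genome()
  pr <- filter_pairs(simulate_contacts(g, "22C"))$pairs
  mm <- bin_contacts(pr, 200, g$chromsizes)
  mod2 <- fit_expected(mm)
  mid <- (mod2$d_lo + mod2$d_hi) / 2
  fit <- lm(log(p) ~ log(mid), data = data.frame(p = mod2$p, mid = mid),
            weights = mod2$n_contacts)
  expect_lt(abs(coef(fit)[2] + 1), 0.15)
  expect_true(all(diff(mod2$p) <= 1e-15))
  expect_warning(fit_expected(mm, n_distance_bins = 1e5), "fewer occupied")
})

test_that("equal-occupancy bins carry comparable contact counts", {
  g <- small_genome()
  pr <- filter_pairs(simulate_contacts(g, "22C"))$pairs
  mm <- bin_contacts(pr, 200, g$chromsizes)
  # pure equal-occupancy construction (span guard off): every bin within
  # 2x of each other except possibly the final remainder bin
  mod <- fit_expected(mm, n_distance_bins = 20, max_span_ratio = Inf)
  occ <- mod$n_contacts
  body <- occ[-length(occ)]
  expect_lt(max(body) / min(body), 2)
})

test_that("planted loops are recovered and a null stays quiet", {
  cfg <- sim_config(seed = 55, n_chroms = 2, chrom_length = 6e5,
                    n_genes = 200, n_background_pairs = 8e5, n_loops = 60,
                    fivess_rate = 0, n_hotspots = 0, n_enhancers = 30)
  g <- generate_genome(cfg)
  m <- bin_contacts(filter_pairs(simulate_contacts(g, "22C"))$pairs, 200,
                    g$chromsizes)
  mod <- fit_expected(m)
  calls <- call_stable_contacts(m, mod, q_threshold = 0.01)
  truth <- g$truth$loops
  hits <- finechrom:::match_truth_loops(truth, calls, 200)
  expect_gt(mean(hits), 0.7)
  fp <- 1 - mean(finechrom:::match_loop_calls(calls, truth, 200))
  expect_lt(fp, 0.1)
  # q ordering consistent and monotone call count in threshold
  expect_true(all(diff(calls$qvalue) >= 0))
  expect_lte(nrow(call_stable_contacts(m, mod, 0.001)), nrow(calls))
  expect_lte(nrow(calls), nrow(call_stable_contacts(m, mod, 0.05)))
  # fold = 1 plants nothing: near-zero calls
  cfg0 <- cfg; cfg0$loop_fold <- 1; cfg0$seed <- 56
  g0 <- generate_genome(cfg0)
  m0 <- bin_contacts(filter_pairs(simulate_contacts(g0, "22C"))$pairs, 200,
                     g0$chromsizes)
  calls0 <- call_stable_contacts(m0, fit_expected(m0), 0.01)
  expect_lte(nrow(calls0) / attr(calls0, "n_tested"), 0.01)
})

test_that("condition intersection equals brute-force set intersection", {
  mk <- function(df) as.data.table(df)
  a <- mk(data.frame(chrom1 = "chr1", bin1 = c(1L, 5L, 9L), chrom2 = "chr1",
                     bin2 = c(11L, 15L, 19L)))
  b <- mk(data.frame(chrom1 = "chr1", bin1 = c(5L, 9L, 30L), chrom2 = "chr1",
                     bin2 = c(15L, 19L, 40L)))
  out <- intersect_conditions(list(x = a, y = b))
  expect_equal(out$bin1, c(5L, 9L))
  expect_equal(intersect_conditions(list(a, a))[, .(bin1, bin2)],
               a[, .(bin1, bin2)])
  disj <- mk(data.frame(chrom1 = "chr1", bin1 = 100L, chrom2 = "chr1",
                        bin2 = 200L))
  expect_equal(nrow(intersect_conditions(list(a, disj))), 0L)
  # random sets against a string-keyed oracle
  set.seed(7)
  rnd <- function() unique(mk(data.frame(
    chrom1 = "chr1", bin1 = sample(1:30, 20, TRUE), chrom2 = "chr1",
    bin2 = sample(31:60, 20, TRUE))))
  for (i in 1:10) {
    x <- rnd(); y <- rnd(); z <- rnd()
    got <- intersect_conditions(list(x, y, z))
    key <- function(d) paste(d$chrom1, d$bin1, d$chrom2, d$bin2)
    want <- Reduce(intersect, list(key(x), key(y), key(z)))
    expect_setequal(key(got), want)
  }
  # slack of one bin tolerates anchor jitter
  shifted <- copy(a)[, bin1 := bin1 + 1L]
  expect_equal(nrow(intersect_conditions(list(a, shifted), slack = 0L)), 0L)
  expect_equal(nrow(intersect_conditions(list(a, shifted), slack = 1L)), 3L)
})
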