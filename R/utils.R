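#' @importFrom data.table data.table as.data.table setnames setorder setorderv
#'   setkey fwrite fread copy rbindlist := .N .SD fifelse CJ foverlaps
#' @importFrom stats pbinom p.adjust cor lm coef runif rnorm rpois rbinom
#'   quantile sd ks.test pt setNames complete.cases
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  ".", "chrom", "chrom1", "chrom2", "pos1", "pos2", "strand1", "strand2",
  "mapq1", "mapq2", "bin1", "bin2", "count", "distance", "pvalue", "qvalue",
  "gene_id", "start", "end", "strand", "exon_rank", "value", "condition",
  "replicate", "geneA", "geneB", "support", "n_conditions", "cov1", "cov2",
  "degree", "d_bin", "k", "p_exp", "i.start", "i.end", "mid", "offset",
  "orientation", "class_kind", "anchor", "tss", "len", "density", "weight",
  "x", "y", "i.gene_id", "i.strand", "i.tss", "idx", "idx2", "bin"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage seed from a master seed
#'
#' Stable small-integer seeds per named stage so that toggling one stochastic
#' stage does not perturb the stream of another. The result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param stage character scalar naming the stage.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(as.numeric(master)) * 69069 + h * 7919 + 1) %% (2^31 - 2)
  as.integer(s) + 1L
}

abort_stage <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

# population (n-denominator) standard deviation
sd_pop <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}
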