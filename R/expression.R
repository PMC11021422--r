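#' Expression tables
#'
#' Expression values are stored long: one row per `gene_id, condition,
#' replicate` with a finite `value` (library-normalized units). The three
#' standard conditions are `22C`, `cold3h` and `cold12h`.
#'
#' @param x data.frame with columns `gene_id, condition, replicate, value`.
#' @return a long `data.table`.
#' @export
expression_table <- function(x) {
  x <- as.data.table(x)[, .(gene_id = as.character(gene_id),
                            condition = as.character(condition),
                            replicate = as.integer(replicate),
                            value = as.numeric(value))]
  if (any(!is.finite(x$value)))
    stop("non-finite expression values", call. = FALSE)
  if (anyDuplicated(x[, .(gene_id, condition, replicate)]))
    stop("duplicated gene/condition/replicate rows", call. = FALSE)
  setkey(x, NULL)
  x[]
}

#' @rdname expression_table
#' @param path TSV with header `gene_id condition replicate value`.
#' @export
read_expression <- function(path) expression_table(fread(path, sep = "\t"))

#' @rdname expression_table
#' @param expr a long expression table.
#' @export
write_expression <- function(expr, path) {
  fwrite(expr, path, sep = "\t")
  invisible(path)
}

#' Expression sample matrix
#'
#' Reshapes a long expression table into a genes x samples matrix, samples
#' ordered by condition then replicate.
#'
#' @inheritParams write_expression
#' @return numeric matrix, rownames = gene ids.
#' @export
expression_matrix <- function(expr) {
  expr <- as.data.table(expr)
  setorder(expr, condition, replicate, gene_id)
  samples <- unique(expr[, .(condition, replicate)])
  genes <- sort(unique(expr$gene_id))
  m <- matrix(NA_real_, nrow = length(genes), ncol = nrow(samples),
              dimnames = list(genes, paste0(samples$condition, ".r",
                                            samples$replicate)))
  for (j in seq_len(nrow(samples))) {
    sub <- expr[condition == samples$condition[j] &
                  replicate == samples$replicate[j]]
    m[sub$gene_id, j] <- sub$value
  }
  if (anyNA(m)) stop("expression table is not complete over samples",
                     call. = FALSE)
  m
}
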