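#' Chromosome sizes
#'
#' A named vector of chromosome lengths (bp). The order of the names fixes
#' the chromosome order used to canonicalize contact pairs.
#'
#' @param names character vector of unique chromosome names.
#' @param lengths positive integer lengths (bp).
#' @return a `chrom_sizes` object (named numeric vector).
#' @examples
#' cs <- chrom_sizes(c("chr1", "chr2"), c(5e5, 3e5))
#' @export
chrom_sizes <- function(names, lengths) {
  stopifnot(length(names) == length(lengths), !anyDuplicated(names))
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  structure(setNames(lengths, as.character(names)), class = "chrom_sizes")
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat("chrom_sizes:", length(x), "chromosomes,",
      format(sum(x), big.mark = ","), "bp total\n")
  print(unclass(x))
  invisible(x)
}

#' Read chromosome sizes from a two-column TSV
#'
#' @param path file with `name<TAB>length` rows.
#' @return a [chrom_sizes()] object, chromosomes in file order.
#' @export
read_chromsizes <- function(path) {
  d <- fread(path, header = FALSE, sep = "\t",
             col.names = c("name", "length"))
  chrom_sizes(d$name, d$length)
}

#' @rdname read_chromsizes
#' @param chromsizes a `chrom_sizes` object to write.
#' @export
write_chromsizes <- function(chromsizes, path) {
  fwrite(data.table(name = names(chromsizes), length = as.integer(chromsizes)),
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

chrom_index <- function(chrom, chromsizes) {
  i <- match(as.character(chrom), names(chromsizes))
  if (anyNA(i)) {
    bad <- unique(as.character(chrom)[is.na(i)])
    stop("chromosome(s) not in chrom sizes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  i
}
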