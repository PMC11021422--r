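#' Contact pair tables
#'
#' A contact pair table is a `data.table` with one valid ligation contact per
#' row and columns `chrom1, pos1, strand1, chrom2, pos2, strand2, mapq1,
#' mapq2`. Positions are 0-based bp. Tables are kept in canonical order:
#' `(chrom1, pos1) <= (chrom2, pos2)` by chromosome order (the order of the
#' `chrom_sizes` names) and then position.
#'
#' @param chrom1,pos1,strand1,chrom2,pos2,strand2,mapq1,mapq2 column vectors.
#' @param chromsizes a [chrom_sizes()] object; pairs are validated against it
#'   and canonicalized.
#' @return canonical contact pair `data.table`.
#' @export
contact_pairs <- function(chrom1, pos1, strand1, chrom2, pos2, strand2,
                          mapq1 = 60L, mapq2 = 60L, chromsizes) {
  dt <- data.table(
    chrom1 = as.character(chrom1), pos1 = as.integer(pos1),
    strand1 = as.character(strand1),
    chrom2 = as.character(chrom2), pos2 = as.integer(pos2),
    strand2 = as.character(strand2),
    mapq1 = as.integer(mapq1), mapq2 = as.integer(mapq2))
  canonicalize_pairs(dt, chromsizes)
}

validate_pairs <- function(pairs, chromsizes) {
  i1 <- chrom_index(pairs$chrom1, chromsizes)
  i2 <- chrom_index(pairs$chrom2, chromsizes)
  bad <- pairs$pos1 < 0 | pairs$pos2 < 0 |
    pairs$pos1 >= chromsizes[i1] | pairs$pos2 >= chromsizes[i2]
  if (any(bad))
    stop("position outside chromosome bounds at row(s) ",
         paste(head(which(bad), 5), collapse = ", "), call. = FALSE)
  if (!all(c(pairs$strand1, pairs$strand2) %in% c("+", "-")))
    stop("strands must be '+' or '-'", call. = FALSE)
  invisible(pairs)
}

#' Canonicalize a contact pair table
#'
#' Swaps the two ends of each pair so that end 1 is not after end 2 in
#' chromosome order (order of appearance in the `chrom_sizes`) and position.
#'
#' @param pairs contact pair table.
#' @inheritParams contact_pairs
#' @return canonical contact pair `data.table` (a copy).
#' @export
canonicalize_pairs <- function(pairs, chromsizes) {
  pairs <- as.data.table(pairs)
  validate_pairs(pairs, chromsizes)
  i1 <- chrom_index(pairs$chrom1, chromsizes)
  i2 <- chrom_index(pairs$chrom2, chromsizes)
  swap <- i2 < i1 | (i1 == i2 & pairs$pos2 < pairs$pos1)
  if (any(swap)) {
    sw <- pairs[swap]
    pairs[swap, `:=`(chrom1 = sw$chrom2, pos1 = sw$pos2, strand1 = sw$strand2,
                     mapq1 = sw$mapq2, chrom2 = sw$chrom1, pos2 = sw$pos1,
                     strand2 = sw$strand1, mapq2 = sw$mapq1)]
  }
  pairs[]
}

#' Read contact pairs from a pairs TSV
#'
#' Expects eight tab-separated columns per line: `chrom1 pos1 strand1 chrom2
#' pos2 strand2 mapq1 mapq2`; lines starting with `#` are comments. Pairs are
#' canonicalized on load.
#'
#' @param path pairs TSV file.
#' @inheritParams contact_pairs
#' @return canonical contact pair `data.table`.
#' @export
read_pairs <- function(path, chromsizes) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  if (!any(keep))
    return(contact_pairs(character(), integer(), character(), character(),
                         integer(), character(), integer(), integer(),
                         chromsizes))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 8L)) {
    bad_line <- which(keep)[which(nf != 8L)[1]]
    stop(sprintf("malformed pairs line %d in %s: expected 8 fields, got %d",
                 bad_line, path, nf[nf != 8L][1]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 8L, byrow = TRUE)
  pos <- suppressWarnings(cbind(as.integer(m[, 2]), as.integer(m[, 5])))
  mq <- suppressWarnings(cbind(as.integer(m[, 7]), as.integer(m[, 8])))
  if (anyNA(pos) || anyNA(mq)) {
    bad_line <- which(keep)[which(is.na(pos[, 1]) | is.na(pos[, 2]) |
                                    is.na(mq[, 1]) | is.na(mq[, 2]))[1]]
    stop(sprintf("malformed pairs line %d in %s: non-integer field",
                 bad_line, path), call. = FALSE)
  }
  contact_pairs(m[, 1], pos[, 1], m[, 3], m[, 4], pos[, 2], m[, 6],
                mq[, 1], mq[, 2], chromsizes)
}

#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  fwrite(pairs, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
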