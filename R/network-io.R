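#' Write / read a PPI network edge list
#'
#' Tab-separated export consumable by external network viewers: one row per
#' edge with `geneA geneB class orientation n_conditions conditions support`.
#' `read_network_edges()` of a written file reproduces the edge table
#' exactly.
#'
#' @param network a [build_ppi_network()] result.
#' @param path output TSV.
#' @export
write_network_edges <- function(network, path) {
  e <- copy(network$edges)
  e[, conditions := vapply(conditions, paste, character(1), collapse = ",")]
  fwrite(e[, .(geneA, geneB, class = class_kind, orientation,
               n_conditions, conditions, support)],
         path, sep = "\t")
  invisible(path)
}

#' @rdname write_network_edges
#' @return for `read_network_edges`, an edge `data.table` with the same
#'   columns as `network$edges`.
#' @export
read_network_edges <- function(path) {
  e <- fread(path, sep = "\t", colClasses = list(
    character = c("geneA", "geneB", "class", "orientation", "conditions")))
  setnames(e, "class", "class_kind")
  e[orientation == "", orientation := NA_character_]
  e[, conditions := lapply(strsplit(conditions, ",", fixed = TRUE),
                           function(x) x[nzchar(x)])]
  e[, .(geneA, geneB, class_kind, orientation, n_conditions, conditions,
        support)]
}
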