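#' Default pipeline configuration
#'
#' A single list drives [run_pipeline()]: either a `synthetic` block
#' (arguments to [sim_config()]) or an `inputs` block with file paths
#' (`chromsizes`, per-condition `pairs`, `annotation`, `enhancers` BED,
#' per-condition `tracks` bedGraph, `expression` TSV), plus analysis
#' settings.
#'
#' @param seed master seed (mandatory; every stochastic stage derives its
#'   own stream from it).
#' @param out_dir output directory.
#' @param synthetic list of [sim_config()] overrides, or `NULL` when file
#'   inputs are given.
#' @param inputs list of input file paths, or `NULL` for synthetic runs.
#' @param resolution,mapq_min,q_threshold,promoter_upstream,
#'   promoter_downstream,proximal_max_bp,n_reps analysis settings (see the
#'   stage functions).
#' @param stages character vector of optional stage switches; subset of
#'   `c("coexpression", "profiles")`.
#' @return config list for [run_pipeline()].
#' @export
pipeline_config <- function(seed, out_dir = tempfile("finechrom_"),
                            synthetic = list(), inputs = NULL,
                            resolution = 200L, mapq_min = 10L,
                            q_threshold = 0.01, promoter_upstream = 500L,
                            promoter_downstream = 100L,
                            proximal_max_bp = 2000L, n_reps = 1000L,
                            stages = c("profiles", "coexpression")) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  as.list(environment())
}

demo_sim_overrides <- function() {
  # desk-scale smoke-test conditions: small but non-trivial
  list(n_chroms = 5L, chrom_length = 3e5, n_genes = 300L,
       n_background_pairs = 5e5, n_loops = 100L, n_enhancers = 40L)
}

#' Run the full contact-analysis pipeline
#'
#' Stages, in order: input simulation or loading, pair filtering, binning,
#' VC normalization, decay curve, stable-contact calling per condition,
#' condition intersection (primed contacts), anchor
#' annotation/classification, PPI network and hotspots, gene-density and
#' 5'SS profiles with activity correlation, and PPI co-expression testing.
#' Every output file is written under `config$out_dir` together with a
#' provenance record (config hash, seed, package version).
#'
#' @param config a [pipeline_config()] list, or a path to a YAML file with
#'   the same fields.
#' @return (invisibly) list of in-memory stage results, including
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% tempfile("finechrom_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res_list <- list(out_dir = out_dir)
  resolution <- config$resolution %||% 200L

  # --- inputs ------------------------------------------------------------
  if (!is.null(config$synthetic) && is.null(config$inputs)) {
    stage <- "synthetic_data"
    sc <- do.call(sim_config, c(list(seed = config$seed), config$synthetic))
    genome <- tryCatch(generate_genome(sc),
                       error = function(e) abort_stage(stage, conditionMessage(e)))
    conds <- conditions_of(sc)
    pairs_raw <- lapply(conds, function(cond)
      simulate_contacts(genome, cond))
    names(pairs_raw) <- conds
    act <- simulate_activity_and_expression(genome)
    chromsizes <- genome$chromsizes
    annotation <- genome$annotation
    enhancers <- genome$enhancers
    tracks <- act$tracks
    expression <- act$expression
    res_list$genome <- genome
    write_chromsizes(chromsizes, file.path(out_dir, "genome.sizes"))
    write_annotation_gff3(annotation, file.path(out_dir, "genes.gff3"))
    fwrite(enhancers[, .(chrom, start, end, enhancer_id)],
           file.path(out_dir, "enhancers.bed"), sep = "\t",
           col.names = FALSE)
    write_expression(expression, file.path(out_dir, "expression.tsv"))
    jsonlite::write_json(
      list(loops = genome$truth$loops,
           ppi_pairs = genome$truth$ppi_pairs,
           condition_weights = as.list(genome$truth$condition_weights)),
      file.path(out_dir, "truth.json"), dataframe = "columns")
  } else if (!is.null(config$inputs)) {
    stage <- "load_inputs"
    inp <- config$inputs
    chromsizes <- read_chromsizes(inp$chromsizes)
    pairs_raw <- lapply(inp$pairs, read_pairs, chromsizes = chromsizes)
    annotation <- read_annotation(inp$annotation)
    enhancers <- if (!is.null(inp$enhancers)) {
      b <- fread(inp$enhancers, header = FALSE)
      data.table(enhancer_id = if (ncol(b) >= 4) as.character(b[[4]]) else
        sprintf("E%03d", seq_len(nrow(b))),
        chrom = as.character(b[[1]]), start = as.integer(b[[2]]),
        end = as.integer(b[[3]]))
    } else data.table(enhancer_id = character(), chrom = character(),
                      start = integer(), end = integer())
    tracks <- if (!is.null(inp$tracks))
      lapply(inp$tracks, read_signal_track, chromsizes = chromsizes,
             bin_width = resolution) else NULL
    expression <- if (!is.null(inp$expression))
      read_expression(inp$expression) else NULL
  } else abort_stage("config", "neither synthetic block nor inputs given")
  conds <- names(pairs_raw)

  # --- contact processing ------------------------------------------------
  filtered <- lapply(conds, function(cond) {
    f <- filter_pairs(pairs_raw[[cond]], mapq_min = config$mapq_min %||% 10L,
                      resolution = resolution)
    write_pairs(f$pairs, file.path(out_dir,
                                   sprintf("pairs.%s.filtered.tsv", cond)))
    f
  })
  names(filtered) <- conds
  res_list$filter_reports <- lapply(filtered, `[[`, "report")
  matrices <- lapply(conds, function(cond)
    bin_contacts(filtered[[cond]]$pairs, resolution, chromsizes))
  names(matrices) <- conds
  for (cond in conds) {
    write_contact_matrix(matrices[[cond]],
                         file.path(out_dir, sprintf("matrix.%s.tsv", cond)))
    vc <- vc_normalize(matrices[[cond]])
    write_contact_matrix(vc, file.path(out_dir,
                                       sprintf("matrix.%s.vc.tsv", cond)))
  }
  res_list$matrices <- matrices
  res_list$decay <- lapply(conds, function(cond)
    decay_curve(filtered[[cond]]$pairs,
                d_max = max(as.numeric(chromsizes))))
  names(res_list$decay) <- conds

  # --- loop calling ------------------------------------------------------
  calls <- lapply(conds, function(cond) {
    model <- fit_expected(matrices[[cond]])
    cl <- call_stable_contacts(matrices[[cond]], model,
                               q_threshold = config$q_threshold %||% 0.01)
    write_loop_calls(cl, file.path(out_dir, sprintf("loops.%s.tsv", cond)))
    cl
  })
  names(calls) <- conds
  res_list$calls <- calls
  primed <- if (length(conds) >= 2) intersect_conditions(calls) else
    calls[[1]][, .(chrom1, bin1, chrom2, bin2)]
  fwrite(primed, file.path(out_dir, "primed_contacts.tsv"), sep = "\t")
  res_list$primed <- primed

  # --- classification & network -----------------------------------------
  classified <- classify_contacts(
    primed, annotation, enhancers, chromsizes, resolution,
    proximal_max_bp = config$proximal_max_bp %||% 2000L,
    promoter_upstream = config$promoter_upstream %||% 500L,
    promoter_downstream = config$promoter_downstream %||% 100L)
  fwrite(classified[, .(chrom1, mid1, chrom2, mid2, kind, orientation,
                        range, side, geneA, geneB, enhancer_id)],
         file.path(out_dir, "classified_contacts.tsv"), sep = "\t")
  res_list$classified <- classified
  summary_tab <- classification_summary(classified)
  fwrite(summary_tab, file.path(out_dir, "classification_summary.tsv"),
         sep = "\t")
  res_list$class_summary <- summary_tab
  network <- build_ppi_network(classified, annotation, conditions = conds)
  write_network_edges(network, file.path(out_dir, "ppi_edges.tsv"))
  write_degree_table(network, file.path(out_dir, "ppi_degrees.tsv"))
  res_list$network <- network
  res_list$hotspots <- detect_hotspots(network)
  fwrite(res_list$hotspots, file.path(out_dir, "hotspots.tsv"), sep = "\t")

  # --- profiles ----------------------------------------------------------
  if ("profiles" %in% (config$stages %||% "profiles")) {
    dens <- gene_contact_density(filtered[[1]]$pairs, annotation)
    fwrite(dens, file.path(out_dir, "gene_density.tsv"), sep = "\t")
    res_list$gene_density <- dens
    if (!is.null(tracks)) {
      g <- annotation$genes
      actv <- track_interval_mean(tracks[[1]], g$chrom, g$start, g$end)
      ok <- is.finite(actv) & is.finite(dens$density)
      res_list$activity_correlation <-
        spearman(dens$density[ok], actv[ok])
    }
    pairs_by_cond <- lapply(filtered, `[[`, "pairs")
    res_list$ss_profile <- tryCatch(
      splice_site_profile(pairs_by_cond, annotation),
      error = function(e) NULL)
    if (!is.null(res_list$ss_profile))
      fwrite(res_list$ss_profile,
             file.path(out_dir, "splice_site_profile.tsv"), sep = "\t")
  }

  # --- co-expression -----------------------------------------------------
  if ("coexpression" %in% (config$stages %||% character())) {
    if (is.null(expression))
      abort_stage("coexpression", "no expression input configured")
    edges <- network$edges
    if (nrow(edges) >= 3) {
      res_list$coexpr <- compare_to_null(
        expression, annotation, edges[, .(geneA, geneB)],
        n_reps = config$n_reps %||% 1000L,
        seed = derive_seed(config$seed, "coexpr"))
      jsonlite::write_json(
        list(observed_mean = res_list$coexpr$observed_mean,
             observed_median = res_list$coexpr$observed_median,
             n_pairs = res_list$coexpr$n_pairs,
             p_A = res_list$coexpr$null_A$p,
             p_B = res_list$coexpr$null_B$p),
        file.path(out_dir, "coexpression.json"), auto_unbox = TRUE)
    }
  }

  # --- provenance --------------------------------------------------------
  cfg_json <- file.path(out_dir, "provenance.json")
  safe_cfg <- config[!vapply(config, is.function, logical(1))]
  jsonlite::write_json(
    list(config = safe_cfg, seed = config$seed,
         package_version = as.character(utils::packageVersion("finechrom"))),
    cfg_json, auto_unbox = TRUE, force = TRUE)
  hash <- unname(tools::md5sum(cfg_json))
  prov <- jsonlite::read_json(cfg_json)
  prov$config_hash <- hash
  jsonlite::write_json(prov, cfg_json, auto_unbox = TRUE)
  res_list$config_hash <- hash
  invisible(res_list)
}

#' Run the fully synthetic demo pipeline
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param ... [pipeline_config()] overrides.
#' @return invisible stage-result list.
#' @export
run_demo <- function(seed, out_dir = tempfile("finechrom_demo_"), ...) {
  cfg <- pipeline_config(seed = seed, out_dir = out_dir,
                         synthetic = demo_sim_overrides(), ...)
  run_pipeline(cfg)
}

# TRUE where both anchors of a call fall inside the same (1-bin expanded)
# gene body
calls_within_genes <- function(calls, genes, resolution, slack_bins = 1L) {
  if (!nrow(calls)) return(logical(0))
  hit <- rep(FALSE, nrow(calls))
  g <- as.data.table(genes)
  for (ci in unique(calls$chrom1)) {
    gc <- g[chrom == ci]
    if (!nrow(gc)) next
    sel <- which(calls$chrom1 == ci & calls$chrom2 == ci)
    if (!length(sel)) next
    lo <- gc$start %/% resolution - slack_bins
    hi <- (gc$end - 1L) %/% resolution + slack_bins
    for (s in sel) {
      hit[s] <- any(calls$bin1[s] >= lo & calls$bin2[s] <= hi)
    }
  }
  hit
}

match_loop_calls <- function(calls, truth_loops, resolution, slack = 1L) {
  if (!nrow(calls)) return(logical(0))
  tb1 <- truth_loops$pos1 %/% resolution
  tb2 <- truth_loops$pos2 %/% resolution
  key <- paste(truth_loops$chrom, tb1, tb2)
  hit <- rep(FALSE, nrow(calls))
  for (d1 in -slack:slack) for (d2 in -slack:slack) {
    k <- paste(calls$chrom1, calls$bin1 + d1, calls$bin2 + d2)
    hit <- hit | k %in% key
  }
  hit
}

match_truth_loops <- function(truth_loops, calls, resolution, slack = 1L) {
  if (!nrow(truth_loops)) return(logical(0))
  key <- paste(calls$chrom1, calls$bin1, calls$bin2)
  tb1 <- truth_loops$pos1 %/% resolution
  tb2 <- truth_loops$pos2 %/% resolution
  hit <- rep(FALSE, nrow(truth_loops))
  for (d1 in -slack:slack) for (d2 in -slack:slack) {
    k <- paste(truth_loops$chrom, tb1 + d1, tb2 + d2)
    hit <- hit | k %in% key
  }
  hit
}

#' Score pipeline outputs against the synthetic ground truth
#'
#' Computes, from a synthetic [run_pipeline()] result: per-condition
#' loop-call sensitivity and empirical FDR against the planted loops
#' (anchor match within +/- 1 bin), hotspot recovery (when hub promoters
#' were planted at the contact level), the 5'SS condition-ordering check
#' (mean Z over offsets 0..+50 ordered `22C > cold12h > cold3h`), and the
#' co-expression p-values.
#'
#' @param results a [run_pipeline()] result from a synthetic run.
#' @param truth `genome$truth` (defaults to the truth inside `results`).
#' @param resolution bin width of the run.
#' @return list of recovery metrics.
#' @export
validate_against_truth <- function(results, truth = NULL,
                                   resolution = 200L) {
  truth <- truth %||% results$genome$truth
  if (is.null(truth)) stop("missing truth", call. = FALSE)
  out <- list()
  if (!is.null(results$calls)) {
    genes <- results$genome$annotation$genes
    pausing <- !is.null(results$genome) &&
      (results$genome$config$fivess_rate %||% 0) > 0
    per <- lapply(results$calls, function(cl) {
      sens <- mean(match_truth_loops(truth$loops, cl, resolution))
      fdr <- if (nrow(cl))
        1 - mean(match_loop_calls(cl, truth$loops, resolution)) else NA_real_
      # structure-aware FDR: pausing-window contacts plant real intra-gene
      # enrichment, so calls with both anchors inside one gene body are
      # planted structure, not false positives
      fdr_structured <- if (nrow(cl)) {
        ok <- match_loop_calls(cl, truth$loops, resolution)
        if (pausing && nrow(genes))
          ok <- ok | calls_within_genes(cl, genes, resolution)
        1 - mean(ok)
      } else NA_real_
      list(sensitivity = sens, fdr = fdr,
           fdr_structured = fdr_structured, n_calls = nrow(cl))
    })
    out$loops <- per
    out$sensitivity_mean <- mean(vapply(per, `[[`, numeric(1),
                                        "sensitivity"))
    out$fdr_mean <- mean(vapply(per, `[[`, numeric(1), "fdr"), na.rm = TRUE)
    out$fdr_structured_mean <- mean(vapply(per, `[[`, numeric(1),
                                           "fdr_structured"), na.rm = TRUE)
  }
  if (!is.null(results$hotspots) && length(truth$hubs) &&
      any(truth$loops$kind == "hub")) {
    out$hotspot_recovery <- mean(names(truth$hubs) %in%
                                   results$hotspots$gene_id)
  }
  if (!is.null(results$ss_profile)) {
    zbar <- results$ss_profile[offset >= 0 & offset <= 50,
                               .(z = mean(z)), by = condition]
    zv <- setNames(zbar$z, zbar$condition)
    if (all(c("22C", "cold3h", "cold12h") %in% names(zv)))
      out$ss_ordering_ok <- unname(zv["22C"] > zv["cold12h"] &
                                     zv["cold12h"] > zv["cold3h"])
    out$ss_mean_z <- as.list(zv)
  }
  if (!is.null(results$coexpr)) {
    out$coexpr_p_A <- results$coexpr$null_A$p
    out$coexpr_p_B <- results$coexpr$null_B$p
  }
  out
}
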