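# Orchestration: per-block regression -> selections -> enrichment, then the
# pooled analyses (cross-timepoint overlap, variance-filtered clustering,
# MI network). Every number in the run report is recomputed from the stage
# results; the report is derived, never authoritative.

#' Pipeline configuration
#'
#' Collects the tunable knobs of the full analysis with their defaults.
#' Precedence when running from the CLI: flag > config file > these defaults.
#'
#' @param p_cutoff_analysis P cutoff for the broad significant set (default
#'   0.05, the "analysis" threshold).
#' @param p_cutoff_report P cutoff for the reported per-direction lists
#'   (default 0.01).
#' @param regression_scale \code{"raw"} or \code{"log2"} for
#'   \code{\link{fit_dose_regression}}.
#' @param collapse_rule Probe-to-gene rule for \code{\link{collapse_probes}}.
#' @param sd_threshold SD threshold for \code{\link{center_and_filter}}.
#' @param cluster_scale Scale for the pooled clustering matrix
#'   (default \code{"log2"}; SD > 1 on raw MAS5 signal would retain nearly
#'   every probe).
#' @param cluster_center \code{"grand"} or \code{"gene"} centering.
#' @param linkage Ward dialect / linkage for sample clustering.
#' @param mi_bins,mi_scheme,mi_distance_mode Network-analysis knobs (see
#'   \code{\link{mi_adjacency}}, \code{\link{mi_distance}}).
#' @param module_linkage,module_min_size,n_candidate_cuts Module-detection
#'   knobs (see \code{\link{detect_modules}}).
#' @param max_network_genes Cap on the number of highest-SD genes entering
#'   the MI network (keeps the O(G^2) step bounded).
#' @param seed Seed for any stochastic step (currently only permutation
#'   nulls when requested).
#' @return A \code{PipelineConfig} list.
#' @export
pipeline_config <- function(p_cutoff_analysis = 0.05,
                            p_cutoff_report = 0.01,
                            regression_scale = "raw",
                            collapse_rule = "min_p",
                            sd_threshold = 1,
                            cluster_scale = "log2",
                            cluster_center = "grand",
                            linkage = "ward.D2",
                            mi_bins = 3,
                            mi_scheme = "equal_frequency",
                            mi_distance_mode = "one_minus_nmi",
                            module_linkage = "average",
                            module_min_size = 4,
                            n_candidate_cuts = NULL,
                            max_network_genes = 1000,
                            seed = 1) {
  cfg <- list(p_cutoff_analysis = p_cutoff_analysis,
              p_cutoff_report = p_cutoff_report,
              regression_scale = regression_scale,
              collapse_rule = collapse_rule,
              sd_threshold = sd_threshold,
              cluster_scale = cluster_scale,
              cluster_center = cluster_center,
              linkage = linkage,
              mi_bins = mi_bins, mi_scheme = mi_scheme,
              mi_distance_mode = mi_distance_mode,
              module_linkage = module_linkage,
              module_min_size = module_min_size,
              n_candidate_cuts = n_candidate_cuts,
              max_network_genes = max_network_genes,
              seed = as.integer(seed))
  stopifnot(cfg$p_cutoff_analysis > 0, cfg$p_cutoff_analysis <= 1,
            cfg$p_cutoff_report > 0, cfg$p_cutoff_report <= 1,
            cfg$sd_threshold >= 0, cfg$mi_bins >= 2,
            cfg$module_min_size >= 3, cfg$max_network_genes >= 2)
  structure(cfg, class = "PipelineConfig")
}

#' Load a pipeline configuration from a YAML/JSON key-value file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#'
#' @param path YAML (or JSON, a YAML subset) file of configuration keys.
#' @return A \code{PipelineConfig}.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")))
  do.call(pipeline_config, vals)
}

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[cdtox] ", fmt), ...))
}

#' Run the per-block analysis chain
#'
#' \code{filter_present} -> \code{fit_dose_regression} -> \code{select_genes}
#' (both directions at the reporting cutoff plus the broad analysis set) ->
#' optional probe collapsing -> optional gene-set enrichment. Artifacts are
#' written under \code{out_dir} when given.
#'
#' @param study An \code{ExpressionStudy} (unfiltered; the present-call
#'   filter is applied here).
#' @param block Exposure duration in days (e.g. 1 or 13).
#' @param config A \code{\link{pipeline_config}}.
#' @param annotation Optional probe annotation (enables gene-level collapse).
#' @param gene_sets Optional \code{GeneSetCollection} (enables enrichment;
#'   requires \code{annotation}).
#' @param out_dir Optional output directory for stage TSVs.
#' @param verbose Log stage progress to stderr.
#' @return List with the stage objects (\code{regression},
#'   \code{selection_*}, \code{collapsed}, \code{enrichment}) and a
#'   \code{report} fragment of counts.
#' @export
run_block_analysis <- function(study, block, config = pipeline_config(),
                               annotation = NULL, gene_sets = NULL,
                               out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(study, "ExpressionStudy"),
            inherits(config, "PipelineConfig"))
  present <- filter_present(study)
  stage_log(verbose, "block %g: %d / %d probes present in >= 1 sample",
            block, n_probes(present), n_probes(study))
  res <- fit_dose_regression(present, block, config$regression_scale)
  sel_analysis <- select_genes(res, config$p_cutoff_analysis, "any")
  sel_pos <- select_genes(res, config$p_cutoff_report, "positive")
  sel_neg <- select_genes(res, config$p_cutoff_report, "negative")
  stage_log(verbose,
            "block %g: %d significant at P < %g; %d positive / %d negative at P < %g",
            block, sel_analysis$n_selected, config$p_cutoff_analysis,
            sel_pos$n_selected, sel_neg$n_selected, config$p_cutoff_report)
  collapsed <- NULL; enrichment <- NULL
  if (!is.null(annotation)) {
    collapsed <- collapse_probes(res, annotation, config$collapse_rule)
    if (!is.null(gene_sets)) {
      gene_sel <- collapsed$symbol[collapsed$p_value < config$p_cutoff_analysis]
      enrichment <- enrich_gene_sets(gene_sel, collapsed$symbol, gene_sets)
      stage_log(verbose, "block %g: %d gene set(s) tested, %d at q < 0.05",
                block, nrow(enrichment), sum(enrichment$q_value < 0.05))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pre <- file.path(out_dir, sprintf("block%g", block))
    write_regression_table(res, paste0(pre, "_regression.tsv"), annotation)
    utils::write.table(pvalue_histogram(res),
                       paste0(pre, "_pvalue_histogram.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(enrichment))
      utils::write.table(enrichment, paste0(pre, "_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(block = block,
       regression = res,
       selection_analysis = sel_analysis,
       selection_positive = sel_pos,
       selection_negative = sel_neg,
       collapsed = collapsed,
       enrichment = enrichment,
       report = list(block = block,
                     n_probes_input = n_probes(study),
                     n_present = n_probes(present),
                     n_significant_analysis = sel_analysis$n_selected,
                     n_positive_report = sel_pos$n_selected,
                     n_negative_report = sel_neg$n_selected,
                     n_enriched_sets_q05 = if (is.null(enrichment)) NA_integer_
                       else sum(enrichment$q_value < 0.05)))
}

#' Run the full pooled analysis
#'
#' Both blocks' chains, the positive- and negative-list overlap tests over
#' the present-probe universe, pooled grand-mean centering + SD filtering,
#' Ward clustering of the samples, and the MI network chain on the retained
#' genes. A consolidated run report is returned and, when \code{out_dir} is
#' given, written as JSON and as human-readable text alongside the stage
#' artifacts.
#'
#' @inheritParams run_block_analysis
#' @param blocks The two exposure durations (default \code{c(1, 13)}).
#' @return List with \code{blocks} (per-block results),
#'   \code{overlap_positive}, \code{overlap_negative}, \code{centered},
#'   \code{sample_hclust}, \code{sample_clusters_k2}, \code{mi},
#'   \code{modules} and \code{report}.
#' @export
run_combined_analysis <- function(study, config = pipeline_config(),
                                  annotation = NULL, gene_sets = NULL,
                                  blocks = c(1, 13), out_dir = NULL,
                                  verbose = FALSE) {
  stopifnot(length(blocks) == 2)
  blk <- lapply(blocks, function(b)
    run_block_analysis(study, b, config, annotation, gene_sets,
                       out_dir = out_dir, verbose = verbose))
  names(blk) <- paste0("block", blocks)
  present <- filter_present(study)
  universe <- rownames(present$signal)
  ov_pos <- overlap_significance(blk[[1]]$selection_positive$ids,
                                 blk[[2]]$selection_positive$ids, universe)
  ov_neg <- overlap_significance(blk[[1]]$selection_negative$ids,
                                 blk[[2]]$selection_negative$ids, universe)
  stage_log(verbose, "overlap: positive r = %d (P = %.3g), negative r = %d (P = %.3g)",
            ov_pos$r, ov_pos$p_value, ov_neg$r, ov_neg$p_value)

  centered <- center_and_filter(present, config$sd_threshold,
                                config$cluster_scale, config$cluster_center)
  stage_log(verbose, "pooled: %d genes with SD > %g", nrow(centered$matrix),
            config$sd_threshold)
  sample_hc <- NULL; k2 <- NULL; mi <- NULL; modules <- NULL
  if (nrow(centered$matrix) >= 2) {
    sample_hc <- ward_cluster(pearson_dissimilarity(centered, "samples"),
                              config$linkage)
    k2 <- cut_tree(sample_hc, 2)
    net_m <- centered$matrix
    if (nrow(net_m) > config$max_network_genes) {
      keep <- order(-centered$gene_sd[centered$mask])[
        seq_len(config$max_network_genes)]
      net_m <- net_m[sort(keep), , drop = FALSE]
    }
    if (nrow(net_m) > config$module_min_size) {
      mi <- mi_adjacency(net_m, config$mi_bins, config$mi_scheme)
      modules <- detect_modules(mi, config$module_min_size,
                                config$n_candidate_cuts,
                                config$module_linkage,
                                config$mi_distance_mode)
      stage_log(verbose, "network: %d gene(s), %d module(s)",
                nrow(net_m), length(modules))
    }
  }
  report <- list(
    config = unclass(config),
    blocks = lapply(blk, `[[`, "report"),
    overlap_positive = list(M = ov_pos$M, K = ov_pos$K, n = ov_pos$n,
                            r = ov_pos$r, expected = ov_pos$expected,
                            p_value = ov_pos$p_value),
    overlap_negative = list(M = ov_neg$M, K = ov_neg$K, n = ov_neg$n,
                            r = ov_neg$r, expected = ov_neg$expected,
                            p_value = ov_neg$p_value),
    n_high_sd_genes = nrow(centered$matrix),
    n_modules = length(modules),
    top_module = if (length(modules))
      list(size = length(modules[[1]]$members),
           separation = modules[[1]]$separation,
           members = modules[[1]]$members) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_overlap_result(ov_pos, file.path(out_dir, "overlap_positive.tsv"))
    write_overlap_result(ov_neg, file.path(out_dir, "overlap_negative.tsv"))
    if (!is.null(sample_hc))
      dendrogram_newick(sample_hc, file.path(out_dir, "sample_dendrogram.nwk"))
    if (!is.null(mi))
      write_network(mi, modules, file.path(out_dir, "network_edges.tsv"),
                    file.path(out_dir, "network_modules.tsv"),
                    distance_mode = config$mi_distance_mode)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(format_run_report(report), file.path(out_dir, "run_report.txt"))
  }
  list(blocks = blk, overlap_positive = ov_pos, overlap_negative = ov_neg,
       centered = centered, sample_hclust = sample_hc,
       sample_clusters_k2 = k2, mi = mi, modules = modules, report = report)
}

#' Format a run report as human-readable lines
#'
#' @param report The \code{report} element returned by
#'   \code{\link{run_combined_analysis}}.
#' @return Character vector of report lines.
#' @export
format_run_report <- function(report) {
  ln <- c("cdtox run report", "=================")
  for (b in report$blocks)
    ln <- c(ln, sprintf(
      "block %g d: %d/%d present; %d sig (analysis cutoff); %d pos / %d neg (report cutoff)",
      b$block, b$n_present, b$n_probes_input, b$n_significant_analysis,
      b$n_positive_report, b$n_negative_report))
  for (nm in c("overlap_positive", "overlap_negative")) {
    o <- report[[nm]]
    ln <- c(ln, sprintf("%s: r = %d of (%d x %d) in M = %d, expected %.2f, P = %.3g",
                        nm, o$r, o$K, o$n, o$M, o$expected, o$p_value))
  }
  ln <- c(ln, sprintf("high-SD genes: %d; modules: %d", report$n_high_sd_genes,
                      report$n_modules))
  if (!is.null(report$top_module))
    ln <- c(ln, sprintf("top module: %d genes, separation %.3f (%s)",
                        report$top_module$size, report$top_module$separation,
                        paste(report$top_module$members, collapse = ", ")))
  ln
}
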