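# End-to-end pipeline: similarity -> soft threshold -> adjacency -> TOM ->
# average-linkage tree -> dynamic cut -> optional refinement, with a
# manifest that makes every run replayable.

#' Pipeline configuration
#'
#' Collects the tunable settings of the full pipeline.  Every default
#' matches the corresponding function's default, so
#' `run_pipeline(expr, pipeline_config())` is the canonical analysis.
#'
#' @param correlation_method `"distance_correlation"` or
#'   `"absolute_pearson"`.
#' @param cv_threshold optional CV cutoff; `NULL` (default) skips the gene
#'   filter (inputs already reduced to informative genes).
#' @param require_above_mean_intensity passed to [cv_filter()] when
#'   filtering is enabled.
#' @param candidate_betas,r2_cut soft-threshold scan, see
#'   [pick_soft_threshold()].
#' @param min_module_size,cut_height dynamic cut settings, see
#'   [dynamic_tree_cut()].
#' @param refinement character vector naming the refiners to run:
#'   any of `"k_module"`, `"k_eigengene"`; empty for none.
#' @param max_iter refinement iteration cap.
#' @param reassign_grey refine grey genes too, see [k_module_refine()].
#' @param include_self_in_denominator mean-connectivity denominator
#'   convention, see [mean_connectivity()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(correlation_method = "distance_correlation",
                            cv_threshold = NULL,
                            require_above_mean_intensity = TRUE,
                            candidate_betas = 1:20,
                            r2_cut = 0.85,
                            min_module_size = 30,
                            cut_height = 0.99,
                            refinement = c("k_module", "k_eigengene"),
                            max_iter = 100,
                            reassign_grey = FALSE,
                            include_self_in_denominator = TRUE) {
  structure(list(
    correlation_method = match.arg(correlation_method,
                                   c("distance_correlation",
                                     "absolute_pearson")),
    cv_threshold = cv_threshold,
    require_above_mean_intensity = require_above_mean_intensity,
    candidate_betas = candidate_betas,
    r2_cut = r2_cut,
    min_module_size = min_module_size,
    cut_height = cut_height,
    refinement = refinement,
    max_iter = max_iter,
    reassign_grey = reassign_grey,
    include_self_in_denominator = include_self_in_denominator
  ), class = "pipeline_config")
}

# network-construction stages shared by run_pipeline and the stability
# module; returns all intermediates.
pipeline_stages <- function(expr, config = pipeline_config()) {
  expr <- expression_matrix(expr)
  if (!is.null(config$cv_threshold)) {
    expr <- cv_filter(expr, config$cv_threshold,
                      config$require_above_mean_intensity)
  }
  sim <- pairwise_similarity(expr, config$correlation_method)
  sft <- pick_soft_threshold(sim, config$candidate_betas, config$r2_cut,
                             n_samples = ncol(expr))
  adj <- adjacency(sim, sft$beta)
  tom <- tom_similarity(adj)
  diss <- tom_dissimilarity(tom)
  tree <- average_linkage_tree(diss)
  partition <- dynamic_tree_cut(tree, config$min_module_size,
                                config$cut_height)
  list(expr = expr, similarity = sim, sft = sft, adjacency = adj,
       tom = tom, dissimilarity = diss, tree = tree, partition = partition)
}

#' Run the full co-expression module pipeline
#'
#' Executes, in order: optional CV gene filter, pairwise similarity,
#' soft-threshold selection, adjacency, TOM, average-linkage clustering,
#' dynamic tree cut, and the configured refinement algorithms.  All
#' intermediates are returned; when `out_dir` is given, partitions
#' (pre- and post-refinement), the soft-threshold diagnostic table, the
#' refinement logs, a metrics report, and a manifest (config + input +
#' package version) are written there, and rerunning from the manifest
#' reproduces identical outputs.
#'
#' @param expr expression matrix, or the path of a delimited expression
#'   file (read with [read_expression()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory, created if missing.
#' @return a `pipeline_result` list: the stages of [pipeline_stages] plus
#'   `refinements` (per-method `refinement_result`s), `metrics` (per-method
#'   silhouette, Dunn, proportion of genes in their highest-connectivity
#'   module, change rate vs the unrefined partition, iterations), and
#'   `manifest`.
#' @export
run_pipeline <- function(expr, config = pipeline_config(), out_dir = NULL) {
  input_path <- NULL
  if (is.character(expr) && length(expr) == 1L) {
    input_path <- expr
    expr <- read_expression(expr)
  }
  st <- pipeline_stages(expr, config)

  refinements <- list()
  if ("k_module" %in% config$refinement) {
    refinements$k_module <- k_module_refine(
      st$partition, st$adjacency, max_iter = config$max_iter,
      reassign_grey = config$reassign_grey,
      include_self_in_denominator = config$include_self_in_denominator)
  }
  if ("k_eigengene" %in% config$refinement) {
    refinements$k_eigengene <- k_eigengene_refine(
      st$expr, st$partition, max_iter = config$max_iter,
      reassign_grey = config$reassign_grey)
  }

  partitions <- c(list(wgcna = st$partition),
                  lapply(refinements, `[[`, "partition"))
  metrics <- do.call(rbind, lapply(names(partitions), function(m) {
    p <- partitions[[m]]
    can_score <- length(module_ids(p)) >= 2
    data.frame(
      method = m,
      n_modules = length(module_ids(p)),
      n_grey = sum(p == 0L),
      silhouette = if (can_score) silhouette_mean(st$dissimilarity, p) else NA,
      dunn = if (can_score) dunn_index(st$dissimilarity, p) else NA,
      proportion_highest_mc = if (length(module_ids(p)) >= 1) {
        proportion_highest_mc(p, st$adjacency,
                              config$include_self_in_denominator)
      } else NA,
      change_rate = change_rate(st$partition, p),
      iterations = if (m == "wgcna") 0L else refinements[[m]]$iterations,
      stringsAsFactors = FALSE)
  }))

  manifest <- list(
    package = "kmodule",
    version = as.character(utils::packageVersion("kmodule")),
    input = input_path,
    config = unclass(config),
    beta = st$sft$beta,
    sft_r2 = st$sft$sft_r2
  )
  result <- c(st, list(refinements = refinements, metrics = metrics,
                       manifest = manifest))
  class(result) <- "pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(input_path)) {
      input_path <- file.path(out_dir, "input_expression.tsv")
      write_expression(expr, input_path)
      manifest$input <- result$manifest$input <- input_path
    }
    utils::write.table(st$sft$fit_table,
                       file.path(out_dir, "soft_threshold.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_partition(st$partition, file.path(out_dir, "partition_wgcna.tsv"))
    for (m in names(refinements)) {
      write_partition(refinements[[m]]$partition,
                      file.path(out_dir, paste0("partition_", m, ".tsv")))
      utils::write.table(
        data.frame(iteration = seq_along(refinements[[m]]$changes_per_iteration),
                   n_changes = refinements[[m]]$changes_per_iteration),
        file.path(out_dir, paste0("refinement_log_", m, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' Replay a pipeline run from its manifest
#'
#' Reads a `manifest.json` written by [run_pipeline()] and re-executes the
#' run with the recorded input and configuration; with the same inputs this
#' reproduces identical outputs.
#'
#' @param manifest_path path to a manifest.json.
#' @param out_dir optional output directory for the replayed run.
#' @return a `pipeline_result`, as [run_pipeline()].
#' @export
rerun_from_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- man$config
  config <- pipeline_config(
    correlation_method = cfg$correlation_method,
    cv_threshold = if (length(cfg$cv_threshold) == 0) NULL else cfg$cv_threshold,
    require_above_mean_intensity = cfg$require_above_mean_intensity,
    candidate_betas = cfg$candidate_betas,
    r2_cut = cfg$r2_cut,
    min_module_size = cfg$min_module_size,
    cut_height = cfg$cut_height,
    refinement = cfg$refinement %||% character(0),
    max_iter = cfg$max_iter,
    reassign_grey = cfg$reassign_grey,
    include_self_in_denominator = cfg$include_self_in_denominator)
  run_pipeline(man$input, config, out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Co-expression module pipeline result\n")
  cat("  genes:", nrow(x$expr), " samples:", ncol(x$expr), "\n")
  cat("  method:", x$manifest$config$correlation_method,
      " beta:", x$manifest$beta,
      " (signed R^2 =", signif(x$manifest$sft_r2, 3), ")\n")
  cat("  metrics:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
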