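# Module preservation between partitions built from independent sample
# splits: overlap counts and one-sided Fisher's exact tests, computed in
# log space so that overlaps with p-values around 1e-300 and far beyond
# remain finite on the -log10 scale.

#' Module overlap table with one-sided Fisher's exact significance
#'
#' For every pair of modules (A_i, B_j) from two partitions of the same
#' gene set, counts the overlap o and computes the one-sided Fisher's exact
#' p-value for enrichment, i.e. the hypergeometric upper tail
#' P(X >= o) with population n, draws |A_i| and successes |B_j|.  The
#' p-values are evaluated on the log scale and reported as -log10(p)
#' ("preservation significance"), capped at 1e6.  Grey (label 0) rows and
#' columns are included in the table for display but flagged, and are
#' excluded from [preservation_count()].
#'
#' @param part_a,part_b module partitions over the identical gene set.
#' @return a `preservation_table`: list with `modules_a`, `modules_b`
#'   (label vectors including grey where present), `overlap_counts`
#'   (integer matrix), `neg_log10_p` (matrix), and `grey_a`, `grey_b`
#'   (logical flags per row/column).
#' @export
overlap_fisher <- function(part_a, part_b) {
  if (length(part_a) != length(part_b) ||
      !setequal(names(part_a), names(part_b))) {
    stop("partitions cover different gene sets", call. = FALSE)
  }
  part_b <- part_b[names(part_a)]
  n <- length(part_a)
  la <- sort(unique(part_a))
  lb <- sort(unique(part_b))
  counts <- matrix(0L, length(la), length(lb), dimnames = list(la, lb))
  for (i in seq_along(la)) {
    for (j in seq_along(lb)) {
      counts[i, j] <- sum(part_a == la[i] & part_b == lb[j])
    }
  }
  size_a <- rowSums(counts)
  size_b <- colSums(counts)
  nlp <- matrix(0, length(la), length(lb), dimnames = list(la, lb))
  for (i in seq_along(la)) {
    for (j in seq_along(lb)) {
      o <- counts[i, j]
      if (o == 0) { nlp[i, j] <- 0; next }
      logp <- stats::phyper(o - 1, size_b[j], n - size_b[j], size_a[i],
                            lower.tail = FALSE, log.p = TRUE)
      nlp[i, j] <- min(-logp / log(10), 1e6)
    }
  }
  structure(
    list(modules_a = la, modules_b = lb,
         overlap_counts = counts, neg_log10_p = nlp,
         grey_a = la == 0L, grey_b = lb == 0L,
         n_genes = n),
    class = "preservation_table")
}

#' @export
print.preservation_table <- function(x, digits = 1, ...) {
  cat("Module preservation over", x$n_genes, "genes\n")
  cat("overlap counts (rows: partition A, cols: partition B; 0 = grey):\n")
  print(x$overlap_counts)
  cat("preservation significance, -log10 Fisher p:\n")
  print(round(x$neg_log10_p, digits))
  invisible(x)
}

#' Count preserved modules
#'
#' A module of partition A counts as preserved when its best overlap
#' significance - the maximum -log10 Fisher p over the non-grey modules of
#' partition B - strictly exceeds `significance_cut`.  The default cut of
#' 50 (p < 1e-50) marks strongly preserved modules.
#'
#' @param table a `preservation_table` from [overlap_fisher()].
#' @param significance_cut positive -log10(p) threshold, default 50.
#' @return integer count of preserved non-grey modules of partition A.
#' @export
preservation_count <- function(table, significance_cut = 50) {
  stopifnot(inherits(table, "preservation_table"), significance_cut > 0)
  rows <- which(!table$grey_a)
  cols <- which(!table$grey_b)
  if (length(rows) == 0 || length(cols) == 0) return(0L)
  best <- apply(table$neg_log10_p[rows, cols, drop = FALSE], 1, max)
  sum(best > significance_cut)
}

#' Module stability from precomputed sample parts
#'
#' Runs the full network pipeline (similarity, soft threshold, adjacency,
#' TOM, average-linkage tree, dynamic cut, optional refinement)
#' independently on each expression part, then computes
#' [preservation_count()] for every unordered pair of parts and each
#' requested method.  Returns a per-method summary (mean and range over
#' part pairs, both directions of each pair) plus the per-part partitions.
#'
#' @param parts list of >= 2 expression matrices over the same genes
#'   (e.g. from [split_samples()]).
#' @param config pipeline settings from [pipeline_config()].
#' @param significance_cut preservation cut, default 50.
#' @return list with `summary` (data frame: method, mean, min, max),
#'   `counts` (per-method list of per-comparison counts), and `partitions`.
#' @export
stability_from_parts <- function(parts, config = pipeline_config(),
                                 significance_cut = 50) {
  stopifnot(is.list(parts), length(parts) >= 2)
  methods <- config$refinement
  partitions <- lapply(parts, function(e) {
    st <- pipeline_stages(e, config)
    out <- list(wgcna = st$partition)
    if ("k_module" %in% methods) {
      out$k_module <- k_module_refine(
        st$partition, st$adjacency, max_iter = config$max_iter,
        reassign_grey = config$reassign_grey,
        include_self_in_denominator = config$include_self_in_denominator
      )$partition
    }
    if ("k_eigengene" %in% methods) {
      out$k_eigengene <- k_eigengene_refine(
        e, st$partition, max_iter = config$max_iter,
        reassign_grey = config$reassign_grey)$partition
    }
    out
  })
  all_methods <- names(partitions[[1]])
  pairs <- utils::combn(length(parts), 2, simplify = FALSE)
  counts <- lapply(all_methods, function(m) {
    unlist(lapply(pairs, function(p) {
      tab <- overlap_fisher(partitions[[p[1]]][[m]], partitions[[p[2]]][[m]])
      # count preserved modules of each side against the other
      c(preservation_count(tab, significance_cut),
        preservation_count(swap_preservation(tab), significance_cut))
    }))
  })
  names(counts) <- all_methods
  summary <- data.frame(
    method = all_methods,
    mean = vapply(counts, mean, numeric(1)),
    min = vapply(counts, min, numeric(1)),
    max = vapply(counts, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, counts = counts, partitions = partitions)
}

# transpose a preservation table (swap roles of the two partitions)
swap_preservation <- function(table) {
  structure(
    list(modules_a = table$modules_b, modules_b = table$modules_a,
         overlap_counts = t(table$overlap_counts),
         neg_log10_p = t(table$neg_log10_p),
         grey_a = table$grey_b, grey_b = table$grey_a,
         n_genes = table$n_genes),
    class = "preservation_table")
}

#' Split-sample module stability
#'
#' Randomly splits the samples into `n_parts` disjoint parts
#' ([split_samples()]) and delegates to [stability_from_parts()]: each part
#' is processed independently through the full pipeline and module
#' preservation is scored for every pair of parts and every method.  With
#' `n_parts = 2` this is the split-half design; with `n_parts = 5` the
#' five-fold design whose mean and range are the usual stability report.
#'
#' @param expr expression matrix.
#' @param n_parts number of sample parts, default 2.
#' @param seed integer seed for the random split.
#' @param config pipeline settings from [pipeline_config()].
#' @param significance_cut preservation cut, default 50.
#' @return as [stability_from_parts()], plus the `parts` sample split.
#' @export
split_stability <- function(expr, n_parts = 2, seed,
                            config = pipeline_config(),
                            significance_cut = 50) {
  parts <- split_samples(expr, n_parts, seed)
  res <- stability_from_parts(parts, config, significance_cut)
  res$parts <- lapply(parts, colnames)
  res
}
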