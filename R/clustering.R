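# Module detection: average-linkage hierarchical clustering on TOM
# dissimilarity, followed by a tree-based dynamic cut.
#
# A module partition is represented as a named integer vector: names are
# gene ids, values are module labels, and 0 is the distinguished "grey"
# label for unassigned genes.  Non-grey labels are 1..k in decreasing order
# of module size.

#' Construct and validate a module partition
#'
#' @param labels integer vector of module labels (0 = grey/unassigned),
#'   either named by gene id or accompanied by `gene_ids`.
#' @param gene_ids optional gene ids; defaults to `names(labels)`.
#' @return named integer vector of labels.
#' @export
module_partition <- function(labels, gene_ids = names(labels)) {
  if (is.null(gene_ids)) stop("gene ids are required for a partition", call. = FALSE)
  if (length(gene_ids) != length(labels)) {
    stop("labels and gene_ids differ in length", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in partition", call. = FALSE)
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 0)) {
    stop("labels must be non-negative integers (0 = grey)", call. = FALSE)
  }
  names(labels) <- as.character(gene_ids)
  labels
}

#' Module labels present in a partition (grey excluded)
#' @param partition named integer label vector.
#' @return sorted integer vector of non-grey module labels.
#' @export
module_ids <- function(partition) {
  sort(unique(partition[partition > 0L]))
}

#' Module sizes of a partition (grey excluded)
#' @param partition named integer label vector.
#' @return named integer vector of module sizes, indexed by module label.
#' @export
module_sizes <- function(partition) {
  ids <- module_ids(partition)
  stats::setNames(vapply(ids, function(m) sum(partition == m), integer(1)),
                  ids)
}

# Relabel non-grey modules as 1..k in decreasing size order; ties broken by
# the position of the module's first member gene.
relabel_by_size <- function(partition) {
  ids <- unique(partition[partition > 0L])
  if (length(ids) == 0) return(partition)
  size <- vapply(ids, function(m) sum(partition == m), integer(1))
  first <- vapply(ids, function(m) which(partition == m)[1], integer(1))
  ord <- ids[order(-size, first)]
  out <- partition
  for (i in seq_along(ord)) out[partition == ord[i]] <- i
  out
}

#' Average-linkage hierarchical clustering tree
#'
#' Builds the agglomerative average-linkage (UPGMA) dendrogram of a
#' dissimilarity matrix, as used on 1 - TOM.  Input must be square,
#' symmetric, non-negative, with zero diagonal.  The result is a standard
#' `hclust` object (merge table, heights, leaf order).
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal.
#' @return an object of class `hclust`.
#' @export
average_linkage_tree <- function(diss) {
  check_square_symmetric(diss, "dissimilarity matrix")
  if (min(diss) < 0) stop("dissimilarities must be non-negative", call. = FALSE)
  if (any(diag(unclass(diss)) != 0)) {
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  }
  stats::hclust(stats::as.dist(diss), method = "average")
}

#' Tree-based dynamic cut of a dendrogram into modules
#'
#' Cuts all merges above a height threshold, takes the resulting subtrees
#' as candidate branches, accepts branches with at least `min_module_size`
#' leaves as modules, and assigns every other gene to grey (label 0).
#' Modules are relabeled 1..k in decreasing size order (ties broken by the
#' first member's position).
#'
#' @param tree `hclust` object from [average_linkage_tree()].
#' @param min_module_size smallest branch accepted as a module, default 30.
#' @param cut_height cut threshold.  Interpreted as a fraction of the
#'   maximum merge height (default 0.99) unless `absolute_height` is set.
#' @param absolute_height treat `cut_height` as an absolute height.
#' @return a module partition (named integer vector, 0 = grey).
#' @export
dynamic_tree_cut <- function(tree, min_module_size = 30, cut_height = 0.99,
                             absolute_height = FALSE) {
  stopifnot(inherits(tree, "hclust"))
  stopifnot(min_module_size >= 1)
  h <- if (absolute_height) cut_height else {
    stopifnot(cut_height > 0, cut_height <= 1)
    cut_height * max(tree$height)
  }
  branches <- stats::cutree(tree, h = h)
  sizes <- table(branches)
  keep <- as.integer(names(sizes)[sizes >= min_module_size])
  labels <- ifelse(branches %in% keep, branches, 0L)
  relabel_by_size(module_partition(labels, tree$labels %||% names(branches)))
}

#' Write a module partition as two-column TSV
#' @param partition named integer label vector.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(gene_id = names(partition), module_label = as.integer(partition),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a module partition written by [write_partition()]
#' @param path path to the TSV file.
#' @return named integer label vector.
#' @export
read_partition <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  module_partition(tab$module_label, tab$gene_id)
}
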