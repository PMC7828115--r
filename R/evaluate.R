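# Cluster-validity metrics and refinement diagnostics.
#
# Silhouette and Dunn are computed on whatever dissimilarity the caller
# supplies; the pipeline uses TOM dissimilarity (1 - TOM), the same matrix
# the clustering itself used.  Grey genes are unassigned by definition and
# are excluded from both metrics.

#' Mean silhouette width of a partition
#'
#' Standard silhouette on a dissimilarity matrix: for each non-grey gene,
#' a = mean dissimilarity to the other members of its own module, b = the
#' minimum over other modules of the mean dissimilarity to that module's
#' members, and s = (b - a) / max(a, b).  Genes in singleton modules
#' contribute s = 0.  Returns the mean over all non-grey genes, a value in
#' \[-1, 1\]; values near 1 indicate well-separated modules and values near
#' 0 indicate no meaningful separation.
#'
#' @param diss symmetric dissimilarity matrix over all genes.
#' @param partition module partition; needs >= 2 non-grey modules.
#' @return mean silhouette width.
#' @export
silhouette_mean <- function(diss, partition) {
  check_square_symmetric(diss, "dissimilarity matrix")
  if (nrow(diss) != length(partition)) {
    stop("dissimilarity and partition differ in gene count", call. = FALSE)
  }
  ids <- module_ids(partition)
  if (length(ids) < 2) stop("silhouette needs >= 2 non-grey modules", call. = FALSE)
  d <- unclass(diss)
  keep <- partition > 0L
  d <- d[keep, keep, drop = FALSE]
  lab <- partition[keep]
  n <- length(lab)
  # mean dissimilarity of every gene to every module
  member <- vapply(ids, function(m) as.numeric(lab == m), numeric(n))
  sizes <- colSums(member)
  md <- (d %*% member) / matrix(sizes, n, length(ids), byrow = TRUE)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- match(lab[i], ids)
    if (sizes[own] == 1) { s[i] <- 0; next }
    a <- md[i, own] * sizes[own] / (sizes[own] - 1)  # exclude self (d_ii = 0)
    b <- min(md[i, -own])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Dunn index of a partition
#'
#' Ratio of the smallest dissimilarity between genes in different modules
#' to the largest dissimilarity within a module.  Larger is better.  Grey
#' genes are excluded.
#'
#' @param diss symmetric dissimilarity matrix over all genes.
#' @param partition module partition; needs >= 2 non-grey modules.
#' @return a non-negative number.
#' @export
dunn_index <- function(diss, partition) {
  check_square_symmetric(diss, "dissimilarity matrix")
  if (nrow(diss) != length(partition)) {
    stop("dissimilarity and partition differ in gene count", call. = FALSE)
  }
  if (length(module_ids(partition)) < 2) {
    stop("Dunn index needs >= 2 non-grey modules", call. = FALSE)
  }
  d <- unclass(diss)
  keep <- partition > 0L
  d <- d[keep, keep, drop = FALSE]
  lab <- partition[keep]
  same <- outer(lab, lab, "==")
  diag(same) <- NA                       # ignore self-pairs
  intra <- d[same & !is.na(same)]
  inter <- d[!same & !is.na(same)]
  max_intra <- if (length(intra) == 0) 0 else max(intra)
  if (max_intra == 0) {
    stop("largest intra-module dissimilarity is zero; Dunn index undefined",
         call. = FALSE)
  }
  min(inter) / max_intra
}

#' Proportion of genes in their highest-mean-connectivity module
#'
#' For every non-grey gene, checks whether its own module attains the
#' maximum mean connectivity over all non-grey modules (ties count as
#' attaining it), and returns the fraction of genes for which this holds.
#' A converged k-module refinement yields exactly 1 by construction; the
#' shortfall from 1 measures how far a partition is from the k-module
#' fixed point.
#'
#' @param partition module partition.
#' @param adj adjacency matrix aligned with the partition.
#' @param include_self_in_denominator as in [mean_connectivity()].
#' @return a fraction in \[0, 1\].
#' @export
proportion_highest_mc <- function(partition, adj,
                                  include_self_in_denominator = TRUE) {
  check_square_symmetric(adj, "adjacency matrix")
  ids <- module_ids(partition)
  if (length(ids) == 0) stop("no non-grey modules", call. = FALSE)
  mc <- mean_connectivity_matrix(adj, partition, ids,
                                 include_self_in_denominator)
  nongrey <- which(partition > 0L)
  own <- match(partition[nongrey], ids)
  hit <- vapply(seq_along(nongrey), function(r) {
    row <- mc[nongrey[r], ]
    row[own[r]] >= max(row)
  }, logical(1))
  mean(hit)
}

#' Fraction of genes whose module label differs between two partitions
#'
#' @param before,after module partitions over the identical gene set.
#' @return a fraction in \[0, 1\].
#' @export
change_rate <- function(before, after) {
  if (length(before) != length(after) ||
      !setequal(names(before), names(after))) {
    stop("partitions cover different gene sets", call. = FALSE)
  }
  after <- after[names(before)]
  mean(before != after)
}
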