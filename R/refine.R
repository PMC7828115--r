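# Module refinement: the k-module algorithm (reassignment by mean
# connectivity) and the k-eigengene comparator (reassignment by correlation
# with module eigengenes).
#
# Both refiners use synchronous (batch) updates: within one iteration every
# gene's target module is computed against the memberships frozen at the
# start of the iteration, so results do not depend on gene order.  Ties in
# any argmax are broken toward the lowest module label.

# n x k matrix of mean connectivities of every gene to every module in
# `ids`, given start-of-iteration labels.  The adjacency diagonal is zero,
# so a member gene's self-term contributes 0 to the sum while the
# denominator n_m still counts it (the literal mean-connectivity
# definition).  `include_self_in_denominator = FALSE` switches to the
# (n_m - 1) denominator for a gene's own module; a singleton own module then
# scores 0.
mean_connectivity_matrix <- function(adj, labels, ids,
                                     include_self_in_denominator = TRUE) {
  a <- unclass(adj)
  diag(a) <- 0
  member <- vapply(ids, function(m) as.numeric(labels == m),
                   numeric(length(labels)))        # n x k indicator
  sums <- a %*% member
  sizes <- colSums(member)
  denom <- matrix(sizes, nrow = nrow(a), ncol = length(ids), byrow = TRUE)
  if (!include_self_in_denominator) {
    denom <- denom - member
    denom[denom < 1] <- Inf                        # own singleton: score 0
  }
  mc <- sums / denom
  dimnames(mc) <- list(rownames(a), ids)
  mc
}

#' Mean connectivity of one gene to one module
#'
#' The mean connectivity of gene g_i to module m is the average adjacency
#' between g_i and the member genes of m: (1 / n_m) * sum over g_j in S_m
#' of a_ij, where n_m is the module size.  When g_i itself belongs to m,
#' its self-term contributes 0 (self-adjacency is excluded) while n_m still
#' counts it; set `include_self_in_denominator = FALSE` for the (n_m - 1)
#' variant.
#'
#' @param gene gene id (character) or row index.
#' @param module non-grey module label.
#' @param adj adjacency matrix.
#' @param partition module partition aligned with `adj`.
#' @param include_self_in_denominator see description; default `TRUE`.
#' @return a single non-negative number.
#' @export
mean_connectivity <- function(gene, module, adj, partition,
                              include_self_in_denominator = TRUE) {
  check_square_symmetric(adj, "adjacency matrix")
  module <- as.integer(module)
  if (module <= 0) stop("module must be a non-grey label", call. = FALSE)
  if (!any(partition == module)) {
    stop("module ", module, " is empty", call. = FALSE)
  }
  i <- if (is.character(gene)) match(gene, names(partition)) else as.integer(gene)
  if (is.na(i) || i < 1 || i > length(partition)) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  mc <- mean_connectivity_matrix(adj, partition, module,
                                 include_self_in_denominator)
  unname(mc[i, 1])
}

new_refinement_result <- function(partition, changes, converged, oscillation,
                                  retired, method) {
  structure(
    list(partition = partition,
         iterations = length(changes),
         changes_per_iteration = changes,
         converged = converged,
         oscillation_detected = oscillation,
         retired_modules = retired,
         method = method),
    class = "refinement_result")
}

#' @export
print.refinement_result <- function(x, ...) {
  cat("Refinement result (", x$method, ")\n", sep = "")
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  label changes per iteration:",
      paste(x$changes_per_iteration, collapse = ", "), "\n")
  if (x$oscillation_detected) cat("  oscillation detected\n")
  if (length(x$retired_modules)) {
    cat("  emptied module(s) retired:",
        paste(x$retired_modules, collapse = ", "), "\n")
  }
  sz <- module_sizes(x$partition)
  cat("  modules:", length(sz), " grey genes:", sum(x$partition == 0L), "\n")
  invisible(x)
}

# shared bookkeeping for both refiners: run `target_fun(labels, ids)`
# (returning the argmax module per eligible gene) until labels stop
# changing, a previously seen state recurs (oscillation), or max_iter.
refine_loop <- function(partition, max_iter, reassign_grey, target_fun,
                        method) {
  stopifnot(max_iter >= 1)
  labels <- partition
  eligible <- if (reassign_grey) rep(TRUE, length(labels)) else labels > 0L
  if (!any(labels > 0L)) stop("no non-grey module to refine", call. = FALSE)

  changes <- integer(0)
  oscillation <- FALSE
  retired <- integer(0)
  seen <- new.env(parent = emptyenv())
  assign(paste(labels, collapse = ","), TRUE, envir = seen)

  for (it in seq_len(max_iter)) {
    ids <- sort(unique(labels[labels > 0L]))
    target <- target_fun(labels, ids)
    new_labels <- labels
    new_labels[eligible] <- target[eligible]
    n_changed <- sum(new_labels != labels)
    changes <- c(changes, n_changed)

    emptied <- setdiff(ids, unique(new_labels[new_labels > 0L]))
    if (length(emptied) > 0) {
      warning("module(s) emptied during ", method, " refinement and retired: ",
              paste(emptied, collapse = ", "), call. = FALSE)
      retired <- c(retired, emptied)
    }

    labels <- new_labels
    if (n_changed == 0L) {
      return(new_refinement_result(labels, changes, TRUE, oscillation,
                                   retired, method))
    }
    key <- paste(labels, collapse = ",")
    if (exists(key, envir = seen, inherits = FALSE)) oscillation <- TRUE
    assign(key, TRUE, envir = seen)
  }
  new_refinement_result(labels, changes, FALSE, oscillation, retired, method)
}

#' k-module refinement of a partition
#'
#' Iteratively reassigns each gene to the module to which it has the
#' highest mean connectivity.  Each iteration computes, for every eligible
#' gene, its mean connectivity to every non-grey module using the
#' memberships frozen at the start of the iteration, moves each gene to the
#' argmax module (ties toward the lowest label), and counts label changes.
#' The loop stops when no label changes or after `max_iter` iterations.  At
#' convergence every refined gene sits in its highest-mean-connectivity
#' module - the algorithm's defining postcondition.
#'
#' Grey (label 0) genes are left untouched unless `reassign_grey` is set;
#' grey is never a target module.  The set of module labels is preserved
#' unless a module loses all members, in which case its id is retired with
#' a warning.
#'
#' @param partition initial module partition (e.g. from
#'   [dynamic_tree_cut()]).
#' @param adj adjacency matrix aligned with the partition's gene ids.
#' @param max_iter iteration cap, default 100.
#' @param reassign_grey also reassign grey genes into modules.  Default
#'   `FALSE`: unassigned genes stay outside the reassignment universe.
#' @param include_self_in_denominator use the full module size n_m as the
#'   mean-connectivity denominator even for the gene's own module (default);
#'   `FALSE` selects the (n_m - 1) variant.
#' @return a `refinement_result`: final partition, per-iteration change
#'   counts, convergence and oscillation flags, retired module ids.
#' @export
k_module_refine <- function(partition, adj, max_iter = 100,
                            reassign_grey = FALSE,
                            include_self_in_denominator = TRUE) {
  check_square_symmetric(adj, "adjacency matrix")
  if (nrow(adj) != length(partition)) {
    stop("adjacency and partition differ in gene count", call. = FALSE)
  }
  target_fun <- function(labels, ids) {
    mc <- mean_connectivity_matrix(adj, labels, ids,
                                   include_self_in_denominator)
    ids[max.col(mc, ties.method = "first")]
  }
  refine_loop(partition, max_iter, reassign_grey, target_fun, "k-module")
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene x sample expression submatrix: genes are standardized to zero mean
#' and unit variance, and the eigengene is the first right singular vector
#' (a unit-norm score vector over samples).  The proportion of the module's
#' (standardized) expression variance captured by the eigengene is reported
#' alongside.  The eigengene's sign is fixed so that it correlates
#' non-negatively with the module's mean standardized expression profile.
#'
#' @param expr expression matrix.
#' @param partition module partition over the same genes.
#' @return an `eigengene_set`: list with `eigengenes` (samples x modules
#'   matrix, columns named by module label), `variance_proportion` (named
#'   vector in \[0, 1\]), and `module_ids`.
#' @export
module_eigengene <- function(expr, partition) {
  expr <- expression_matrix(expr)
  if (nrow(expr) != length(partition) ||
      !all(rownames(expr) == names(partition))) {
    stop("expression matrix and partition gene ids do not match", call. = FALSE)
  }
  ids <- module_ids(partition)
  if (length(ids) == 0) stop("no non-grey modules", call. = FALSE)
  eg <- matrix(NA_real_, nrow = ncol(expr), ncol = length(ids),
               dimnames = list(colnames(expr), ids))
  vp <- stats::setNames(numeric(length(ids)), ids)
  for (j in seq_along(ids)) {
    sub <- expr[partition == ids[j], , drop = FALSE]
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0)) {
      stop("module ", ids[j], " contains constant gene(s): ",
           paste(rownames(sub)[sds == 0], collapse = ", "), call. = FALSE)
    }
    z <- t(scale(t(sub)))                       # genes standardized
    sv <- svd(z)
    e <- sv$v[, 1]
    if (sum(colMeans(z) * e) < 0) e <- -e       # sign: follow mean profile
    eg[, j] <- e
    vp[j] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(list(eigengenes = eg, variance_proportion = vp, module_ids = ids),
            class = "eigengene_set")
}

#' k-eigengene refinement of a partition
#'
#' Comparator to [k_module_refine()]: each iteration recomputes the module
#' eigengenes from the current memberships and reassigns every eligible
#' gene to the module whose eigengene it correlates with most strongly in
#' absolute value, argmax_j |cor(g_i, eg_j)| (Pearson; ties toward the
#' lowest label).  Stops on zero changes or at `max_iter`.  Because the
#' centroids move with the memberships, this refiner can cycle: when a
#' previously seen label vector recurs without convergence,
#' `oscillation_detected` is set (the run still continues to `max_iter`).
#'
#' A module reduced to a single gene uses that gene's standardized profile
#' as its eigengene; an emptied module is retired with a warning.
#'
#' @param expr expression matrix.
#' @param partition initial module partition.
#' @param max_iter iteration cap, default 100.
#' @param reassign_grey also reassign grey genes; default `FALSE`.
#' @return a `refinement_result` (see [k_module_refine()]).
#' @export
k_eigengene_refine <- function(expr, partition, max_iter = 100,
                               reassign_grey = FALSE) {
  expr <- expression_matrix(expr)
  if (nrow(expr) != length(partition)) {
    stop("expression matrix and partition differ in gene count", call. = FALSE)
  }
  target_fun <- function(labels, ids) {
    eg <- matrix(NA_real_, nrow = ncol(expr), ncol = length(ids))
    for (j in seq_along(ids)) {
      sub <- expr[labels == ids[j], , drop = FALSE]
      if (nrow(sub) == 1L) {
        x <- drop(sub)
        if (stats::sd(x) == 0) {
          stop("module ", ids[j], " reduced to a constant gene", call. = FALSE)
        }
        eg[, j] <- (x - mean(x)) / stats::sd(x) / sqrt(length(x) - 1)
      } else {
        es <- module_eigengene(expr[labels == ids[j], , drop = FALSE],
                               module_partition(rep(1L, nrow(sub)),
                                                rownames(sub)))
        eg[, j] <- es$eigengenes[, 1]
      }
    }
    ac <- abs(suppressWarnings(stats::cor(t(expr), eg)))
    ac[!is.finite(ac)] <- -Inf
    ids[max.col(ac, ties.method = "first")]
  }
  refine_loop(partition, max_iter, reassign_grey, target_fun, "k-eigengene")
}
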