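# Gene-gene similarity: distance correlation (default) or absolute Pearson.
#
# Distance correlation is implemented as the original V-statistic: pairwise
# Euclidean distance matrices are double-centered, dCov^2 is the mean of the
# elementwise product of the centered matrices, and
# dCor = dCov / sqrt(dVar_x * dVar_y).  This captures nonlinear as well as
# linear dependence and is always in [0, 1], so the resulting network is
# unsigned.  Cost is O(m^2) per gene pair and O(n^2 m^2) for the full
# similarity matrix of n genes over m samples.

# double-centered Euclidean distance matrix of a univariate sample
double_center <- function(x) {
  d <- abs(outer(x, x, "-"))
  rm_ <- rowMeans(d)
  d - outer(rm_, rep(1, length(x))) - outer(rep(1, length(x)), rm_) + mean(d)
}

#' Distance correlation of two vectors
#'
#' Computes the (biased, V-statistic) distance correlation of Szekely's
#' energy-statistics framework for two univariate samples.  The value lies
#' in \[0, 1\], is invariant to shifting either vector and to rescaling by a
#' nonzero constant, and equals 1 for an exact affine relation.  When either
#' vector is constant its distance variance is zero and the correlation is
#' defined as 0 (a note is emitted).
#'
#' @param x,y numeric vectors of equal length >= 2, finite values.
#' @return a single number in \[0, 1\].
#' @export
distance_correlation <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  a <- double_center(x)
  b <- double_center(y)
  dvar_x <- mean(a * a)
  dvar_y <- mean(b * b)
  if (dvar_x <= 0 || dvar_y <= 0) {
    message("distance_correlation: constant input vector; returning 0")
    return(0)
  }
  dcov2 <- mean(a * b)
  # V-statistic dCov^2 is non-negative in exact arithmetic; clamp rounding
  r <- sqrt(max(dcov2, 0)) / sqrt(sqrt(dvar_x * dvar_y))
  min(max(r, 0), 1)
}

# Flattened double-centered distance matrices, one row per gene.
# Returns an n x m^2 matrix C such that dCov^2(i, j) = mean(C[i,] * C[j,]).
dcor_row_basis <- function(expr) {
  m <- ncol(expr)
  t(apply(expr, 1, function(x) as.vector(double_center(x))))
}

#' Pairwise gene-gene similarity matrix
#'
#' Computes the similarity s_ij between all gene pairs: either the distance
#' correlation of the two expression profiles (default) or the absolute
#' Pearson correlation.  Both choices are in \[0, 1\], so positive and
#' negative co-expression are treated equally (an unsigned network).  The
#' diagonal is set to 1.  Constant genes have zero similarity to everything
#' and are listed in a warning.
#'
#' @param expr expression matrix with >= 2 genes and >= 2 samples.
#' @param method `"distance_correlation"` or `"absolute_pearson"`.
#' @return symmetric numeric similarity matrix with unit diagonal, gene ids
#'   as dimnames, and the method stored in attribute `"method"`.
#' @export
pairwise_similarity <- function(expr,
                                method = c("distance_correlation",
                                           "absolute_pearson")) {
  method <- match.arg(method)
  expr <- expression_matrix(expr)
  n <- nrow(expr)
  if (n < 2 || ncol(expr) < 2) {
    stop("need at least 2 genes and 2 samples", call. = FALSE)
  }

  if (method == "absolute_pearson") {
    sds <- apply(expr, 1, stats::sd)
    constant <- sds == 0
    s <- abs(suppressWarnings(stats::cor(t(expr))))
    s[constant, ] <- 0
    s[, constant] <- 0
  } else {
    cmat <- dcor_row_basis(expr)
    m2 <- ncol(cmat)
    v <- cmat %*% t(cmat) / m2           # dCov^2 for every pair
    dvar <- diag(v)
    constant <- dvar <= 0
    denom <- sqrt(outer(dvar, dvar))
    s <- sqrt(pmax(v, 0)) / sqrt(denom)
    s[!is.finite(s)] <- 0
  }

  if (any(constant)) {
    warning("constant gene(s) with zero similarity to all others: ",
            paste(rownames(expr)[constant], collapse = ", "), call. = FALSE)
  }
  s[s > 1] <- 1
  s[s < 0] <- 0
  s <- (s + t(s)) / 2                    # enforce exact symmetry
  diag(s) <- 1
  dimnames(s) <- list(rownames(expr), rownames(expr))
  attr(s, "method") <- method
  s
}

#' Write a similarity (or any symmetric gene-gene) matrix as TSV
#'
#' @param sim symmetric matrix with gene ids as dimnames.
#' @param path output path.
#' @export
write_similarity <- function(sim, path) {
  check_square_symmetric(sim, "similarity matrix")
  df <- data.frame(gene_id = rownames(sim), sim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity()]
#'
#' @param path path to the TSV file.
#' @return symmetric numeric matrix with gene ids as dimnames.
#' @export
read_similarity <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  check_square_symmetric(m, "similarity matrix")
  m
}
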