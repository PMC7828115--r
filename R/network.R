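# Weighted-network construction: soft-thresholded adjacency, scale-free
# topology fit, and the topological overlap matrix (TOM).

#' Soft-thresholded adjacency matrix
#'
#' Raises the similarity matrix elementwise to the soft-thresholding power
#' beta, a_ij = s_ij^beta.  The diagonal is set to 0: self-connections are
#' excluded from every connectivity, TOM, and mean-connectivity computation
#' in this package.
#'
#' @param sim symmetric similarity matrix with entries in \[0, 1\].
#' @param beta positive soft-thresholding power.
#' @return symmetric adjacency matrix with zero diagonal and attribute
#'   `"beta"`.
#' @export
adjacency <- function(sim, beta) {
  check_square_symmetric(sim, "similarity matrix")
  stopifnot(is.numeric(beta), length(beta) == 1L, beta > 0)
  a <- unclass(sim)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  attr(a, "method") <- attr(sim, "method")
  a
}

#' Network connectivity
#'
#' Connectivity of gene i is k_i = sum over j != i of a_ij.  The adjacency
#' diagonal is ignored.
#'
#' @param adj adjacency matrix (zero or unit diagonal; diagonal is dropped).
#' @return named numeric vector of connectivities.
#' @export
connectivity <- function(adj) {
  check_square_symmetric(adj, "adjacency matrix")
  a <- unclass(adj)
  diag(a) <- 0
  rowSums(a)
}

#' Scale-free topology fit index of a connectivity distribution
#'
#' Discretizes the connectivities into `n_bins` equal-width bins, and
#' regresses log10(proportion of genes in bin) on log10(mean connectivity
#' in bin) over the nonempty bins.  Returns the regression R^2 multiplied
#' by the negated sign of the slope (the usual signed scale-free index), so
#' an approximately scale-free (decreasing power-law) connectivity
#' distribution scores near +1 and an increasing relation scores
#' negatively.
#'
#' @param k numeric vector of connectivities (or an adjacency matrix, whose
#'   connectivities are computed first).
#' @param n_bins number of equal-width bins, default 10.
#' @return signed R^2 in \[-1, 1\], or `NA` with a warning when the fit is
#'   undefined (all connectivities equal, or fewer than 3 nonempty bins).
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  if (is.matrix(k)) k <- connectivity(k)
  stopifnot(is.numeric(k), all(is.finite(k)))
  if (diff(range(k)) == 0) {
    warning("all connectivities equal; scale-free fit undefined", call. = FALSE)
    return(NA_real_)
  }
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  mean_k <- tapply(k, bin, mean)
  freq <- tapply(k, bin, length) / length(k)
  ok <- !is.na(mean_k) & !is.na(freq) & mean_k > 0
  if (sum(ok) < 3) {
    warning("fewer than 3 nonempty bins; scale-free fit undefined", call. = FALSE)
    return(NA_real_)
  }
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are legitimate
  slope <- stats::coef(fit)[2]
  unname(-sign(slope) * r2)
}

#' Choose the soft-thresholding power by scale-free topology fit
#'
#' Scans the candidate powers in order and returns the smallest one whose
#' signed scale-free fit R^2 reaches `r2_cut`.  When no candidate
#' qualifies - routine for strongly modular or small data sets, whose
#' connectivity distribution is multi-modal rather than scale-free - a
#' prominent warning is emitted and the fallback power is used: the
#' standard recommended power for unsigned networks at the given sample
#' count (9 below 20 samples, 8 below 30, 7 below 40, 6 otherwise) when
#' `n_samples` is supplied, or the candidate with the maximal signed R^2
#' when it is not.  Maximizing R^2 alone is not a safe fallback: on
#' non-scale-free data the fit index typically keeps growing with the
#' power while the network decays toward emptiness.  The full diagnostic
#' table is always returned.
#'
#' @param sim similarity matrix.
#' @param candidate_betas ordered positive powers to scan, default `1:20`.
#' @param r2_cut signed R^2 threshold, default 0.85.
#' @param n_bins bins for [scale_free_fit()].
#' @param n_samples optional number of samples behind `sim`; enables the
#'   sample-size-based fallback power.
#' @param min_mean_k minimal mean connectivity a candidate power must
#'   retain to qualify (default 1).  A power that empties the network can
#'   score a spuriously high fit index - a scale-free fit on a near-empty
#'   network is meaningless - so such candidates are reported in the table
#'   but never selected by the R^2 rule.
#' @return a list with elements `beta` (the chosen power), `sft_r2` (its
#'   signed R^2), `qualified` (logical), and `fit_table` (a data frame with
#'   columns beta, sft_r2, mean_k, median_k, max_k).
#' @export
pick_soft_threshold <- function(sim, candidate_betas = 1:20, r2_cut = 0.85,
                                n_bins = 10, n_samples = NULL,
                                min_mean_k = 1) {
  check_square_symmetric(sim, "similarity matrix")
  stopifnot(length(candidate_betas) >= 1, all(candidate_betas > 0))
  if (diff(range(unclass(sim)[upper.tri(sim)])) == 0) {
    stop("degenerate similarity matrix: all off-diagonal entries equal",
         call. = FALSE)
  }
  rows <- lapply(candidate_betas, function(b) {
    k <- connectivity(adjacency(sim, b))
    r2 <- suppressWarnings(scale_free_fit(k, n_bins = n_bins))
    data.frame(beta = b, sft_r2 = r2, mean_k = mean(k),
               median_k = stats::median(k), max_k = max(k))
  })
  fit_table <- do.call(rbind, rows)
  ok <- !is.na(fit_table$sft_r2) & fit_table$sft_r2 >= r2_cut &
    fit_table$mean_k >= min_mean_k
  if (any(ok)) {
    i <- which(ok)[1]
    qualified <- TRUE
  } else {
    if (all(is.na(fit_table$sft_r2))) {
      stop("scale-free fit undefined for every candidate power", call. = FALSE)
    }
    qualified <- FALSE
    if (!is.null(n_samples)) {
      default_beta <- if (n_samples < 20) 9 else if (n_samples < 30) 8
                      else if (n_samples < 40) 7 else 6
      i <- which.min(abs(fit_table$beta - default_beta))
      warning("no candidate power reached signed R^2 >= ", r2_cut,
              "; falling back to the default unsigned-network power beta = ",
              fit_table$beta[i], " for ", n_samples, " samples", call. = FALSE)
    } else {
      eligible <- which(fit_table$mean_k >= min_mean_k &
                          !is.na(fit_table$sft_r2))
      if (length(eligible) == 0) eligible <- which(!is.na(fit_table$sft_r2))
      i <- eligible[which.max(fit_table$sft_r2[eligible])]
      warning("no candidate power reached signed R^2 >= ", r2_cut,
              "; falling back to beta = ", fit_table$beta[i],
              " with the best fit (R^2 = ", signif(fit_table$sft_r2[i], 3),
              ")", call. = FALSE)
    }
  }
  list(beta = fit_table$beta[i], sft_r2 = fit_table$sft_r2[i],
       qualified = qualified, fit_table = fit_table)
}

#' Topological overlap matrix
#'
#' Computes the unsigned TOM of an adjacency matrix:
#' TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij), where
#' l_ij = sum over u != i, j of a_iu * a_uj and k_i is the connectivity of
#' gene i.  TOM_ii = 1.  Entries lie in \[0, 1\] and credit gene pairs that
#' share network neighbors even when their direct adjacency is modest.
#'
#' @param adj adjacency matrix with entries in \[0, 1\]; the diagonal is
#'   ignored (treated as 0).
#' @return symmetric TOM matrix with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  check_square_symmetric(adj, "adjacency matrix")
  a <- unclass(adj)
  attributes(a) <- attributes(a)[c("dim", "dimnames")]
  diag(a) <- 0
  if (min(a) < 0 || max(a) > 1) {
    stop("adjacency entries must lie in [0, 1]", call. = FALSE)
  }
  k <- rowSums(a)
  l <- a %*% a                       # a_ii = 0, so u = i and u = j drop out
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  tom <- (tom + t(tom)) / 2
  tom
}

#' Topological overlap dissimilarity
#'
#' d_ij = 1 - TOM_ij, with zero diagonal; the distance fed to hierarchical
#' clustering.
#'
#' @param tom TOM matrix from [tom_similarity()] (or any symmetric
#'   similarity in \[0, 1\] with unit diagonal).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
tom_dissimilarity <- function(tom) {
  check_square_symmetric(tom, "TOM matrix")
  d <- 1 - unclass(tom)
  attributes(d) <- attributes(d)[c("dim", "dimnames")]
  diag(d) <- 0
  d
}
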