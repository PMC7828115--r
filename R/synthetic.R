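# Synthetic expression data with planted module structure.
#
# Each module is driven by one latent factor drawn independently per sample;
# module genes are noisy linear (optionally negated or nonlinearly
# transformed) readouts of their factor, and grey genes are pure noise.
# This emulates the block-correlated structure co-expression analysis
# assumes while keeping ground-truth labels available for validation.

#' Specification for a synthetic expression data set
#'
#' Defaults describe a well-separated, moderately noisy study:
#' 300 genes x 60 samples, 5 balanced modules, factor loading 0.9 against
#' noise with standard deviation 0.5 (per-gene within-module correlations
#' around 0.75), and 10% unassigned (grey) genes of pure unit-variance
#' noise.  `nonlinear_fraction` turns the leading genes of each module into
#' even-function readouts g(f) = (f^2 - 1) / sqrt(2) of their factor -
#' approximately uncorrelated (Pearson) with their linear module-mates but
#' strongly dependent on them, the case that motivates distance
#' correlation.  `anti_fraction` negates the loading of the trailing genes
#' of each module.
#'
#' @param n_genes total number of genes.
#' @param n_samples number of samples.
#' @param n_modules number of planted modules.
#' @param module_sizes optional integer vector of module sizes; must sum to
#'   `round(n_genes * (1 - grey_fraction))`.  Balanced by default.
#' @param loading factor weight in (0, 1].
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param grey_fraction fraction of genes left unassigned (pure noise).
#' @param nonlinear_fraction fraction of each module's genes tied to the
#'   factor through the standardized square.
#' @param anti_fraction fraction of each module's genes with negated
#'   loading.
#' @param seed integer seed; all randomness of [simulate_expression()]
#'   flows from it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 300, n_samples = 60, n_modules = 5,
                           module_sizes = NULL, loading = 0.9,
                           noise_sd = 0.5, grey_fraction = 0.1,
                           nonlinear_fraction = 0, anti_fraction = 0,
                           seed = 1) {
  stopifnot(n_genes >= 2, n_samples >= 2, n_modules >= 1,
            loading > 0, loading <= 1, noise_sd > 0,
            grey_fraction >= 0, grey_fraction < 1,
            nonlinear_fraction >= 0, nonlinear_fraction <= 1,
            anti_fraction >= 0, anti_fraction <= 1)
  n_assigned <- round(n_genes * (1 - grey_fraction))
  if (is.null(module_sizes)) {
    module_sizes <- rep(n_assigned %/% n_modules, n_modules) +
      as.integer(seq_len(n_modules) <= n_assigned %% n_modules)
  }
  if (length(module_sizes) != n_modules || sum(module_sizes) != n_assigned) {
    stop("module_sizes must have length ", n_modules, " and sum to ",
         n_assigned, call. = FALSE)
  }
  if (any(module_sizes < 1)) stop("every module needs >= 1 gene", call. = FALSE)
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 n_modules = n_modules, module_sizes = module_sizes,
                 loading = loading, noise_sd = noise_sd,
                 grey_fraction = grey_fraction,
                 nonlinear_fraction = nonlinear_fraction,
                 anti_fraction = anti_fraction, seed = seed),
            class = "synthetic_spec")
}

#' Generate synthetic expression data with planted modules
#'
#' Draws one standard-normal latent factor per module across samples.  A
#' linear module gene is `loading * f + noise_sd * e`, an anti-regulated
#' gene is `-loading * f + noise_sd * e`, and a nonlinear gene is
#' `loading * (f^2 - 1) / sqrt(2) + noise_sd * e`, with `e` independent
#' standard normal.  Grey genes are independent standard normal noise.
#' Genes are assigned to modules at random positions (seeded), so two
#' data sets generated with different seeds have independent module
#' memberships.  Fully reproducible from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `expr` (expression matrix), `partition` (the planted
#'   module partition; 0 = grey), and `gene_type` (named character vector:
#'   `"linear"`, `"nonlinear"`, `"anti"`, or `"grey"`).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n_genes
    m <- spec$n_samples
    gene_ids <- sprintf("G%04d", seq_len(n))
    sample_ids <- sprintf("S%03d", seq_len(m))

    # planted labels at random gene positions
    flat <- rep(seq_len(spec$n_modules), times = spec$module_sizes)
    labels <- integer(n)
    labels[sample.int(n, length(flat))] <- flat

    factors <- matrix(stats::rnorm(spec$n_modules * m), spec$n_modules, m)
    x <- matrix(stats::rnorm(n * m), n, m)       # becomes noise / grey values
    gene_type <- rep("grey", n)
    for (mod in seq_len(spec$n_modules)) {
      idx <- which(labels == mod)
      n_nl <- floor(spec$nonlinear_fraction * length(idx))
      n_anti <- floor(spec$anti_fraction * (length(idx) - n_nl))
      f <- factors[mod, ]
      g <- (f^2 - 1) / sqrt(2)                   # standardized even readout
      for (r in seq_along(idx)) {
        type <- if (r <= n_nl) "nonlinear"
                else if (r <= n_nl + n_anti) "anti"
                else "linear"
        signal <- switch(type, nonlinear = g, anti = -f, linear = f)
        gene_type[idx[r]] <- type
        x[idx[r], ] <- spec$loading * signal + spec$noise_sd * x[idx[r], ]
      }
    }
    dimnames(x) <- list(gene_ids, sample_ids)
    list(expr = expression_matrix(x),
         partition = module_partition(labels, gene_ids),
         gene_type = stats::setNames(gene_type, gene_ids))
  })
}

#' Randomly corrupt a module partition
#'
#' Reassigns `floor(fraction * n_nongrey)` randomly chosen non-grey genes
#' to a random *other* non-grey module, emulating the isolated misplaced
#' assignments hierarchical clustering can produce.  Grey genes are never
#' touched.  Deterministic per seed.
#'
#' @param partition module partition with >= 2 non-grey modules when
#'   `fraction > 0`.
#' @param fraction fraction of non-grey genes to misassign, in \[0, 1\].
#' @param seed integer seed.
#' @return the corrupted partition.
#' @export
corrupt_partition <- function(partition, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction == 0) return(partition)
  ids <- module_ids(partition)
  if (length(ids) < 2) {
    stop("corruption needs >= 2 non-grey modules", call. = FALSE)
  }
  nongrey <- which(partition > 0L)
  n_corrupt <- floor(fraction * length(nongrey))
  with_local_seed(seed, {
    victims <- sample(nongrey, n_corrupt)
    out <- partition
    for (i in victims) {
      others <- setdiff(ids, partition[i])
      out[i] <- if (length(others) == 1) others else sample(others, 1)
    }
    out
  })
}
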