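#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix with genes in rows and
#' samples in columns, gene identifiers as row names and sample identifiers
#' as column names.  Values are normalized expression measurements
#' (log-intensities or log-transformed counts); the package never normalizes
#' raw data itself.  This constructor enforces the invariants every
#' downstream function assumes: unique identifiers on both axes and finite
#' values throughout (missing values must be rejected or imputed upstream).
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   the row names of `values`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the column names of `values`.
#' @return a numeric matrix with validated dimnames.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must be a numeric matrix", call. = FALSE)
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length of gene_ids (", length(gene_ids), ") does not match row count (",
         nrow(values), ")", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length of sample_ids (", length(sample_ids),
         ") does not match column count (", ncol(values), ")", call. = FALSE)
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    stop("duplicate gene identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0) {
    stop("duplicate sample identifier(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite expression value for gene '", gene_ids[bad[1]],
         "', sample '", sample_ids[bad[2]], "'", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Read an expression matrix from delimited text
#'
#' Reads a TSV or CSV file with one header row of sample identifiers and one
#' identifier column of gene identifiers.  The delimiter is auto-detected
#' from the header line (tab wins over comma) unless given explicitly.
#'
#' @param path path to the delimited text file.
#' @param orientation `"genes_in_rows"` (default) when rows are genes, or
#'   `"genes_in_columns"` when the file is transposed.
#' @param sep optional field separator; auto-detected when `NULL`.
#' @return a validated expression matrix (see [expression_matrix()]).
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows", "genes_in_columns"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "", quote = "\"")
  if (ncol(tab) < 2) stop("expected at least one identifier column and one data column in ",
                          path, call. = FALSE)
  ids <- as.character(tab[[1]])
  dat <- tab[, -1, drop = FALSE]
  for (j in seq_along(dat)) {
    col <- dat[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0) {
        stop("non-numeric value '", col[bad[1]], "' at data line ", bad[1],
             " (identifier '", ids[bad[1]], "'), column '",
             colnames(dat)[j], "' in ", path, call. = FALSE)
      }
      dat[[j]] <- num
    }
  }
  m <- as.matrix(dat)
  rownames(m) <- ids
  if (orientation == "genes_in_columns") m <- t(m)
  expression_matrix(m)
}

#' Write an expression matrix as delimited text
#'
#' @param expr expression matrix (genes x samples).
#' @param path output path.
#' @param sep field separator, tab by default.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  expr <- expression_matrix(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter genes by coefficient of variation and mean intensity
#'
#' Reduces an expression matrix to its informative genes.  When
#' `require_above_mean_intensity` is set, genes whose mean expression does
#' not exceed the grand mean of all gene means are dropped first.  The
#' remaining genes are kept when their coefficient of variation,
#' CV = sd / mean with the sample (n - 1) standard deviation, strictly
#' exceeds `cv_threshold`.  Genes with non-positive mean have an undefined
#' CV and are excluded with a warning.  Gene order is preserved.
#'
#' The removed genes and the reason for removal are attached to the result
#' as attribute `"filter_log"` (a data frame with columns `gene_id` and
#' `reason`).
#'
#' @param expr expression matrix (genes x samples, >= 2 samples).
#' @param cv_threshold non-negative CV cutoff, e.g. `0.05` for 5%.
#' @param require_above_mean_intensity drop genes at or below the grand mean
#'   intensity before applying the CV cutoff.  Default `TRUE`.
#' @return the filtered expression matrix with a `"filter_log"` attribute.
#' @export
cv_filter <- function(expr, cv_threshold,
                      require_above_mean_intensity = TRUE) {
  expr <- expression_matrix(expr)
  stopifnot(is.numeric(cv_threshold), length(cv_threshold) == 1L,
            cv_threshold >= 0)
  if (ncol(expr) < 2) stop("cv_filter needs at least 2 samples", call. = FALSE)

  gene_means <- rowMeans(expr)
  keep <- rep(TRUE, nrow(expr))
  reason <- rep(NA_character_, nrow(expr))

  if (isTRUE(require_above_mean_intensity)) {
    low <- gene_means <= mean(gene_means)
    reason[low] <- "at_or_below_mean_intensity"
    keep <- keep & !low
  }

  nonpos <- keep & gene_means <= 0
  if (any(nonpos)) {
    warning("CV undefined (mean <= 0) for gene(s): ",
            paste(rownames(expr)[nonpos], collapse = ", "),
            "; excluded", call. = FALSE)
    reason[nonpos] <- "nonpositive_mean"
    keep <- keep & !nonpos
  }

  gene_sds <- apply(expr, 1, stats::sd)
  cv <- gene_sds / gene_means
  low_cv <- keep & !(cv > cv_threshold)
  reason[low_cv] <- "cv_at_or_below_threshold"
  keep <- keep & !low_cv

  out <- expr[keep, , drop = FALSE]
  attr(out, "filter_log") <- data.frame(
    gene_id = rownames(expr)[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out
}

#' Partition samples into random disjoint parts
#'
#' Splits the sample columns into `n_parts` disjoint, exhaustive parts of
#' near-equal size (sizes differ by at most one), uniformly at random.
#' The gene set is identical across parts and the split is reproducible
#' from `seed`.
#'
#' @param expr expression matrix.
#' @param n_parts integer >= 2; every part must receive at least 2 samples.
#' @param seed integer seed controlling the random assignment.
#' @return a list of `n_parts` expression matrices.
#' @export
split_samples <- function(expr, n_parts, seed) {
  expr <- expression_matrix(expr)
  n <- ncol(expr)
  stopifnot(is.numeric(n_parts), length(n_parts) == 1L, n_parts >= 2)
  n_parts <- as.integer(n_parts)
  if (n_parts * 2L > n) {
    stop("cannot split ", n, " samples into ", n_parts,
         " parts of at least 2 samples each", call. = FALSE)
  }
  sizes <- rep(n %/% n_parts, n_parts) + as.integer(seq_len(n_parts) <= n %% n_parts)
  perm <- with_local_seed(seed, sample.int(n))
  idx <- split(perm, rep(seq_len(n_parts), times = sizes))
  lapply(idx, function(i) expr[, sort(i), drop = FALSE])
}
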