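test_that("reading a written matrix round-trips, in both orientations", {
  x <- random_expr(3, 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(x, path)

  got <- read_expression(path)
  expect_identical(dim(got), c(3L, 2L))
  expect_equal(got, x)

  # transposed file with orientation flag gives the identical matrix
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(sample_id = colnames(x), t(x), check.names = FALSE)
  utils::write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(tpath, orientation = "genes_in_columns"), x)
})

test_that("comma-delimited files are auto-detected", {
  x <- random_expr(4, 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  expect_equal(read_expression(path), x)
})

test_that("malformed input is rejected with the offending identifier named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "G1\t1\t2", "G1\t3\t4"), path)
  expect_error(read_expression(path), "G1")

  writeLines(c("gene_id\tS1\tS2", "G1\t1\t2", "G2\tx\t4"), path)
  expect_error(read_expression(path), "G2")

  expect_error(expression_matrix(matrix(c(1, NA), 1, 2,
                                        dimnames = list("G1", c("S1", "S2")))),
               "non-finite")
})

test_that("cv_filter applies the CV and intensity rules as documented", {
  x <- expression_matrix(rbind(
    constant = rep(7, 4),
    varying  = c(10, 10, 10, 14),
    low      = c(1, 1.01, 0.99, 1)
  ), gene_ids = c("constant", "varying", "low"), sample_ids = paste0("S", 1:4))

  # sample-sd CV of (10,10,10,14): sd = 2, mean = 11, CV = 2/11
  cv <- sd(c(10, 10, 10, 14)) / mean(c(10, 10, 10, 14))
  expect_equal(cv, 2 / 11)

  out <- cv_filter(x, cv_threshold = 0.05, require_above_mean_intensity = FALSE)
  expect_identical(rownames(out), "varying")  # constant CV = 0, low CV small? keep check below
  expect_true(cv > 0.05)

  # threshold above 2/11 removes the varying gene too
  out2 <- cv_filter(x, cv_threshold = 0.2, require_above_mean_intensity = FALSE)
  expect_false("varying" %in% rownames(out2))

  # intensity gate: grand mean of gene means is (7 + 11 + 1)/3; only genes
  # above it survive the first stage
  out3 <- cv_filter(x, cv_threshold = 0, require_above_mean_intensity = TRUE)
  expect_identical(rownames(out3), "varying")
  expect_true("at_or_below_mean_intensity" %in%
                attr(out3, "filter_log")$reason)

  # vacuous filter keeps every varying gene
  y <- random_expr(10, 5, seed = 3)
  expect_identical(rownames(cv_filter(abs(y) + 1, 0,
                                      require_above_mean_intensity = FALSE)),
                   rownames(y))
})

test_that("cv_filter warns on non-positive means and is idempotent", {
  x <- expression_matrix(rbind(neg = c(-5, -4, -6, -5),
                               pos = c(5, 6, 4, 5)),
                         gene_ids = c("neg", "pos"),
                         sample_ids = paste0("S", 1:4))
  expect_warning(out <- cv_filter(x, 0.05, require_above_mean_intensity = FALSE),
                 "neg")
  expect_identical(rownames(out), "pos")

  y <- abs(random_expr(30, 8, seed = 4)) + 0.5
  once <- cv_filter(y, 0.1, require_above_mean_intensity = FALSE)
  twice <- cv_filter(once, 0.1, require_above_mean_intensity = FALSE)
  expect_true(all(rownames(once) %in% rownames(y)))
  expect_equal(unclass(twice)[, ], unclass(once)[, ])
})

test_that("split_samples partitions samples disjointly, reproducibly, evenly", {
  x <- random_expr(5, 10, seed = 5)
  parts <- split_samples(x, 2, seed = 42)
  expect_length(parts, 2)
  expect_identical(sort(c(colnames(parts[[1]]), colnames(parts[[2]]))),
                   sort(colnames(x)))
  expect_length(intersect(colnames(parts[[1]]), colnames(parts[[2]])), 0)
  expect_identical(rownames(parts[[1]]), rownames(x))

  # determinism
  again <- split_samples(x, 2, seed = 42)
  expect_identical(parts, again)

  # 258 samples into 5 folds: sizes 52, 52, 52, 51, 51
  big <- random_expr(2, 258, seed = 6)
  sizes <- sort(unname(vapply(split_samples(big, 5, seed = 1), ncol,
                              integer(1))), decreasing = TRUE)
  expect_identical(sizes, c(52L, 52L, 52L, 51L, 51L))

  # parts reassemble to a permutation of the input
  reassembled <- do.call(cbind, split_samples(big, 5, seed = 9))
  expect_equal(reassembled[, colnames(big)], big[, ])

  expect_error(split_samples(x, 6, seed = 1), "at least 2 samples")
})
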