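test_that("adjacency is the elementwise soft-thresholded similarity", {
  s <- block_matrix(c(2, 2), within = 0.5, between = 0.2, diag_value = 1)
  a <- adjacency(s, beta = 2)
  expect_equal(a["G01", "G02"], 0.25)
  expect_equal(unname(diag(a)), rep(0, 4))

  # beta = 1 leaves the off-diagonal untouched
  a1 <- adjacency(s, beta = 1)
  expect_equal(a1[upper.tri(a1)], s[upper.tri(s)])

  # elementwise against an explicit loop
  s6 <- pairwise_similarity(random_expr(6, 9, seed = 21))
  a6 <- adjacency(s6, beta = 6)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(a6[i, j], if (i == j) 0 else s6[i, j]^6, tolerance = 1e-15)
  }
})

test_that("scale-free fit scores an exact discretized power law near 1", {
  # counts 64, 16, 4, 1 at connectivities 1, 2, 4, 8: log-log exactly linear
  k <- rep(c(1, 2, 4, 8), times = c(64, 16, 4, 1))
  expect_gt(scale_free_fit(k), 0.9)

  # increasing frequency with connectivity: anti-scale-free, negative sign
  k_anti <- rep(c(1, 2, 4, 8), times = c(1, 4, 16, 64))
  expect_lt(scale_free_fit(k_anti), 0)

  expect_warning(r <- scale_free_fit(rep(3, 50)), "undefined")
  expect_true(is.na(r))
})

test_that("pick_soft_threshold returns the smallest qualifying power", {
  d <- simulate_expression(synthetic_spec(n_genes = 80, n_samples = 30, seed = 22))
  s <- pairwise_similarity(d$expr, "absolute_pearson")

  # vacuous cut: first candidate wins
  res <- pick_soft_threshold(s, candidate_betas = c(2, 4, 6), r2_cut = -1)
  expect_equal(res$beta, 2)
  expect_true(res$qualified)

  # unattainable cut: fall back to argmax R^2 with a warning
  expect_warning(res2 <- pick_soft_threshold(s, candidate_betas = c(2, 4, 6),
                                             r2_cut = 1.01),
                 "falling back")
  expect_false(res2$qualified)
  expect_equal(res2$beta,
               res2$fit_table$beta[which.max(res2$fit_table$sft_r2)])

  # the chosen beta is minimal among qualifying candidates (exhaustive scan)
  cut <- stats::median(res2$fit_table$sft_r2)
  res3 <- suppressWarnings(pick_soft_threshold(s, candidate_betas = c(2, 4, 6),
                                               r2_cut = cut))
  qualifying <- res3$fit_table$beta[!is.na(res3$fit_table$sft_r2) &
                                      res3$fit_table$sft_r2 >= cut]
  if (length(qualifying) > 0) expect_equal(res3$beta, min(qualifying))

  # degenerate similarity is rejected
  flat <- block_matrix(c(4), within = 0.5, between = 0.5, diag_value = 1)
  expect_error(pick_soft_threshold(flat), "degenerate")
})

test_that("powers that empty the network never qualify", {
  d <- simulate_expression(synthetic_spec(seed = 8))
  s <- pairwise_similarity(d$expr, "distance_correlation")
  res <- suppressWarnings(pick_soft_threshold(s, n_samples = 60))
  tab <- res$fit_table
  if (res$qualified) {
    expect_gte(tab$mean_k[tab$beta == res$beta], 1)
  }
  # this instance has a high-power candidate whose fit index clears the
  # cut while its mean connectivity is below one neighbor per gene; the
  # eligibility floor must skip it
  spurious <- tab$beta[!is.na(tab$sft_r2) & tab$sft_r2 >= 0.85 & tab$mean_k < 1]
  expect_gt(length(spurious), 0)
  expect_false(res$beta %in% spurious)
})

test_that("TOM has its closed forms on empty and complete networks", {
  # empty network: identity pattern
  empty <- block_matrix(c(5), within = 0, between = 0)
  expect_equal(unclass(tom_similarity(empty)), diag(5), ignore_attr = TRUE)

  # complete network with all a_ij = 1, n = 5: every TOM_ij = 1
  full <- block_matrix(c(5), within = 1, between = 1)
  expect_equal(max(abs(tom_similarity(full) - 1)), 0)
})

test_that("TOM matches the naive triple-loop oracle", {
  for (seed in 1:20) {
    a <- random_adjacency(20, seed)
    expect_equal(unclass(tom_similarity(a)), oracle_tom(a),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("TOM entries stay in [0, 1] and are permutation-equivariant", {
  a <- random_adjacency(15, seed = 23)
  tom <- tom_similarity(a)
  expect_true(all(tom >= 0 & tom <= 1))

  set.seed(24)
  p <- sample(15)
  tom_p <- tom_similarity(a[p, p])
  expect_equal(unclass(tom_p), unclass(tom)[p, p], tolerance = 1e-12)
})

test_that("TOM dissimilarity is the involutive complement", {
  a <- random_adjacency(10, seed = 25)
  tom <- tom_similarity(a)
  d <- tom_dissimilarity(tom)
  expect_equal(unname(diag(d)), rep(0, 10))
  expect_equal(1 - d, unclass(tom), ignore_attr = TRUE)
  # identity-pattern TOM maps to all-ones off-diagonal
  d0 <- tom_dissimilarity(diag(5))
  expect_equal(d0[upper.tri(d0)], rep(1, 10))
})

test_that("the network pipeline is deterministic", {
  x <- random_expr(25, 12, seed = 26)
  run <- function() {
    s <- pairwise_similarity(x)
    tom_dissimilarity(tom_similarity(adjacency(s, 4)))
  }
  expect_identical(run(), run())
})
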