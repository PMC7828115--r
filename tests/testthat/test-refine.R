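test_that("mean connectivity follows its definition, self-term included", {
  # S_m = {g2, g3}, a_12 = 0.8, a_13 = 0.4, g1 outside the module
  a <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  a[1, 2] <- a[2, 1] <- 0.8
  a[1, 3] <- a[3, 1] <- 0.4
  p <- module_partition(c(0L, 1L, 1L), paste0("g", 1:3))
  expect_equal(mean_connectivity("g1", 1, a, p), 0.6)

  # g1 inside S_m = {g1, g2}: self-term 0, denominator still 2
  p2 <- module_partition(c(1L, 1L, 0L), paste0("g", 1:3))
  expect_equal(mean_connectivity("g1", 1, a, p2), 0.4)
  # (n_m - 1) variant divides by 1 instead
  expect_equal(mean_connectivity("g1", 1, a, p2,
                                 include_self_in_denominator = FALSE), 0.8)

  expect_error(mean_connectivity("g1", 2, a, p2), "empty")
})

test_that("mean connectivity matches the double-loop oracle over all modules", {
  a <- random_adjacency(10, seed = 41)
  p <- random_partition(10, 3, seed = 42)
  for (g in 1:10) for (m in module_ids(p)) {
    expect_equal(mean_connectivity(g, m, a, p),
                 oracle_mean_connectivity(g, m, a, p), tolerance = 1e-12)
  }
})

test_that("a self-consistent partition is a k-module fixed point", {
  d <- two_block_diss()
  a <- 1 - d; diag(a) <- 0
  p <- two_block_labels()
  r <- k_module_refine(p, a)
  expect_identical(r$partition, p)
  expect_identical(r$changes_per_iteration, 0L)
  expect_true(r$converged)
})

test_that("k-module moves a mislabeled gene home in two iterations", {
  # two 3-gene blocks, within a = 0.9, between a = 0.1; G03 mislabeled into B
  a <- block_matrix(c(3, 3), within = 0.9, between = 0.1)
  p <- module_partition(c(1L, 1L, 2L, 2L, 2L, 2L), rownames(a))
  # hand computation: G03 -> A mean (0.9 + 0.9)/2 = 0.9;
  #                   G03 -> B mean (0 + 0.1 * 3)/4 = 0.075
  expect_equal(mean_connectivity("G03", 1, a, p), 0.9)
  expect_equal(mean_connectivity("G03", 2, a, p), 0.075)
  r <- k_module_refine(p, a)
  expect_true(r$converged)
  expect_identical(r$changes_per_iteration, c(1L, 0L))
  expect_identical(unname(r$partition["G03"]), 1L)
})

test_that("converged k-module runs satisfy the self-consistency postcondition", {
  n_checked <- 0
  for (seed in 1:5) {
    d <- simulate_expression(synthetic_spec(n_genes = 60, n_samples = 30,
                                            n_modules = 3, seed = 50 + seed))
    a <- adjacency(pairwise_similarity(d$expr, "absolute_pearson"), 6)
    p <- corrupt_partition(d$partition, 0.2, seed = 60 + seed)
    r <- suppressWarnings(k_module_refine(p, a))
    if (!r$converged) next
    n_checked <- n_checked + 1
    ids <- module_ids(r$partition)
    for (g in which(r$partition > 0L)) {
      own <- mean_connectivity(g, r$partition[g], a, r$partition)
      best <- max(vapply(ids, function(m) mean_connectivity(g, m, a, r$partition),
                         numeric(1)))
      expect_gte(own, best - 1e-12)
    }
  }
  expect_gte(n_checked, 3)
})

test_that("grey genes are frozen by default but refinable on request", {
  a <- block_matrix(c(3, 3), within = 0.9, between = 0.1)
  p <- module_partition(c(1L, 1L, 0L, 2L, 2L, 2L), rownames(a))
  r <- k_module_refine(p, a)
  expect_identical(unname(r$partition["G03"]), 0L)
  r2 <- k_module_refine(p, a, reassign_grey = TRUE)
  expect_identical(unname(r2$partition["G03"]), 1L)
  expect_false(any(r2$partition == 0L & p != 0L))  # grey never a target
})

test_that("an emptied module is retired with a warning", {
  # 2-gene pseudo-module whose genes connect 0.5 to every big-module gene
  # but barely to each other, while the big module stays self-consistent
  a <- block_matrix(c(4, 2), within = 0.9, between = 0.5)
  a["G05", "G06"] <- a["G06", "G05"] <- 0.05
  p <- module_partition(c(rep(1L, 4), 2L, 2L), rownames(a))
  expect_warning(r <- k_module_refine(p, a), "retired: 2")
  expect_identical(r$retired_modules, 2L)
  expect_identical(length(module_ids(r$partition)), 1L)
  expect_true(r$converged)
})

test_that("k-module detects an engineered two-gene oscillation", {
  a <- oscillating_adjacency()
  p <- oscillating_partition()
  r <- k_module_refine(p, a, max_iter = 12)
  expect_false(r$converged)
  expect_true(r$oscillation_detected)
  expect_identical(r$iterations, 12L)
  # exactly the two shuttle genes swap every iteration
  expect_true(all(r$changes_per_iteration == 2L))
})

test_that("module eigengenes capture rank-1 structure exactly", {
  base <- sin(1:12)
  x <- rbind(g1 = base, g2 = 2 * base + 5, g3 = -base)
  colnames(x) <- paste0("S", 1:12)
  p <- module_partition(c(1L, 1L, 1L), rownames(x))
  es <- module_eigengene(expression_matrix(x), p)
  expect_equal(unname(es$variance_proportion["1"]), 1)
  expect_equal(sum(es$eigengenes[, "1"]^2), 1)     # unit norm
  # sign-flipped member still correlates +/-1 with the eigengene
  expect_equal(abs(cor(x["g3", ], es$eigengenes[, "1"])), 1)
})

test_that("eigengene variance proportions match the covariance-eigenvalue oracle", {
  x <- random_expr(8, 20, seed = 43)
  p <- module_partition(rep(1L, 8), rownames(x))
  es <- module_eigengene(x, p)
  ev <- eigen(cor(t(x)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(unname(es$variance_proportion["1"]), ev[1] / sum(ev),
               tolerance = 1e-10)
  # eigengene correlates non-negatively with the module mean profile
  z <- t(scale(t(x)))
  expect_gte(cor(colMeans(z), es$eigengenes[, "1"]), 0)
})

test_that("constant genes in a module are reported by name", {
  x <- rbind(g1 = rep(1, 6), g2 = rnorm(6))
  colnames(x) <- paste0("S", 1:6)
  p <- module_partition(c(1L, 1L), rownames(x))
  expect_error(module_eigengene(expression_matrix(x), p), "g1")
})

test_that("k-eigengene converges immediately with a single module", {
  x <- random_expr(10, 15, seed = 44)
  p <- module_partition(rep(1L, 10), rownames(x))
  r <- k_eigengene_refine(x, p)
  expect_true(r$converged)
  expect_identical(r$iterations, 1L)
  expect_identical(r$partition, p)
})

test_that("k-eigengene keeps correct labels on planted factor data", {
  d <- simulate_expression(synthetic_spec(n_genes = 60, n_samples = 40,
                                          n_modules = 3, grey_fraction = 0,
                                          noise_sd = 0.3, seed = 45))
  r <- k_eigengene_refine(d$expr, d$partition)
  expect_true(r$converged)
  expect_identical(r$partition, d$partition)
})

test_that("both refiners are deterministic and respect max_iter", {
  d <- simulate_expression(synthetic_spec(n_genes = 80, n_samples = 30, seed = 46))
  cp <- corrupt_partition(d$partition, 0.2, seed = 47)
  s <- pairwise_similarity(d$expr, "absolute_pearson")
  a <- adjacency(s, 6)
  r1 <- k_module_refine(cp, a)
  r2 <- k_module_refine(cp, a)
  expect_identical(r1, r2)
  e1 <- k_eigengene_refine(d$expr, cp)
  e2 <- k_eigengene_refine(d$expr, cp)
  expect_identical(e1, e2)
  expect_lte(e1$iterations, 100L)
  r3 <- k_module_refine(cp, a, max_iter = 1)
  expect_identical(r3$iterations, 1L)
  expect_error(k_module_refine(cp, a, max_iter = 0), "max_iter")
})

test_that("k-module change counts shrink on well-separated data", {
  nonincreasing_tail <- vapply(1:20, function(seed) {
    d <- simulate_expression(synthetic_spec(n_genes = 100, n_samples = 40,
                                            seed = seed))
    cp <- corrupt_partition(d$partition, 0.15, seed = seed + 500)
    a <- adjacency(pairwise_similarity(d$expr, "absolute_pearson"), 6)
    r <- k_module_refine(cp, a)
    all(diff(r$changes_per_iteration) <= 0)
  }, logical(1))
  expect_gte(mean(nonincreasing_tail), 0.9)  # observed regularity, not a theorem
})
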