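# fixtures shared across tests; everything is built in code

# symmetric matrix with constant within-block and between-block values
block_matrix <- function(sizes, within, between, diag_value = 0) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), times = sizes)
  m <- matrix(between, n, n)
  for (b in seq_along(sizes)) m[lab == b, lab == b] <- within
  diag(m) <- diag_value
  dimnames(m) <- list(sprintf("G%02d", 1:n), sprintf("G%02d", 1:n))
  m
}

# the uniform two-block instance: within-d 0.1, between-d 0.9, 3 + 3 genes
two_block_diss <- function() block_matrix(c(3, 3), within = 0.1, between = 0.9)
two_block_labels <- function() {
  module_partition(rep(1:2, each = 3), sprintf("G%02d", 1:6))
}

random_expr <- function(n, m, seed) {
  set.seed(seed)
  matrix(rnorm(n * m), n, m,
         dimnames = list(sprintf("G%03d", 1:n), sprintf("S%03d", 1:m)))
}

# random symmetric adjacency in [0, 1] with zero diagonal
random_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("G%03d", 1:n), sprintf("G%03d", 1:n))
  a
}

# random partition of n genes into k modules (at least one gene each)
random_partition <- function(n, k, seed, grey_frac = 0) {
  set.seed(seed)
  lab <- c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE))
  if (grey_frac > 0) lab[sample(n, floor(grey_frac * n))] <- 0L
  module_partition(lab[sample(n)], sprintf("G%03d", 1:n))
}

# adjacency engineered so k-module refinement cycles with period 2:
# two 3-gene modules {a1, a2, x} and {b1, b2, y}; x and y are strongly
# connected to each other, weakly to both cores, so each always prefers
# the module currently hosting the other (their own membership contributes
# a zero self-term that dilutes the home module's mean connectivity)
oscillating_adjacency <- function() {
  ids <- c("a1", "a2", "x", "b1", "b2", "y")
  a <- matrix(0, 6, 6, dimnames = list(ids, ids))
  a["a1", "a2"] <- 0.8
  a["b1", "b2"] <- 0.8
  a["x", "y"] <- 0.9
  a["x", "a1"] <- a["x", "a2"] <- a["x", "b1"] <- a["x", "b2"] <- 0.1
  a["y", "a1"] <- a["y", "a2"] <- a["y", "b1"] <- a["y", "b2"] <- 0.1
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  a
}

# expression-level adversarial instance for the refiners: two 2-gene cores
# driven by independent factors u, v, plus two boundary genes x, y lying on
# the bisector between the cores with mirrored residuals.  Numerical search
# over this family (and the joint-avoidance variant) shows the margin of a
# strict two-gene k-eigengene swap cycle approaches 0 only from below: the
# |cor|-to-eigengene map is self-attracting, so the eigengene refiner
# settles, while the mean-connectivity refiner (whose self-term is 0)
# shuttles x and y between the modules indefinitely.
oscillation_expression_fixture <- function() {
  set.seed(424242)
  m <- 12
  u <- rnorm(m); v <- rnorm(m); w <- rnorm(m)
  u <- u / sd(u); v <- v / sd(v); w <- w / sd(w)
  X <- rbind(
    a1 = u + 0.05 * rnorm(m), a2 = u + 0.05 * rnorm(m),
    b1 = v + 0.05 * rnorm(m), b2 = v + 0.05 * rnorm(m),
    x  = (u + v) / sqrt(2) + 0.3 * w,
    y  = (u + v) / sqrt(2) - 0.3 * w)
  colnames(X) <- sprintf("S%02d", 1:m)
  list(expr = expression_matrix(X),
       partition = module_partition(c(1L, 1L, 2L, 2L, 1L, 2L), rownames(X)))
}

oscillating_partition <- function() {
  module_partition(c(1L, 1L, 1L, 2L, 2L, 2L),
                   c("a1", "a2", "x", "b1", "b2", "y"))
}

# naive brute-force oracles --------------------------------------------------

# distance correlation by explicit double loops
oracle_dcor <- function(x, y) {
  m <- length(x)
  A <- matrix(0, m, m); B <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m) {
    A[i, j] <- abs(x[i] - x[j]); B[i, j] <- abs(y[i] - y[j])
  }
  center <- function(d) {
    out <- matrix(0, m, m)
    for (i in 1:m) for (j in 1:m) {
      out[i, j] <- d[i, j] - mean(d[i, ]) - mean(d[, j]) + mean(d)
    }
    out
  }
  A <- center(A); B <- center(B)
  dcov2 <- sum(A * B) / m^2
  dvx <- sum(A * A) / m^2
  dvy <- sum(B * B) / m^2
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0)) / sqrt(sqrt(dvx * dvy))
}

# TOM by explicit triple loop
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# textbook silhouette by explicit loops (grey excluded, singletons 0)
oracle_silhouette <- function(d, lab) {
  keep <- lab > 0
  d <- d[keep, keep, drop = FALSE]; lab <- lab[keep]
  ids <- sort(unique(lab))
  s <- numeric(length(lab))
  for (i in seq_along(lab)) {
    own <- which(lab == lab[i] & seq_along(lab) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(ids, lab[i]),
                    function(mm) mean(d[i, lab == mm]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

# Dunn index by explicit enumeration
oracle_dunn <- function(d, lab) {
  keep <- lab > 0
  d <- d[keep, keep, drop = FALSE]; lab <- lab[keep]
  inter <- Inf; intra <- 0
  n <- length(lab)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (lab[i] == lab[j]) intra <- max(intra, d[i, j])
    else inter <- min(inter, d[i, j])
  }
  inter / intra
}

# mean connectivity by explicit double loop
oracle_mean_connectivity <- function(gene_idx, mod, adj, lab) {
  members <- which(lab == mod)
  total <- 0
  for (j in members) if (j != gene_idx) total <- total + adj[gene_idx, j]
  total / length(members)
}
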