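# Independent oracle implementations and small fixture builders used across
# the test files. Oracles deliberately take the dumbest correct route
# (loops, direct summation, general-purpose solvers) so they share no code
# path with the package internals they check.

# direct-summation KL divergence over a shared grid
brute_kl <- function(mass1, mass2) {
  s <- 0
  for (g in seq_along(mass1)) {
    s <- s + mass1[g] * log(mass1[g] / mass2[g])
  }
  s
}

brute_symmetric_kl <- function(mass1, mass2) {
  (brute_kl(mass1, mass2) + brute_kl(mass2, mass1)) / 2
}

# Benjamini-Hochberg step-up by its definition: find the largest k with
# p_(k) <= k*q/m and reject the k smallest p values
brute_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= q * seq_len(m) / m)
  reject <- logical(m)
  if (length(below)) reject[o[seq_len(max(below))]] <- TRUE
  reject
}

# diffusion-map scores through the general (nonsymmetric) eigensolver on
# the Markov operator itself, with the same multiscale scaling convention
oracle_diffusion_scores <- function(W, alpha = 0.5, n_components = 10L) {
  d <- rowSums(W)
  W1 <- W / outer(d^alpha, d^alpha)
  d1 <- rowSums(W1)
  P <- W1 / d1
  e <- eigen(P)
  ord <- order(Re(e$values), decreasing = TRUE)
  vals <- Re(e$values)[ord]
  vecs <- Re(e$vectors)[, ord, drop = FALSE]
  R <- nrow(W)
  # renormalize each eigenvector the way the symmetric-conjugate route
  # does: unit norm in the sqrt(d1)-weighted metric, then divide by the
  # stationary eigenvector
  psi <- matrix(0, R, R)
  for (c in seq_len(R)) {
    v <- vecs[, c] * sqrt(d1)
    v <- v / sqrt(sum(v^2))
    psi[, c] <- v / sqrt(d1)
  }
  psi <- psi / psi[, 1L]
  k <- min(n_components, R - 1L)
  lam <- vals[2L:(k + 1L)]
  psi[, 2L:(k + 1L), drop = FALSE] * rep(lam / (1 - lam), each = R)
}

# random symmetric connected affinity with positive diagonal
random_affinity <- function(R, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(R * 5L), R, 5L)
  W <- abs(tcrossprod(X)) + 0.01
  W <- (W + t(W)) / 2
  diag(W) <- diag(W) + 1
  W / max(W)
}

# density pair on a shared grid from log-normal vertex-area draws
random_density_pair <- function(seed) {
  set.seed(seed)
  v1 <- stats::rlnorm(40, log(0.5) + stats::rnorm(1, 0, 0.3), 0.35)
  v2 <- stats::rlnorm(40, log(0.5) + stats::rnorm(1, 0, 0.3), 0.35)
  grid <- common_area_grid(list(a = v1, b = v2))
  list(f1 = estimate_density(v1, grid), f2 = estimate_density(v2, grid))
}

# small cohort configuration for fast structural/IO tests
tiny_config <- function(seed = 42L, ...) {
  cohort_config(n_controls = 6L, n_patients = 6L, n_roi = 40L,
                n_timepoints = 120L, vertices_per_roi = 30L, seed = seed, ...)
}

# align oracle/test score signs component-wise before comparison
match_signs <- function(a, b) {
  for (c in seq_len(ncol(a))) {
    if (sum(a[, c] * b[, c]) < 0) b[, c] <- -b[, c]
  }
  b
}

discrete_density <- function(mass, grid = seq_along(mass)) {
  structure(list(grid = grid, mass = mass), class = "discrete_density")
}
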