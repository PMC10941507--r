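test_that("functional connectome matches hand-computed Fisher-Z values", {
  ts <- cbind(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  fc <- functional_connectome(ts)
  expect_equal(fc["a", "b"], atanh(0.6), tolerance = 1e-12)
  expect_equal(fc["a", "b"], fc["b", "a"])
  expect_equal(diag(unclass(fc)), c(a = 0, b = 0))
})

test_that("perfect and zero correlations hit the clip and exact-zero paths", {
  x <- c(1, -1, 1, -1)
  y <- c(1, 1, -1, -1)
  fc <- functional_connectome(cbind(a = x, b = y, c = x))
  expect_equal(fc["a", "b"], 0, tolerance = 1e-12)        # orthogonal, zero mean
  expect_equal(fc["a", "c"], atanh(1 - 1e-7))             # identical columns
  expect_true(all(is.finite(fc)))
})

test_that("zero-variance ROI is reported by name", {
  ts <- cbind(a = rnorm(10), flatroi = rep(2, 10))
  expect_error(functional_connectome(ts), "flatroi")
})

test_that("functional connectome is invariant to per-ROI affine rescaling", {
  set.seed(1)
  ts <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("r", 1:4)))
  ts2 <- sweep(sweep(ts, 2, c(2, 0.5, 10, 3), "*"), 2, c(-1, 4, 0, 7), "+")
  expect_equal(unclass(functional_connectome(ts)),
               unclass(functional_connectome(ts2)), tolerance = 1e-10)
})

test_that("connectomes are equivariant under ROI permutation", {
  set.seed(2)
  ts <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("r", 1:6)))
  perm <- c(4, 1, 6, 2, 5, 3)
  fc1 <- unclass(functional_connectome(ts))
  fc2 <- unclass(functional_connectome(ts[, perm]))
  expect_equal(fc2, fc1[perm, perm], tolerance = 1e-12, ignore_attr = TRUE)

  areas <- lapply(1:4, function(i) rlnorm(25, log(0.5) + 0.2 * i, 0.3))
  names(areas) <- paste0("r", 1:4)
  k1 <- unclass(structural_connectome(areas))
  k2 <- unclass(structural_connectome(areas[c(3, 1, 4, 2)]))
  expect_equal(k2, k1[c(3, 1, 4, 2), c(3, 1, 4, 2)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("confound regression removes planted covariate effects only", {
  set.seed(3)
  n <- 200
  age <- rnorm(n, 60, 10)
  sex <- rbinom(n, 1, 0.5)
  noise <- rnorm(n, 0, 0.02)
  mats <- lapply(seq_len(n), function(j) {
    v <- matrix(0, 3, 3, dimnames = list(paste0("r", 1:3), paste0("r", 1:3)))
    v[1, 2] <- v[2, 1] <- 0.01 * age[j] + noise[j]
    v[1, 3] <- v[3, 1] <- 0.5                       # constant edge
    connectograd:::new_connectivity(v, "functional", paste0("r", 1:3))
  })
  out <- regress_confounds(mats, data.frame(age = age, sex = sex))
  edge <- vapply(out, function(m) m[1, 2], numeric(1))
  expect_lt(abs(cor(edge, age)), 0.05)
  expect_equal(mean(edge), mean(0.01 * age + noise), tolerance = 1e-8)
  const <- vapply(out, function(m) m[1, 3], numeric(1))
  expect_equal(const, rep(0.5, n), tolerance = 1e-10)  # constant edge unchanged
  expect_equal(unclass(out[[1]]), t(unclass(out[[1]])))
})

test_that("edges orthogonal to the covariates pass through unchanged", {
  age <- c(1, 2, 3, 4)
  sex <- c(0, 1, 0, 1)
  e <- c(1, -1, -1, 1)            # orthogonal to intercept, age and sex
  mats <- lapply(seq_along(age), function(j) {
    v <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    v[1, 2] <- v[2, 1] <- e[j]
    connectograd:::new_connectivity(v, "functional", c("a", "b"))
  })
  out <- regress_confounds(mats, data.frame(age = age, sex = sex))
  expect_equal(vapply(out, function(m) m[1, 2], numeric(1)), e,
               tolerance = 1e-8)
})

test_that("rank-deficient covariate design is rejected", {
  mats <- lapply(1:4, function(j) {
    v <- matrix(0, 2, 2)
    connectograd:::new_connectivity(v, "functional", c("a", "b"))
  })
  expect_error(regress_confounds(mats, data.frame(age = 1:4, age2 = 2 * (1:4))),
               "rank")
})

test_that("density estimates are normalized, symmetric and match a histogram", {
  set.seed(4)
  v <- rlnorm(500, log(0.5), 0.35)
  grid <- common_area_grid(list(a = v))
  d <- estimate_density(v, grid)
  expect_equal(sum(d$mass), 1, tolerance = 1e-12)
  expect_true(all(d$mass > 0))

  # symmetric sample on a symmetric grid -> symmetric density
  vs <- c(5 - c(1, 0.5, 0.2), 5, 5 + c(0.2, 0.5, 1))
  gs <- seq(2, 8, length.out = 257)
  ds <- estimate_density(vs, gs)
  expect_lt(max(abs(ds$mass - rev(ds$mass))), 1e-8)

  # large-sample KDE mass tracks a histogram on the same bins
  set.seed(5)
  big <- rlnorm(1e5, log(0.5), 0.35)
  grid <- common_area_grid(list(a = big))
  kde <- estimate_density(big, grid)
  step <- diff(grid[1:2])
  breaks <- c(grid - step / 2, grid[length(grid)] + step / 2)
  hist_mass <- hist(big, breaks = breaks, plot = FALSE)$counts / length(big)
  expect_lt(sum(abs(kde$mass - hist_mass)) / 2, 0.02)   # total variation
})

test_that("identical vertex values fall back to a positive bandwidth", {
  grid <- seq(0.9, 1.1, length.out = 64)
  expect_warning(d <- estimate_density(rep(1, 10), grid), "bandwidth")
  expect_equal(sum(d$mass), 1, tolerance = 1e-12)
  expect_true(all(is.finite(d$mass)))
})

test_that("KL divergence matches direct summation and is asymmetric", {
  f1 <- discrete_density(c(0.5, 0.25, 0.25))
  f2 <- discrete_density(c(0.25, 0.5, 0.25))
  expect_equal(kl_divergence(f1, f2), 0.5 * log(2) + 0.25 * log(0.5),
               tolerance = 1e-12)
  expect_equal(kl_divergence(f1, f2), 0.17329, tolerance = 1e-4)
  expect_equal(kl_divergence(f1, f1), 0)

  g1 <- discrete_density(c(0.9, 0.1))
  g2 <- discrete_density(c(0.5, 0.5))
  expect_equal(kl_divergence(g1, g2), brute_kl(g1$mass, g2$mass))
  expect_false(isTRUE(all.equal(kl_divergence(g1, g2), kl_divergence(g2, g1))))

  expect_error(kl_divergence(f1, discrete_density(c(0.5, 0.5))), "grid")
})

test_that("symmetric KL is symmetric, zero on identity, matches the example", {
  f1 <- discrete_density(c(0.5, 0.25, 0.25))
  f2 <- discrete_density(c(0.25, 0.5, 0.25))
  expect_equal(symmetric_kl(f1, f2), 0.17329, tolerance = 1e-4)
  expect_equal(symmetric_kl(f1, f2), symmetric_kl(f2, f1))
  expect_equal(symmetric_kl(f2, f2), 0)
  for (seed in 1:10) {
    p <- random_density_pair(seed)
    expect_equal(symmetric_kl(p$f1, p$f2), symmetric_kl(p$f2, p$f1))
    expect_gte(symmetric_kl(p$f1, p$f2), 0)
  }
})

test_that("structural connectome obeys the symmetric-KL contract", {
  set.seed(6)
  shared <- rlnorm(30, log(0.5), 0.3)
  same <- list(r1 = shared, r2 = shared, r3 = shared)
  m0 <- structural_connectome(same)
  expect_equal(max(abs(m0)), 0, tolerance = 1e-12)

  areas <- lapply(1:5, function(i) rlnorm(30, log(0.4) + 0.15 * i, 0.3))
  names(areas) <- paste0("r", 1:5)
  m <- structural_connectome(areas)
  expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-10)
  expect_equal(diag(unclass(m)), setNames(rep(0, 5), names(areas)))
  expect_true(all(m >= 0))
  expect_s3_class(m, "connectivity_matrix")
  expect_identical(attr(m, "kind"), "structural_kl")
})

test_that("structural connectome is invariant to a common area rescaling", {
  set.seed(7)
  areas <- lapply(1:6, function(i) rlnorm(50, log(0.4) + 0.12 * i, 0.35))
  names(areas) <- paste0("r", 1:6)
  m1 <- unclass(structural_connectome(areas))
  m2 <- unclass(structural_connectome(lapply(areas, `*`, 2)))
  expect_lt(max(abs(m1 - m2)), 5e-2)
})

test_that("missing or degenerate ROIs are reported by name", {
  expect_error(structural_connectome(list(r1 = c(1, 2), r2 = 3)), "r2")
  expect_error(structural_connectome(list(r1 = c(1, 2), r2 = c(-1, 2))), "r2")
})
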