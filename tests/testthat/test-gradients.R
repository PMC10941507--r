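test_that("row sparsification keeps the top entries with deterministic ties", {
  m <- matrix(0, 6, 6)
  m[1, ] <- c(0, 5, 4, 3, 2, 1)
  out <- sparsify_rows(m, keep_fraction = 0.4)   # ceil(0.4 * 5) = 2 kept
  expect_equal(out[1, ], c(0, 5, 4, 0, 0, 0))

  tie <- matrix(0, 4, 4)
  tie[1, ] <- c(0, 7, 7, 7)
  out2 <- sparsify_rows(tie, keep_fraction = 0.4)  # ceil(0.4 * 3) = 2 kept
  expect_equal(out2[1, ], c(0, 7, 7, 0))           # lower column index wins

  set.seed(8)
  neg <- matrix(rnorm(25), 5, 5)
  expect_true(all(sparsify_rows(neg, 0.5) >= 0))
})

test_that("keep_fraction = 1 leaves a nonnegative matrix unchanged off-diagonal", {
  set.seed(9)
  m <- abs(matrix(rnorm(36), 6, 6))
  out <- sparsify_rows(m, keep_fraction = 1)
  off <- !diag(6)
  expect_equal(out[off], m[off])
})

test_that("each sparsified row has exactly ceil(f * (R - 1)) nonzeros", {
  set.seed(10)
  for (f in c(0.1, 0.25, 0.5)) {
    R <- 37
    m <- abs(matrix(rnorm(R * R), R, R)) + 0.01
    out <- sparsify_rows(m, f)
    expect_equal(unname(rowSums(out != 0)), rep(ceiling(f * (R - 1)), R))
  }
})

test_that("cosine affinity matches hand-computed values", {
  rows <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 0))
  a <- cosine_affinity(rows)
  expect_equal(a[1, 2], 0.5)
  expect_equal(a[1, 3], 1)             # identical rows
  expect_equal(diag(unclass(a)), rep(1, 3))
  orth <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(cosine_affinity(orth)[1, 2], 0)
  bad <- rbind(c(1, 0), c(0, 0))
  rownames(bad) <- c("a", "zero_roi")
  expect_error(cosine_affinity(bad), "zero_roi")
})

test_that("diffusion map separates a two-block affinity by sign", {
  R <- 40
  blocks <- rep(1:2, each = 20)
  W <- matrix(0.05, R, R)
  W[blocks == 1, blocks == 1] <- 1
  W[blocks == 2, blocks == 2] <- 1
  gs <- diffusion_map(W, n_components = 3)
  g1 <- gs$scores[, 1]
  expect_true(all(sign(g1[blocks == 1]) == sign(g1[1])))
  expect_true(all(sign(g1[blocks == 2]) == -sign(g1[1])))
})

test_that("diffusion map matches the general-eigensolver oracle", {
  for (seed in 1:5) {
    W <- random_affinity(50, seed)
    ours <- diffusion_map(W, n_components = 8)$scores
    oracle <- match_signs(ours, oracle_diffusion_scores(W, n_components = 8))
    expect_lt(max(abs(ours - oracle)), 1e-6)
  }
})

test_that("Markov eigenvalues are in (-1, 1) after dropping the stationary one", {
  W <- random_affinity(30, 99)
  gs <- diffusion_map(W, n_components = 29)
  expect_true(all(gs$eigenvalues < 1))
  expect_true(all(gs$eigenvalues > -1))
  expect_true(all(diff(gs$eigenvalues) <= 1e-12))
  # the stationary eigenvector of the Markov operator is constant
  d <- rowSums(W)
  W1 <- W / outer(sqrt(d), sqrt(d))   # alpha = 0.5
  P <- W1 / rowSums(W1)
  e <- eigen(P)
  v <- Re(e$vectors[, which.max(Re(e$values))])
  expect_lt(max(abs(v / v[1] - 1)), 1e-8)
})

test_that("embedding is equivariant under node permutation", {
  set.seed(11)
  ts <- matrix(rnorm(120 * 20), 120, 20,
               dimnames = list(NULL, sprintf("r%02d", 1:20)))
  fc <- functional_connectome(ts)
  perm <- sample(20)
  fc_p <- connectograd:::new_connectivity(unclass(fc)[perm, perm],
                                          "functional", rownames(fc)[perm])
  g1 <- connectome_gradients(fc, keep_fraction = 0.3, n_components = 4)$scores
  g2 <- connectome_gradients(fc_p, keep_fraction = 0.3, n_components = 4)$scores
  expect_lt(max(abs(match_signs(g1[perm, ], g2) - g1[perm, ])), 1e-8)
})

test_that("disconnected affinities are rejected with component sizes", {
  W <- diag(10)
  W[1:5, 1:5] <- 1
  W[6:10, 6:10] <- 1
  expect_error(diffusion_map(W), "component sizes: 5, 5")
})

test_that("Procrustes alignment recovers known rotations", {
  set.seed(12)
  X <- matrix(rnorm(30 * 5), 30, 5)
  Qs <- lapply(1:4, function(i) qr.Q(qr(matrix(rnorm(25), 5, 5))))
  sets <- c(list(X), lapply(Qs, function(Q) X %*% Q))
  res <- procrustes_align(sets, n_iter = 10)
  for (al in res$aligned) {
    expect_lt(max(abs(al$scores - X)), 1e-6)
  }
  for (Rm in res$rotations) {
    expect_lt(max(abs(crossprod(Rm) - diag(5))), 1e-8)
  }
})

test_that("identical inputs align with identity rotations and zero discrepancy", {
  set.seed(13)
  X <- matrix(rnorm(40), 10, 4)
  res <- procrustes_align(list(X, X, X))
  expect_lt(max(abs(res$rotations[[2]] - diag(4))), 1e-8)
  expect_lt(res$discrepancy[length(res$discrepancy)], 1e-12)
})

test_that("alignment discrepancy is non-increasing and variance never grows", {
  set.seed(14)
  base <- matrix(rnorm(25 * 3), 25, 3)
  sets <- lapply(1:6, function(i) {
    (base + matrix(rnorm(75, 0, 0.3), 25, 3)) %*% qr.Q(qr(matrix(rnorm(9), 3, 3)))
  })
  res <- procrustes_align(sets, n_iter = 10)
  expect_true(all(diff(res$discrepancy) <= 1e-10))
  var_at_roi <- function(mats) {
    mean(apply(simplify2array(mats), c(1, 2), var))
  }
  v_before <- var_at_roi(sets)
  v_after <- var_at_roi(lapply(res$aligned, `[[`, "scores"))
  expect_lte(v_after, v_before)
})

test_that("gradient span is the range over included ROIs", {
  expect_equal(gradient_span(rep(3, 7)), 0)
  expect_equal(gradient_span(c(-2, 0, 3)), 5)
  set.seed(15)
  for (i in 1:10) {
    v <- rnorm(50)
    expect_equal(gradient_span(v), max(v) - min(v))
  }
  v <- setNames(c(1, 5, 9), c("a", "b", "c"))
  expect_equal(gradient_span(v, roi_subset = c("a", "b")), 4)
  expect_error(gradient_span(v, roi_subset = character(0)), "empty")
})

test_that("principal selection returns component 1 with its eigenvalue share", {
  gs <- connectograd:::new_gradient_set(
    scores = matrix(0, 5, 3), eigenvalues = c(0.5, 0.3, 0.2),
    explained_ratio = c(0.5, 0.3, 0.2) / 1, alpha = 0.5, diffusion_time = 0,
    aligned = FALSE, variance_ratio = c(0.6, 0.25, 0.15))
  sel <- select_principal(gs)
  expect_identical(sel$index, 1L)
  expect_equal(sel$explained_ratio, 0.5)
  expect_true(all(diff(sel$scree$explained_ratio) <= 0))
})

test_that("orientation fixes signs by reference and by network anchors", {
  set.seed(16)
  sc <- matrix(rnorm(20), 10, 2)
  gs <- connectograd:::as_gradient_set(sc)
  flipped <- connectograd:::as_gradient_set(-sc)
  out <- orient_gradients(flipped, reference = sc)
  expect_equal(out$scores, sc)
  # anchor orientation: association mean must exceed primary mean
  sc2 <- matrix(c(rep(-1, 5), rep(1, 5)), 10, 1)
  g <- orient_gradients(connectograd:::as_gradient_set(-sc2),
                        assoc_rois = 6:10, primary_rois = 1:5)
  expect_true(mean(g$scores[6:10, 1]) > mean(g$scores[1:5, 1]))
})
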