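test_that("network scores are group-by means of component scores", {
  sc <- matrix(c(1, 3, 5), 3, 1, dimnames = list(c("r1", "r2", "r3"), NULL))
  part <- data.frame(roi_id = c("r1", "r2", "r3"),
                     network = c("A", "A", "B"))
  expect_equal(network_scores(sc, part), c(A = 2, B = 5))

  const <- matrix(7, 3, 1, dimnames = list(c("r1", "r2", "r3"), NULL))
  expect_equal(unname(network_scores(const, part)), c(7, 7))

  set.seed(17)
  sc2 <- matrix(rnorm(60), 60, 1, dimnames = list(sprintf("r%02d", 1:60), NULL))
  part2 <- data.frame(roi_id = rownames(sc2),
                      network = sample(LETTERS[1:5], 60, replace = TRUE))
  got <- network_scores(sc2, part2)
  want <- c(tapply(sc2[part2$roi_id, 1], part2$network, mean))
  expect_equal(got[sort(names(got))], want[sort(names(want))],
               tolerance = 1e-12)
})

test_that("identical paired groups give t = 0, p = 1; constant shifts are flagged", {
  a <- matrix(rnorm(30), 10, 3)
  res <- roiwise_compare(a, a, paired = TRUE)
  expect_equal(res$t, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  expect_false(any(res$degenerate))

  b <- a + 1   # constant difference per ROI: zero variance, nonzero mean
  res2 <- roiwise_compare(a, b, paired = TRUE)
  expect_true(all(res2$degenerate))
  expect_true(all(is.na(res2$p)))
})

test_that("planted ROI shifts are detected with FDR control", {
  set.seed(18)
  hits <- 0L
  total <- 0L
  for (rep in 1:100) {
    a <- matrix(rnorm(40 * 100), 40, 100)
    b <- matrix(rnorm(40 * 100), 40, 100)
    b[, 1:20] <- b[, 1:20] + 1          # 1-SD shift in 20 of 100 ROIs
    res <- roiwise_compare(a, b, q = 0.05)
    hits <- hits + sum(res$reject[1:20])
    total <- total + 20L
  }
  expect_gte(hits / total, 0.80)
})

test_that("BH adjustment matches the step-up definition", {
  got <- fdr_bh(c(0.01, 0.02, 0.04, 0.05), q = 0.05)
  expect_true(all(got$reject))
  expect_equal(fdr_bh(rep(1, 6))$reject, rep(FALSE, 6))

  set.seed(19)
  for (i in 1:20) {
    p <- runif(50)^2
    got <- fdr_bh(p, q = 0.05)
    expect_equal(got$reject, brute_bh_reject(p, 0.05))
    o <- order(p)
    expect_true(all(diff(got$p_adjusted[o]) >= -1e-12))
    expect_true(all(got$p_adjusted >= p))
  }
  expect_error(fdr_bh(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("a 10-SD separation is classified perfectly", {
  set.seed(20)
  n <- 40
  x <- cbind(f1 = c(rnorm(n / 2), rnorm(n / 2) + 10), f2 = rnorm(n))
  y <- rep(c("control", "patient"), each = n / 2)
  rep <- classify(list(FCG1 = x), y, feature_sets = "FCG1", folds = 5,
                  seed = 1)$FCG1
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$auc, 1.0)
  expect_true(all(diff(rep$roc_points$fpr) >= 0))
  expect_true(all(diff(rep$roc_points$tpr) >= 0))
})

test_that("permuted labels classify at chance", {
  set.seed(22)
  n <- 110
  x <- matrix(rnorm(n * 7), n, 7)
  y <- sample(rep(c("control", "patient"), c(55, 55)))
  rep <- classify(list(FCG1 = x), y, feature_sets = "FCG1", folds = 5,
                  seed = 2)$FCG1
  band <- 1.96 * sqrt(0.25 / n)
  expect_gt(rep$accuracy, 0.5 - band)
  expect_lt(rep$accuracy, 0.5 + band)
})

test_that("single-class folds are rejected with advice", {
  x <- matrix(rnorm(12), 6, 2)
  y <- c("a", "a", "a", "a", "a", "b")
  expect_error(classify(list(F = x), y, feature_sets = "F", folds = 5),
               "fewer folds")
})

test_that("delta features follow the absolute-magnitude convention", {
  pre <- matrix(c(-0.4, 0.2), 1, 2, dimnames = list(NULL, c("DAN", "DMN")))
  post <- matrix(c(0.1, 0.2), 1, 2, dimnames = list(NULL, c("DAN", "DMN")))
  d <- delta_features(pre, post)
  expect_equal(unname(d[1, "DAN"]), 0.4 - 0.1)
  expect_equal(unname(d[1, "DMN"]), 0)
  subj <- data.frame(updrs3_pre = 31, updrs3_post = 28)
  expect_equal(delta_clinical(subj), 3)
  expect_error(delta_clinical(data.frame(updrs3_pre = 31,
                                         updrs3_post = NA_real_)), "missing")
})

test_that("partial correlation removes shared covariate effects", {
  expect_equal(partial_correlation(1:10, 1:10)$r, 1)

  set.seed(23)
  n <- 500
  age <- rnorm(n, 60, 10)
  x <- 0.1 * age + rnorm(n)
  y <- -0.05 * age + rnorm(n)
  res <- partial_correlation(x, y, data.frame(age = age, sex = rbinom(n, 1, 0.5)))
  expect_lt(abs(res$r), 0.1)

  # planted residual correlation of 0.5 at n = 76 is recovered
  set.seed(24)
  rs <- replicate(20, {
    n <- 76
    age <- rnorm(n, 60, 10)
    sex <- rbinom(n, 1, 0.5)
    z <- rnorm(n)
    x <- 0.05 * age + 0.3 * sex + z + rnorm(n)
    y <- -0.02 * age + 0.1 * sex + 0.5 * (z + rnorm(n))  # shared component
    partial_correlation(x, y, data.frame(age = age, sex = sex))$r
  })
  expect_lt(abs(mean(rs) - 0.5), 0.15)
})

test_that("partial correlation with constant covariates is plain Pearson", {
  set.seed(25)
  x <- rnorm(30)
  y <- rnorm(30)
  res <- partial_correlation(x, y, data.frame(z = rep(1, 30)))
  expect_equal(res$r, cor(x, y))
  expect_equal(res$p, cor.test(x, y)$p.value, tolerance = 1e-12)
  expect_error(partial_correlation(1:4, 1:4, data.frame(a = 1:4, b = 2 * 1:4)),
               "rank|n >")
})
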