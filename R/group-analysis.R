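#' Network-mean gradient scores
#'
#' Aggregates one gradient component to the network level: the arithmetic
#' mean of the component's ROI scores within each network of the
#' parcellation.
#'
#' @param gs a \code{gradient_set} (aligned scores) or R x k score matrix
#'   with ROI rownames.
#' @param partition data.frame with columns \code{roi_id} and
#'   \code{network}, or a named character vector \code{roi_id -> network}.
#' @param component component index (default 1, the principal gradient).
#' @return named numeric vector of per-network means, ordered by first
#'   appearance of each network in the partition.
#' @export
network_scores <- function(gs, partition, component = 1L) {
  sc <- gradient_scores(gs)
  part <- as_partition(partition)
  rois <- names(part)
  if (!all(rois %in% rownames(sc))) {
    stop("partition references ROIs absent from the gradient set: ",
         paste(setdiff(rois, rownames(sc)), collapse = ", "))
  }
  v <- sc[rois, component]
  labels <- unique(unname(part))
  out <- vapply(labels, function(l) {
    idx <- part == l
    if (!any(idx)) stop("empty network: ", l)
    mean(v[idx])
  }, numeric(1L))
  names(out) <- labels
  out
}

as_partition <- function(partition) {
  if (is.data.frame(partition)) {
    stats::setNames(as.character(partition$network),
                    as.character(partition$roi_id))
  } else {
    stats::setNames(as.character(partition), names(partition))
  }
}

#' Unit-wise two-sample comparison with FDR correction
#'
#' Runs, per column (ROI or network), a two-sided t test between two groups
#' — Welch's test for independent groups, a paired t test when
#' \code{paired = TRUE} — then adjusts the p values across units by the
#' Benjamini-Hochberg procedure.
#'
#' Degenerate units are flagged rather than returning infinities: when the
#' relevant variance is zero and the mean difference is also zero the unit
#' gets \code{t = 0, p = 1}; when the variance is zero but the means
#' differ, \code{degenerate = TRUE} and \code{t}/\code{p} are \code{NA}
#' (excluded from the FDR family).
#'
#' @param a,b numeric matrices, subjects x units; equal row counts in
#'   matched order when \code{paired = TRUE}.
#' @param paired paired t test instead of Welch (default FALSE).
#' @param q FDR level for the rejection mask (default 0.05).
#' @return data.frame: unit, t, p, p_fdr, direction (sign of mean(a) -
#'   mean(b)), reject, degenerate.
#' @export
roiwise_compare <- function(a, b, paired = FALSE, q = 0.05) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b)) stop("groups must share units")
  if (nrow(a) < 3L || nrow(b) < 3L) stop("need at least 3 subjects per group")
  if (paired && nrow(a) != nrow(b)) {
    stop("paired comparison requires equal, matched subject counts")
  }
  units <- colnames(a)
  if (is.null(units)) units <- paste0("unit", seq_len(ncol(a)))
  # variance indistinguishable from zero at double precision (the same
  # guard scale t.test uses before declaring data essentially constant)
  flat <- function(v) stats::sd(v) < 1e4 * .Machine$double.eps *
    max(1, abs(mean(v)))
  res <- lapply(seq_len(ncol(a)), function(i) {
    x <- a[, i]; y <- b[, i]
    if (paired) {
      d <- x - y
      if (flat(d)) {
        if (abs(mean(d)) < 1e4 * .Machine$double.eps) {
          return(c(t = 0, p = 1, deg = 0))
        }
        return(c(t = NA_real_, p = NA_real_, deg = 1))
      }
      tt <- stats::t.test(x, y, paired = TRUE)
    } else {
      if (flat(x) && flat(y)) {
        if (abs(mean(x) - mean(y)) < 1e4 * .Machine$double.eps) {
          return(c(t = 0, p = 1, deg = 0))
        }
        return(c(t = NA_real_, p = NA_real_, deg = 1))
      }
      tt <- stats::t.test(x, y, var.equal = FALSE)
    }
    c(t = unname(tt$statistic), p = tt$p.value, deg = 0)
  })
  res <- do.call(rbind, res)
  fdr <- fdr_bh(res[, "p"], q = q)
  data.frame(unit = units,
             t = res[, "t"],
             p = res[, "p"],
             p_fdr = fdr$p_adjusted,
             direction = sign(colMeans(a) - colMeans(b)),
             reject = fdr$reject,
             degenerate = res[, "deg"] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment of a vector of p values plus the rejection mask
#' at level \code{q}. \code{NA} p values are carried through unadjusted and
#' never rejected.
#'
#' @param pvals numeric p values in \code{[0, 1]} (NAs allowed).
#' @param q FDR level (default 0.05).
#' @return list with \code{p_adjusted} and logical \code{reject}.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p values must lie in [0, 1]")
  adj <- rep(NA_real_, length(pvals))
  adj[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  list(p_adjusted = adj, reject = !is.na(adj) & adj <= q)
}

#' SVM classification of network gradient features
#'
#' Discriminates patients from controls with a linear-kernel support vector
#' machine on network-level gradient scores, evaluated by stratified k-fold
#' cross-validation: features are standardized with training-fold
#' statistics only, out-of-fold decision values are pooled into one ROC
#' curve, and accuracy is the pooled out-of-fold correct fraction.
#'
#' @param features named list of per-subject feature matrices (subjects x
#'   networks), e.g. \code{list(FCG1 = ..., STG1 = ...)}; feature set
#'   \code{"combined"} concatenates all of them column-wise.
#' @param labels factor or character vector of class labels per subject
#'   (two classes; the second level is treated as the positive class).
#' @param feature_sets which reports to produce: any of the names of
#'   \code{features} and \code{"combined"} (default all plus combined).
#' @param folds number of stratified CV folds (default 5).
#' @param cost SVM regularization constant C (default 1).
#' @param seed seed for the fold assignment.
#' @return named list of \code{classifier_report}s: each a list with
#'   \code{feature_set}, \code{accuracy}, \code{auc}, \code{roc_points}
#'   (data.frame fpr/tpr), \code{cv_scheme}.
#' @export
classify <- function(features, labels, feature_sets = NULL, folds = 5L,
                     cost = 1, seed = 1L) {
  stopifnot(is.list(features), length(features) >= 1L)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("exactly two classes required")
  n <- length(y)
  for (f in features) {
    if (nrow(as.matrix(f)) != n) stop("features and labels disagree on n")
  }
  if (is.null(feature_sets)) {
    feature_sets <- c(names(features),
                      if (length(features) > 1L) "combined")
  }
  fold_id <- stratified_folds(y, folds, seed)
  if (min(table(y, fold_id)) < 1L) {
    stop("a fold has a single class; use fewer folds")
  }
  pos <- levels(y)[2L]
  reports <- lapply(feature_sets, function(fs) {
    X <- if (fs == "combined") {
      do.call(cbind, lapply(features, as.matrix))
    } else {
      as.matrix(features[[fs]])
    }
    dv <- numeric(n)
    pred <- character(n)
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      mu <- colMeans(X[tr, , drop = FALSE])
      sd_ <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
      sd_[sd_ == 0] <- 1
      Xs <- sweep(sweep(X, 2L, mu), 2L, sd_, "/")
      fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "linear",
                        cost = cost, scale = FALSE)
      pr <- stats::predict(fit, Xs[!tr, , drop = FALSE],
                           decision.values = TRUE)
      d <- drop(attr(pr, "decision.values"))
      # decision values are signed toward the first class in the colname
      if (grepl(paste0("^", pos, "/"), colnames(attr(pr, "decision.values"))[1L])) {
        d <- d
      } else {
        d <- -d
      }
      dv[!tr] <- d
      pred[!tr] <- as.character(pr)
    }
    roc <- pROC::roc(response = y, predictor = dv, levels = levels(y),
                     direction = "<", quiet = TRUE)
    list(feature_set = fs,
         accuracy = mean(pred == as.character(y)),
         auc = as.numeric(pROC::auc(roc)),
         roc_points = data.frame(fpr = rev(1 - roc$specificities),
                                 tpr = rev(roc$sensitivities)),
         cv_scheme = sprintf("stratified %d-fold, linear SVM, C=%g, seed=%d",
                             folds, cost, as.integer(seed)))
  })
  names(reports) <- feature_sets
  reports
}

stratified_folds <- function(y, folds, seed) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)
  fold_id <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_id
}

#' Per-network gradient change between sessions
#'
#' \code{|pre network score| - |post network score|}, per network and
#' subject: positive values mean the gradient magnitude moved toward zero
#' after treatment.
#'
#' @param pre,post subjects x networks matrices of network gradient scores
#'   in matched subject order.
#' @return subjects x networks matrix of score changes.
#' @export
delta_features <- function(pre, post) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  if (!all(dim(pre) == dim(post))) stop("pre/post sessions are not matched")
  abs(pre) - abs(post)
}

#' Clinical motor-score change
#'
#' Pre-treatment minus post-treatment UPDRS-III total score; positive
#' values are improvement.
#'
#' @param subjects data.frame with \code{updrs3_pre} and \code{updrs3_post}.
#' @return numeric vector of score changes.
#' @export
delta_clinical <- function(subjects) {
  if (anyNA(subjects$updrs3_pre) || anyNA(subjects$updrs3_post)) {
    stop("missing pre or post clinical score")
  }
  subjects$updrs3_pre - subjects$updrs3_post
}

#' Covariate-controlled Pearson correlation
#'
#' Residualizes both variables on \code{[intercept, covariates]} by least
#' squares and reports the Pearson correlation of the residuals, with a
#' two-sided p value on \code{n - 2 - n_covariates} degrees of freedom.
#' With no covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional data.frame or matrix of covariates (e.g. age
#'   and sex), one row per observation.
#' @param label optional label (e.g. the network name) carried into the
#'   result.
#' @return data.frame: label, r, p, n, df, covariates (comma-separated).
#' @export
partial_correlation <- function(x, y, covariates = NULL, label = NA_character_) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1L)
    cov_names <- ""
  } else {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(v) stats::sd(as.numeric(v)) > 0,
                   logical(1L))
    Z <- if (any(keep)) {
      stats::model.matrix(~ ., data = covariates[, keep, drop = FALSE])
    } else {
      matrix(1, n, 1L)
    }
    cov_names <- paste(names(covariates)[keep], collapse = ",")
  }
  n_cov <- ncol(Z) - 1L
  if (n <= n_cov + 2L) stop("need n > number of covariates + 2")
  if (qr(Z)$rank < ncol(Z)) stop("covariate design is rank deficient")
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  r <- stats::cor(rx, ry)
  df <- n - 2L - n_cov
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tval), df)
  }
  data.frame(label = label, r = r, p = p, n = n, df = df,
             covariates = cov_names, stringsAsFactors = FALSE)
}
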