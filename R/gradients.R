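#' Row-wise sparsification of a connectivity matrix
#'
#' Keeps, per row, the top \code{keep_fraction} of off-diagonal entries by
#' value and zeroes the rest; negative entries are zeroed first and the
#' diagonal is excluded from the ranking. Ties are broken in favour of the
#' lower column index so the result is deterministic. This is the standard
#' preprocessing step before computing a cosine-affinity matrix from a
#' connectome.
#'
#' @param m square numeric matrix (a \code{connectivity_matrix} or plain
#'   matrix).
#' @param keep_fraction fraction of off-diagonal entries retained per row,
#'   in (0, 1]; default 0.10 (i.e. 90\% row sparsity).
#' @return nonnegative matrix of the same dimensions; diagonal zero.
#' @export
sparsify_rows <- function(m, keep_fraction = 0.10) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  x <- unclass(as.matrix(m))
  R <- nrow(x)
  x[x < 0] <- 0
  diag(x) <- 0
  n_keep <- ceiling(keep_fraction * (R - 1L))
  out <- matrix(0, R, R, dimnames = dimnames(x))
  for (i in seq_len(R)) {
    row <- x[i, ]
    idx <- setdiff(order(row, seq_len(R), decreasing = c(TRUE, FALSE),
                         method = "radix"), i)
    keep <- idx[seq_len(n_keep)]
    out[i, keep] <- row[keep]
  }
  out
}

#' Cosine-similarity affinity matrix
#'
#' Entry (i, k) is the cosine of rows i and k of the sparsified connectivity
#' matrix: the similarity of two regions' connectivity profiles. Negative
#' cosines are clipped to zero so the matrix is a valid nonnegative affinity
#' for the Markov construction of the diffusion map; the diagonal is 1.
#'
#' @param rows sparsified connectivity matrix (see [sparsify_rows()]).
#' @return an \code{affinity_matrix}: symmetric R x R matrix with entries in
#'   \code{[0, 1]} and unit diagonal.
#' @export
cosine_affinity <- function(rows) {
  x <- unclass(as.matrix(rows))
  norms <- sqrt(rowSums(x^2))
  if (any(norms == 0)) {
    stop("all-zero row(s) for ROI(s): ",
         paste(rownames(x)[norms == 0], collapse = ", "))
  }
  a <- tcrossprod(x / norms)
  a[a < 0] <- 0
  a[a > 1] <- 1
  a <- (a + t(a)) / 2
  diag(a) <- 1
  structure(a, class = c("affinity_matrix", "matrix", "array"))
}

#' Diffusion-map embedding of an affinity matrix
#'
#' Computes connectome gradients: the affinity W is density-normalized with
#' parameter \code{alpha} (\code{W' = D^-alpha W D^-alpha}, D the diagonal
#' of row sums), turned into a Markov transition operator by row
#' normalization, and eigendecomposed. The trivial stationary eigenvector
#' (eigenvalue 1) is dropped; component c is the next eigenvector scaled by
#' \code{lambda_c^t}, or by the multiscale factor \code{lambda_c / (1 -
#' lambda_c)} when \code{diffusion_time = 0}. \code{alpha = 0.5} retains the
#' global relations between points while discounting sampling density.
#'
#' The eigenproblem of the (nonsymmetric) Markov operator is solved through
#' its symmetric conjugate \code{D'^-1/2 W' D'^-1/2}, which shares its
#' eigenvalues and maps eigenvectors by \code{D'^-1/2}.
#'
#' @param aff symmetric nonnegative affinity matrix with positive diagonal,
#'   connected as a graph.
#' @param alpha anisotropic normalization parameter in \code{[0, 1]}
#'   (default 0.5).
#' @param diffusion_time diffusion time t; 0 (default) selects multiscale
#'   scaling.
#' @param n_components number of non-trivial components to retain.
#' @return a \code{gradient_set}: list with \code{scores} (R x k matrix),
#'   \code{eigenvalues}, \code{explained_ratio} (eigenvalue of each retained
#'   component over the retained total), \code{variance_ratio} (each
#'   component's scaling weight over the retained total — the share of
#'   embedding variance a scree plot shows), \code{alpha},
#'   \code{diffusion_time}, \code{aligned = FALSE}.
#' @export
diffusion_map <- function(aff, alpha = 0.5, diffusion_time = 0,
                          n_components = 10L) {
  W <- unclass(as.matrix(aff))
  R <- nrow(W)
  if (max(abs(W - t(W))) > 1e-10) stop("affinity must be symmetric")
  if (min(W) < 0) stop("affinity must be nonnegative")
  comp <- graph_components(W > 0)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop("affinity graph is disconnected; component sizes: ",
         paste(sizes, collapse = ", "))
  }
  d <- rowSums(W)
  W1 <- W * tcrossprod(d^(-alpha))
  d1 <- rowSums(W1)
  inv_sqrt <- 1 / sqrt(d1)
  S <- W1 * tcrossprod(inv_sqrt)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  lambdas <- es$values
  psi <- es$vectors * inv_sqrt            # eigenvectors of the Markov operator
  # scale relative to the stationary eigenvector (constant up to normalization)
  psi <- psi / psi[, 1L]
  k <- min(n_components, R - 1L)
  lam <- lambdas[2L:(k + 1L)]
  scale_fac <- if (diffusion_time == 0) lam / (1 - lam) else lam^diffusion_time
  scores <- psi[, 2L:(k + 1L), drop = FALSE] *
    rep(scale_fac, each = R)
  rownames(scores) <- if (is.null(rownames(W))) {
    paste0("roi", seq_len(R))
  } else {
    rownames(W)
  }
  new_gradient_set(scores = scores, eigenvalues = lam,
                   explained_ratio = lam / sum(lam),
                   variance_ratio = scale_fac / sum(scale_fac),
                   alpha = alpha, diffusion_time = diffusion_time,
                   aligned = FALSE)
}

#' Iterative Procrustes alignment of gradient sets
#'
#' Aligns each subject's gradient components onto a common template by
#' orthogonal rotation. Iteratively: the reference is the element-wise mean
#' of the currently aligned sets (initialized to the first set, typically a
#' group-average template placed first in the list); each set is rotated
#' onto the reference by the orthogonal transform minimizing the Frobenius
#' discrepancy, obtained from the singular value decomposition of the
#' crossproduct. Stops after \code{n_iter} iterations or when the
#' discrepancy improves by less than \code{tol}.
#'
#' @param sets list of \code{gradient_set} objects (or R x k score
#'   matrices) sharing dimensions.
#' @param n_iter maximum iterations (default 10).
#' @param tol convergence tolerance on the summed squared discrepancy.
#' @return list with \code{aligned} (the aligned gradient sets),
#'   \code{rotations} (per-subject k x k orthogonal matrices),
#'   \code{reference} (final R x k template), \code{iterations_run} and
#'   \code{discrepancy} (per-iteration summed squared residual,
#'   non-increasing).
#' @export
procrustes_align <- function(sets, n_iter = 10L, tol = 1e-8) {
  mats <- lapply(sets, gradient_scores)
  dims <- lapply(mats, dim)
  if (length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L) {
    stop("all gradient sets must share R and k")
  }
  n <- length(mats)
  k <- ncol(mats[[1L]])
  rotations <- rep(list(diag(k)), n)
  aligned <- mats
  reference <- mats[[1L]]
  disc_hist <- numeric(0L)
  for (it in seq_len(n_iter)) {
    disc <- 0
    for (j in seq_len(n)) {
      sv <- svd(crossprod(mats[[j]], reference))
      Q <- sv$u %*% t(sv$v)
      rotations[[j]] <- Q
      aligned[[j]] <- mats[[j]] %*% Q
      disc <- disc + sum((aligned[[j]] - reference)^2)
    }
    disc_hist <- c(disc_hist, disc)
    reference_new <- Reduce(`+`, aligned) / n
    if (it > 1L && disc_hist[it - 1L] - disc < tol) {
      reference <- reference_new
      break
    }
    reference <- reference_new
  }
  aligned_sets <- lapply(seq_along(sets), function(j) {
    gs <- as_gradient_set(sets[[j]])
    gs$scores <- aligned[[j]]
    gs$aligned <- TRUE
    gs
  })
  list(aligned = aligned_sets, rotations = rotations, reference = reference,
       iterations_run = length(disc_hist), discrepancy = disc_hist)
}

#' Gradient span of one component
#'
#' The range (max minus min) of a gradient component's scores over the
#' included ROIs — a per-participant summary of functional (or structural)
#' differentiation along that axis.
#'
#' @param scores numeric vector of one component's ROI scores, or a
#'   \code{gradient_set} (then \code{component} selects the column).
#' @param roi_subset optional character or integer subset of ROIs.
#' @param component component index used when \code{scores} is a
#'   \code{gradient_set} (default 1).
#' @return nonnegative scalar.
#' @export
gradient_span <- function(scores, roi_subset = NULL, component = 1L) {
  if (inherits(scores, "gradient_set")) scores <- scores$scores[, component]
  v <- as.numeric(scores)
  names(v) <- names(scores)
  if (!is.null(roi_subset)) v <- v[roi_subset]
  if (length(v) == 0L || anyNA(v)) stop("empty or invalid ROI subset")
  max(v) - min(v)
}

#' Principal-gradient selection with scree report
#'
#' Returns the index of the principal component (largest eigenvalue) plus a
#' scree table for reporting: per component, the eigenvalue, its share of
#' the retained eigenvalue mass (\code{explained_ratio}) and its share of
#' the component scaling weights (\code{variance_ratio}) — the latter is
#' the quantity a scree plot of the embedding shows, since component
#' scores are scaled by those weights.
#'
#' @param gs a \code{gradient_set}.
#' @return list with \code{index} (always 1: components are sorted),
#'   \code{explained_ratio} and \code{variance_ratio} of the chosen
#'   component, and \code{scree}, a data.frame of component, eigenvalue
#'   and both ratios.
#' @export
select_principal <- function(gs) {
  gs <- as_gradient_set(gs)
  k <- length(gs$eigenvalues)
  scree <- data.frame(component = seq_len(k),
                      eigenvalue = gs$eigenvalues,
                      explained_ratio = gs$explained_ratio,
                      variance_ratio = gs$variance_ratio)
  list(index = 1L, explained_ratio = gs$explained_ratio[1L],
       variance_ratio = gs$variance_ratio[1L], scree = scree)
}

#' Orient gradient components by a sign convention
#'
#' Eigenvector signs are arbitrary; this fixes them. With a
#' \code{reference} matrix, each component is flipped so its correlation
#' with the matching reference column is positive. Without one, each
#' component is oriented so the mean score of the designated association
#' network exceeds the mean score of the designated primary (visual)
#' network — the principal functional gradient then runs low-to-high from
#' primary to association cortex; components for which the two network
#' means tie fall back to making the largest-magnitude score positive.
#'
#' @param gs \code{gradient_set} (or score matrix).
#' @param reference optional R x k reference score matrix.
#' @param assoc_rois,primary_rois ROI indices (or names) of the association
#'   and primary networks, used when no reference is given.
#' @return the gradient set with consistently oriented columns.
#' @export
orient_gradients <- function(gs, reference = NULL, assoc_rois = NULL,
                             primary_rois = NULL) {
  g <- as_gradient_set(gs)
  sc <- g$scores
  for (c in seq_len(ncol(sc))) {
    v <- sc[, c]
    flip <- FALSE
    if (!is.null(reference)) {
      s <- sum(v * reference[, c])
      flip <- s < 0
    } else if (!is.null(assoc_rois) && !is.null(primary_rois)) {
      delta <- mean(v[assoc_rois]) - mean(v[primary_rois])
      flip <- if (delta != 0) delta < 0 else v[which.max(abs(v))] < 0
    } else {
      flip <- v[which.max(abs(v))] < 0
    }
    if (flip) sc[, c] <- -v
  }
  g$scores <- sc
  g
}

# ---- internal ---------------------------------------------------------------

new_gradient_set <- function(scores, eigenvalues, explained_ratio, alpha,
                             diffusion_time, aligned,
                             variance_ratio = rep(NA_real_, ncol(scores))) {
  structure(list(scores = scores, eigenvalues = eigenvalues,
                 explained_ratio = explained_ratio,
                 variance_ratio = variance_ratio, alpha = alpha,
                 diffusion_time = diffusion_time, aligned = aligned),
            class = "gradient_set")
}

as_gradient_set <- function(x) {
  if (inherits(x, "gradient_set")) return(x)
  m <- as.matrix(x)
  new_gradient_set(scores = m, eigenvalues = rep(NA_real_, ncol(m)),
                   explained_ratio = rep(NA_real_, ncol(m)),
                   alpha = NA_real_, diffusion_time = NA_real_,
                   aligned = FALSE)
}

gradient_scores <- function(x) {
  if (inherits(x, "gradient_set")) x$scores else as.matrix(x)
}

# connected components of an undirected adjacency (logical) matrix
graph_components <- function(adj) {
  R <- nrow(adj)
  comp <- integer(R)
  cur <- 0L
  for (s in seq_len(R)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(sprintf("<gradient_set> %d ROIs x %d components, alpha=%s, t=%s, %s\n",
              nrow(x$scores), ncol(x$scores), format(x$alpha),
              format(x$diffusion_time),
              if (isTRUE(x$aligned)) "aligned" else "unaligned"))
  invisible(x)
}
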