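#' Fisher-Z functional connectome from a parcellated time series
#'
#' Computes the region-by-region Pearson correlation matrix of a T x R
#' ROI time-series matrix and applies the Fisher Z-transformation
#' (\code{atanh}) to every off-diagonal entry. Correlations are clipped to
#' \code{|r| <= 1 - clip} before the transform so the result is always
#' finite; the diagonal is set to zero.
#'
#' @param ts numeric T x R matrix (rows = time points, columns = ROIs) or a
#'   \code{parcellated_ts} object from [read_timeseries_tsv()]. Column names
#'   are used as ROI identifiers.
#' @param clip distance from 1 at which correlations are clipped
#'   (default \code{1e-7}).
#' @return a \code{connectivity_matrix}: symmetric R x R matrix with zero
#'   diagonal and attributes \code{kind = "functional"} and \code{roi_ids}.
#' @examples
#' ts <- matrix(rnorm(400), 100, 4, dimnames = list(NULL, paste0("roi", 1:4)))
#' fc <- functional_connectome(ts)
#' @export
functional_connectome <- function(ts, clip = 1e-7) {
  x <- as_ts_matrix(ts)
  if (nrow(x) < 3L) stop("time series must have at least 3 time points")
  if (anyNA(x)) stop("time series contains missing values")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance time series for ROI(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(x)
  r <- pmin(pmax(r, -1 + clip), 1 - clip)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  new_connectivity(z, kind = "functional", roi_ids = colnames(x))
}

#' Regress confounds out of a collection of connectomes
#'
#' For every edge independently, fits ordinary least squares across subjects
#' on \code{[intercept, covariates]} and replaces the edge value by
#' \code{residual + intercept}: covariate effects are removed while the
#' grand mean is preserved. Symmetry of each matrix is preserved because the
#' same operation is applied to entries (i,k) and (k,i).
#'
#' @param mats list of \code{connectivity_matrix} objects (same ROI order).
#' @param covariates data.frame or matrix of per-subject covariates (e.g.
#'   age in years and a 0/1 sex indicator), one row per matrix.
#' @return list of residualized \code{connectivity_matrix} objects.
#' @export
regress_confounds <- function(mats, covariates) {
  stopifnot(is.list(mats), length(mats) >= 3L)
  X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  # center the covariate columns so the intercept carries the group mean
  X[, -1L] <- scale(X[, -1L, drop = FALSE], center = TRUE, scale = FALSE)
  if (nrow(X) != length(mats)) {
    stop("covariates must have one row per connectivity matrix")
  }
  if (qr(X)$rank < ncol(X)) stop("covariate design is rank deficient")
  roi_ids <- attr(mats[[1L]], "roi_ids")
  kind <- attr(mats[[1L]], "kind")
  R <- nrow(mats[[1L]])
  for (m in mats) {
    if (!identical(dim(m), c(R, R))) stop("all matrices must share dimensions")
  }
  ut <- upper.tri(matrix(0, R, R))
  E <- vapply(mats, function(m) unclass(m)[ut], numeric(sum(ut)))
  if (is.null(dim(E))) E <- matrix(E, nrow = 1L)
  E <- t(E)                                  # subjects x edges
  fit <- stats::lm.fit(X, E)
  resid <- as.matrix(fit$residuals)
  intercepts <- as.matrix(fit$coefficients)[1L, ]
  E_out <- sweep(resid, 2L, intercepts, "+")
  lapply(seq_along(mats), function(j) {
    v <- matrix(0, R, R)
    v[ut] <- E_out[j, ]
    v <- v + t(v)
    new_connectivity(v, kind = kind, roi_ids = roi_ids)
  })
}

#' Kernel density of vertex surface-area values on a common grid
#'
#' Gaussian kernel density estimate with Silverman's rule-of-thumb
#' bandwidth, evaluated on a shared equispaced grid, floored at a small
#' positive mass and renormalized to sum to one. The floor guarantees the
#' Kullback-Leibler divergence between any two densities on the grid is
#' finite.
#'
#' @param values numeric vector of vertex surface-area values (mm^2), >= 2.
#' @param grid equispaced numeric grid covering all values (see
#'   [common_area_grid()]).
#' @param floor minimum mass per grid point before renormalization.
#' @return a \code{discrete_density}: list with \code{grid} and \code{mass}
#'   (sums to 1).
#' @export
estimate_density <- function(values, grid, floor = 1e-12) {
  if (length(values) < 2L) stop("need at least 2 values per ROI")
  if (min(values) < min(grid) || max(values) > max(grid)) {
    stop("grid does not cover the value range")
  }
  if (stats::sd(values) == 0) {
    h <- 1e-3 * mean(values)
    warning("identical values: falling back to bandwidth 1e-3 * mean(values)")
  } else {
    h <- stats::bw.nrd0(values)
  }
  d <- stats::density(values, bw = h, kernel = "gaussian",
                      from = min(grid), to = max(grid), n = length(grid))
  mass <- pmax(d$y, 0)
  mass <- mass / sum(mass)
  mass <- pmax(mass, floor)
  mass <- mass / sum(mass)
  structure(list(grid = grid, mass = mass), class = "discrete_density")
}

#' Common evaluation grid for one subject's vertex-area densities
#'
#' Builds the shared equispaced grid over \code{[min - 3h, max + 3h]} of the
#' pooled values, where \code{h} is the largest Silverman bandwidth across
#' ROIs, so that every per-ROI density lives on one grid and the R x R
#' divergence computation reduces to shared density vectors.
#'
#' @param area_list list of numeric vectors, one per ROI.
#' @param n_points grid resolution (default 256).
#' @return numeric grid vector of length \code{n_points}.
#' @export
common_area_grid <- function(area_list, n_points = 256L) {
  pooled <- unlist(area_list, use.names = FALSE)
  bws <- vapply(area_list, function(v) {
    if (stats::sd(v) == 0) 1e-3 * mean(v) else stats::bw.nrd0(v)
  }, numeric(1L))
  h <- max(bws)
  seq(min(pooled) - 3 * h, max(pooled) + 3 * h, length.out = n_points)
}

#' Kullback-Leibler divergence between two discrete densities
#'
#' \code{sum(f1 * log(f1 / f2))} over the shared grid, in nats. Both inputs
#' must be floored (strictly positive) densities on the same grid.
#'
#' @param f1,f2 \code{discrete_density} objects on the same grid.
#' @return nonnegative scalar (nats).
#' @export
kl_divergence <- function(f1, f2) {
  check_same_grid(f1, f2)
  sum(f1$mass * (log(f1$mass) - log(f2$mass)))
}

#' Symmetric Kullback-Leibler divergence
#'
#' The mean of the two directed divergences,
#' \code{(KL(f1 || f2) + KL(f2 || f1)) / 2}; symmetric in its arguments and
#' zero iff the two densities coincide on the grid.
#'
#' @inheritParams kl_divergence
#' @return nonnegative scalar (nats).
#' @export
symmetric_kl <- function(f1, f2) {
  (kl_divergence(f1, f2) + kl_divergence(f2, f1)) / 2
}

#' Symmetric-KL structural connectome from vertex surface areas
#'
#' Estimates a per-ROI density of vertex surface-area values on one
#' subject-wide common grid and fills the R x R matrix of pairwise symmetric
#' KL divergences: small divergence means similar cortical morphology. The
#' result has zero diagonal, is symmetric and nonnegative.
#'
#' @param vt a \code{vertex_area_table} (see [read_vertex_areas_tsv()]) or a
#'   named list of numeric vectors, one per ROI.
#' @param n_points grid resolution passed to [common_area_grid()].
#' @param floor density floor passed to [estimate_density()].
#' @return a \code{connectivity_matrix} with \code{kind = "structural_kl"}.
#' @export
structural_connectome <- function(vt, n_points = 256L, floor = 1e-12) {
  areas <- as_area_list(vt)
  roi_ids <- names(areas)
  bad <- vapply(areas, function(v) length(v) < 2L || any(v <= 0), logical(1L))
  if (any(bad)) {
    stop("ROI(s) with fewer than 2 vertices or non-positive areas: ",
         paste(roi_ids[bad], collapse = ", "))
  }
  grid <- common_area_grid(areas, n_points = n_points)
  dens <- lapply(areas, estimate_density, grid = grid, floor = floor)
  M <- do.call(rbind, lapply(dens, `[[`, "mass"))   # R x G
  L <- log(M)
  self_ent <- rowSums(M * L)
  cross <- M %*% t(L)                                # cross[i,k] = sum f_i log f_k
  kl_dir <- self_ent - cross                         # KL(f_i || f_k)
  v <- (kl_dir + t(kl_dir)) / 2
  v[v < 0] <- 0                                      # guard tiny negative rounding
  diag(v) <- 0
  new_connectivity(v, kind = "structural_kl", roi_ids = roi_ids)
}

# ---- internal constructors / coercions --------------------------------------

new_connectivity <- function(values, kind, roi_ids) {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (is.null(roi_ids)) roi_ids <- paste0("roi", seq_len(nrow(values)))
  dimnames(values) <- list(roi_ids, roi_ids)
  structure(values, kind = kind, roi_ids = roi_ids,
            class = c("connectivity_matrix", "matrix", "array"))
}

as_ts_matrix <- function(ts) {
  if (inherits(ts, "parcellated_ts")) ts <- ts$data
  x <- as.matrix(ts)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("roi", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) stop("duplicate ROI identifiers")
  x
}

as_area_list <- function(vt) {
  if (inherits(vt, "vertex_area_table")) vt <- vt$areas
  if (!is.list(vt) || is.null(names(vt)) || anyDuplicated(names(vt))) {
    stop("vertex areas must be a named list with unique ROI identifiers")
  }
  lapply(vt, as.numeric)
}

check_same_grid <- function(f1, f2) {
  if (length(f1$grid) != length(f2$grid) ||
      max(abs(f1$grid - f2$grid)) > 1e-9) {
    stop("densities are not on the same grid")
  }
  invisible(TRUE)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> kind=%s, %d x %d ROIs\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}
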