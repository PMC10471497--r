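#' PCA of the adversity matrix with varimax rotation
#'
#' Standardises the adversity columns, extracts principal components of the
#' correlation matrix, and applies a varimax rotation to the loading
#' submatrix (loadings on the correlation scale, i.e. eigenvector times
#' singular value). Scores are recomputed from the rotated loadings with
#' variance equal to the rotated component variance (sum of squared
#' loadings), so downstream square-root-of-eigenvalue scaling is natural.
#' Each loading column's sign is fixed so its largest-magnitude entry is
#' positive, making outputs reproducible across linear-algebra backends.
#'
#' @param A numeric matrix/data.frame, subjects x adversities; complete.
#' @param n_components number of components to retain (default 3).
#' @param tol varimax convergence tolerance (default 1e-8).
#' @return A `pc_decomp`: `loadings` (adversities x components, rotated),
#'   `scores` (subjects x components, variance = `eigenvalues`),
#'   `eigenvalues` (rotated component variances), `explained`
#'   (fractions of total variance), `cumulative`, `unrotated_eigenvalues`,
#'   `rotation` (the orthogonal rotation matrix), `n_components`.
#' @export
pca_varimax <- function(A, n_components = 3, tol = 1e-8) {
  A <- as.matrix(A)
  if (anyNA(A)) stop("adversity matrix must be complete")
  if (n_components < 1) stop("n_components must be >= 1")
  p <- ncol(A)
  if (n_components > p) stop("more components than adversities")
  if (any(apply(A, 2, sd) == 0)) stop("constant adversity column")
  Z <- scale(A)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  k <- n_components
  L <- pc$rotation[, seq_len(k), drop = FALSE] %*%
    diag(pc$sdev[seq_len(k)], k)
  R <- if (k > 1) varimax(L, normalize = FALSE, eps = tol)$rotmat else
    diag(1)
  Lr <- L %*% R
  ## sign convention: largest-|loading| entry of each column positive
  flip <- vapply(seq_len(k), function(j) {
    sign(Lr[which.max(abs(Lr[, j])), j])
  }, numeric(1))
  Lr <- sweep(Lr, 2, flip, "*")
  R <- sweep(R, 2, flip, "*")
  ss <- colSums(Lr^2)
  Fstd <- Z %*% pc$rotation[, seq_len(k), drop = FALSE] %*%
    diag(1 / pc$sdev[seq_len(k)], k)
  scores <- (Fstd %*% R) %*% diag(sqrt(ss), k)
  dimnames(Lr) <- list(colnames(A), paste0("PC", seq_len(k)))
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(loadings = Lr, scores = scores, eigenvalues = ss,
                 explained = ss / p, cumulative = cumsum(ss) / p,
                 unrotated_eigenvalues = pc$sdev[seq_len(k)]^2,
                 rotation = R, n_components = k,
                 centre = attr(Z, "scaled:center"),
                 scale = attr(Z, "scaled:scale")),
            class = "pc_decomp")
}

#' @export
print.pc_decomp <- function(x, ...) {
  cat("pc_decomp:", x$n_components, "varimax-rotated components,",
      round(100 * x$cumulative[x$n_components]), "% of variance\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Cross-validated normative model on PC scores
#'
#' Identical engine to [crossval_fit()] with the rotated component scores
#' replacing the individual adversities; sex and TIV stay in the design.
#'
#' @param pcs a [pca_varimax()] decomposition.
#' @param cov covariate data.frame with `sex` and `tiv` columns, same
#'   subjects (and order) as the decomposition.
#' @param Y a [voxel_stack()] or matrix.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return A `voxel_fit`.
#' @export
fit_pc_model <- function(pcs, cov, Y, k = 10, seed = 1) {
  stopifnot(inherits(pcs, "pc_decomp"))
  X <- cbind(pcs$scores, sex = cov$sex, tiv = cov$tiv)
  crossval_fit(X, Y, k = k, seed = seed)
}

#' Per-component slope maps at sampling points
#'
#' Evaluates the fitted PC model's prediction at `n_points` values of one
#' component's score (all other components held at 0, sex and TIV at their
#' sample means) and expresses each as a per-voxel slope relative to the
#' all-zero-score baseline: positive slopes mark expansion with increasing
#' component score, negative slopes contraction. Sampling points live on the
#' standardised component scale and are multiplied by the square root of the
#' component's eigenvalue. With `mode = "quantile"` (default) the points are
#' the 5/35/65/95 percent quantiles of the observed standardised scores;
#' `mode = "random"` draws standard-normal points under the seed. For a
#' linear model all sampling points give the same slope map.
#'
#' @param fit a `voxel_fit` from [fit_pc_model()].
#' @param pcs the matching `pc_decomp`.
#' @param component component index (1-based).
#' @param n_points number of sampling points (>= 2, default 4).
#' @param mode `"quantile"` or `"random"`.
#' @param seed seed for `mode = "random"`.
#' @return List: `points` (score values used), `slopes`
#'   (`n_points` x voxels matrix), `baseline` (per-voxel prediction at zero
#'   scores), `component`.
#' @export
pc_slope_maps <- function(fit, pcs, component = 1, n_points = 4,
                          mode = c("quantile", "random"), seed = 1) {
  mode <- match.arg(mode)
  if (component > pcs$n_components) stop("component out of range")
  if (n_points < 2) stop("need at least 2 sampling points")
  ev <- pcs$eigenvalues[component]
  std_scores <- pcs$scores[, component] / sqrt(ev)
  pts_std <- if (mode == "quantile") {
    quantile(std_scores, probs = seq(0.05, 0.95, length.out = n_points),
             names = FALSE)
  } else {
    with_seed(child_seed(seed, "sampling"), rnorm(n_points))
  }
  pts <- pts_std * sqrt(ev)
  predict_at <- function(raw) {
    xs <- (raw - fit$scaling$centre) / fit$scaling$scale
    as.numeric(crossprod(fit$coef, c(1, xs)))
  }
  ## baseline profile: zero component scores, sex and TIV at sample means
  base_raw <- fit$col_means
  base_raw[paste0("PC", seq_len(pcs$n_components))] <- 0
  baseline <- predict_at(base_raw)
  slopes <- matrix(NA_real_, n_points, ncol(fit$coef))
  for (i in seq_len(n_points)) {
    raw <- base_raw
    raw[paste0("PC", component)] <- pts[i]
    slopes[i, ] <- (predict_at(raw) - baseline) / pts[i]
  }
  list(points = pts, slopes = slopes, baseline = baseline,
       component = component)
}
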