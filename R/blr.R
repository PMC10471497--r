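## Bayesian linear regression with Gaussian noise and evidence-optimised
## hyperparameters (type-II maximum likelihood).
##
## Model: y = X w + eps,  eps ~ N(0, 1/beta),  w_j ~ N(0, 1/alpha) for
## penalised columns; the intercept carries a fixed, effectively flat prior
## (precision 1e-8) following growth-chart convention.  Posterior:
##   S = (A + beta X'X)^{-1},  m = beta S X'y,  A = diag(prior precisions)
## Log evidence:
##   L = 1/2 log|A| - 1/2 log|A + beta X'X| + n/2 log(beta/2pi)
##       - beta/2 ||y - Xm||^2 - 1/2 m'Am

.INTERCEPT_PREC <- 1e-8

## core fit from sufficient statistics; la = log alpha, lb = log beta
blr_core_eval <- function(la, lb, XtX, Xty, yty, n, pen, grad = FALSE) {
  p <- nrow(XtX)
  avec <- rep(.INTERCEPT_PREC, p)
  avec[pen] <- exp(la)
  beta <- exp(lb)
  Sigma <- beta * XtX
  diag(Sigma) <- diag(Sigma) + avec
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) return(list(L = -Inf))
  m <- beta * backsolve(R, backsolve(R, Xty, transpose = TRUE))
  qXX <- as.numeric(crossprod(m, XtX %*% m))
  rss <- max(yty - 2 * sum(m * Xty) + qXX, 0)
  L <- 0.5 * sum(log(avec)) - sum(log(diag(R))) +
    0.5 * n * (lb - log(2 * pi)) - 0.5 * beta * rss -
    0.5 * sum(avec * m^2)
  out <- list(L = L, m = m, R = R, beta = beta, avec = avec, rss = rss)
  if (grad) {
    S <- chol2inv(R)
    dS <- diag(S)
    npen <- sum(pen)
    alpha <- exp(la)
    g_la <- 0.5 * (npen - alpha * (sum(dS[pen]) + sum(m[pen]^2)))
    g_lb <- 0.5 * (n - beta * rss - (p - sum(avec * dS)))
    out$grad <- c(g_la, g_lb)
    out$S <- S
  }
  out
}

blr_optimize <- function(XtX, Xty, yty, n, pen, tol = 1e-6,
                         starts = list(c(0, 0), c(-2, 2))) {
  negL <- function(par) -blr_core_eval(par[1], par[2], XtX, Xty, yty, n, pen)$L
  negG <- function(par) {
    -blr_core_eval(par[1], par[2], XtX, Xty, yty, n, pen, grad = TRUE)$grad
  }
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negL, negG, method = "L-BFGS-B",
            lower = c(-30, -30), upper = c(30, 30),
            control = list(factr = tol / .Machine$double.eps, maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("evidence optimisation failed at every start")
  list(par = best$par, converged = conv)
}

#' Fit a Bayesian linear regression with evidence-optimised hyperparameters
#'
#' Computes the closed-form Gaussian posterior over coefficients and, unless
#' both are supplied, maximises the log marginal likelihood (evidence) over
#' the prior precision `alpha` and noise precision `beta` by quasi-Newton
#' search on `(log alpha, log beta)` with analytic gradients and two fixed
#' restarts. The intercept column is unpenalised (flat prior).
#'
#' @param X numeric matrix or data.frame of predictors (no intercept column;
#'   one is added when `intercept = TRUE`). Must be full column rank.
#' @param y numeric outcome vector, `length(y) == nrow(X)`; more rows than
#'   columns are required.
#' @param alpha,beta optional fixed hyperparameters; supply both to skip
#'   evidence optimisation (used by the ridge-equivalence oracle).
#' @param intercept add an unpenalised intercept column (default TRUE).
#' @param tol convergence tolerance on the objective (default 1e-6).
#' @return A `blr_fit` with posterior mean `m`, covariance `S`,
#'   hyperparameters `alpha`, `beta`, `log_evidence`, a `converged` flag and
#'   bookkeeping (`terms`, `n`). Non-convergence is a warning, not an error.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 20, 2)
#' y <- X %*% c(1, -1) + rnorm(20, sd = 0.3)
#' fit <- fit_blr(X, y)
#' predict(fit, X)$mean
fit_blr <- function(X, y, alpha = NULL, beta = NULL, intercept = TRUE,
                    tol = 1e-6) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) stop("non-finite values")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  n <- nrow(Xd); p <- ncol(Xd)
  if (n <= p) stop("need more rows than columns")
  if (qr(Xd)$rank < p) stop("design matrix is rank-deficient")
  pen <- rep(TRUE, p)
  if (intercept) pen[1] <- FALSE
  XtX <- crossprod(Xd)
  Xty <- crossprod(Xd, y)[, 1]
  yty <- sum(y^2)
  converged <- TRUE
  if (is.null(alpha) || is.null(beta)) {
    opt <- blr_optimize(XtX, Xty, yty, n, pen, tol = tol)
    alpha <- exp(opt$par[1]); beta <- exp(opt$par[2])
    converged <- opt$converged
    if (!converged) warning("evidence optimisation did not fully converge")
  }
  ev <- blr_core_eval(log(alpha), log(beta), XtX, Xty, yty, n, pen,
                      grad = TRUE)
  fit <- list(m = setNames(ev$m, colnames(Xd)), S = ev$S,
              alpha = alpha, beta = beta, log_evidence = ev$L,
              converged = converged, n = n, terms = colnames(Xd),
              intercept = intercept, penalised = pen)
  class(fit) <- "blr_fit"
  fit
}

#' Log marginal likelihood at fixed hyperparameters
#'
#' Evaluates the evidence of the Gaussian BLR model at user-supplied
#' `(alpha, beta)` without optimisation — useful for probing the evidence
#' surface around an optimised fit.
#'
#' @inheritParams fit_blr
#' @return The log evidence (scalar).
#' @export
blr_log_evidence <- function(X, y, alpha, beta, intercept = TRUE) {
  X <- as.matrix(X)
  Xd <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  pen <- rep(TRUE, ncol(Xd)); if (intercept) pen[1] <- FALSE
  blr_core_eval(log(alpha), log(beta), crossprod(Xd),
                crossprod(Xd, y)[, 1], sum(y^2), nrow(Xd), pen)$L
}

#' @export
print.blr_fit <- function(x, ...) {
  cat("Bayesian linear regression fit (", x$n, " obs, ",
      length(x$m), " coefficients)\n", sep = "")
  cat("  alpha =", signif(x$alpha, 4), " beta =", signif(x$beta, 4),
      " log evidence =", signif(x$log_evidence, 6), "\n")
  print(signif(x$m, 4))
  invisible(x)
}

#' Predictive distribution of a fitted BLR model
#'
#' @param object a `blr_fit`.
#' @param newdata matrix/data.frame with the training predictor columns (the
#'   intercept is added automatically if the model used one).
#' @param ... unused.
#' @return List with `mean` and `variance` per row; the variance is
#'   `1/beta + x' S x`, i.e. noise floor plus coefficient uncertainty, so it
#'   is never below `1/beta`.
#' @export
predict.blr_fit <- function(object, newdata, ...) {
  Xs <- as.matrix(newdata)
  if (is.null(colnames(Xs))) colnames(Xs) <- paste0("x", seq_len(ncol(Xs)))
  if (object$intercept) Xs <- cbind(`(Intercept)` = 1, Xs)
  if (!identical(colnames(Xs), object$terms)) {
    if (!setequal(colnames(Xs), object$terms)) {
      stop("prediction columns do not match training columns")
    }
    Xs <- Xs[, object$terms, drop = FALSE]
  }
  mean <- as.numeric(Xs %*% object$m)
  variance <- 1 / object$beta + rowSums((Xs %*% object$S) * Xs)
  list(mean = mean, variance = variance)
}

#' Deviation z-scores against a predictive distribution
#'
#' `z = (observed - predicted mean) / predictive sd`: the subject-level
#' deviation statistic behind normative probability maps.
#'
#' @param y observed values.
#' @param pred list with `mean` and `variance` (as from [predict.blr_fit()]).
#' @return Numeric z vector.
#' @export
zscore <- function(y, pred) {
  if (length(y) != length(pred$mean)) stop("length mismatch")
  if (any(pred$variance <= 0)) stop("non-positive predictive variance")
  (y - pred$mean) / sqrt(pred$variance)
}

#' Prediction accuracy metrics
#'
#' Pearson correlation between true and predicted values (with two-sided
#' p-value) and the standardised mean squared error
#' `SMSE = mean((y - yhat)^2) / mean((y - mean(y))^2)`, whose value for the
#' mean predictor is exactly 1; explained variance is `1 - SMSE`.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 3).
#' @return List `rho`, `rho_p`, `smse`, `ev`. For a constant `y_true` the
#'   correlation is undefined: `rho`/`rho_p`/`smse` are `NA` with a warning.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 3) stop("need at least 3 points")
  denom <- mean((y_true - mean(y_true))^2)
  if (denom == 0) {
    warning("constant y_true: metrics undefined")
    return(list(rho = NA_real_, rho_p = NA_real_, smse = NA_real_,
                ev = NA_real_))
  }
  smse <- mean((y_true - y_pred)^2) / denom
  if (sd(y_pred) == 0) {
    rho <- NA_real_; rho_p <- NA_real_
  } else {
    ct <- cor.test(y_true, y_pred, alternative = "two.sided")
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  list(rho = rho, rho_p = rho_p, smse = smse, ev = 1 - smse)
}

## training-fold standardisation: z-score continuous columns, leave binary
## columns untouched
design_scaling <- function(X) {
  is_binary <- apply(X, 2, function(v) all(v %in% c(0, 1)))
  centre <- ifelse(is_binary, 0, colMeans(X))
  scale_ <- ifelse(is_binary, 1, apply(X, 2, sd))
  if (any(scale_ == 0)) {
    stop("constant non-binary column(s): ",
         paste(colnames(X)[scale_ == 0], collapse = ", "))
  }
  list(centre = centre, scale = scale_)
}

apply_scaling <- function(X, sc) {
  sweep(sweep(X, 2, sc$centre, "-"), 2, sc$scale, "/")
}

#' Cross-validated voxel-wise normative model
#'
#' Fits an independent evidence-optimised BLR per voxel under k-fold
#' cross-validation: every subject's predictive mean/variance and z-score
#' come from the fold in which that subject was held out. Continuous
#' predictors are standardised with training-fold statistics only (binary
#' 0/1 columns are left as is), preventing leakage across folds. A full-data
#' fit per voxel supplies coefficient maps on the standardised scale.
#'
#' @param X predictor matrix or data.frame (subjects x predictors), no
#'   intercept column.
#' @param Y a [voxel_stack()] or a subjects x voxels matrix.
#' @param k number of folds (default 10; `k = n` gives leave-one-out).
#' @param seed integer seed for the fold permutation.
#' @return A `voxel_fit` with: `yhat`, `s2`, `z` (subjects x voxels CV
#'   predictive mean, variance, z-scores); `metrics` data.frame per voxel
#'   (`rho`, `rho_p`, `smse`, `ev`); `coef` and `coef_sd` (predictors x
#'   voxels, full-data posterior, standardised scale); `hyper` (`alpha`,
#'   `beta` per voxel, full-data); `folds` (assignment vector); `qc`
#'   (per-voxel convergence records); and the stack geometry when `Y` was a
#'   `voxel_stack`.
#' @export
crossval_fit <- function(X, Y, k = 10, seed = 1) {
  stack <- NULL
  if (inherits(Y, "voxel_stack")) { stack <- Y; Y <- Y$data }
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); V <- ncol(Y); p <- ncol(X)
  if (nrow(Y) != n) stop("X and Y disagree on subject count")
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("more folds than subjects")
  folds <- with_seed(child_seed(seed, "folds"),
                     sample(rep_len(seq_len(k), n)))
  if (n - max(table(folds)) <= p + 1) {
    stop("a training fold has fewer subjects than predictors + intercept")
  }
  yhat <- matrix(NA_real_, n, V)
  s2 <- matrix(NA_real_, n, V)
  fold_nonconv <- integer(V)
  pen <- c(FALSE, rep(TRUE, p))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    sc <- design_scaling(X[tr, , drop = FALSE])
    Xtr <- cbind(1, apply_scaling(X[tr, , drop = FALSE], sc))
    Xte <- cbind(1, apply_scaling(X[te, , drop = FALSE], sc))
    XtX <- crossprod(Xtr)
    XtY <- crossprod(Xtr, Y[tr, , drop = FALSE])
    yty_all <- colSums(Y[tr, , drop = FALSE]^2)
    ntr <- sum(tr)
    for (v in seq_len(V)) {
      opt <- blr_optimize(XtX, XtY[, v], yty_all[v], ntr, pen)
      if (!opt$converged) fold_nonconv[v] <- fold_nonconv[v] + 1L
      ev <- blr_core_eval(opt$par[1], opt$par[2], XtX, XtY[, v],
                          yty_all[v], ntr, pen, grad = TRUE)
      yhat[te, v] <- Xte %*% ev$m
      s2[te, v] <- 1 / ev$beta + rowSums((Xte %*% ev$S) * Xte)
    }
  }
  z <- (Y - yhat) / sqrt(s2)
  metrics <- do.call(rbind, lapply(seq_len(V), function(v) {
    m <- evaluate_predictions(Y[, v], yhat[, v])
    data.frame(voxel = v, rho = m$rho, rho_p = m$rho_p, smse = m$smse,
               ev = m$ev)
  }))
  ## full-data posterior for coefficient maps
  sc <- design_scaling(X)
  Xs <- cbind(1, apply_scaling(X, sc))
  XtX <- crossprod(Xs)
  XtY <- crossprod(Xs, Y)
  yty_all <- colSums(Y^2)
  coef <- matrix(NA_real_, p + 1, V,
                 dimnames = list(c("(Intercept)", colnames(X)), NULL))
  coef_sd <- coef
  hyper <- matrix(NA_real_, 2, V, dimnames = list(c("alpha", "beta"), NULL))
  full_conv <- logical(V)
  for (v in seq_len(V)) {
    opt <- blr_optimize(XtX, XtY[, v], yty_all[v], n, pen)
    ev <- blr_core_eval(opt$par[1], opt$par[2], XtX, XtY[, v], yty_all[v],
                        n, pen, grad = TRUE)
    coef[, v] <- ev$m
    coef_sd[, v] <- sqrt(diag(ev$S))
    hyper[, v] <- exp(opt$par)
    full_conv[v] <- opt$converged
  }
  out <- list(yhat = yhat, s2 = s2, z = z, metrics = metrics,
              coef = coef, coef_sd = coef_sd, hyper = hyper,
              folds = folds, k = k, seed = seed,
              scaling = sc, predictors = colnames(X),
              col_means = colMeans(X),
              qc = data.frame(voxel = seq_len(V), full_converged = full_conv,
                              cv_folds_nonconverged = fold_nonconv),
              stack = stack)
  class(out) <- "voxel_fit"
  out
}

#' @export
print.voxel_fit <- function(x, ...) {
  cat("voxel_fit:", ncol(x$z), "voxels,", nrow(x$z), "subjects,",
      x$k, "folds\n")
  cat("  median CV rho =", signif(median(x$metrics$rho, na.rm = TRUE), 3),
      " median SMSE =", signif(median(x$metrics$smse, na.rm = TRUE), 3), "\n")
  invisible(x)
}
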