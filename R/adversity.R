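#' Bin an adversity score under count constraints
#'
#' Categorises a raw score into at most `max_bins` ordered bins, each holding
#' at least `min_count` subjects, balancing differing score severities before
#' they enter the normative model. Cuts are placed only between distinct raw
#' values, so identical raw scores are never split across bins. A dynamic
#' programme over the distinct-value boundaries finds the largest feasible
#' number of bins (up to `max_bins`) and, among feasible cut placements,
#' chooses the one whose bin sizes track equal occupancy most closely —
#' deterministic and reproducible.
#'
#' @param x numeric raw scores, `length(x) >= min_count`.
#' @param max_bins maximum number of bins (default 4).
#' @param min_count minimum subjects per bin (default 10).
#' @return List with `binned` (integer codes `0..k-1`, monotone in `x`) and
#'   `rule` (upper raw-value edge of each bin, resulting counts, and the
#'   constraints).
#' @export
bin_scores <- function(x, max_bins = 4, min_count = 10) {
  n <- length(x)
  if (n < min_count) {
    stop("cannot satisfy min_count = ", min_count, " with ", n, " subjects")
  }
  if (anyNA(x)) stop("missing scores")
  tab <- table(x)
  vals <- as.numeric(names(tab))
  d <- length(vals)
  cum <- cumsum(as.integer(tab))                # cum[j] = count of x <= vals[j]
  count_from <- function(i, j) cum[j] - if (i > 1) cum[i - 1] else 0L
  ## H[[b + 1]][i]: suffix vals[i..d] can be split into exactly b valid bins
  ## (position d + 1 denotes the empty suffix)
  kmax <- min(max_bins, d)
  H <- vector("list", kmax + 1)
  H[[1]] <- c(rep(FALSE, d), TRUE)
  for (b in seq_len(kmax)) {
    ok <- rep(FALSE, d + 1)
    suffix_any <- rev(cummax(rev(H[[b]])))      # any TRUE at position >= i
    for (i in seq_len(d)) {
      jmin <- match(TRUE, cum >= (if (i > 1) cum[i - 1] else 0L) + min_count)
      if (!is.na(jmin) && jmin <= d && suffix_any[jmin + 1] > 0) {
        ok[i] <- TRUE
      }
    }
    H[[b + 1]] <- ok
  }
  k <- max(which(vapply(seq_len(kmax + 1), function(b) H[[b]][1],
                        logical(1)))) - 1L
  ## reconstruct, balancing bin occupancy toward the remaining average
  edges <- numeric(0)
  i <- 1L
  for (b in k:1) {
    if (b == 1) { edges <- c(edges, vals[d]); break }
    target <- (n - (if (i > 1) cum[i - 1] else 0L)) / b
    best_j <- NA_integer_; best_dev <- Inf
    for (j in i:(d - 1)) {
      if (count_from(i, j) < min_count) next
      if (!H[[b]][j + 1]) next
      dev <- abs(count_from(i, j) - target)
      if (dev < best_dev) { best_dev <- dev; best_j <- j }
    }
    edges <- c(edges, vals[best_j])
    i <- best_j + 1L
  }
  code <- findInterval(x, c(-Inf, edges[-length(edges)]), left.open = TRUE)
  list(binned = code - 1L,
       rule = list(edges = edges, max_bins = max_bins,
                   min_count = min_count,
                   counts = tabulate(code, nbins = length(edges))))
}

#' Structure coefficients of a cross-validated voxel model
#'
#' For each predictor and voxel, the Pearson correlation across subjects
#' between the raw predictor and the model's (cross-validated) predicted
#' outcome — a collinearity-robust measure of each adversity's contribution
#' to the predicted morphometric pattern.
#'
#' @param fit a `voxel_fit` from [crossval_fit()] (its CV predictions are
#'   used; pass `yhat` explicitly for a full-data refit variant).
#' @param X predictor matrix/data.frame (subjects x predictors); typically
#'   the adversity columns only.
#' @param yhat optional subjects x voxels prediction matrix overriding
#'   `fit$yhat`.
#' @return Matrix predictors x voxels of correlations in `[-1, 1]`; a
#'   constant predictor yields a row of `NA` with a warning.
#' @export
structure_coefficients <- function(fit, X, yhat = NULL) {
  if (is.null(yhat)) yhat <- fit$yhat
  X <- as.matrix(X)
  if (nrow(X) != nrow(yhat)) stop("subject count mismatch")
  const <- apply(X, 2, sd) == 0
  if (any(const)) warning("constant predictor(s): ",
                          paste(colnames(X)[const], collapse = ", "))
  out <- suppressWarnings(cor(X, yhat))
  out[const, ] <- NA_real_
  rownames(out) <- colnames(X)
  out
}

#' Select the top fraction of a voxel map
#'
#' Marks the highest (`sign = "positive"`) or lowest (`sign = "negative"`)
#' `fraction` of masked voxel values. The number selected is
#' `round(fraction * length(values))`; ties at the cut are broken
#' deterministically by value then by voxel linear index (stable order).
#'
#' @param values numeric vector of masked voxel values.
#' @param fraction fraction in `(0, 1]` (default 0.02, the top 2 percent).
#' @param sign `"positive"` or `"negative"`.
#' @return Logical vector with attributes `sign`, `fraction`, `n_selected`.
#' @export
threshold_top <- function(values, fraction = 0.02,
                          sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (length(values) == 0) stop("empty map")
  n_sel <- round(fraction * length(values))
  if (n_sel < 1) stop("fraction selects fewer than one voxel")
  idx <- seq_along(values)
  ord <- if (sign == "positive") order(-values, idx) else order(values, idx)
  sel <- logical(length(values))
  sel[ord[seq_len(n_sel)]] <- TRUE
  attr(sel, "sign") <- sign
  attr(sel, "fraction") <- fraction
  attr(sel, "n_selected") <- n_sel
  sel
}

#' Dice overlap of two binary maps
#'
#' `2 |A & B| / (|A| + |B|)`; when both maps are empty the overlap is
#' defined as 0 with a warning.
#'
#' @param a,b logical vectors on the same masked grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (length(a) != length(b)) stop("maps are on different grids")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) {
    warning("both maps empty; dice defined as 0")
    return(0)
  }
  2 * sum(a & b) / (na + nb)
}

#' Pairwise dice overlap of thresholded effect maps
#'
#' Thresholds each predictor's voxel map at the top `fraction` (positive and
#' negative tails separately) and computes all pairwise dice coefficients:
#' per sign, their mean, and a sign-pooled version on the union of the two
#' tails.
#'
#' @param sc predictors x voxels matrix (e.g. [structure_coefficients()]).
#' @param fraction tail fraction (default 0.02).
#' @return List of predictor x predictor matrices: `positive`, `negative`,
#'   `mean` (average of the two), `pooled` (union of signs).
#' @export
dice_matrix <- function(sc, fraction = 0.02) {
  p <- nrow(sc)
  nm <- rownames(sc)
  pos <- lapply(seq_len(p), function(j) threshold_top(sc[j, ], fraction,
                                                      "positive"))
  neg <- lapply(seq_len(p), function(j) threshold_top(sc[j, ], fraction,
                                                      "negative"))
  mk <- function(maps) {
    m <- diag(1, p)
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i != j) m[i, j] <- dice(maps[[i]], maps[[j]])
    }
    dimnames(m) <- list(nm, nm)
    m
  }
  pooled_maps <- lapply(seq_len(p), function(j) pos[[j]] | neg[[j]])
  list(positive = mk(pos), negative = mk(neg),
       mean = (mk(pos) + mk(neg)) / 2, pooled = mk(pooled_maps))
}

#' Voxel-wise correlation between two metric maps
#'
#' Pearson correlation across masked voxels between two maps (e.g. the rho
#' maps of two model variants, or the same model at two time points), with a
#' two-sided p-value from the Fisher z transform.
#'
#' @param map1,map2 numeric vectors over the same mask (>= 3 voxels).
#' @return List `r`, `p`, `n`.
#' @export
compare_models <- function(map1, map2) {
  if (length(map1) != length(map2)) stop("maps are on different masks")
  ok <- is.finite(map1) & is.finite(map2)
  n <- sum(ok)
  if (n < 3) stop("fewer than 3 masked voxels")
  r <- cor(map1[ok], map2[ok])
  p <- if (n > 3 && abs(r) < 1) {
    2 * pnorm(-abs(atanh(r)) * sqrt(n - 3))
  } else if (abs(r) >= 1) 0 else 1
  list(r = r, p = p, n = n)
}
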