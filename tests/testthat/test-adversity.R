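## exhaustive search over monotone cut placements: returns the largest
## feasible number of bins (each >= min_count) using at most max_bins bins
max_feasible_bins <- function(x, max_bins = 4, min_count = 10) {
  vals <- sort(unique(x))
  if (length(vals) == 1) return(1)
  cut_pool <- vals[-length(vals)]          # cut after each distinct value
  for (k in rev(seq_len(min(max_bins, length(vals))))) {
    if (k == 1) return(1)
    combs <- utils::combn(cut_pool, k - 1, simplify = FALSE)
    for (cuts in combs) {
      code <- findInterval(x, c(-Inf, cuts), left.open = TRUE)
      if (all(tabulate(code, nbins = k) >= min_count)) return(k)
    }
  }
  1
}

test_that("score binning satisfies the bin-count constraints", {
  ## two distinct values, both frequent: exactly two bins coded 0/1
  x <- rep(c(0, 3), c(15, 20))
  b <- bin_scores(x)
  expect_identical(sort(unique(b$binned)), c(0L, 1L))
  expect_identical(b$binned, as.integer(x > 0))

  ## cohort-sized skewed count score: <= 4 bins, all >= 10
  set.seed(1)
  x <- rpois(169, 1.2)
  b <- bin_scores(x)
  counts <- table(b$binned)
  expect_lte(length(counts), 4)
  expect_true(all(counts >= 10))

  ## identical raw scores never split across bins
  expect_true(all(tapply(b$binned, x, function(v) length(unique(v))) == 1))
  expect_error(bin_scores(rnorm(5)), "min_count")
})

test_that("binning is monotone and attains the exhaustively-verified bin count", {
  set.seed(2)
  for (i in 1:5) {
    x <- sample(0:6, 200, replace = TRUE,
                prob = prop.table(runif(7, 0.2, 1)))
    b <- bin_scores(x)
    ## rank order preserved
    expect_equal(suppressWarnings(cor(x, b$binned, method = "spearman")) > 0,
                 TRUE)
    expect_true(all(diff(tapply(b$binned, x, unique)[order(sort(unique(x)))]) >= 0))
    ## same number of bins as an exhaustive search over monotone cuts
    expect_equal(length(unique(b$binned)), max_feasible_bins(x))
  }
})

test_that("structure coefficients equal per-voxel predictor-prediction correlations", {
  set.seed(3)
  n <- 80
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  yhat <- cbind(2 * x1 + 1, x1 + 0.5 * x2, rnorm(n))
  fake_fit <- list(yhat = yhat)
  sc <- structure_coefficients(fake_fit, cbind(x1 = x1, x2 = x2, x3 = x3))
  ## single-driver voxel: |corr| = 1 for its driver
  expect_equal(unname(sc["x1", 1]), 1, tolerance = 1e-12)
  ## direct per-voxel correlation loop oracle
  for (j in 1:3) {
    for (v in 1:3) {
      expect_equal(unname(sc[j, v]), cor(list(x1, x2, x3)[[j]], yhat[, v]),
                   tolerance = 1e-12)
    }
  }
  ## orthogonal inert predictor stays near zero on the driven voxel
  expect_lt(abs(sc["x3", 1]), 0.3)
  expect_warning(structure_coefficients(fake_fit,
                                        cbind(c1 = rep(1, n), x1 = x1)),
                 "constant")
})

test_that("top-fraction thresholding matches a sort-based oracle including ties", {
  ## strictly increasing values: exactly the 2 largest of 100
  v <- seq_len(100) + 0.5
  sel <- threshold_top(v, 0.02, "positive")
  expect_identical(which(sel), c(99L, 100L))
  expect_equal(attr(sel, "n_selected"), 2L)

  ## all voxels at fraction 1
  expect_true(all(threshold_top(v, 1, "positive")))

  ## ties at the cut: deterministic (value, index) order
  set.seed(4)
  for (i in 1:5) {
    vals <- sample(rep(1:10, each = 10))
    for (sgn in c("positive", "negative")) {
      sel <- threshold_top(vals, 0.07, sgn)
      idx <- seq_along(vals)
      ord <- if (sgn == "positive") order(-vals, idx) else order(vals, idx)
      expect_identical(which(sel), sort(ord[1:7]))
    }
  }
  expect_error(threshold_top(v, 0.001), "fewer than one")
  expect_error(threshold_top(v, 1.5), "fraction")
})

test_that("dice overlap matches hand computation and is a symmetric [0,1] measure", {
  expect_equal(dice(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE)),
               0.5)
  a <- c(TRUE, TRUE, FALSE); expect_equal(dice(a, a), 1)
  expect_equal(dice(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_warning(d0 <- dice(logical(3), logical(3)), "empty")
  expect_equal(d0, 0)
  set.seed(5)
  for (i in 1:10) {
    a <- runif(50) < 0.3; b <- runif(50) < 0.3
    d <- suppressWarnings(dice(a, b))
    expect_identical(d, suppressWarnings(dice(b, a)))
    expect_gte(d, 0); expect_lte(d, 1)
  }
  expect_error(dice(logical(3), logical(4)), "different grids")
})

test_that("dice matrix of planted maps separates overlapping from disjoint effects", {
  set.seed(6)
  V <- 500
  shared <- rnorm(V)
  sc <- rbind(a1 = shared + rnorm(V, sd = 0.1),
              a2 = shared + rnorm(V, sd = 0.1),
              a3 = rnorm(V))
  dm <- dice_matrix(sc, fraction = 0.05)
  expect_gt(dm$mean["a1", "a2"], dm$mean["a1", "a3"])
  expect_equal(diag(dm$pooled), c(a1 = 1, a2 = 1, a3 = 1))
  expect_equal(dm$positive, t(dm$positive))
})

test_that("map comparison reproduces direct Pearson/Fisher computations", {
  m1 <- rnorm(200)
  expect_equal(compare_models(m1, m1)$r, 1)
  expect_equal(compare_models(m1, -m1)$r, -1)
  m2 <- 0.8 * m1 + rnorm(200, sd = 0.5)
  cm <- compare_models(m1, m2)
  expect_equal(cm$r, cor(m1, m2), tolerance = 1e-12)
  expect_equal(cm$p, 2 * pnorm(-abs(atanh(cor(m1, m2))) * sqrt(200 - 3)),
               tolerance = 1e-12)
  expect_error(compare_models(rnorm(2), rnorm(2)), "fewer than 3")
})

test_that("planted single-adversity effects dominate that adversity's structure coefficients", {
  hits <- 0
  for (seed in 1:5) {
    s <- small_planted_setup(n = 150, shape = c(6L, 6L, 6L), seed = seed,
                             active = adversity_names()[5],
                             effect_size = 0.8)
    A <- as.matrix(s$cov[, s$adversities])
    fit <- crossval_fit(cbind(A, sex = s$cov$sex, tiv = s$cov$tiv),
                        s$stack, k = 5, seed = seed)
    sc <- structure_coefficients(fit, A)
    vidx <- which(s$mask)
    affected <- which(s$atlas$coefficients[[s$active]][vidx] != 0)
    mean_active <- mean(abs(sc[s$active, affected]))
    mean_others <- vapply(setdiff(s$adversities, s$active),
                          function(nm) mean(abs(sc[nm, affected])),
                          numeric(1))
    if (mean_active > max(mean_others)) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
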