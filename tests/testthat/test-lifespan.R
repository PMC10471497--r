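## independent Cox-de Boor recursion for B-spline basis evaluation
deboor_basis <- function(x, degree, interior, boundary) {
  knots <- c(rep(boundary[1], degree + 1), interior,
             rep(boundary[2], degree + 1))
  nb <- length(interior) + degree + 1
  B <- outer(seq_len(length(knots) - 1), x, function(i, xx) {
    as.numeric(knots[i] <= xx & xx < knots[i + 1])
  })
  ## make the basis right-continuous at the upper boundary
  B[max(which(knots < boundary[2])), x == boundary[2]] <- 1
  for (d in seq_len(degree)) {
    Bn <- matrix(0, length(knots) - 1 - d, length(x))
    for (i in seq_len(nrow(Bn))) {
      den1 <- knots[i + d] - knots[i]
      den2 <- knots[i + d + 1] - knots[i + 1]
      t1 <- if (den1 > 0) (x - knots[i]) / den1 * B[i, ] else 0
      t2 <- if (den2 > 0) (knots[i + d + 1] - x) / den2 * B[i + 1, ] else 0
      Bn[i, ] <- t1 + t2
    }
    B <- Bn
  }
  t(B[seq_len(nb), , drop = FALSE])
}

test_that("spline design matches an independent Cox-de Boor evaluation", {
  basis <- spline_basis(c(8, 97), degree = 3, n_knots = 5)
  ages <- c(8, 12.5, 30, 55.2, 80, 97)
  X <- bspline_design(ages, basis, sex = rep(0, 6), site = rep("s1", 6))
  ref <- deboor_basis(ages, 3, basis$knots, c(8, 97))
  ## bs() drops the first basis function (absorbed by the intercept)
  expect_equal(unname(X[, 1:8]), ref[, -1], tolerance = 1e-10)
})

test_that("a degree-1, no-knot basis reproduces an affine age fit", {
  basis <- spline_basis(c(10, 90), degree = 1, n_knots = 0)
  set.seed(1)
  age <- runif(100, 10, 90)
  y <- 2 + 0.05 * age + rnorm(100, sd = 0.1)
  X <- bspline_design(age, basis, sex = rep(0, 100), site = rep("a", 100))
  fit <- fit_blr(X[, "age_bs1", drop = FALSE], y)
  lmfit <- lm(y ~ age)
  pred_ages <- c(20, 50, 80)
  Xp <- bspline_design(pred_ages, basis, sex = rep(0, 3), site = rep("a", 3))
  pr <- predict(fit, Xp[, "age_bs1", drop = FALSE])
  expect_equal(pr$mean, unname(predict(lmfit,
                                       data.frame(age = pred_ages))),
               tolerance = 0.01)
})

test_that("design handles the full 8-97 age range, clamps and checks sites", {
  basis <- spline_basis(c(8, 97))
  X <- bspline_design(c(8, 97), basis, sex = c(0, 1), site = c("a", "b"))
  expect_true(all(is.finite(X)))
  expect_warning(
    bspline_design(c(5, 50), basis, sex = c(0, 0), site = c("a", "a")),
    "clamped")
  expect_error(
    bspline_design(50, basis, sex = 0, site = "new",
                   site_levels = c("a", "b")),
    "unknown site")
})

test_that("the sinh-arcsinh warp is the identity at (0,1) and inverts exactly", {
  set.seed(2)
  y <- rnorm(1000, sd = 3)
  w_id <- c(eps = 0, delta = 1)
  expect_equal(shash_warp(y, w_id), y, tolerance = 1e-14)
  for (w in list(c(eps = 0.7, delta = 1.3), c(eps = -0.4, delta = 0.6))) {
    expect_lt(max(abs(shash_unwarp(shash_warp(y, w), w) - y)), 1e-10)
  }
  expect_error(shash_warp(y, c(eps = 0, delta = -1)), "delta")
  expect_error(shash_warp(c(1, NA), w_id), "non-finite")
})

test_that("warping symmetric input flips skewness consistently with a numeric oracle", {
  set.seed(3)
  y <- rnorm(5000)
  for (eps in c(0.5, -0.5)) {
    w <- c(eps = eps, delta = 1)
    ## unwarp with positive eps produces right skew (numeric oracle below)
    sk_unwarp <- sample_skewness(shash_unwarp(y, w))
    sk_warp <- sample_skewness(shash_warp(y, w))
    expect_equal(sign(sk_unwarp), sign(eps))
    expect_equal(sign(sk_warp), -sign(eps))
  }
})

test_that("identity-warp lifespan fit reduces exactly to the Gaussian BLR", {
  sim <- generate_lifespan(400, lifespan_spec(n_voxels = 2, n_sites = 3,
                                              skew_eps = 0), seed = 4)
  fit <- fit_warped(sim$covariates, sim$stack, seed = 4, warp = "identity")
  tr <- fit$train
  X <- bspline_design(sim$covariates$age[tr], fit$basis,
                      sim$covariates$sex[tr], sim$covariates$site[tr],
                      fit$site_levels)
  ref <- fit_blr(X, sim$stack$data[tr, 1])
  expect_equal(fit$models[[1]]$fit$m, ref$m, tolerance = 1e-10)
  expect_equal(fit$models[[1]]$fit$beta, ref$beta, tolerance = 1e-8)
})

test_that("Gaussian data drive the fitted warp toward the identity", {
  sim <- generate_lifespan(1200, lifespan_spec(n_voxels = 2, skew_eps = 0,
                                               skew_delta = 1), seed = 5)
  fit <- fit_warped(sim$covariates, sim$stack, seed = 5)
  expect_lt(max(abs(fit$metrics$eps)), 0.15)
  expect_lt(max(abs(fit$metrics$delta - 1)), 0.15)
  ## and the warped fit does not lose accuracy against plain BLR
  fid <- fit_warped(sim$covariates, sim$stack, seed = 5, warp = "identity")
  expect_equal(fit$metrics$ev, fid$metrics$ev, tolerance = 0.05)
})

test_that("centile curves are ordered, symmetric under the identity warp, and default to seven levels", {
  sim <- generate_lifespan(600, lifespan_spec(n_voxels = 1, n_sites = 2,
                                              skew_eps = 0), seed = 6)
  fit <- fit_warped(sim$covariates, sim$stack, seed = 6, warp = "identity")
  ages <- seq(10, 95, by = 2.5)
  cc <- centile_curves(fit, ages, sex = 1, site = "1")
  expect_identical(colnames(cc), paste0("c", c(1, 5, 25, 50, 75, 95, 99)))
  ## non-crossing at every age
  expect_true(all(apply(cc, 1, diff) > 0))
  ## identity warp: median equals predictive mean, (25, 75) symmetric about it
  X <- bspline_design(ages, fit$basis, rep(1, length(ages)),
                      rep("1", length(ages)), fit$site_levels)
  pr <- predict(fit$models[[1]]$fit, X)
  expect_equal(unname(cc[, "c50"]), pr$mean, tolerance = 1e-10)
  expect_equal(cc[, "c75"] - cc[, "c50"], cc[, "c50"] - cc[, "c25"],
               tolerance = 1e-10)
  expect_error(centile_curves(fit, numeric(0), site = "1"), "empty age grid")
  expect_error(centile_curves(fit, 50, site = "1", levels = c(0, 50)),
               "levels")
})

test_that("planted skewed centiles are recovered on the original scale", {
  spec <- lifespan_spec(n_voxels = 2, skew_eps = 0.5)
  sim <- generate_lifespan(1500, spec, seed = 7)
  fit <- fit_warped(sim$covariates, sim$stack, seed = 7)
  ages <- seq(12, 92, by = 4)
  err <- c()
  for (v in 1:2) {
    for (lv in c(5, 50, 95)) {
      cc <- centile_curves(fit, ages, sex = 0, site = "1", levels = lv,
                           voxel = v)
      planted <- vapply(ages, function(a) {
        spec$amp * exp(-((a - spec$peak_age) / spec$peak_width)^2) -
          spec$decline * (a - 8) + spec$site_offsets[1] +
          spec$resid_scale *
            shash_unwarp(qnorm(lv / 100), c(eps = spec$skew_eps,
                                            delta = spec$skew_delta))
      }, numeric(1))
      err <- c(err, abs(cc[, 1] - planted))
    }
  }
  expect_lt(median(err) / spec$resid_scale, 0.1)
})
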