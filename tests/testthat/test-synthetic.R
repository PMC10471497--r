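test_that("adversity marginals match their specification within sampling error", {
  n <- 500
  specs <- default_adversity_specs()
  cov <- generate_adversities(n, specs, seed = 42)
  for (s in specs) {
    x <- cov[[s$name]]
    expect_gte(min(x), s$range[1])
    expect_lte(max(x), s$range[2])
    expect_lt(abs(mean(x) - s$mean), 3 * s$sd / sqrt(n))
    ## sd estimator has s.e. ~ sd / sqrt(2n)
    expect_lt(abs(sd(x) - s$sd), 3 * s$sd / sqrt(2 * n))
    if (s$kind == "count") expect_true(all(x == round(x)))
  }
  expect_true(all(cov$sex %in% c(0, 1)))
  expect_true(all(cov$tiv > 0))
})

test_that("adversity generation is bit-reproducible and respects the correlation dial", {
  a <- generate_adversities(300, seed = 7)
  b <- generate_adversities(300, seed = 7)
  expect_identical(a, b)
  adv <- adversity_names()
  ## positive co-occurrence at the default level
  cc <- cor(as.matrix(a[, adv]))
  expect_gt(mean(cc[upper.tri(cc)]), 0.1)
  ## independence case
  ind <- generate_adversities(800, corr = 0, seed = 8)
  ci <- cor(as.matrix(ind[, adv]))
  expect_lt(max(abs(ci[upper.tri(ci)])), 4 / sqrt(800))
})

test_that("adversity generator rejects invalid input", {
  expect_error(generate_adversities(0), "n must be")
  expect_error(generate_adversities(10, specs = list()), "empty")
  expect_error(adversity_spec("x", c(0, 2), mean = 5, sd = 1), "range")
  expect_error(adversity_spec("x", c(0, 2), mean = 1, sd = -1))
})

test_that("jd stack follows the planted linear forward model", {
  cov <- generate_adversities(400, seed = 3)
  adv <- adversity_names()
  mask <- ellipsoid_mask(c(6L, 6L, 6L))

  ## all-zero coefficients and zero noise give an all-zero image
  null_atlas <- planted_effect_atlas(mask, active = character(), inert = adv,
                                     noise_sd = 0)
  s0 <- generate_jd_stack(cov, null_atlas, seed = 3)
  expect_true(all(s0$data == 0))

  ## noiseless identifiability: OLS reproduces the atlas exactly
  atlas <- planted_effect_atlas(mask, active = adv[1:2], inert = adv[-(1:2)],
                                effect_size = 0.5, noise_sd = 0)
  s1 <- generate_jd_stack(cov, atlas, seed = 3)
  vidx <- which(mask)
  X <- as.matrix(cov[, adv[1:2]])
  for (v in c(1, ncol(s1$data))) {
    b_true <- vapply(adv[1:2], function(nm) atlas$coefficients[[nm]][vidx[v]],
                     numeric(1))
    b_ols <- coef(lm(s1$data[, v] ~ X))[-1]
    expect_equal(unname(b_ols), unname(b_true), tolerance = 1e-8)
  }

  ## noisy case: OLS estimate of a planted 0.5 effect within 3 s.e.
  atlas2 <- planted_effect_atlas(mask, active = adv[1], inert = adv[-1],
                                 effect_size = 0.5, noise_sd = 1)
  s2 <- generate_jd_stack(cov, atlas2, seed = 4)
  v_active <- which(atlas2$coefficients[[adv[1]]][vidx] != 0)[1]
  fitv <- lm(s2$data[, v_active] ~ cov[[adv[1]]])
  est <- summary(fitv)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])

  ## shape/column validation
  expect_error(generate_jd_stack(cov[, 1:3], atlas2), "lack predictor")
})

test_that("lifespan cohort tracks the planted trajectories", {
  spec <- lifespan_spec(n_voxels = 2, skew_eps = 0, skew_delta = 1)
  sim <- generate_lifespan(3000, spec, seed = 9)
  expect_true(all(sim$covariates$age >= 8 & sim$covariates$age <= 97))
  expect_equal(length(unique(sim$covariates$site)), 9)

  ## Gaussian case: residual skewness near zero
  y <- sim$stack$data[, 1]
  ages <- sim$covariates$age
  res <- y - vapply(seq_along(y), function(i) {
    voxnorm:::lifespan_median(spec, ages[i],
                              sim$covariates$sex[i],
                              as.integer(as.character(sim$covariates$site[i])))
  }, numeric(1))
  expect_lt(abs(sample_skewness(res)), 0.15)

  ## binned empirical medians track the planted 50th-centile curve
  site1 <- sim$covariates$site == "1"
  bins <- cut(ages, breaks = seq(8, 97, length.out = 8))
  for (b in levels(bins)[2:6]) {
    sel <- bins == b & site1
    if (sum(sel) < 20) next
    planted <- voxnorm:::lifespan_median(spec, mean(ages[sel]), 0.5, 1)
    ## sex enters additively; use the mid-sex planted value
    expect_lt(abs(median(y[sel]) - planted), 0.15)
  }

  ## per-site means differ by the planted offsets
  site_means <- tapply(y, sim$covariates$site, mean)
  offs <- spec$site_offsets
  expect_gt(cor(site_means[order(names(site_means))],
                offs[order(as.integer(names(site_means)))]), 0.9)

  expect_error(lifespan_spec(age_range = c(5, 97)), "within")
})

test_that("psychopathology generator plants a recoverable burden effect", {
  set.seed(10)
  burden <- rpois(300, 3)

  ## null effect: anxiety independent of burden
  clin0 <- generate_psychopathology(burden, effect = 0, seed = 20)
  mm0 <- fit_mixed(clin0)
  b0 <- mm0$table[mm0$table$term == "burden", ]
  expect_lt(abs(b0$estimate), 3 * b0$se)

  ## planted slope recovered within 3 s.e.
  clin <- generate_psychopathology(burden, effect = 0.07, seed = 21,
                                   intercept_mean = 5)
  mm <- fit_mixed(clin)
  b1 <- mm$table[mm$table$term == "burden", ]
  expect_lt(abs(b1$estimate - 0.07), 3 * b1$se)

  ## censoring at zero and long format
  expect_true(all(clin$anxiety >= 0))
  expect_equal(nrow(clin), 600)
  expect_error(generate_psychopathology(burden, 0.1, times = 0), "times")
})
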