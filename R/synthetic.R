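#' Specification of one adversity score
#'
#' Describes the marginal distribution of a raw adversity score: its
#' admissible range, target mean and standard deviation, and whether the
#' score is count-like (small integer support) or continuous.
#'
#' @param name column label.
#' @param range numeric length-2, `(min, max)` on the raw scale.
#' @param mean,sd target sample moments; `min <= mean <= max`, `sd > 0`.
#' @param kind `"count"` or `"continuous"`.
#' @return An `adversity_spec` object.
#' @export
adversity_spec <- function(name, range, mean, sd, kind = c("count", "continuous")) {
  kind <- match.arg(kind)
  stopifnot(length(range) == 2L, range[1] < range[2], sd > 0)
  if (mean < range[1] || mean > range[2]) {
    stop("mean must lie inside the score range for '", name, "'")
  }
  structure(list(name = name, range = as.numeric(range), mean = mean,
                 sd = sd, kind = kind),
            class = "adversity_spec")
}

#' Reference panel of seven lifetime adversities
#'
#' Default marginals for the seven adversity scores used throughout the
#' package, spanning the prenatal (maternal smoking and stress), perinatal
#' (obstetric risk) and postnatal period (maternal sensitivity reversed to
#' insensitivity direction is *not* applied here — raw sensitivity values are
#' kept and z-scored downstream), with ranges, means and standard deviations
#' typical of a prospectively followed at-risk birth cohort.
#'
#' @return List of seven [adversity_spec()] objects.
#' @export
default_adversity_specs <- function() {
  list(
    adversity_spec("maternal_smoking",     c(0, 2),     0.36,   0.71,   "count"),
    adversity_spec("prenatal_stress",      c(0, 8),     2.74,   1.81,   "count"),
    adversity_spec("maternal_sensitivity", c(0, 1015),  503.43, 176.56, "continuous"),
    adversity_spec("obstetric_adversity",  c(0, 4),     0.95,   0.98,   "count"),
    adversity_spec("family_adversity",     c(0, 10),    3.50,   2.41,   "count"),
    adversity_spec("life_events",          c(24, 116),  53.04,  16.59,  "continuous"),
    adversity_spec("childhood_trauma",     c(25, 63),   29.60,  5.92,   "continuous")
  )
}

## moments of a normal censored (clipped) to [lo, hi]
censored_normal_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  pa <- pnorm(a); pb <- pnorm(b)
  da <- dnorm(a); db <- dnorm(b)
  pmid <- pb - pa
  ex <- lo * pa + hi * (1 - pb) + mu * pmid + sigma * (da - db)
  ex2 <- lo^2 * pa + hi^2 * (1 - pb) +
    (mu^2 + sigma^2) * pmid + sigma * ((lo + mu) * da - (hi + mu) * db)
  v <- max(ex2 - ex^2, 0)
  c(mean = ex, sd = sqrt(v))
}

## moments of round(clip(N(mu, sigma), lo, hi)) on integer support lo..hi
discretised_normal_moments <- function(mu, sigma, lo, hi) {
  k <- lo:hi
  upper <- pnorm((k + 0.5 - mu) / sigma)
  lower <- pnorm((k - 0.5 - mu) / sigma)
  p <- upper - lower
  p[1] <- upper[1]                       # censor lower tail into lo
  p[length(p)] <- 1 - lower[length(p)]   # censor upper tail into hi
  ex <- sum(k * p)
  v <- max(sum(k^2 * p) - ex^2, 0)
  c(mean = ex, sd = sqrt(v))
}

## latent (mu, sigma) whose clipped/discretised marginal matches spec moments
calibrate_marginal <- function(spec) {
  target <- c(spec$mean, spec$sd)
  mom <- if (spec$kind == "count") {
    function(p) discretised_normal_moments(p[1], exp(p[2]),
                                           spec$range[1], spec$range[2])
  } else {
    function(p) censored_normal_moments(p[1], exp(p[2]),
                                        spec$range[1], spec$range[2])
  }
  obj <- function(p) {
    m <- mom(p)
    sum(((m - target) / c(max(abs(target[1]), 1), target[2]))^2)
  }
  fit <- optim(c(spec$mean, log(spec$sd)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  list(mu = fit$par[1], sigma = exp(fit$par[2]), objective = fit$value)
}

## map latent standard-normal draws to the raw score scale (monotone in z)
marginal_from_latent <- function(z, spec, calib) {
  x <- calib$mu + calib$sigma * z
  x <- pmin(pmax(x, spec$range[1]), spec$range[2])
  if (spec$kind == "count") x <- round(x)
  x
}

#' Generate a correlated adversity cohort
#'
#' Draws `n` subjects with seven (or however many are specified) adversity
#' scores through a Gaussian copula: a latent multivariate normal with
#' exchangeable correlation `corr` is transformed per variable so each
#' marginal matches its [adversity_spec()] mean and standard deviation while
#' respecting the score range (continuous scores are censored at the range
#' ends; count scores are discretised by thresholding the latent variable,
#' both with moment-calibrated latent parameters). Sex (binary, 58% coded 1,
#' the female fraction typical of the reference cohort) and total
#' intracranial volume (TIV, mm^3 scale) are appended.
#'
#' @param n number of subjects (>= 1).
#' @param specs list of [adversity_spec()]; default [default_adversity_specs()].
#' @param corr target latent pairwise correlation in `[0, 1)`; the induced
#'   raw-scale correlations are positive and slightly attenuated by
#'   discretisation. Default 0.3 — a moderate positive co-occurrence of
#'   adversities.
#' @param seed integer seed (a child stream is derived; see [child_seed()]).
#' @param female_frac fraction coded `sex = 1` (default 0.58).
#' @param tiv_mean,tiv_sd TIV moments in mm^3 (defaults 1.45e6, 1.3e5).
#' @return A `data.frame` with columns `subject`, one column per adversity,
#'   `sex` and `tiv`.
#' @export
generate_adversities <- function(n, specs = default_adversity_specs(),
                                 corr = 0.3, seed = 1,
                                 female_frac = 0.58,
                                 tiv_mean = 1.45e6, tiv_sd = 1.3e5) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be >= 1")
  if (length(specs) == 0L) stop("empty adversity spec list")
  if (corr < 0 || corr >= 1) stop("corr must be in [0, 1)")
  p <- length(specs)
  with_seed(child_seed(seed, "adversities"), {
    shared <- rnorm(n)
    z <- sqrt(corr) * matrix(shared, n, p) +
      sqrt(1 - corr) * matrix(rnorm(n * p), n, p)
    cols <- lapply(seq_len(p), function(j) {
      marginal_from_latent(z[, j], specs[[j]], calibrate_marginal(specs[[j]]))
    })
    names(cols) <- vapply(specs, `[[`, "", "name")
    sex <- rbinom(n, 1L, female_frac)
    tiv <- abs(rnorm(n, tiv_mean, tiv_sd))
    data.frame(subject = seq_len(n), cols, sex = sex, tiv = tiv,
               check.names = FALSE)
  })
}

#' Ground-truth voxel effect atlas
#'
#' The forward model for synthetic Jacobian-determinant images: one 3D
#' coefficient map per predictor (volume change per unit predictor) plus a
#' per-voxel noise standard-deviation map, all on a common masked grid.
#'
#' @param mask 3D logical array.
#' @param coefficients named list of 3D numeric arrays (one per predictor),
#'   each of the mask's dimension.
#' @param noise_sd 3D numeric array, or a scalar recycled over the grid.
#' @return An `effect_atlas` object.
#' @export
effect_atlas <- function(mask, coefficients, noise_sd = 1) {
  mask <- array(as.logical(mask), dim = dim(mask))
  if (length(noise_sd) == 1L) noise_sd <- array(noise_sd, dim = dim(mask))
  stopifnot(is.list(coefficients), length(names(coefficients)) ==
              length(coefficients))
  for (nm in names(coefficients)) {
    b <- coefficients[[nm]]
    if (!identical(dim(b), dim(mask))) {
      stop("coefficient map '", nm, "' does not match the mask grid")
    }
    if (!all(is.finite(b))) stop("non-finite coefficients in '", nm, "'")
  }
  if (!identical(dim(noise_sd), dim(mask)) || any(noise_sd < 0)) {
    stop("noise_sd must be a non-negative array on the mask grid")
  }
  structure(list(mask = mask, coefficients = coefficients,
                 noise_sd = noise_sd),
            class = "effect_atlas")
}

#' Planted block-effect atlas
#'
#' Convenience constructor giving each listed predictor a contiguous
#' rectangular block of voxels with constant effect (alternating sign across
#' predictors so both expansions and contractions are planted), and zero
#' effect elsewhere. Blocks are laid out along the x-axis so different
#' predictors occupy different (partially non-overlapping) territories.
#'
#' @param mask 3D logical array.
#' @param active character vector of predictors receiving a planted effect.
#' @param inert character vector of predictors included with all-zero maps.
#' @param effect_size absolute per-unit effect within a block (default 0.5).
#' @param noise_sd scalar or array noise sd (default 1).
#' @return An `effect_atlas`.
#' @export
planted_effect_atlas <- function(mask, active, inert = character(),
                                 effect_size = 0.5, noise_sd = 1) {
  mask <- array(as.logical(mask), dim = dim(mask))
  dims <- dim(mask)
  k <- length(active)
  coefs <- list()
  if (k > 0) {
    ## slabs of the x-range, one per active predictor
    edges <- round(seq(0, dims[1], length.out = k + 1))
    for (j in seq_len(k)) {
      b <- array(0, dim = dims)
      xs <- (edges[j] + 1):edges[j + 1]
      b[xs, , ] <- effect_size * (-1)^(j - 1)
      b[!mask] <- 0
      coefs[[active[j]]] <- b
    }
  }
  for (nm in inert) coefs[[nm]] <- array(0, dim = dims)
  effect_atlas(mask, coefs, noise_sd)
}

#' Simulate a Jacobian-determinant voxel stack from covariates
#'
#' Applies the linear forward model `y_v = sum_j beta_{v,j} x_j + eps_v`
#' voxel-wise, with independent Gaussian noise `eps_v ~ N(0, sd_v^2)` per
#' subject and voxel. Values are on the log-Jacobian scale (0 = no volume
#' change).
#'
#' @param cov covariate `data.frame` containing every predictor named in the
#'   atlas.
#' @param atlas an [effect_atlas()].
#' @param seed integer seed.
#' @return A [voxel_stack()].
#' @export
generate_jd_stack <- function(cov, atlas, seed = 1) {
  stopifnot(inherits(atlas, "effect_atlas"))
  preds <- names(atlas$coefficients)
  missing_cols <- setdiff(preds, names(cov))
  if (length(missing_cols)) {
    stop("covariates lack predictor column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(cov)
  vidx <- which(atlas$mask)
  B <- vapply(preds, function(nm) atlas$coefficients[[nm]][vidx],
              numeric(length(vidx)))        # V x p
  X <- as.matrix(cov[, preds, drop = FALSE])  # n x p
  mu <- X %*% t(B)                            # n x V
  sdv <- atlas$noise_sd[vidx]
  with_seed(child_seed(seed, "jd_stack"), {
    eps <- matrix(rnorm(n * length(vidx)), n) *
      matrix(sdv, n, length(vidx), byrow = TRUE)
    voxel_stack(mu + eps, atlas$mask, subjects = cov$subject)
  })
}

#' Specification of a synthetic lifespan cohort
#'
#' @param age_range ages in years, within `[8, 97]`.
#' @param n_sites number of scan sites (default 9).
#' @param site_offsets per-site additive shifts (default evenly spread in
#'   `[-0.3, 0.3]`).
#' @param sex_effect additive shift for `sex = 1` (default 0.1).
#' @param n_voxels number of synthetic voxels (laid out in a thin 3D grid).
#' @param peak_age,peak_width,decline age-trajectory shape: the voxel median
#'   follows `amp * exp(-((age - peak_age)/peak_width)^2) - decline * (age - 8)`,
#'   a rise-and-fall curve qualitatively matching regional volume development.
#' @param amp trajectory amplitude.
#' @param skew_eps,skew_delta sinh-arcsinh residual shape; `(0, 1)` is
#'   Gaussian. Default `(0.5, 1)` plants right-skew so an identity-warp
#'   Gaussian model is misspecified.
#' @param resid_scale residual scale multiplying the sinh-arcsinh draw.
#' @return A `lifespan_spec` object.
#' @export
lifespan_spec <- function(age_range = c(8, 97), n_sites = 9,
                          site_offsets = NULL, sex_effect = 0.1,
                          n_voxels = 20, peak_age = 25, peak_width = 30,
                          decline = 0.01, amp = 1,
                          skew_eps = 0.5, skew_delta = 1,
                          resid_scale = 0.3) {
  stopifnot(length(age_range) == 2L, age_range[1] < age_range[2])
  if (age_range[1] < 8 || age_range[2] > 97) {
    stop("age range must lie within [8, 97]")
  }
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (is.null(site_offsets)) {
    site_offsets <- if (n_sites == 1) 0 else
      seq(-0.3, 0.3, length.out = n_sites)
  }
  stopifnot(length(site_offsets) == n_sites, skew_delta > 0, resid_scale > 0)
  structure(list(age_range = age_range, n_sites = n_sites,
                 site_offsets = site_offsets, sex_effect = sex_effect,
                 n_voxels = n_voxels, peak_age = peak_age,
                 peak_width = peak_width, decline = decline, amp = amp,
                 skew_eps = skew_eps, skew_delta = skew_delta,
                 resid_scale = resid_scale),
            class = "lifespan_spec")
}

## median (50th-centile) trajectory implied by a lifespan_spec
lifespan_median <- function(spec, age, sex = 0, site = 1) {
  mu <- spec$amp * exp(-((age - spec$peak_age) / spec$peak_width)^2) -
    spec$decline * (age - spec$age_range[1])
  mu + spec$site_offsets[site] + spec$sex_effect * sex +
    spec$resid_scale * shash_unwarp(0, c(eps = spec$skew_eps,
                                         delta = spec$skew_delta))
}

#' Simulate a lifespan cohort for the ageing normative model
#'
#' Ages are uniform on the spec range, sites balanced, sex Bernoulli(0.5).
#' Every voxel shares the spec trajectory shape; residuals are sinh-arcsinh
#' distributed (`unwarp(Z)` for standard-normal `Z`), so the planted centile
#' at level `q` is `median_curve + resid_scale * unwarp(qnorm(q))` and a
#' Gaussian model is misspecified whenever `skew_eps != 0` or
#' `skew_delta != 1`.
#'
#' @param n number of subjects.
#' @param spec a [lifespan_spec()].
#' @param seed integer seed.
#' @return List with `covariates` (`data.frame`: subject, age, sex, site),
#'   `stack` (a [voxel_stack()] on an `n_voxels x 1 x 1` grid) and `spec`
#'   (the ground truth, for recovery checks).
#' @export
generate_lifespan <- function(n, spec = lifespan_spec(), seed = 1) {
  if (n < 1) stop("n must be >= 1")
  with_seed(child_seed(seed, "lifespan"), {
    age <- runif(n, spec$age_range[1], spec$age_range[2])
    site <- rep_len(seq_len(spec$n_sites), n)[sample.int(n)]
    sex <- rbinom(n, 1L, 0.5)
    mu <- spec$amp * exp(-((age - spec$peak_age) / spec$peak_width)^2) -
      spec$decline * (age - spec$age_range[1]) +
      spec$site_offsets[site] + spec$sex_effect * sex
    w <- c(eps = spec$skew_eps, delta = spec$skew_delta)
    V <- spec$n_voxels
    z <- matrix(rnorm(n * V), n, V)
    y <- mu + spec$resid_scale * shash_unwarp(z, w)
    mask <- array(TRUE, dim = c(V, 1L, 1L))
    list(covariates = data.frame(subject = seq_len(n), age = age,
                                 sex = sex, site = factor(site)),
         stack = voxel_stack(y, mask),
         spec = spec)
  })
}

#' Simulate longitudinal anxiety driven by deviation burden
#'
#' Anxiety at each of `times` assessments is a random-intercept linear
#' function of a per-subject negative-deviation burden, censored at zero to
#' mimic the bounded low end of symptom checklists:
#' `anxiety_{i,t} = max(0, b0 + u_i + effect * burden_i + b_t * (t - 1) + e_{it})`
#' with `u_i ~ N(0, intercept_sd^2)` and `e_{it} ~ N(0, resid_sd^2)`.
#' Defaults place scores on the scale of a 0-14 anxiety-problems checklist
#' (population mean near 2.8).
#'
#' @param burden numeric vector, one non-negative burden per subject.
#' @param effect slope of anxiety on burden.
#' @param times number of assessment waves (>= 1, default 2).
#' @param intercept_mean,intercept_sd fixed and random intercept parameters.
#' @param time_effect additive change per wave (default 0).
#' @param resid_sd occasion-level noise sd.
#' @param seed integer seed.
#' @return Long-format `data.frame`: `subject`, `time`, `anxiety`, `burden`.
#' @export
generate_psychopathology <- function(burden, effect, times = 2,
                                     intercept_mean = 2.8, intercept_sd = 1,
                                     time_effect = 0, resid_sd = 1.5,
                                     seed = 1) {
  if (times < 1) stop("times must be >= 1")
  if (!all(is.finite(burden))) stop("burden must be finite")
  if (!is.finite(effect)) stop("effect must be finite")
  n <- length(burden)
  with_seed(child_seed(seed, "psychopath"), {
    u <- rnorm(n, 0, intercept_sd)
    out <- do.call(rbind, lapply(seq_len(times), function(t) {
      e <- rnorm(n, 0, resid_sd)
      y <- intercept_mean + u + effect * burden + time_effect * (t - 1) + e
      data.frame(subject = seq_len(n), time = t,
                 anxiety = pmax(0, y), burden = burden)
    }))
    rownames(out) <- NULL
    out
  })
}
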