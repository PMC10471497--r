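#' Threshold a subject's deviation z-map
#'
#' Splits a voxel-wise z-map into disjoint positive (`z > threshold`,
#' expansions beyond the normative prediction) and negative
#' (`z < -threshold`, contractions) binary maps. The default threshold 2.6
#' corresponds to a two-sided tail probability below 0.005 per sign under
#' the standard normal.
#'
#' @param z numeric vector of z-scores over masked voxels. Non-finite values
#'   are excluded (treated as sub-threshold) with a warning.
#' @param threshold positive cut (default 2.6).
#' @return List with logical `positive` and `negative` maps and the counts
#'   `n_positive`, `n_negative`.
#' @export
threshold_npm <- function(z, threshold = 2.6) {
  if (threshold <= 0) stop("threshold must be > 0")
  bad <- !is.finite(z)
  if (any(bad)) {
    warning(sum(bad), " non-finite z value(s) excluded")
    z[bad] <- 0
  }
  pos <- z > threshold
  neg <- z < -threshold
  list(positive = pos, negative = neg,
       n_positive = sum(pos), n_negative = sum(neg))
}

#' Per-subject deviation burden
#'
#' Summarises each subject's supra-threshold deviations, by sign: the count
#' of voxels beyond the threshold (default) or the mean absolute z over
#' them (0 when none).
#'
#' @param z subjects x voxels z-score matrix (e.g. `fit$z` from
#'   [crossval_fit()]).
#' @param threshold positive cut (default 2.6).
#' @param statistic `"count"` or `"mean_abs_z"`.
#' @return data.frame: `subject`, `negative`, `positive`.
#' @export
deviation_burden <- function(z, threshold = 2.6,
                             statistic = c("count", "mean_abs_z")) {
  statistic <- match.arg(statistic)
  z <- as.matrix(z)
  if (nrow(z) < 1 || ncol(z) < 1) stop("empty z matrix")
  summarise <- function(zrow, sel) {
    if (statistic == "count") sum(sel)
    else if (!any(sel)) 0 else mean(abs(zrow[sel]))
  }
  neg <- apply(z, 1, function(r) summarise(r, is.finite(r) & r < -threshold))
  pos <- apply(z, 1, function(r) summarise(r, is.finite(r) & r > threshold))
  data.frame(subject = seq_len(nrow(z)), negative = neg, positive = pos)
}

#' Voxel-wise deviation prevalence
#'
#' Fraction of subjects whose thresholded deviation map is active at each
#' voxel, for one sign.
#'
#' @param z subjects x voxels z matrix.
#' @param sign `"positive"` or `"negative"`.
#' @param threshold positive cut (default 2.6).
#' @return Numeric vector in `[0, 1]`, one value per voxel.
#' @export
prevalence_map <- function(z, sign = c("negative", "positive"),
                           threshold = 2.6) {
  sign <- match.arg(sign)
  z <- as.matrix(z)
  if (nrow(z) < 1) stop("need at least one subject")
  hits <- if (sign == "positive") z > threshold else z < -threshold
  hits[!is.finite(z)] <- FALSE
  colMeans(hits)
}

#' Box-Cox normalisation of deviation burdens
#'
#' Power-transforms a non-negative score toward normality:
#' `y = (x^lambda - 1)/lambda` (`log x` at `lambda = 0`), with `lambda`
#' chosen to maximise the profile log-likelihood. Since burdens can be zero,
#' a shift of `1 - min(x)` is applied first whenever any value is <= 0 and
#' recorded in the output. The transform is monotone for every `lambda`.
#'
#' @param x numeric vector.
#' @param lambda optional fixed lambda (skips estimation).
#' @param range search interval for lambda (default `c(-3, 3)`).
#' @return List: `transformed`, `lambda`, `shift`.
#' @export
boxcox_transform <- function(x, lambda = NULL, range = c(-3, 3)) {
  if (anyNA(x)) stop("missing values")
  shift <- if (min(x) <= 0) 1 - min(x) else 0
  xs <- x + shift
  if (length(unique(xs)) == 1L) {
    warning("all values identical; returning identity transform")
    return(list(transformed = xs, lambda = 1, shift = shift))
  }
  bc <- function(l) if (abs(l) < 1e-12) log(xs) else (xs^l - 1) / l
  if (is.null(lambda)) {
    n <- length(xs)
    slx <- sum(log(xs))
    profile_ll <- function(l) {
      y <- bc(l)
      -n / 2 * log(mean((y - mean(y))^2)) + (l - 1) * slx
    }
    lambda <- optimize(profile_ll, interval = range,
                       maximum = TRUE, tol = 1e-6)$maximum
  }
  list(transformed = bc(lambda), lambda = lambda, shift = shift)
}

#' Multiple-comparison corrected significance level
#'
#' Bonferroni correction over psychopathology outcomes and deviation signs:
#' `base / (n_outcomes * n_scores)`. An explicit `override` value (e.g. a
#' pre-registered corrected level) is returned unchanged when supplied.
#'
#' @param base family-wise level in `(0, 1)` (default 0.05).
#' @param n_outcomes number of psychopathology outcomes (default 4).
#' @param n_scores number of deviation scores (default 2: positive and
#'   negative).
#' @param override optional explicit corrected level.
#' @return The corrected alpha.
#' @export
corrected_alpha <- function(base = 0.05, n_outcomes = 4, n_scores = 2,
                            override = NULL) {
  if (!is.null(override)) return(override)
  if (base <= 0 || base >= 1) stop("base must be in (0, 1)")
  if (n_outcomes < 1 || n_scores < 1) stop("counts must be >= 1")
  base / (n_outcomes * n_scores)
}

#' Linear mixed model of psychopathology on deviation burden
#'
#' Fits `outcome ~ burden + time [+ covariates] + (1 | subject)` by REML via
#' lme4, mirroring a random-intercept longitudinal symptom model. Two-sided
#' p-values use a normal approximation on the t-ratios by default;
#' `df = "satterthwaite"` switches to Satterthwaite degrees of freedom via
#' lmerTest. Partial eta-squared per fixed effect is `t^2 / (t^2 + df)`.
#'
#' @param data long-format data.frame with columns `subject`, `time`, the
#'   outcome, and the predictor(s).
#' @param outcome outcome column name (default `"anxiety"`).
#' @param predictors character vector of fixed-effect column names (burden
#'   first, by convention).
#' @param include_time add `time` as a fixed effect (default TRUE when
#'   more than one time point is present).
#' @param df `"normal"` (default) or `"satterthwaite"`.
#' @return A `mixed_result`: `table` (term, estimate, se, t, df, p, eta2),
#'   `ranef_var` (random-intercept variance), `singular` flag, `n_subjects`,
#'   `n_obs`, and the underlying `model`.
#' @export
fit_mixed <- function(data, outcome = "anxiety", predictors = "burden",
                      include_time = NULL, df = c("normal", "satterthwaite")) {
  df <- match.arg(df)
  if (!all(c("subject", "time", outcome, predictors) %in% names(data))) {
    stop("missing required column(s)")
  }
  if (all(is.na(data[[outcome]]))) stop("all-missing outcome")
  if (is.null(include_time)) include_time <- length(unique(data$time)) > 1
  rhs <- paste(c(predictors, if (include_time) "time"), collapse = " + ")
  one_per_subject <- !any(duplicated(data$subject[!is.na(data[[outcome]])]))
  if (one_per_subject) {
    ## a random intercept is unidentifiable with one observation per
    ## subject; the model degenerates to OLS with zero intercept variance
    warning("one observation per subject: random-intercept variance fixed ",
            "at 0 (ordinary least squares)")
    fit <- lm(as.formula(paste(outcome, "~", rhs)), data = data)
    cf <- coef(summary(fit))
    n_obs <- length(fit$residuals)
    ranef_var <- 0
    resid_var <- summary(fit)$sigma^2
    singular <- TRUE
    df_resid <- fit$df.residual
  } else {
    form <- as.formula(paste(outcome, "~", rhs, "+ (1 | subject)"))
    fit <- if (df == "satterthwaite") {
      lmerTest::lmer(form, data = data, REML = TRUE)
    } else {
      lme4::lmer(form, data = data, REML = TRUE)
    }
    singular <- lme4::isSingular(fit)
    if (singular) {
      warning("singular mixed-model fit (random-intercept variance near 0)")
    }
    cf <- coef(summary(fit))
    n_obs <- nrow(fit@frame)
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_var <- vc$vcov[vc$grp == "subject"]
    resid_var <- vc$vcov[vc$grp == "Residual"]
    df_resid <- n_obs - nrow(cf)
  }
  if (df == "satterthwaite" && "df" %in% colnames(cf)) {
    dfs <- cf[, "df"]
    pvals <- cf[, "Pr(>|t|)"]
  } else {
    dfs <- rep(df_resid, nrow(cf))
    pvals <- 2 * pnorm(-abs(cf[, "t value"]))
  }
  tval <- cf[, "t value"]
  tab <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                    se = cf[, "Std. Error"], t = tval, df = dfs, p = pvals,
                    eta2 = tval^2 / (tval^2 + dfs), row.names = NULL)
  structure(list(table = tab,
                 ranef_var = ranef_var,
                 resid_var = resid_var,
                 singular = singular,
                 n_subjects = length(unique(data$subject)),
                 n_obs = n_obs, model = fit),
            class = "mixed_result")
}

#' @export
print.mixed_result <- function(x, ...) {
  cat("mixed_result:", x$n_obs, "observations,", x$n_subjects,
      "subjects; random-intercept var =", signif(x$ranef_var, 3), "\n")
  print(transform(x$table, estimate = signif(estimate, 3),
                  se = signif(se, 3), t = signif(t, 3),
                  p = signif(p, 3), eta2 = signif(eta2, 3)))
  invisible(x)
}
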