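#' Pipeline run configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Every sensitivity
#' toggle corresponds to a documented model variant: dropping TIV or sex
#' from the design, using raw (unbinned) adversity scores, or excluding
#' individual adversities. Unknown keys are rejected.
#'
#' @param ... configuration values overriding the defaults; alternatively a
#'   single named list. Keys: `n_subjects`, `shape`, `seed`, `corr`, `folds`,
#'   `threshold`, `fraction`, `n_components`, `n_points`, `effect_size`,
#'   `noise_sd`, `active`, `clinical_effect`, `times`, `no_tiv`, `no_sex`,
#'   `unbinned`, `drop`.
#' @param yaml optional path to a YAML file whose entries are applied before
#'   `...` overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(..., yaml = NULL) {
  defaults <- list(
    n_subjects = 169L, shape = c(12L, 12L, 12L), seed = 1L, corr = 0.3,
    folds = 10L, threshold = 2.6, fraction = 0.02,
    n_components = 3L, n_points = 4L,
    effect_size = 0.5, noise_sd = 1,
    active = c("maternal_smoking", "family_adversity", "childhood_trauma"),
    clinical_effect = 0.3, times = 2L,
    no_tiv = FALSE, no_sex = FALSE, unbinned = FALSE, drop = character()
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.null(names(overrides)) &&
      is.list(overrides[[1]])) {
    overrides <- overrides[[1]]
  }
  if (!is.null(yaml)) {
    overrides <- modifyList(yaml::read_yaml(yaml), overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- modifyList(defaults, overrides)
  structure(cfg, class = "run_config")
}

#' Run the full synthetic adversity pipeline
#'
#' Executes the whole workflow on a synthetic cohort: generate adversities
#' and a Jacobian-determinant stack with planted effects; bin scores (unless
#' `unbinned`); fit the cross-validated voxel-wise normative model on the
#' configured design; compute structure coefficients and their pairwise dice
#' overlap; fit the PC-based model; threshold deviation maps and summarise
#' burdens; generate deviation-driven anxiety and fit the mixed model. All
#' artefacts are written under `out_dir` (TSV tables, NIfTI maps) together
#' with a JSON manifest (configuration, seeds, file MD5 hashes) that fully
#' determines the outputs: the same configuration reruns bit-identically.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("voxnorm_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  msg <- function(...) message("[voxnorm] ", ...)

  msg("stage 1/6: simulate cohort")
  specs <- default_adversity_specs()
  cov <- generate_adversities(config$n_subjects, specs, corr = config$corr,
                              seed = config$seed)
  adversities <- setdiff(vapply(specs, `[[`, "", "name"), config$drop)
  mask <- ellipsoid_mask(config$shape)
  atlas <- planted_effect_atlas(mask,
                                active = intersect(config$active, adversities),
                                inert = setdiff(adversities, config$active),
                                effect_size = config$effect_size,
                                noise_sd = config$noise_sd)
  stack <- generate_jd_stack(cov, atlas, seed = config$seed)
  write_covariates(cov, p("covariates.tsv"))
  write_voxel_stack(stack, p("jd.nii.gz"), p("mask.nii.gz"))

  msg("stage 2/6: design (", if (config$unbinned) "raw" else "binned",
      " scores)")
  A <- as.matrix(cov[, adversities, drop = FALSE])
  if (!config$unbinned) {
    A <- vapply(adversities, function(nm) bin_scores(cov[[nm]])$binned,
                numeric(config$n_subjects))
    colnames(A) <- adversities
  }
  X <- A
  if (!config$no_sex) X <- cbind(X, sex = cov$sex)
  if (!config$no_tiv) X <- cbind(X, tiv = cov$tiv)

  msg("stage 3/6: cross-validated normative fit (", config$folds, " folds)")
  fit <- crossval_fit(X, stack, k = config$folds, seed = config$seed)
  write_covariates(fit$metrics, p("metrics.tsv"))
  write_covariates(fit$qc, p("qc.tsv"))
  write_map(stack, fit$metrics$rho, p("rho.nii.gz"))
  write_map(stack, fit$metrics$smse, p("smse.nii.gz"))
  write_map(stack, fit$coef, p("coef.nii.gz"))
  write_map(stack, fit$z, p("z.nii.gz"))

  msg("stage 4/6: structure coefficients and dice overlap")
  sc <- structure_coefficients(fit, A)
  write_map(stack, sc, p("structure_coefficients.nii.gz"))
  dm <- dice_matrix(sc, fraction = config$fraction)
  write_covariates(data.frame(adversity = rownames(dm$mean),
                              round(dm$mean, 6), check.names = FALSE),
                   p("dice_mean.tsv"))

  msg("stage 5/6: PC model (", config$n_components, " components)")
  pcs <- pca_varimax(cov[, adversities, drop = FALSE],
                     n_components = config$n_components)
  pc_fit <- fit_pc_model(pcs, cov, stack, k = config$folds,
                         seed = config$seed)
  write_covariates(data.frame(adversity = rownames(pcs$loadings),
                              round(pcs$loadings, 6)), p("pc_loadings.tsv"))
  write_covariates(data.frame(component = seq_along(pcs$explained),
                              eigenvalue = pcs$eigenvalues,
                              explained = pcs$explained),
                   p("pc_explained.tsv"))

  msg("stage 6/6: deviations and clinical model")
  burden <- deviation_burden(fit$z, threshold = config$threshold)
  bc <- boxcox_transform(burden$negative)
  burden$negative_bc <- bc$transformed
  write_covariates(burden, p("burden.tsv"))
  clin <- generate_psychopathology(burden$negative,
                                   effect = config$clinical_effect,
                                   times = config$times, seed = config$seed)
  clin$burden_bc <- bc$transformed[clin$subject]
  mm <- fit_mixed(clin, predictors = "burden_bc")
  write_covariates(mm$table, p("mixed_model.tsv"))
  write_covariates(clin, p("clinical.tsv"))

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("voxnorm")),
    config = unclass(config),
    alpha = corrected_alpha(),
    outputs = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files)))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
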