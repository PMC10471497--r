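## Shared fixture builders. All randomness is seeded at the call site.

adversity_names <- function() {
  vapply(default_adversity_specs(), `[[`, "", "name")
}

## small cohort + planted-effect stack used across pipeline-level tests
small_planted_setup <- function(n = 120, shape = c(8L, 8L, 8L), seed = 1,
                                effect_size = 0.5, noise_sd = 1,
                                active = NULL) {
  adv <- adversity_names()
  if (is.null(active)) active <- adv[c(1, 5, 7)]
  cov <- generate_adversities(n, seed = seed)
  mask <- ellipsoid_mask(shape)
  atlas <- planted_effect_atlas(mask, active = active,
                                inert = setdiff(adv, active),
                                effect_size = effect_size,
                                noise_sd = noise_sd)
  stack <- generate_jd_stack(cov, atlas, seed = seed)
  list(cov = cov, mask = mask, atlas = atlas, stack = stack,
       adversities = adv, active = active)
}

## sample skewness (moment estimator), used as an independent shape oracle
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
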