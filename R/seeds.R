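#' Derive a child seed for a named random stream
#'
#' All generators in the package draw their randomness from one integer master
#' seed through a documented splitting scheme: each named operation receives
#' `(seed + offset(stream)) mod (2^31 - 1)` where the offsets are fixed,
#' well-separated constants. This keeps independent pipeline stages
#' reproducible in isolation (rerunning one stage does not perturb another)
#' while a single `--seed` still determines the whole run.
#'
#' @param seed integer master seed.
#' @param stream character, one of the registered stream names.
#' @return An integer seed for the requested stream.
#' @export
#' @examples
#' child_seed(1, "adversities")
child_seed <- function(seed, stream) {
  offsets <- c(
    adversities   = 1000003L,
    jd_stack      = 2000029L,
    lifespan      = 3000017L,
    psychopath    = 4000037L,
    folds         = 5000011L,
    split_half    = 6000023L,
    sampling      = 7000003L
  )
  if (!stream %in% names(offsets)) {
    stop("unknown random stream: ", stream)
  }
  as.integer((as.numeric(seed) + offsets[[stream]]) %% (2^31 - 1))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
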