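#' Derive a stage-specific random seed from a top-level seed
#'
#' All stochastic stages of the pipeline (SMOTE, cross-validation folds,
#' classifier training, permutation draws, synthetic data) draw their seeds
#' from one top-level integer through this function, so that stages never
#' share an RNG stream and a single seed reproduces a whole run.
#'
#' The derivation is a fixed polynomial hash of the stage name folded into
#' the seed modulo 2^31 - 1 (a Mersenne prime), keeping the result a valid
#' positive 32-bit integer seed.
#'
#' @param seed integer top-level seed.
#' @param stage character stage name, e.g. `"smote"`, `"cv"`, `"svm"`.
#' @return a positive integer seed, distinct per stage for a given seed.
#' @export
#' @examples
#' derive_seed(1L, "smote")
#' derive_seed(1L, "cv")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  out <- (abs(as.numeric(seed)) %% m + h * 7919) %% m
  as.integer(out %% (m - 1) + 1)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. Mersenne-Twister is pinned so results do not depend on the
# session's RNGkind.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Progress/log messages go to stderr via message(); quiet option respected.
nc_log <- function(...) {
  if (!isTRUE(getOption("netconstraint.quiet", FALSE))) {
    message(...)
  }
  invisible(NULL)
}
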