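#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rnorm rbinom runif var sd cor setNames
#' @importFrom utils head
NULL

# Evaluate `code` with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards so package functions never clobber user RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps derived seeds inside 32-bit range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a single finite number."))
  }
}

pipeline_log <- function(stage, ...) {
  inform(paste0("[", stage, "] ", paste0(..., collapse = "")))
}
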