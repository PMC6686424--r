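#' Derive a reproducible sub-seed from a base seed and index keys
#'
#' Hashes a base seed together with any number of integer or character keys
#' into a single seed in `[1, 2^31 - 2]`. Used so that every generated unit
#' (gene set, sample, sample-by-caller replicate) owns an independent,
#' stable RNG stream: adding samples to a cohort never reshuffles the draws
#' of earlier samples.
#'
#' @param seed Base integer seed.
#' @param ... Integer or character keys identifying the stream.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  keys <- list(...)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in keys) {
    if (is.character(k)) {
      k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    }
    for (ki in as.numeric(k)) {
      h <- (h * 1000003 + (ki %% m) + 12289) %% m
    }
  }
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a local RNG seed
#'
#' Sets the seed, evaluates, and restores the caller's RNG state, so that
#' library code never perturbs the user's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_config <- function(msg) stop(msg, call. = FALSE)
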