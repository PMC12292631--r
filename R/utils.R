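#' @importFrom stats rnorm rpois runif rbinom sd cor quantile median setNames
#'   predict aggregate
#' @importFrom utils read.csv write.csv head
NULL

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All package randomness flows through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a stage-specific seed from a top-level seed
#'
#' Deterministic scheme used by [run_pipeline()] so that every stochastic
#' stage gets its own reproducible stream: the stage name is folded into a
#' 31-bit integer via a polynomial byte hash and combined with the top-level
#' seed.
#'
#' @param seed Integer top-level seed.
#' @param stage Character stage name (e.g. `"cluster"`, `"augment"`).
#' @return A single integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 1103 + h) %% 2147483647)
}

# half-up rounding to `digits` decimals; R's round() is round-half-even,
# but the printed tables we mirror use conventional half-up percentages
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
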