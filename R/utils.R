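## Internal helpers shared across stages.

## Evaluate `expr` under a local RNG state seeded with `seed`.
## The caller's .Random.seed is restored on exit, so no generator
## leaks global state (every stochastic exported function funnels
## its randomness through here).
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

.assertProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop("'", name, "' must be a single number in [0, 1]", call. = FALSE)
  x
}

.assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (positive && x <= 0)
    stop("'", name, "' must be > 0", call. = FALSE)
  if (nonneg && x < 0)
    stop("'", name, "' must be >= 0", call. = FALSE)
  x
}

## largest-remainder rounding of percentages to integers summing to `total`
.largestRemainder <- function(p, total = 100L) {
  if (length(p) == 0L) return(integer(0))
  scaled <- p / sum(p) * total
  fl <- floor(scaled)
  rem <- scaled - fl
  short <- total - sum(fl)
  out <- fl
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    out[idx] <- out[idx] + 1
  }
  stats::setNames(as.integer(out), names(p))
}
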