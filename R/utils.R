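# Internal helpers.

# Evaluate expr with a temporarily seeded RNG, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic child seed below 2^31, derived from a parent seed and a tag.
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.double(seed) * 48271 + h) %% 2147483587) + 1L
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Population standard deviation (denominator n).
popSd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Midrank empirical percentile of value g within pool column x, in [0, 1].
midrankPercentile <- function(g, x) {
  n <- length(x)
  (sum(x < g) + 0.5 * sum(x == g)) / n
}

vnorm <- function(v) sqrt(sum(v * v))

unitVec <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
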