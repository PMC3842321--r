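# Internal helpers shared across modules.

# Run code with a temporarily seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a per-stage seed from a global seed and a stage
# name, kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

# Percent rounding: nearest integer, halves away from zero.
pct_round <- function(p) {
  x <- p * 100
  sign(x) * floor(abs(x) + 0.5)
}

# Trapezoidal integral over (x, y); x may be in descending order.
trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
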