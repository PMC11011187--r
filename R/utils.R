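# Internal helpers shared across modules.

NUTRIENTS <- c("dm", "cp", "ee", "cf", "nfe")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so simulation never perturbs user code.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a single integer seed is required", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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
  expr
}

# Normal draw truncated to [lo, hi] by resampling; fine for the mild
# truncations used here (tails are rare by construction).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(pmax(x, lo), hi)
}

# Multiplicative measurement noise: lognormal with unit mean and the
# requested coefficient of variation.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

stop_fe <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

warn_fe <- function(...) warning(paste0(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
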