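# Internal numeric and RNG helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so library functions never clobber user randomness.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Stable derived stream: mixes a master seed with one or more indices so each
# subject / replicate gets an independent reproducible substream. Kept below
# 2^31 - 1 (R integer range).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in idx) {
    x <- (x * 48271 + as.double(i) * 16807 + 12345) %% 2147483647
  }
  as.integer(x)
}

# Centered moving average with shrinking windows at the edges.
moving_average <- function(x, width = 3L) {
  n <- length(x)
  if (width <= 1L || n < 3L) return(x)
  half <- (width - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    out[i] <- mean(x[lo:hi])
  }
  out
}

# Trapezoidal integral of a uniformly sampled signal, treating the signal as
# rising from / falling to zero over one extra sample at each boundary (a
# rectangular pulse of k samples therefore integrates to k * dt * amplitude).
trapz_padded <- function(x, dt) {
  y <- c(0, x, 0)
  sum((y[-1] + y[-length(y)]) / 2) * dt
}

# Indices of strict-or-plateau local maxima of a vector.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L] && x[i] >= x[i + 1L]) {
      # walk over a plateau; report its first index
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j == n || x[j + 1L] < x[i]) out <- c(out, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
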