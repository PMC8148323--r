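# Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(structure(
    class = c("vapedose_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_config <- function(...) {
  stop(structure(
    class = c("vapedose_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x <= 0)) {
    stop_invalid("`", name, "` must be strictly positive, got ",
                 paste(format(x), collapse = ", "))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x < 0)) {
    stop_invalid("`", name, "` must be non-negative")
  }
  invisible(x)
}

#' Signed trapezoidal integral of a sampled series
#' @noRd
trapz_ <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Tridiagonal LU factorization (Thomas algorithm) precomputed for repeated
# solves with a fixed matrix: a = subdiagonal (n-1), b = diagonal (n),
# c = superdiagonal (n-1).
tridiag_factor <- function(a, b, c) {
  n <- length(b)
  cp <- numeric(n)     # modified superdiagonal
  den <- numeric(n)    # pivot denominators
  den[1] <- b[1]
  if (n > 1L) {
    cp[1] <- c[1] / den[1]
    for (i in 2:n) {
      den[i] <- b[i] - a[i - 1L] * cp[i - 1L]
      if (i < n) cp[i] <- c[i] / den[i]
    }
  }
  list(a = a, cp = cp, den = den, n = n)
}

tridiag_solve <- function(fac, d) {
  n <- fac$n
  dp <- numeric(n)
  dp[1] <- d[1] / fac$den[1]
  if (n > 1L) {
    for (i in 2:n) {
      dp[i] <- (d[i] - fac$a[i - 1L] * dp[i - 1L]) / fac$den[i]
    }
    for (i in (n - 1L):1L) {
      dp[i] <- dp[i] - fac$cp[i] * dp[i + 1L]
    }
  }
  dp
}

# Run code with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
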