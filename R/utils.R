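# internal helpers shared across modules

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Centered moving average; width in samples (coerced odd), edges use the
# available part of the window so the output has the input's length.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width <= 1L) return(x)
  if (width %% 2L == 0L) width <- width + 1L
  half <- (width - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(0L, seq_len(n) - half - 1L)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Magnitude of the analytic signal (FFT construction).
analytic_magnitude <- function(x) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

# Best rational approximation p/q of `x` with q <= max_den (continued
# fractions); used to drive polyphase resampling.
rational_approx <- function(x, max_den = 1000L) {
  stopifnot(x > 0)
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(r - a) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p = p1, q = q1)
}

round_half_up <- function(x) floor(x + 0.5)

stop_cavesong <- function(msg, class) {
  stop(structure(class = c(class, "cavesong_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
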