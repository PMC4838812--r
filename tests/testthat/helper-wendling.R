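# Shared fixtures: the published equilibrium/eigenvalue tables of the
# four-phase scenario (A = 5, G = 20, p = 90), frozen as printed, plus
# independent oracles used across test files.

phase_model <- function(B, ...) wendling_model(A = 5, B = B, G = 20, ...)

# Equilibrium points (y_out, y0..y4; derivative states are all zero).
reference_equilibria <- function() {
  df <- read.table(header = TRUE, text = "
B  stability y_out  y0    y1     y2     y3    y4
45 stable   -0.124 0.008  6.097  5.882 0.339 0.174
45 unstable  2.526 0.031 11.777  8.962 0.290 0.266
45 unstable  5.087 0.094 30.864 25.749 0.028 0.763
38 stable    1.018 0.014  7.037  5.600 0.419 0.166
38 unstable  1.781 0.022  8.553  6.358 0.415 0.188
38 unstable  5.416 0.105 31.220 25.768 0.036 0.764
37 unstable  5.466 0.106 31.254 25.750 0.037 0.763
8  stable   10.004 0.226 31.500 19.258 2.238 0.571
")
  df$stability <- as.character(df$stability)
  df
}

ref_state <- function(row) {
  c(as.numeric(row[c("y0", "y1", "y2", "y3", "y4")]), rep(0, 5))
}

# Published eigenvalue spectra, one complex vector per equilibrium,
# keyed "<B>_<root index>" (roots in increasing y_out order).
reference_spectra <- function() {
  cx <- function(re, im = rep(0, length(re))) complex(real = re, imaginary = im)
  pair <- function(re, im) cx(c(re, re), c(im, -im))
  list(
    "45_1" = c(cx(c(-178.1, -65.9, -50, -50)),
               pair(-24.0, 24.5), pair(-352.4, 24.5), pair(-101.7, 83.1)),
    "45_2" = c(cx(c(-241.4, -60.7, -50, -50, -30.3, 48.7)),
               pair(-99.5, 156.0), pair(-358.7, 42.7)),
    "45_3" = c(cx(c(-181.9, -78.5, -50, -50)),
               pair(-134.4, 98.9), pair(15.9, 78.8), pair(-351.3, 19.0)),
    "38_1" = c(cx(c(-197.9, -63.2, -50, -50)),
               pair(-100.0, 107.1), pair(-14.2, 14.0), pair(-355.2, 35.9)),
    "38_2" = c(cx(c(-216.7, -61.8, -50, -50, -25.0, 17.1)),
               pair(-357.6, 42.5), pair(-99.2, 129.5)),
    "38_3" = c(cx(c(-142.3, -84.0, -50, -50)),
               pair(-155.6, 91.8), pair(-351.5, 21.4), pair(20.3, 89.2)),
    "37_1" = c(cx(c(-137.8, -84.7, -50, -50)),
               pair(-157.9, 91.9), pair(-351.6, 21.9), pair(20.7, 90.2)),
    "8_1"  = c(cx(c(-172.0, -59.3, -50, -50)),
               pair(-352.2, 23.6), pair(-32.6, 9.8), pair(-99.5, 77.1))
  )
}

sort_spectrum <- function(ev) ev[order(Re(ev), Im(ev))]

# componentwise spectrum comparison after canonical ordering; absolute
# tolerance for printed-table checks, relative for numerical identities
expect_spectrum_close <- function(ev, expected, tol, relative = FALSE) {
  stopifnot(length(ev) == length(expected))
  ev <- sort_spectrum(ev); expected <- sort_spectrum(expected)
  scale <- if (relative) pmax(1, Mod(expected)) else 1
  dev <- max(abs(Re(ev) - Re(expected)) / scale,
             abs(Im(ev) - Im(expected)) / scale)
  expect_lt(dev, tol)
}

# Independent transcription of the two equation sets, written term by
# term with its own sigmoid (via plogis); the dual-transcription oracle
# for the drift functions.
oracle_sigmoid <- function(v, m) 2 * m$e0 * stats::plogis(m$r * (v - m$v0))

oracle_drift_full <- function(y, m, p) {
  d <- numeric(10)
  d[1] <- y[6]
  d[2] <- y[7]
  d[3] <- y[8]
  d[4] <- y[9]
  d[5] <- y[10]
  d[6] <- m$A * m$a * oracle_sigmoid(y[2] - y[3] - y[4], m) -
    2 * m$a * y[6] - m$a^2 * y[1]
  d[7] <- m$A * m$a * p + m$A * m$a * m$C2 * oracle_sigmoid(m$C1 * y[1], m) -
    2 * m$a * y[7] - m$a^2 * y[2]
  d[8] <- m$B * m$b * m$C4 * oracle_sigmoid(m$C3 * y[1], m) -
    2 * m$b * y[8] - m$b^2 * y[3]
  d[9] <- m$G * m$g * m$C7 *
    oracle_sigmoid(m$C5 * y[1] - m$C6 * y[5], m) -
    2 * m$g * y[9] - m$g^2 * y[4]
  d[10] <- m$B * m$b * oracle_sigmoid(m$C3 * y[1], m) -
    2 * m$b * y[10] - m$b^2 * y[5]
  d
}

oracle_drift_reduced <- function(z, m, p) {
  d <- numeric(8)
  d[1] <- z[5]
  d[2] <- z[6]
  d[3] <- z[7]
  d[4] <- z[8]
  d[5] <- m$A * m$a * oracle_sigmoid(z[2] - m$C4 * z[3] - z[4], m) -
    2 * m$a * z[5] - m$a^2 * z[1]
  d[6] <- m$A * m$a * p + m$A * m$a * m$C2 * oracle_sigmoid(m$C1 * z[1], m) -
    2 * m$a * z[6] - m$a^2 * z[2]
  d[7] <- m$B * m$b * oracle_sigmoid(m$C3 * z[1], m) -
    2 * m$b * z[7] - m$b^2 * z[3]
  d[8] <- m$G * m$g * m$C7 *
    oracle_sigmoid(m$C5 * z[1] - m$C6 * z[3], m) -
    2 * m$g * z[8] - m$g^2 * z[4]
  d
}

# central finite differences of the drift, oracle for the analytic Jacobian
fd_jacobian <- function(model, state, system, eps = 1e-6) {
  n <- length(state)
  f <- if (system == "full") drift_full else drift_reduced
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- numeric(n); e[j] <- eps
    J[, j] <- (f(state + e, model) - f(state - e, model)) / (2 * eps)
  }
  J
}

# a random full state with the reducibility constraints satisfied
random_consistent_full_state <- function(model) {
  z <- stats::runif(8, -2, 2)
  reduced_to_full(z, model)
}
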