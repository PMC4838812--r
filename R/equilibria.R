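#' Roots of the combined equilibrium (nullcline) equation
#'
#' At an equilibrium every derivative vanishes and each second-order PSP
#' filter sits at its DC gain (`A/a`, `B/b`, `G/g`), so the whole system
#' collapses to one scalar equation in the output:
#' \deqn{y_{out} = (A/a)(p + C_2 S(C_1 y_0)) - (B/b) C_4 S(C_3 y_0)
#'       - (G/g) C_7 S(C_5 y_0 - C_6 y_4)}
#' with \eqn{y_0 = (A/a) S(y_{out})} and
#' \eqn{y_4 = (B/b) S(C_3 y_0)}.  Roots are located by scanning
#' `bracket` on a grid and refining every sign change by bisection
#' ([stats::uniroot()]) until the residual is below 1e-10; roots closer
#' than 1e-4 mV are merged.
#'
#' @param model a [wendling_model()].
#' @param input_mean mean pulse density p used for the deterministic
#'   analysis (s^-1).
#' @param bracket search interval for `y_out` (mV).
#' @param grid scan step (mV).
#' @return sorted numeric vector of `y_out` roots (possibly empty).
#' @examples
#' nullcline_roots(wendling_model(B = 45))   # three equilibria
#' nullcline_roots(wendling_model(B = 8))    # one
#' @export
nullcline_roots <- function(model, input_mean = model$input_mean,
                            bracket = c(-20, 40), grid = 0.01) {
  if (!is.numeric(grid) || grid <= 0) stop("grid must be > 0")
  if (length(bracket) != 2L || !all(is.finite(bracket)) ||
      bracket[1] >= bracket[2])
    stop("bracket must be a finite increasing interval")
  f <- function(y) nullcline_residual(y, model, input_mean)
  xs <- seq(bracket[1], bracket[2], by = grid)
  fs <- f(xs)
  if (any(!is.finite(fs))) stop("nullcline function is not finite on the grid")
  roots <- xs[fs == 0]
  idx <- which(fs[-1] * fs[-length(fs)] < 0)
  for (i in idx) {
    rt <- stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-13)$root
    # Newton-polish so the back-substituted state has drift below 1e-9
    for (k in 1:8) {
      fr <- f(rt)
      if (abs(fr) < 5e-14) break
      df <- (f(rt + 1e-7) - f(rt - 1e-7)) / 2e-7
      step <- fr / df
      if (!is.finite(step) || abs(step) > grid) break
      rt <- rt - step
    }
    roots <- c(roots, rt)
  }
  roots <- sort(roots)
  if (length(roots) > 1L)
    roots <- roots[c(TRUE, diff(roots) > 1e-4)]
  roots
}

# scalar residual F(y_out) = RHS - y_out of the combined equation;
# vectorized over y_out
nullcline_residual <- function(y_out, model, input_mean = model$input_mean) {
  S <- function(v) sigmoid(v, model$v0, model$e0, model$r)
  with(model, {
    y0 <- (A / a) * S(y_out)
    y4 <- (B / b) * S(C3 * y0)
    (A / a) * (input_mean + C2 * S(C1 * y0)) - C4 * y4 -
      (G / g) * C7 * S(C5 * y0 - C6 * y4) - y_out
  })
}

#' Reconstruct the full equilibrium state from an output root
#'
#' Back-substitutes a refined root of the combined nullcline equation
#' into the steady-state relations (DC gains `A/a`, `B/b`, `G/g`) to
#' recover `y0..y4`; the derivative states `y5..y9` are zero at any
#' equilibrium.
#'
#' @param model a [wendling_model()].
#' @param y_out a root from [nullcline_roots()].
#' @param input_mean mean pulse density (s^-1).
#' @return numeric length-10 full state vector.
#' @export
equilibrium_state <- function(model, y_out, input_mean = model$input_mean) {
  S <- function(v) sigmoid(v, model$v0, model$e0, model$r)
  with(model, {
    y0 <- (A / a) * S(y_out)
    y1 <- (A / a) * (input_mean + C2 * S(C1 * y0))
    y4 <- (B / b) * S(C3 * y0)
    y2 <- C4 * y4
    y3 <- (G / g) * C7 * S(C5 * y0 - C6 * y4)
    c(y0, y1, y2, y3, y4, 0, 0, 0, 0, 0)
  })
}

#' Newton refinement of a fixed point
#'
#' Polishes an approximate fixed point (for example one transcribed from
#' a rounded table) by damped Newton iteration on the full drift, using
#' the analytic Jacobian.  Useful to drive the drift norm from the
#' rounding level (~1e-1) to below 1e-9.
#'
#' @param model a [wendling_model()].
#' @param state approximate full state (length 10).
#' @param input_rate input pulse density held at its mean (s^-1).
#' @param tol target max-norm of the drift.
#' @param max_iter iteration cap.
#' @return refined state; error if not converged.
#' @export
refine_equilibrium <- function(model, state, input_rate = model$input_mean,
                               tol = 1e-10, max_iter = 50) {
  s <- state
  for (k in seq_len(max_iter)) {
    fv <- drift_full(s, model, input_rate)
    if (max(abs(fv)) < tol) return(s)
    J <- jacobian_matrix(model, s, system = "full")
    s <- s - solve(J, fv)
  }
  stop("Newton iteration did not converge below tol = ", tol)
}

#' Analytic Jacobian of the drift
#'
#' Linearization of the full (10x10) or reduced (8x8) system at `state`,
#' built from [sigmoid_slope()].  Eigenvalues of this matrix at an
#' equilibrium decide its local stability.
#'
#' @param model a [wendling_model()].
#' @param state full (length 10) or reduced (length 8) state.
#' @param system `"full"` or `"reduced"`; inferred from the state length
#'   when missing.
#' @return square numeric matrix.
#' @export
jacobian_matrix <- function(model, state,
                            system = c("full", "reduced")) {
  if (missing(system))
    system <- if (length(state) == 8L) "reduced" else "full"
  system <- match.arg(system)
  if (any(!is.finite(state))) stop("state must be finite")
  Sp <- function(v) sigmoid_slope(v, model$v0, model$e0, model$r)
  m <- model
  if (system == "full") {
    stopifnot(length(state) == 10L)
    J <- matrix(0, 10, 10)
    for (i in 1:5) J[i, i + 5] <- 1
    sp1 <- Sp(state[2] - state[3] - state[4])
    J[6, 2] <- m$A * m$a * sp1
    J[6, 3] <- -m$A * m$a * sp1
    J[6, 4] <- -m$A * m$a * sp1
    J[6, 1] <- -m$a^2; J[6, 6] <- -2 * m$a
    J[7, 1] <- m$A * m$a * m$C2 * m$C1 * Sp(m$C1 * state[1])
    J[7, 2] <- -m$a^2; J[7, 7] <- -2 * m$a
    J[8, 1] <- m$B * m$b * m$C4 * m$C3 * Sp(m$C3 * state[1])
    J[8, 3] <- -m$b^2; J[8, 8] <- -2 * m$b
    sp4 <- Sp(m$C5 * state[1] - m$C6 * state[5])
    J[9, 1] <- m$G * m$g * m$C7 * m$C5 * sp4
    J[9, 5] <- -m$G * m$g * m$C7 * m$C6 * sp4
    J[9, 4] <- -m$g^2; J[9, 9] <- -2 * m$g
    J[10, 1] <- m$B * m$b * m$C3 * Sp(m$C3 * state[1])
    J[10, 5] <- -m$b^2; J[10, 10] <- -2 * m$b
  } else {
    stopifnot(length(state) == 8L)
    J <- matrix(0, 8, 8)
    for (i in 1:4) J[i, i + 4] <- 1
    sp1 <- Sp(state[2] - m$C4 * state[3] - state[4])
    J[5, 2] <- m$A * m$a * sp1
    J[5, 3] <- -m$A * m$a * m$C4 * sp1
    J[5, 4] <- -m$A * m$a * sp1
    J[5, 1] <- -m$a^2; J[5, 5] <- -2 * m$a
    J[6, 1] <- m$A * m$a * m$C2 * m$C1 * Sp(m$C1 * state[1])
    J[6, 2] <- -m$a^2; J[6, 6] <- -2 * m$a
    J[7, 1] <- m$B * m$b * m$C3 * Sp(m$C3 * state[1])
    J[7, 3] <- -m$b^2; J[7, 7] <- -2 * m$b
    sp4 <- Sp(m$C5 * state[1] - m$C6 * state[3])
    J[8, 1] <- m$G * m$g * m$C7 * m$C5 * sp4
    J[8, 3] <- -m$G * m$g * m$C7 * m$C6 * sp4
    J[8, 4] <- -m$g^2; J[8, 8] <- -2 * m$g
  }
  J
}

#' Classify local stability from an eigenvalue spectrum
#'
#' An equilibrium is `"stable"` when every eigenvalue real part is below
#' `-tol`, `"unstable"` when at least one exceeds `+tol`, and
#' `"marginal"` otherwise.
#'
#' @param eigenvalues complex (or numeric) spectrum.
#' @param tol non-negative margin on the real parts.
#' @return one of `"stable"`, `"unstable"`, `"marginal"`.
#' @export
classify_stability <- function(eigenvalues, tol = 1e-6) {
  if (!length(eigenvalues)) stop("empty spectrum")
  if (tol < 0) stop("tol must be >= 0")
  mr <- max(Re(eigenvalues))
  if (mr < -tol) "stable" else if (mr > tol) "unstable" else "marginal"
}

#' Equilibrium points with stability
#'
#' Finds all equilibria of the model at the mean input, reconstructs the
#' full states, computes Jacobian eigenvalues and classifies stability.
#' The per-phase DC offset of the simulated EEG is the `y_out` of the
#' active stable equilibrium.
#'
#' @inheritParams nullcline_roots
#' @param stability_tol margin for [classify_stability()].
#' @return a `"wendling_equilibria"` object: data frame with columns
#'   `y_out`, `y0..y4`, `max_re`, `stability`, carrying the model and the
#'   eigenvalue spectra (`attr(x, "eigenvalues")`, one complex vector per
#'   row).
#' @examples
#' equilibria(wendling_model(B = 45))
#' @export
equilibria <- function(model, input_mean = model$input_mean,
                       bracket = c(-20, 40), grid = 0.01,
                       stability_tol = 1e-6) {
  roots <- nullcline_roots(model, input_mean, bracket, grid)
  n <- length(roots)
  pts <- data.frame(y_out = roots, y0 = numeric(n), y1 = numeric(n),
                    y2 = numeric(n), y3 = numeric(n), y4 = numeric(n),
                    max_re = numeric(n), stability = character(n),
                    stringsAsFactors = FALSE)
  eigs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- equilibrium_state(model, roots[i], input_mean)
    ev <- eigen(jacobian_matrix(model, s, "full"), only.values = TRUE)$values
    pts[i, c("y0", "y1", "y2", "y3", "y4")] <- s[1:5]
    pts$max_re[i] <- max(Re(ev))
    pts$stability[i] <- classify_stability(ev, stability_tol)
    eigs[[i]] <- ev
  }
  structure(pts, class = c("wendling_equilibria", "data.frame"),
            eigenvalues = eigs, model = model, input_mean = input_mean)
}

#' @export
print.wendling_equilibria <- function(x, digits = 4, ...) {
  m <- attr(x, "model")
  cat(sprintf("Equilibria at A = %g, B = %g, G = %g, p = %g: %d point(s)\n",
              m$A, m$B, m$G, attr(x, "input_mean"), nrow(x)))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
summary.wendling_equilibria <- function(object, ...) {
  ev <- attr(object, "eigenvalues")
  for (i in seq_len(nrow(object))) {
    cat(sprintf("y_out = %.3f (%s), eigenvalues:\n",
                object$y_out[i], object$stability[i]))
    print(round(sort(ev[[i]], decreasing = TRUE), 1))
  }
  invisible(object)
}
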