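#' Deterministic drift of the full 10-equation system
#'
#' Evaluates the right-hand side of the full model with the stochastic
#' input treated as the fixed number `input_rate` for one evaluation.
#' State components 1..5 are the PSP outputs `y0..y4` (mV), components
#' 6..10 their time derivatives `y5..y9`.
#'
#' @param state numeric vector of length 10.
#' @param model a [wendling_model()] object.
#' @param input_rate exogenous pulse density for this evaluation (s^-1);
#'   defaults to the model's mean input.
#' @return numeric vector of length 10, the time derivative of `state`.
#' @seealso [drift_reduced()], [jacobian_matrix()]
#' @export
drift_full <- function(state, model, input_rate = model$input_mean) {
  stopifnot(is.numeric(state), length(state) == 10L, is.finite(input_rate))
  S <- function(v) sigmoid(v, model$v0, model$e0, model$r)
  y <- state
  with(model, c(
    y[6], y[7], y[8], y[9], y[10],
    A * a * S(y[2] - y[3] - y[4]) - 2 * a * y[6] - a^2 * y[1],
    A * a * (input_rate + C2 * S(C1 * y[1])) - 2 * a * y[7] - a^2 * y[2],
    B * b * C4 * S(C3 * y[1]) - 2 * b * y[8] - b^2 * y[3],
    G * g * C7 * S(C5 * y[1] - C6 * y[5]) - 2 * g * y[9] - g^2 * y[4],
    B * b * S(C3 * y[1]) - 2 * b * y[10] - b^2 * y[5]
  ))
}

#' Deterministic drift of the reduced 8-equation system
#'
#' The reduced formulation merges the two output paths of the slow
#' inhibitory interneurons into a single PSP filter: the former `y4` is
#' renamed `y2` (scaled into the pyramidal input by `C4`) and the former
#' `y9` becomes `y6`.  State components 1..4 are `y0..y3`, components
#' 5..8 their derivatives.  The fast-inhibition drive couples to the
#' renamed slow-inhibition PSP (`C6 * y2`), which is what makes the
#' reduced system trajectory-equivalent to the full one.
#'
#' @param state numeric vector of length 8.
#' @inheritParams drift_full
#' @return numeric vector of length 8.
#' @export
drift_reduced <- function(state, model, input_rate = model$input_mean) {
  stopifnot(is.numeric(state), length(state) == 8L, is.finite(input_rate))
  S <- function(v) sigmoid(v, model$v0, model$e0, model$r)
  z <- state
  with(model, c(
    z[5], z[6], z[7], z[8],
    A * a * S(z[2] - C4 * z[3] - z[4]) - 2 * a * z[5] - a^2 * z[1],
    A * a * (input_rate + C2 * S(C1 * z[1])) - 2 * a * z[6] - a^2 * z[2],
    B * b * S(C3 * z[1]) - 2 * b * z[7] - b^2 * z[3],
    G * g * C7 * S(C5 * z[1] - C6 * z[3]) - 2 * g * z[8] - g^2 * z[4]
  ))
}

#' Model output (simulated EEG) from a state vector
#'
#' The model output is the net membrane potential of the pyramidal
#' population: `y1 - y2 - y3` for the full system, and
#' `y1 - C4 * y2 - y3` for the reduced system (where the renamed `y2`
#' carries the unscaled slow-inhibition PSP).
#'
#' @param state full (length 10) or reduced (length 8) state vector.
#' @param C4 synaptic contact number scaling the slow IPSP in the reduced
#'   output.
#' @return `y_out` in mV.
#' @export
output_full <- function(state) {
  stopifnot(length(state) == 10L)
  state[2] - state[3] - state[4]
}

#' @rdname output_full
#' @export
output_reduced <- function(state, C4 = 0.25 * 135) {
  stopifnot(length(state) == 8L)
  state[2] - C4 * state[3] - state[4]
}

#' Map between full and reduced state vectors
#'
#' `full_to_reduced()` renames the slow-inhibition PSP states
#' (`y4 -> y2`, `y9 -> y6`) and drops the redundant pair `(y2, y7)`,
#' which on any trajectory started from consistent initial conditions
#' satisfies `y2 = C4 * y4` and `y7 = C4 * y9`.  States violating that
#' proportionality beyond `tol` are rejected: they are unreachable from
#' zero initial conditions and have no reduced counterpart.
#' `reduced_to_full()` reconstructs the dropped pair exactly.
#'
#' @param state full (length 10) or reduced (length 8) state vector.
#' @param model a [wendling_model()] (only `C4` is used).
#' @param tol absolute tolerance for the consistency check (mV).
#' @return the mapped state vector.
#' @examples
#' m <- wendling_model()
#' z <- full_to_reduced(rep(0, 10), m)
#' reduced_to_full(z, m)
#' @export
full_to_reduced <- function(state, model, tol = 1e-6) {
  stopifnot(length(state) == 10L)
  C4 <- model$C4
  dev <- max(abs(state[3] - C4 * state[5]), abs(state[8] - C4 * state[10]))
  if (dev > tol)
    stop("state is not reducible: |y2 - C4*y4| or |y7 - C4*y9| = ",
         signif(dev, 3), " exceeds tol = ", tol)
  c(state[1], state[2], state[5], state[4],
    state[6], state[7], state[10], state[9])
}

#' @rdname full_to_reduced
#' @export
reduced_to_full <- function(state, model) {
  stopifnot(length(state) == 8L)
  C4 <- model$C4
  c(state[1], state[2], C4 * state[3], state[4], state[3],
    state[5], state[6], C4 * state[7], state[8], state[7])
}
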