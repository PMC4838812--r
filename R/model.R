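#' Construct a Wendling-type neural mass model
#'
#' Creates the parameter object for the extended (four-subgroup) Wendling
#' neural mass model of hippocampal depth-EEG.  The model lumps a cortical
#' volume into pyramidal cells, excitatory interneurons, slow (dendritic,
#' GABA-A,slow) inhibitory interneurons and fast (somatic, GABA-A,fast)
#' inhibitory interneurons.  Each synaptic pathway is a second-order linear
#' pulse-to-voltage filter; populations communicate through the static
#' wave-to-pulse sigmoid [sigmoid()].  The EEG-like output is the summed
#' membrane potential of the pyramidal population, `y1 - y2 - y3`.
#'
#' The defaults are the standard parameter set of the model family.  `A`,
#' `B` and `G` are the excitatory, slow inhibitory and fast inhibitory
#' synaptic gains (mV); varying `B` and `G` moves the model through
#' background, sporadic spiking, sustained spiking, gamma and ictal
#' regimes.  `a`, `b`, `g` are the corresponding lumped rate constants
#' (s^-1), `C1..C7` mean synaptic contact counts, and the exogenous pulse
#' density input is normal with mean `input_mean` (s^-1) and variance
#' `input_variance`.
#'
#' The model family's customary "N(90, 30)" input specification refers
#' to a noise amplitude (standard deviation) of 30 pulses/s — the factor
#' multiplying the unit-variance draw in the stochastic update — so
#' `input_variance` defaults to `900`.  Reading the 30 as a variance
#' (SD ~5.5) shrinks the documented output variances of every
#' integration scheme by a factor of ~30.
#'
#' @param A excitatory synaptic gain (mV).
#' @param B slow inhibitory synaptic gain (mV).
#' @param G fast inhibitory synaptic gain (mV).
#' @param a,b,g lumped dendritic/somatic rate constants (s^-1).
#' @param C1,C2,C3,C4,C5,C6,C7 mean synaptic contact numbers
#'   (dimensionless); defaults are the usual multiples of `C1 = 135`.
#' @param v0 sigmoid half-activation voltage (mV).
#' @param e0 half of the maximal population firing rate (s^-1).
#' @param r sigmoid steepness (mV^-1).
#' @param input_mean mean exogenous pulse density (s^-1).
#' @param input_variance variance of the exogenous pulse density.
#'
#' @return An object of class `"wendling_model"`: a named list of validated
#'   parameters.
#'
#' @seealso [simulate.wendling_model()], [equilibria()], [bifurcation_scan()]
#' @examples
#' m <- wendling_model(A = 5, B = 45, G = 20)
#' m
#' coef(m)
#' @export
wendling_model <- function(A = 5, B = 45, G = 20,
                           a = 100, b = 50, g = 350,
                           C1 = 135, C2 = 0.8 * C1,
                           C3 = 0.25 * C1, C4 = 0.25 * C1,
                           C5 = 0.3 * C1, C6 = 0.1 * C1, C7 = 0.8 * C1,
                           v0 = 6, e0 = 2.5, r = 0.56,
                           input_mean = 90, input_variance = 900) {
  m <- list(A = A, B = B, G = G, a = a, b = b, g = g,
            C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5, C6 = C6, C7 = C7,
            v0 = v0, e0 = e0, r = r,
            input_mean = input_mean, input_variance = input_variance)
  for (nm in names(m)) {
    x <- m[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("parameter '", nm, "' must be a single finite number")
  }
  if (any(c(a, b, g) <= 0)) stop("rate constants a, b, g must be positive")
  if (any(unlist(m[c("C1", "C2", "C3", "C4", "C5", "C6", "C7")]) <= 0))
    stop("connectivity constants C1..C7 must be positive")
  if (e0 <= 0 || r <= 0) stop("sigmoid parameters e0 and r must be positive")
  if (A < 0 || B < 0 || G < 0) stop("synaptic gains A, B, G must be non-negative")
  if (input_variance < 0) stop("input_variance must be non-negative")
  structure(m, class = "wendling_model")
}

#' @export
print.wendling_model <- function(x, ...) {
  cat("Extended Wendling neural mass model\n")
  cat(sprintf("  gains (mV):    A = %g, B = %g, G = %g\n", x$A, x$B, x$G))
  cat(sprintf("  rates (1/s):   a = %g, b = %g, g = %g\n", x$a, x$b, x$g))
  cat(sprintf("  connectivity:  C1..C7 = %s\n",
              paste(signif(unlist(x[c("C1", "C2", "C3", "C4", "C5", "C6", "C7")]), 5),
                    collapse = ", ")))
  cat(sprintf("  sigmoid:       v0 = %g mV, e0 = %g 1/s, r = %g 1/mV\n",
              x$v0, x$e0, x$r))
  cat(sprintf("  input p(t):    mean %g 1/s, variance %g\n",
              x$input_mean, x$input_variance))
  invisible(x)
}

#' @export
coef.wendling_model <- function(object, ...) {
  unlist(object)
}

#' Modify parameters of an existing model
#'
#' @param object a [wendling_model()] object.
#' @param ... parameters to replace, e.g. `B = 38`.
#' @return a new `"wendling_model"` object.
#' @examples
#' m <- wendling_model()
#' update(m, B = 8)
#' @export
update.wendling_model <- function(object, ...) {
  repl <- list(...)
  unknown <- setdiff(names(repl), names(object))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  do.call(wendling_model, modifyList(unclass(object), repl))
}

#' Wave-to-pulse sigmoid
#'
#' Converts a summed membrane potential into a population firing rate:
#' `S(v) = 2 e0 / (1 + exp(r (v0 - v)))`.  Bounded in (0, 2 e0), strictly
#' increasing, with `S(v0) = e0`.  Evaluation is overflow-safe for any
#' finite `v` (saturating to 0 or `2 e0`).
#'
#' @param v membrane potential (mV); vectorized.
#' @param v0 half-activation voltage (mV).
#' @param e0 half of the maximal firing rate (s^-1).
#' @param r steepness (mV^-1).
#' @return firing rate(s), s^-1.
#' @examples
#' sigmoid(6)          # e0 at the half-activation point
#' sigmoid(c(-1e6, 1e6))
#' @export
sigmoid <- function(v, v0 = 6, e0 = 2.5, r = 0.56) {
  2 * e0 / (1 + exp(r * (v0 - v)))
}

#' Derivative of the wave-to-pulse sigmoid
#'
#' Analytic slope `dS/dv`, needed for the system Jacobian.  Computed in a
#' form symmetric about `v0` that cannot overflow:
#' `S'(v) = 2 e0 r / (exp(t/2) + exp(-t/2))^2` with `t = r (v0 - v)`.
#'
#' @inheritParams sigmoid
#' @return slope(s), s^-1 mV^-1; positive everywhere, maximal `e0 r / 2`
#'   at `v = v0`.
#' @examples
#' sigmoid_slope(6)    # e0 * r / 2
#' @export
sigmoid_slope <- function(v, v0 = 6, e0 = 2.5, r = 0.56) {
  t <- r * (v0 - v) / 2
  2 * e0 * r / (exp(t) + exp(-t))^2
}
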