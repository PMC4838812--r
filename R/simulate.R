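#' Simulate the model with a fixed-step scheme
#'
#' Integrates the full (10-equation) or reduced (8-equation) system from
#' `init` for `duration` seconds at step `h`, returning the EEG-like
#' output `y_out`.  Three schemes are available:
#'
#' * `"euler_classical"` / `"rk4_classical"`: the legacy approach.  One
#'   input draw `p ~ N(mean, variance)` is made per step and treated as a
#'   constant forcing over that step (held across all four RK4 stages),
#'   so the noise contribution is scaled by `h`.  This deliberately
#'   reproduces the documented artifact that output variance shrinks
#'   proportionally with the step size.
#' * `"euler_sde"`: the corrected stochastic forward Euler.  The drift
#'   uses the mean input, and the update adds the Wiener-consistent
#'   increment `A * a * sqrt(variance * reference_h * h) * r_n` to the
#'   derivative state driven by the input (`y6` in the full system, `y5`
#'   in the reduced one).  At `h = reference_h` this is algebraically
#'   identical to `"euler_classical"` with the same noise stream.
#'
#' Reproducibility contract: identical parameters, scheme, step, duration
#' and `seed` give a bit-identical result.
#'
#' @param object a [wendling_model()].
#' @param nsim number of independent replicates; if > 1 a list of
#'   simulations is returned.
#' @param seed integer seed, or `NULL` to continue the current RNG
#'   stream.  When a seed is given the caller's RNG state is restored
#'   afterwards, as [stats::simulate()] methods do.
#' @param scheme integration scheme, see Details.
#' @param h step size (s).
#' @param duration total simulated time (s).
#' @param system `"full"` or `"reduced"`.
#' @param init initial state (length 10 or 8); defaults to all zeros.
#' @param record_states if `TRUE`, keep the whole state trajectory in the
#'   `"states"` attribute.
#' @param reference_h reference step (s) of the corrected scheme; 0.001
#'   by convention.
#' @param ... unused.
#'
#' @return A `"wendling_sim"` object: a data frame with columns `time`
#'   and `y_out` and metadata attributes (`scheme`, `h`, `seed`,
#'   `system`, `model`, `final_state`).
#'
#' @examples
#' m <- wendling_model(B = 40)
#' s <- simulate(m, seed = 1, scheme = "euler_sde", h = 1e-3, duration = 2)
#' output_variance(s, discard = 1)
#' @export
simulate.wendling_model <- function(object, nsim = 1, seed = NULL,
                                    scheme = c("euler_sde", "euler_classical",
                                               "rk4_classical"),
                                    h = 1e-3, duration = 10,
                                    system = c("full", "reduced"),
                                    init = NULL, record_states = FALSE,
                                    reference_h = 1e-3, ...) {
  scheme <- match.arg(scheme)
  system <- match.arg(system)
  if (!is.numeric(h) || length(h) != 1L || h <= 0) stop("h must be > 0")
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("duration must be > 0")
  if (reference_h <= 0) stop("reference_h must be > 0")
  nsteps <- as.integer(round(duration / h))
  if (nsteps < 1L) stop("duration must cover at least one step")

  dim <- if (system == "reduced") 8L else 10L
  if (is.null(init)) init <- rep(0, dim)
  if (length(init) != dim)
    stop("init must have length ", dim, " for the ", system, " system")

  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }

  one <- function() {
    noise <- if (object$input_variance > 0 || scheme == "euler_sde")
      rnorm(nsteps) else numeric(nsteps)
    res <- integrate_nmm_cpp(
      init, unclass(object)[c("A", "B", "G", "a", "b", "g",
                              "C1", "C2", "C3", "C4", "C5", "C6", "C7",
                              "v0", "e0", "r")],
      h, nsteps,
      scheme = match(scheme, c("euler_classical", "rk4_classical",
                               "euler_sde")) - 1L,
      noise = noise, reduced = (system == "reduced"),
      record_states = record_states, reference_h = reference_h,
      input_mean = object$input_mean,
      input_sd = sqrt(object$input_variance))
    out <- data.frame(time = seq(0L, nsteps) * h, y_out = res$y_out)
    structure(out,
              class = c("wendling_sim", "data.frame"),
              scheme = scheme, h = h, seed = seed, duration = duration,
              system = system, reference_h = reference_h, model = object,
              final_state = res$final_state,
              states = if (record_states) res$states)
  }

  if (nsim == 1L) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
print.wendling_sim <- function(x, ...) {
  cat(sprintf("wendling_sim: %d samples, scheme %s, h = %g s, %s system\n",
              nrow(x), attr(x, "scheme"), attr(x, "h"), attr(x, "system")))
  cat(sprintf("  y_out: mean %.4f mV, variance %.4g mV^2\n",
              mean(x$y_out), output_variance(x)))
  ph <- attr(x, "phases")
  if (!is.null(ph))
    cat("  phases:", paste(ph$label, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
plot.wendling_sim <- function(x, xlab = "time (s)", ylab = "y_out (mV)",
                              type = "l", ...) {
  plot(x$time, x$y_out, type = type, xlab = xlab, ylab = ylab, ...)
  ph <- attr(x, "phases")
  if (!is.null(ph)) abline(v = ph$start[-1], lty = 3)
  invisible(x)
}

#' Simulate a multi-phase scenario
#'
#' Runs the model through an ordered schedule of parameter regimes
#' (phases), carrying the state continuously across phase boundaries.
#' Each phase sets the inhibitory gains `B` and `G` while all other
#' parameters are shared; this is the classical
#' background / sporadic spiking / sustained spiking / gamma / ictal
#' progression of the model family.
#'
#' @param model a [wendling_model()]; per-phase `B`, `G` override it.
#' @param schedule data frame with columns `label`, `duration` (s), `B`,
#'   `G` — see [read_phase_schedule()] and [default_phase_schedule()].
#' @param seed integer seed for the whole sequence (one RNG stream across
#'   phases), or `NULL`.
#' @param init initial state; defaults to zeros.
#' @inheritParams simulate.wendling_model
#' @return a `"wendling_sim"` object whose `"phases"` attribute holds the
#'   per-phase start/end times; see [phase_summary()].
#' @examples
#' m <- wendling_model()
#' sched <- default_phase_schedule(duration = 2)
#' sim <- run_phase_sequence(m, sched, seed = 1)
#' phase_summary(sim, discard = 1)
#' @export
run_phase_sequence <- function(model, schedule, seed = NULL,
                               scheme = c("euler_sde", "euler_classical",
                                          "rk4_classical"),
                               h = 1e-3, system = c("full", "reduced"),
                               init = NULL, reference_h = 1e-3) {
  scheme <- match.arg(scheme)
  system <- match.arg(system)
  schedule <- as.data.frame(schedule)
  need <- c("label", "duration", "B", "G")
  if (!nrow(schedule)) stop("phase schedule is empty")
  if (!all(need %in% names(schedule)))
    stop("schedule must have columns: ", paste(need, collapse = ", "))
  if (any(schedule$duration <= 0)) stop("phase durations must be positive")

  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
  }

  state <- init
  t0 <- 0
  times <- list(); youts <- list()
  starts <- ends <- numeric(nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    mi <- update(model, B = schedule$B[i], G = schedule$G[i])
    si <- simulate(mi, seed = NULL, scheme = scheme, h = h,
                   duration = schedule$duration[i], system = system,
                   init = state, reference_h = reference_h)
    state <- attr(si, "final_state")
    keep <- if (i == 1L) seq_len(nrow(si)) else seq_len(nrow(si))[-1L]
    times[[i]] <- si$time[keep] + t0
    youts[[i]] <- si$y_out[keep]
    starts[i] <- t0
    t0 <- t0 + schedule$duration[i]
    ends[i] <- t0
  }
  out <- data.frame(time = unlist(times), y_out = unlist(youts))
  structure(out,
            class = c("wendling_sim", "data.frame"),
            scheme = scheme, h = h, seed = seed, system = system,
            duration = sum(schedule$duration), reference_h = reference_h,
            model = model, final_state = state,
            phases = data.frame(label = schedule$label, B = schedule$B,
                                G = schedule$G, start = starts, end = ends))
}

#' Per-phase output summary
#'
#' Mean and variance of `y_out` within each phase of a
#' [run_phase_sequence()] simulation, after discarding an initial
#' settling window in each phase.  The per-phase means are the DC offsets
#' selected by the active stable equilibrium (or limit cycle).
#'
#' @param sim a `"wendling_sim"` with a `"phases"` attribute.
#' @param discard seconds dropped at the start of each phase.
#' @return data frame: `label`, `B`, `G`, `mean`, `variance`.
#' @export
phase_summary <- function(sim, discard = 1) {
  ph <- attr(sim, "phases")
  if (is.null(ph)) stop("sim has no phase information")
  res <- ph[c("label", "B", "G")]
  res$mean <- res$variance <- NA_real_
  for (i in seq_len(nrow(ph))) {
    sel <- sim$time >= ph$start[i] + discard & sim$time <= ph$end[i]
    if (!any(sel)) stop("discard leaves no samples in phase ", ph$label[i])
    x <- sim$y_out[sel]
    res$mean[i] <- mean(x)
    res$variance[i] <- mean((x - mean(x))^2)
  }
  res[c("label", "B", "G", "mean", "variance")]
}

#' Output variance of a simulation
#'
#' Population variance (divide by N) of `y_out` after discarding the
#' leading transient.  The population convention is immaterial at the
#' sample sizes involved but is fixed for bit-reproducibility.
#'
#' @param ts a `"wendling_sim"` or a numeric vector.
#' @param discard leading time (s) to drop (for numeric input, a number
#'   of leading samples).
#' @return variance (mV^2).
#' @export
output_variance <- function(ts, discard = 0) {
  if (inherits(ts, "wendling_sim")) {
    if (discard >= max(ts$time)) stop("discard leaves an empty window")
    x <- ts$y_out[ts$time >= discard]
  } else {
    x <- as.numeric(ts)
    if (discard >= length(x)) stop("discard leaves an empty window")
    if (discard > 0) x <- x[-seq_len(discard)]
  }
  if (!length(x)) stop("empty window")
  mean((x - mean(x))^2)
}

#' Remove the DC offset from a simulated EEG
#'
#' The model output carries a regime-dependent DC offset set by the
#' active equilibrium; EEG hardware removes it by high-pass filtering,
#' analyses often by mean subtraction.  `method = "mean_subtract"`
#' subtracts the sample mean; `method = "highpass"` applies a causal
#' first-order recursive (RC) high-pass with cutoff `fc` (Hz):
#' `y[n] = alpha * (y[n-1] + x[n] - x[n-1])`, `alpha = 1/(1 + 2*pi*fc*h)`.
#'
#' @param ts a `"wendling_sim"` or numeric vector.
#' @param method `"mean_subtract"` or `"highpass"`.
#' @param fc high-pass cutoff (Hz); required for `"highpass"`, must lie
#'   in (0, Nyquist).
#' @param h sample interval (s); taken from `ts` when it is a simulation.
#' @return object of the same type with the offset removed.
#' @export
remove_dc <- function(ts, method = c("mean_subtract", "highpass"),
                      fc = NULL, h = NULL) {
  method <- match.arg(method)
  is_sim <- inherits(ts, "wendling_sim")
  x <- if (is_sim) ts$y_out else as.numeric(ts)
  if (method == "mean_subtract") {
    y <- x - mean(x)
  } else {
    if (is.null(h)) h <- attr(ts, "h")
    if (is.null(h)) stop("h is required for the high-pass filter")
    if (is.null(fc) || !is.numeric(fc) || fc <= 0 || fc >= 1 / (2 * h))
      stop("fc must lie in (0, Nyquist = ", 1 / (2 * h), " Hz)")
    alpha <- 1 / (1 + 2 * pi * fc * h)
    u <- alpha * c(0, diff(x))
    y <- as.numeric(stats::filter(u, alpha, method = "recursive"))
  }
  if (is_sim) { ts$y_out <- y; ts } else y
}
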