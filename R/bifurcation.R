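#' Scan the equilibrium branches over the slow inhibitory gain
#'
#' Computes all nullcline roots and their stability for each value of `B`
#' in `B_values`, then localizes the bifurcations it brackets: a
#' saddle-node where the root count changes between neighbouring grid
#' values (via [find_saddle_node()]) and a stability transition where a
#' unique equilibrium changes stability (via
#' [find_stability_transition()]).
#'
#' @param model a [wendling_model()]; `B` is overridden by the sweep.
#' @param B_values numeric vector of slow inhibitory gains (mV).
#' @param input_mean mean pulse density (s^-1).
#' @param resolution bracket width (mV) to which detected events are
#'   refined.
#' @inheritParams nullcline_roots
#' @return a `"wendling_bifscan"` object: data frame of
#'   `(B, y_out, max_re, stability)` branches with an `"events"`
#'   attribute, a data frame of `(type, value, lo, hi)`.
#' @examples
#' sc <- bifurcation_scan(wendling_model(), B_values = seq(36, 39, by = 1))
#' attr(sc, "events")
#' @export
bifurcation_scan <- function(model, B_values, input_mean = model$input_mean,
                             bracket = c(-20, 40), grid = 0.01,
                             resolution = 0.01) {
  if (!length(B_values)) stop("B_values must be non-empty")
  B_values <- sort(B_values)
  branches <- vector("list", length(B_values))
  counts <- integer(length(B_values))
  stab_unique <- rep(NA_character_, length(B_values))
  for (i in seq_along(B_values)) {
    eq <- equilibria(update(model, B = B_values[i]), input_mean,
                     bracket, grid)
    counts[i] <- nrow(eq)
    if (nrow(eq) == 1L) stab_unique[i] <- eq$stability
    branches[[i]] <- if (nrow(eq))
      data.frame(B = B_values[i], y_out = eq$y_out, max_re = eq$max_re,
                 stability = eq$stability, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, branches)

  events <- data.frame(type = character(), value = numeric(),
                       lo = numeric(), hi = numeric(),
                       stringsAsFactors = FALSE)
  for (i in seq_along(B_values)[-1]) {
    if (counts[i] != counts[i - 1]) {
      sn <- find_saddle_node(model, B_values[i - 1], B_values[i],
                             resolution = min(resolution,
                                              diff(B_values[c(i - 1, i)])),
                             input_mean = input_mean,
                             bracket = bracket, grid = grid)
      events <- rbind(events,
                      data.frame(type = "saddle_node", value = sn$value,
                                 lo = sn$bracket[1], hi = sn$bracket[2]))
    } else if (counts[i] == 1L && !is.na(stab_unique[i]) &&
               !is.na(stab_unique[i - 1]) &&
               stab_unique[i] != stab_unique[i - 1]) {
      st <- find_stability_transition(model, B_values[i - 1], B_values[i],
                                      resolution = min(resolution,
                                                       diff(B_values[c(i - 1, i)])),
                                      input_mean = input_mean,
                                      bracket = bracket, grid = grid)
      events <- rbind(events,
                      data.frame(type = "stability_transition",
                                 value = st$value,
                                 lo = st$bracket[1], hi = st$bracket[2]))
    }
  }
  structure(out, class = c("wendling_bifscan", "data.frame"),
            events = events, model = model, B_values = B_values)
}

#' @export
print.wendling_bifscan <- function(x, ...) {
  cat(sprintf("Bifurcation scan over B: %d grid values, %d branch points\n",
              length(attr(x, "B_values")), nrow(x)))
  ev <- attr(x, "events")
  if (nrow(ev)) {
    cat("Detected events:\n")
    print.data.frame(ev, row.names = FALSE, digits = 6)
  } else cat("No events detected on this grid.\n")
  invisible(x)
}

#' @export
plot.wendling_bifscan <- function(x, xlab = "B (mV)", ylab = "y_out (mV)",
                                  ...) {
  stable <- x$stability == "stable"
  plot(x$B, x$y_out, type = "n", xlab = xlab, ylab = ylab, ...)
  points(x$B[stable], x$y_out[stable], pch = 16)
  points(x$B[!stable], x$y_out[!stable], pch = 1)
  ev <- attr(x, "events")
  if (nrow(ev)) abline(v = ev$value, lty = 3)
  legend("topleft", pch = c(16, 1), legend = c("stable", "unstable"),
         bty = "n")
  invisible(x)
}

#' Localize a saddle-node bifurcation in B
#'
#' Bisects on the nullcline root count between `B_lo` and `B_hi` (which
#' must differ) until the bracket is narrower than `resolution`; the
#' returned value is the final bracket midpoint.  For the default model
#' this is where a stable background equilibrium collides with an
#' unstable one and sustained spiking (a stable limit cycle) emerges.
#'
#' @param model a [wendling_model()].
#' @param B_lo,B_hi bracketing gains (mV).
#' @param resolution final bracket width (mV); must be smaller than the
#'   initial interval.
#' @inheritParams nullcline_roots
#' @return list with elements `value` (midpoint), `bracket`, `found`.
#'   When the root count does not change, `found = FALSE` and `value` is
#'   `NA` (with a message).
#' @examples
#' find_saddle_node(wendling_model(), 30, 45)$value   # ~37.3
#' @export
find_saddle_node <- function(model, B_lo, B_hi, resolution = 0.01,
                             input_mean = model$input_mean,
                             bracket = c(-20, 40), grid = 0.01) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be > 0")
  if (B_hi <= B_lo) stop("B_hi must exceed B_lo")
  if (resolution > B_hi - B_lo)
    stop("resolution is larger than the search interval")
  count <- function(B)
    length(nullcline_roots(update(model, B = B), input_mean, bracket, grid))
  c_lo <- count(B_lo); c_hi <- count(B_hi)
  if (c_lo == c_hi) {
    message("no root-count change in [", B_lo, ", ", B_hi, "]: none found")
    return(list(value = NA_real_, bracket = c(NA_real_, NA_real_),
                found = FALSE))
  }
  while (B_hi - B_lo > resolution) {
    mid <- (B_lo + B_hi) / 2
    if (count(mid) == c_lo) B_lo <- mid else B_hi <- mid
  }
  list(value = (B_lo + B_hi) / 2, bracket = c(B_lo, B_hi), found = TRUE)
}

#' Localize the stability transition of a unique equilibrium in B
#'
#' Bisects on the sign of the maximum eigenvalue real part of the unique
#' equilibrium between `B_lo` (stable) and `B_hi` (unstable) until the
#' bracket is narrower than `resolution`.  For the default model this is
#' where the lone equilibrium regains stability as slow inhibition is
#' reduced and the sustained-spiking limit cycle disappears.
#'
#' @inheritParams find_saddle_node
#' @return list with `value` (bracket midpoint), `bracket`, `found`.
#' @examples
#' \donttest{find_stability_transition(wendling_model(), 5, 20)}
#' @export
find_stability_transition <- function(model, B_lo, B_hi, resolution = 0.005,
                                      input_mean = model$input_mean,
                                      bracket = c(-20, 40), grid = 0.01) {
  if (!is.numeric(resolution) || resolution <= 0)
    stop("resolution must be > 0")
  if (B_hi <= B_lo) stop("B_hi must exceed B_lo (degenerate interval)")
  if (resolution > B_hi - B_lo)
    stop("resolution is larger than the search interval")
  max_re <- function(B) {
    mod <- update(model, B = B)
    r <- nullcline_roots(mod, input_mean, bracket, grid)
    if (length(r) != 1L)
      stop("equilibrium is not unique at B = ", B,
           " (", length(r), " roots)")
    s <- equilibrium_state(mod, r, input_mean)
    max(Re(eigen(jacobian_matrix(mod, s, "full"), only.values = TRUE)$values))
  }
  r_lo <- max_re(B_lo); r_hi <- max_re(B_hi)
  if (sign(r_lo) == sign(r_hi)) {
    message("max eigenvalue real part does not change sign in [",
            B_lo, ", ", B_hi, "]: none found")
    return(list(value = NA_real_, bracket = c(NA_real_, NA_real_),
                found = FALSE))
  }
  while (B_hi - B_lo > resolution) {
    mid <- (B_lo + B_hi) / 2
    if (sign(max_re(mid)) == sign(r_lo)) B_lo <- mid else B_hi <- mid
  }
  list(value = (B_lo + B_hi) / 2, bracket = c(B_lo, B_hi), found = TRUE)
}
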