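#' Write a simulation to CSV with a JSON metadata sidecar
#'
#' The CSV has header `time,y_out` (plus `y0..y9` / `y0..y7` when the
#' state trajectory was recorded), comma-separated, `.` decimal, LF line
#' endings, UTF-8, floats printed with 17 significant digits so the file
#' round-trips bit-exactly.  A JSON sidecar (`<path>.json` by default)
#' records scheme, step, seed, duration, system and the full parameter
#' set.
#'
#' @param sim a `"wendling_sim"`.
#' @param path output CSV path.
#' @param metadata_path sidecar path, or `NULL` to skip it.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(sim, path,
                                 metadata_path = paste0(path, ".json")) {
  stopifnot(inherits(sim, "wendling_sim"))
  df <- data.frame(time = sim$time, y_out = sim$y_out)
  st <- attr(sim, "states")
  if (!is.null(st)) {
    colnames(st) <- paste0("y", seq_len(ncol(st)) - 1L)
    df <- cbind(df, as.data.frame(st))
  }
  con <- file(path, open = "wb")  # binary mode forces LF on every platform
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con, sep = "\n")
  rows <- do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                           sep = ","))
  writeLines(rows, con, sep = "\n")
  if (!is.null(metadata_path)) {
    meta <- list(scheme = attr(sim, "scheme"), h = attr(sim, "h"),
                 seed = attr(sim, "seed"), duration = attr(sim, "duration"),
                 system = attr(sim, "system"),
                 reference_h = attr(sim, "reference_h"),
                 parameters = unclass(attr(sim, "model")))
    ph <- attr(sim, "phases")
    if (!is.null(ph)) meta$phases <- ph
    jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write an equilibrium report as JSON
#'
#' @param eq a `"wendling_equilibria"` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_equilibria_json <- function(eq, path) {
  stopifnot(inherits(eq, "wendling_equilibria"))
  ev <- attr(eq, "eigenvalues")
  pts <- lapply(seq_len(nrow(eq)), function(i) list(
    y_out = eq$y_out[i],
    state = as.numeric(eq[i, c("y0", "y1", "y2", "y3", "y4")]),
    eigenvalues = data.frame(re = Re(ev[[i]]), im = Im(ev[[i]])),
    max_re = eq$max_re[i],
    stability = eq$stability[i]))
  jsonlite::write_json(
    list(parameters = unclass(attr(eq, "model")),
         input_mean = attr(eq, "input_mean"),
         n_points = nrow(eq), points = pts),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a bifurcation scan as JSON (and optionally CSV)
#'
#' @param scan a `"wendling_bifscan"` object.
#' @param path output JSON path.
#' @param csv_path optional CSV path for the `(B, y_out, stability)`
#'   branch table.
#' @return `path`, invisibly.
#' @export
write_bifurcation_json <- function(scan, path, csv_path = NULL) {
  stopifnot(inherits(scan, "wendling_bifscan"))
  jsonlite::write_json(
    list(parameters = unclass(attr(scan, "model")),
         B_values = attr(scan, "B_values"),
         branches = as.data.frame(scan),
         events = attr(scan, "events")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(scan), csv_path, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a phase schedule from a YAML configuration file
#'
#' The file holds a `phases` list (each entry: `label`, `duration` in
#' seconds, `B`, `G` in mV) and optionally top-level model parameter
#' overrides (for example `A`).  Unknown keys are rejected so that typos
#' do not silently fall back to defaults.
#'
#' @param path YAML file; defaults to the shipped four-phase
#'   interictal-to-ictal scenario.
#' @return list with `schedule` (data frame: label, duration, B, G) and
#'   `overrides` (named list of model parameters).
#' @seealso [default_phase_schedule()], [run_phase_sequence()]
#' @export
read_phase_schedule <- function(path = system.file("extdata", "phases.yaml",
                                                   package = "wendling")) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("phases", names(formals(wendling_model)))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$phases) || !length(cfg$phases))
    stop("configuration has no phases")
  sched <- do.call(rbind, lapply(cfg$phases, function(p) {
    extra <- setdiff(names(p), c("label", "duration", "B", "G"))
    if (length(extra))
      stop("unknown phase key(s): ", paste(extra, collapse = ", "))
    if (is.null(p$duration) || p$duration <= 0)
      stop("each phase needs a positive duration")
    if (is.null(p$B) || is.null(p$G)) stop("each phase needs B and G")
    data.frame(label = if (is.null(p$label)) NA_character_ else p$label,
               duration = p$duration, B = p$B, G = p$G,
               stringsAsFactors = FALSE)
  }))
  list(schedule = sched, overrides = cfg[setdiff(names(cfg), "phases")])
}

#' The standard four-phase scenario
#'
#' Background, sporadic spiking, sustained spiking and gamma activity:
#' `B = 45, 38, 37, 8` with `A = 5`, `G = 20`.  The ictal fifth phase of
#' the original scenario requires a simultaneous change of `G` whose
#' published value is not machine-readable, so it is not included here
#' (the shipped YAML file carries it commented out as a placeholder).
#'
#' @param duration seconds per phase.
#' @return data frame usable as a [run_phase_sequence()] schedule.
#' @export
default_phase_schedule <- function(duration = 5) {
  data.frame(
    label = c("background", "sporadic_spiking", "sustained_spiking", "gamma"),
    duration = duration,
    B = c(45, 38, 37, 8),
    G = 20,
    stringsAsFactors = FALSE)
}
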