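#' Firing rate from spike times
#'
#' Counts spikes in a half-open window `[start, end)` and divides by the
#' window length.  The default window is the middle 1 s of the 2 s stimulus,
#' where most of the velocity variation occurs and pursuit is stable.
#'
#' @param spike_times_s numeric vector of spike times (seconds).
#' @param window numeric length-2, `c(start_s, end_s)`.
#' @return firing rate in spikes/s.
#' @export
firing_rate_from_spikes <- function(spike_times_s, window = c(0.5, 1.5)) {
  if (length(window) != 2 || !all(is.finite(window)) || window[2] <= window[1])
    stop("window must be c(start, end) with end > start")
  if (length(spike_times_s) == 0) return(0)
  sum(spike_times_s >= window[1] & spike_times_s < window[2]) /
    (window[2] - window[1])
}

#' Condition grid for a recording block
#'
#' @param headings_deg heading angles in degrees; must span the full circle
#'   at a regular resolution.  Default: 8 directions at 45 deg intervals.
#' @param eye_positions_deg static fixation locations, drawn from
#'   -30/-20/-10/0/10/20/30 deg.
#' @param plane `"horizontal"` or `"sagittal"`.
#' @param reps planned repetitions per condition.
#' @return a `condition_grid` object.
#' @export
condition_grid <- function(headings_deg = seq(0, 315, by = 45),
                           eye_positions_deg = c(-20, 0, 20),
                           plane = c("horizontal", "sagittal"),
                           reps = 5L) {
  plane <- match.arg(plane)
  if (length(headings_deg) < 2 || length(eye_positions_deg) < 1)
    stop("condition grid needs headings and at least one eye position")
  headings_deg <- sort(wrap360(headings_deg))
  if (!all(eye_positions_deg %in% c(-30, -20, -10, 0, 10, 20, 30)))
    stop("eye positions must be drawn from {-30,-20,-10,0,10,20,30} deg")
  structure(list(headings_deg = headings_deg,
                 eye_positions_deg = sort(eye_positions_deg),
                 plane = plane, reps = as.integer(reps)),
            class = "condition_grid")
}

#' Enumerate estimation-task conditions
#'
#' Cartesian product of headings and eye positions; with the default
#' 20 deg heading resolution and three fixations this yields the 54
#' conditions of one estimation block.
#'
#' @param grid a [condition_grid()].  Default: 18 headings at 20 deg
#'   intervals crossed with fixations at -20/0/+20 deg.
#' @return a data.frame of `heading_deg`, `eye_pos_deg`, one row per
#'   condition, with attributes `n_conditions` and `min_trials`
#'   (`n_conditions * reps`).
#' @export
estimation_schedule <- function(grid = condition_grid(seq(0, 340, by = 20),
                                                      c(-20, 0, 20))) {
  if (length(grid$headings_deg) == 0 || length(grid$eye_positions_deg) == 0)
    stop("empty condition grid")
  sched <- expand.grid(heading_deg = grid$headings_deg,
                       eye_pos_deg = grid$eye_positions_deg,
                       KEEP.OUT.ATTRS = FALSE)
  attr(sched, "n_conditions") <- nrow(sched)
  attr(sched, "min_trials") <- nrow(sched) * grid$reps
  sched
}

#' Construct a tuning curve for one neuron and condition
#'
#' Filters the trial table to one neuron, modality and condition, and
#' returns per-heading mean firing rate, s.e.m. and the retained trial
#' values.  Rows carrying spike times instead of rates are converted with
#' [firing_rate_from_spikes()].
#'
#' @param trials a [trial_table()].
#' @param neuron_id neuron identifier.
#' @param modality `"visual"` or `"vestibular"`.
#' @param condition named list selecting the condition, e.g.
#'   `list(eye_pos_deg = -20)` or
#'   `list(protocol = "pursuit", pursuit_dir = "leftward")`.
#' @param grid optional [condition_grid()]; headings present in the grid
#'   but absent from the data raise an error naming them.
#' @param window spike-count window passed to [firing_rate_from_spikes()].
#' @return a `tuning_curve`: list with `headings_deg` (sorted),
#'   `mean_rate_hz`, `sem_hz`, `trials` (list of per-heading rate vectors),
#'   `n_reps` (minimum repetitions) and `label` (the condition).  Curves
#'   with any single-repetition heading have `sem_hz = 0` there and carry
#'   attribute `single_rep = TRUE` (non-testable by ANOVA).
#' @export
build_tuning <- function(trials, neuron_id, modality,
                         condition = list(), grid = NULL,
                         window = c(0.5, 1.5)) {
  df <- as.data.frame(trials)
  keep <- df$neuron_id == neuron_id & df$modality == modality
  for (field in names(condition))
    keep <- keep & df[[field]] == condition[[field]]
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0)
    stop("no trials for neuron '", neuron_id, "' under the given condition")
  df <- df[order(df$heading_deg, df$repetition), , drop = FALSE]

  rates <- if ("rate_hz" %in% names(df)) df$rate_hz else rep(NA_real_, nrow(df))
  if (anyNA(rates)) {
    if (!"spike_times_s" %in% names(df))
      stop("missing rate_hz and no spike_times_s to derive it from")
    idx <- which(is.na(rates))
    rates[idx] <- vapply(df$spike_times_s[idx], firing_rate_from_spikes,
                         0, window = window)
  }

  by_heading <- split(rates, df$heading_deg)
  headings <- as.numeric(names(by_heading))
  o <- order(headings)
  headings <- headings[o]
  by_heading <- by_heading[o]

  if (!is.null(grid)) {
    absent <- setdiff(grid$headings_deg, headings)
    if (length(absent) > 0)
      stop("missing data for grid heading(s): ",
           paste(absent, collapse = ", "), " deg")
  }

  n <- lengths(by_heading)
  means <- vapply(by_heading, mean, 0)
  sems <- vapply(by_heading, function(v)
    if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v)), 0)

  curve <- structure(
    list(headings_deg = headings, mean_rate_hz = unname(means),
         sem_hz = unname(sems), trials = unname(by_heading),
         n_reps = min(n), label = condition),
    class = "tuning_curve")
  if (any(n == 1)) attr(curve, "single_rep") <- TRUE
  curve
}

#' Low-level tuning-curve constructor
#'
#' Builds a `tuning_curve` directly from per-heading trial values, bypassing
#' the trial table.  Used by the simulators and the bootstrap fast path.
#'
#' @param headings_deg heading angles.
#' @param trials list of numeric vectors, one per heading.
#' @param label optional condition label.
#' @return a `tuning_curve` (see [build_tuning()]).
#' @export
tuning_curve <- function(headings_deg, trials, label = list()) {
  stopifnot(length(headings_deg) == length(trials))
  o <- order(headings_deg)
  headings_deg <- headings_deg[o]
  if (anyDuplicated(headings_deg))
    stop("duplicate headings in tuning curve")
  trials <- lapply(trials[o], as.numeric)
  n <- lengths(trials)
  curve <- structure(
    list(headings_deg = headings_deg,
         mean_rate_hz = vapply(trials, mean, 0),
         sem_hz = vapply(trials, function(v)
           if (length(v) < 2) 0 else stats::sd(v) / sqrt(length(v)), 0),
         trials = trials, n_reps = min(n), label = label),
    class = "tuning_curve")
  if (any(n == 1)) attr(curve, "single_rep") <- TRUE
  curve
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("Tuning curve: ", length(x$headings_deg), " headings, ",
      x$n_reps, "+ reps, peak ", round(max(x$mean_rate_hz), 1),
      " spikes/s at ", x$headings_deg[which.max(x$mean_rate_hz)], " deg\n",
      sep = "")
  invisible(x)
}

#' Heading-tuning significance (one-way ANOVA)
#'
#' Tests for an effect of heading on trial firing rates with a one-way
#' ANOVA across headings.  Degenerate inputs with zero variance both within
#' and between headings return `p = 1` with attribute `degenerate = TRUE`.
#'
#' @param curve a `tuning_curve` with at least 2 headings and 2 repetitions
#'   per heading.
#' @return the ANOVA p-value, with attributes `F` and `df`.
#' @export
tuning_significance <- function(curve) {
  groups <- curve$trials
  if (length(groups) < 2)
    stop("need at least 2 headings for an ANOVA")
  if (any(lengths(groups) < 2))
    stop("need at least 2 repetitions per heading for an ANOVA ",
         "(curve flagged single_rep is non-testable)")
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  gm <- vapply(groups, mean, 0)
  grand <- sum(n * gm) / N
  ssb <- sum(n * (gm - grand)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (ssb < 1e-12 && ssw < 1e-12) {
    p <- 1.0
    attr(p, "degenerate") <- TRUE
    attr(p, "F") <- NA_real_
    attr(p, "df") <- c(k - 1, N - k)
    return(p)
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  attr(p, "F") <- Fstat
  attr(p, "df") <- c(k - 1, N - k)
  p
}
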