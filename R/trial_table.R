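#' Trial-level response table
#'
#' The common currency of the package: one row per completed trial, keyed by
#' neuron, stimulus modality, task protocol, eye-position (or pursuit)
#' condition, heading and repetition.  Exactly one of `rate_hz` /
#' `spike_times_s` must carry the response.
#'
#' Required columns: `neuron_id`, `modality` (`"visual"`/`"vestibular"`),
#' `heading_deg`, `repetition`, and `rate_hz` or `spike_times_s` (a list
#' column of numeric spike times in seconds).  Optional columns with
#' defaults: `protocol` (`"eccentric_fixation"`, `"pursuit"` or
#' `"estimation"`; default `"eccentric_fixation"`), `eye_pos_deg` (default
#' 0), `pursuit_dir` (`"none"`, `"leftward"`, `"rightward"`; default
#' `"none"`).  Headings outside `[0, 360)` are normalised modulo 360 with a
#' warning.
#'
#' @param df a data.frame with the columns above.
#' @return the validated table, classed `trial_table`.
#' @export
trial_table <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  required <- c("neuron_id", "modality", "heading_deg", "repetition")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("trial table format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  has_rate  <- "rate_hz" %in% names(df)
  has_spike <- "spike_times_s" %in% names(df)
  if (!has_rate && !has_spike)
    stop("trial table format error: need a 'rate_hz' or 'spike_times_s' column")

  if (is.null(df$protocol)) df$protocol <- "eccentric_fixation"
  if (is.null(df$eye_pos_deg)) df$eye_pos_deg <- 0
  if (is.null(df$pursuit_dir)) df$pursuit_dir <- "none"

  bad_row <- function(test, what) {
    idx <- which(test)
    if (length(idx) > 0)
      stop("trial table validation failed (", what, ") at row(s): ",
           paste(utils::head(idx, 10), collapse = ", "))
  }
  bad_row(!df$modality %in% c("visual", "vestibular"), "modality")
  bad_row(!df$protocol %in% c("eccentric_fixation", "pursuit", "estimation"),
          "protocol")
  bad_row(!df$pursuit_dir %in% c("none", "leftward", "rightward"),
          "pursuit_dir")
  bad_row(!is.finite(df$heading_deg), "heading_deg")
  bad_row(!is.finite(df$repetition) | df$repetition < 1 |
            df$repetition != round(df$repetition), "repetition")
  if (has_rate) {
    rate_given <- !is.na(df$rate_hz)
    bad_row(rate_given & df$rate_hz < 0, "negative rate_hz")
  }

  out_of_range <- df$heading_deg < 0 | df$heading_deg >= 360
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " heading(s) outside [0, 360) normalised modulo 360")
    df$heading_deg <- wrap360(df$heading_deg)
  }

  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read a trial table from delimited text
#'
#' Reads a comma-separated, UTF-8 encoded file with a mandatory header row.
#' Deposited source-data files with other column names can be ingested by
#' supplying `dialect`, a named list/vector mapping canonical column names
#' to the names used in the file, e.g.
#' `dialect = list(heading_deg = "Heading", rate_hz = "FR")`.
#'
#' @param path file path.
#' @param dialect optional named mapping canonical -> file column name.
#' @param sep field separator (default `","`).
#' @return a [trial_table()].
#' @export
load_trial_table <- function(path, dialect = NULL, sep = ",") {
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      src <- dialect[[canon]]
      if (!src %in% names(df))
        stop("trial table format error: dialect column '", src,
             "' not found in ", path)
      names(df)[names(df) == src] <- canon
    }
  }
  if ("spike_times_s" %in% names(df) && is.character(df$spike_times_s)) {
    df$spike_times_s <- lapply(strsplit(df$spike_times_s, ";", fixed = TRUE),
                               function(s) as.numeric(s[nzchar(s)]))
  }
  trial_table(df)
}

#' Write a trial table to CSV
#'
#' Inverse of [load_trial_table()]: spike-time list columns are collapsed to
#' semicolon-separated strings.
#'
#' @param trials a [trial_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  df <- as.data.frame(trials)
  if ("spike_times_s" %in% names(df) && is.list(df$spike_times_s)) {
    df$spike_times_s <- vapply(df$spike_times_s,
                               function(s) paste(s, collapse = ";"), "")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.trial_table <- function(x, ...) {
  cat("Trial table: ", nrow(x), " trials, ",
      length(unique(x$neuron_id)), " neuron(s)\n", sep = "")
  NextMethod()
}
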