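#' Decode a reported heading from a saccade endpoint
#'
#' The choice ring is centred on the fixation location; the polar angle of
#' the endpoint about the ring centre (0 degrees = rightward, 90 degrees =
#' up) maps one-to-one onto heading azimuth (0 = rightward, 90 = forward,
#' 180 = leftward, 270 = backward).
#'
#' @param endpoint numeric length-2, `(x_deg, y_deg)` on the screen.
#' @param ring_center numeric length-2, ring centre on the screen (the
#'   fixation location).
#' @return reported heading in `[0, 360)`.
#' @export
endpoint_to_heading <- function(endpoint, ring_center = c(0, 0)) {
  d <- endpoint - ring_center
  if (sqrt(sum(d^2)) < 1e-9)
    stop("undefined angle: endpoint at the ring centre")
  wrap360(atan2(d[2], d[1]) * 180 / pi)
}

#' Screen position of a heading's target dot
#'
#' Inverse of [endpoint_to_heading()]: the ring dot corresponding to a
#' heading.
#'
#' @param heading_deg heading azimuth.
#' @param ring_center ring centre on screen.
#' @param ring_diameter_deg ring diameter (default 20).
#' @return numeric length-2 `(x_deg, y_deg)`.
#' @export
target_position <- function(heading_deg, ring_center = c(0, 0),
                            ring_diameter_deg = 20) {
  a <- heading_deg * pi / 180
  ring_center + (ring_diameter_deg / 2) * c(cos(a), sin(a))
}

#' Score one estimation trial
#'
#' A choice is correct when the saccade endpoint falls within an
#' axis-aligned reward window centred on the true heading's target dot
#' (default 5 x 5 degrees, i.e. +/- 2.5 degrees per axis).
#'
#' @param endpoint numeric length-2 endpoint on screen.
#' @param true_heading_deg the stimulus heading.
#' @param ring_center ring centre (fixation location).
#' @param ring_diameter_deg ring diameter.
#' @param window_deg numeric length-2 full window extent per axis.
#' @return logical.
#' @export
score_trial <- function(endpoint, true_heading_deg, ring_center = c(0, 0),
                        ring_diameter_deg = 20, window_deg = c(5, 5)) {
  target <- target_position(true_heading_deg, ring_center,
                            ring_diameter_deg)
  all(abs(endpoint - target) <= window_deg / 2)
}

#' Circular summary of heading estimates per condition
#'
#' Groups estimation records by (true heading, eye position) and reports
#' the circular mean and circular SD (`sqrt(-2 ln Rbar)`) of the reported
#' headings.
#'
#' @param records data.frame with `true_heading_deg`, `eye_pos_deg`,
#'   `reported_heading_deg` (or endpoint columns `endpoint_x_deg`,
#'   `endpoint_y_deg`, decoded via [endpoint_to_heading()] with the ring
#'   centred at `(eye_pos_deg, 0)`).
#' @param min_n minimum records per group (default 2); smaller groups are
#'   dropped with a warning.
#' @return data.frame of `true_heading_deg`, `eye_pos_deg`, `n`,
#'   `mean_deg`, `circ_sd_deg`.
#' @export
estimate_summary <- function(records, min_n = 2) {
  if (!"reported_heading_deg" %in% names(records)) {
    stopifnot(all(c("endpoint_x_deg", "endpoint_y_deg") %in% names(records)))
    records$reported_heading_deg <- vapply(seq_len(nrow(records)),
      function(i) endpoint_to_heading(
        c(records$endpoint_x_deg[i], records$endpoint_y_deg[i]),
        c(records$eye_pos_deg[i], 0)), 0)
  }
  groups <- split(records,
                  list(records$true_heading_deg, records$eye_pos_deg),
                  drop = TRUE)
  small <- vapply(groups, nrow, 0L) < min_n
  if (any(small)) {
    warning(sum(small), " group(s) with fewer than ", min_n,
            " records dropped")
    groups <- groups[!small]
  }
  out <- do.call(rbind, lapply(groups, function(g)
    data.frame(true_heading_deg = g$true_heading_deg[1],
               eye_pos_deg = g$eye_pos_deg[1], n = nrow(g),
               mean_deg = circ_mean_deg(g$reported_heading_deg),
               circ_sd_deg = circ_sd_deg(g$reported_heading_deg))))
  rownames(out) <- NULL
  out[order(out$eye_pos_deg, out$true_heading_deg), ]
}

#' Fixation-dependent heading-estimation error
#'
#' For each eccentric fixation, takes the signed circular difference
#' between the mean estimate under that fixation and under central
#' fixation, per matched heading, and averages over headings.  Positive
#' error = estimates shifted toward the fixation side (the sign convention
#' follows the heading axis, so at +20 degrees fixation a fully
#' eye-referenced reporter yields +20).
#'
#' @param summaries output of [estimate_summary()] including eye position
#'   0 and at least one eccentric fixation.
#' @return data.frame of `eye_pos_deg`, `error_deg`, `n_headings`.
#'   Headings missing from either condition are dropped with a warning.
#' @export
estimation_error <- function(summaries) {
  centre <- summaries[summaries$eye_pos_deg == 0, ]
  if (nrow(centre) == 0) stop("no central-fixation summaries")
  ecc <- setdiff(unique(summaries$eye_pos_deg), 0)
  if (length(ecc) == 0) stop("no eccentric-fixation summaries")
  out <- do.call(rbind, lapply(sort(ecc), function(P) {
    sub <- summaries[summaries$eye_pos_deg == P, ]
    common <- intersect(sub$true_heading_deg, centre$true_heading_deg)
    if (length(common) < length(sub$true_heading_deg) ||
        length(common) < length(centre$true_heading_deg))
      warning("unmatched headings between fixation ", P,
              " and centre; using the matched subset")
    d <- wrap180(
      sub$mean_deg[match(common, sub$true_heading_deg)] -
        centre$mean_deg[match(common, centre$true_heading_deg)])
    data.frame(eye_pos_deg = P, error_deg = mean(d),
               n_headings = length(common))
  }))
  rownames(out) <- NULL
  out
}

#' Behavioural analysis, end to end
#'
#' Decodes reported headings from endpoints when needed, summarises them
#' per condition and computes the per-fixation estimation error.
#'
#' @inheritParams estimate_summary
#' @return list with `summaries` and `errors`.
#' @export
analyze_behavior <- function(records, min_n = 2) {
  summaries <- estimate_summary(records, min_n)
  list(summaries = summaries, errors = estimation_error(summaries))
}
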