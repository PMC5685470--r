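#' Evoked response amplitude of a tuning curve
#'
#' Maximum minus minimum mean firing rate across headings.  Differences in
#' this metric across eye positions reflect multiplicative gain modulation
#' rather than an additive eye-position effect (the metric is invariant to
#' additive offsets of the whole curve).
#'
#' @param curve a `tuning_curve`.
#' @return amplitude in spikes/s (>= 0).
#' @export
evoked_response <- function(curve) {
  max(curve$mean_rate_hz) - min(curve$mean_rate_hz)
}

#' Permutation test for eye-position gain modulation
#'
#' Tests whether the evoked-response amplitude differs across eye
#' positions.  The observed statistic is the range (max - min) of the
#' per-eye-position amplitudes; the null distribution is built by permuting
#' eye-position labels among trials within each heading (which preserves
#' the heading tuning but destroys any eye-position effect).  The p-value
#' is the upper-tail permutation probability; the choice of test is a
#' package decision, recorded here, since no canonical test exists for
#' this statistic.
#'
#' @param trials a [trial_table()] (fixation block).
#' @param neuron_id,modality select the neuron.
#' @param n_boot number of label permutations (default 1000).
#' @param seed RNG seed.
#' @return the p-value, with attributes `observed` (the amplitude range)
#'   and `evoked_by_eye` (named per-eye-position amplitudes).  Returns
#'   `NA` flagged `untestable` when any cell has fewer than 3 repetitions.
#' @export
gain_test <- function(trials, neuron_id, modality = "visual",
                      n_boot = 1000, seed = NULL) {
  df <- as.data.frame(trials)
  df <- df[df$neuron_id == neuron_id & df$modality == modality &
             df$protocol == "eccentric_fixation", , drop = FALSE]
  eyes <- sort(unique(df$eye_pos_deg))
  headings <- sort(unique(df$heading_deg))
  ne <- length(eyes); nh <- length(headings)
  if (ne < 2) stop("need at least 2 eye positions for a gain test")

  # rates[rep, heading, eye]; requires a balanced design per cell
  counts <- table(factor(df$eye_pos_deg, eyes),
                  factor(df$heading_deg, headings))
  if (min(counts) < 3) {
    p <- NA_real_
    attr(p, "untestable") <- TRUE
    return(p)
  }
  nr <- min(counts)
  cube <- array(NA_real_, c(nr, nh, ne))
  for (e in seq_len(ne)) for (h in seq_len(nh)) {
    v <- df$rate_hz[df$eye_pos_deg == eyes[e] &
                      df$heading_deg == headings[h]]
    cube[, h, e] <- v[seq_len(nr)]
  }

  amp_range <- function(cb) {
    means <- apply(cb, c(2, 3), mean)        # heading x eye
    amps <- apply(means, 2, function(v) max(v) - min(v))
    max(amps) - min(amps)
  }
  obs_means <- apply(cube, c(2, 3), mean)
  evoked <- apply(obs_means, 2, function(v) max(v) - min(v))
  names(evoked) <- eyes
  obs <- max(evoked) - min(evoked)

  null_stats <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    perm <- cube
    for (h in seq_len(nh)) {
      pool <- as.vector(cube[, h, ])
      perm[, h, ] <- pool[sample.int(length(pool))]
    }
    amp_range(perm)
  }, 0))

  p <- (1 + sum(null_stats >= obs)) / (n_boot + 1)
  attr(p, "observed") <- obs
  attr(p, "evoked_by_eye") <- evoked
  p
}

#' Classify the form of an eye-position gain field
#'
#' Applied to the per-eye-position evoked amplitudes at -20/0/+20 degrees:
#' `"none"` when the gain test is not significant; `"monotonic"` when the
#' amplitudes increase or decrease along eye position; `"nonmonotonic"`
#' when the central amplitude is the strict maximum or minimum.
#' Amplitudes within `tie_tol` (fraction of the largest amplitude) are
#' treated as tied; the category then falls back to the pattern ignoring
#' the tied pair.
#'
#' @param evoked_by_eye numeric length-3, amplitudes ordered by eye
#'   position (-20, 0, +20).
#' @param p_gain p-value from [gain_test()].
#' @param alpha significance gate (default 0.05).
#' @param tie_tol relative tie tolerance (default 0.05).
#' @return one of `"monotonic"`, `"nonmonotonic"`, `"none"`.
#' @export
classify_gain <- function(evoked_by_eye, p_gain, alpha = 0.05,
                          tie_tol = 0.05) {
  stopifnot(length(evoked_by_eye) == 3)
  if (is.na(p_gain) || p_gain >= alpha) return("none")
  a <- as.numeric(evoked_by_eye)
  tol <- tie_tol * max(a)
  cmp <- function(x, y) if (abs(x - y) <= tol) 0L else as.integer(sign(x - y))
  s12 <- cmp(a[2], a[1])
  s23 <- cmp(a[3], a[2])
  if (s12 != 0L && s12 == s23) return("monotonic")
  if (s12 * s23 == -1L) return("nonmonotonic")
  # one (or both) comparisons tied: fall back to the outer comparison
  if (cmp(a[3], a[1]) != 0L) "monotonic" else "nonmonotonic"
}

#' Gain-field analysis for one neuron
#'
#' Combines [gain_test()] and [classify_gain()] and reports the evoked
#' amplitudes.
#'
#' @inheritParams gain_test
#' @param alpha significance gate.
#' @return a `gain_result`: `evoked_by_eye`, `p_gain`, `category`.
#' @export
gain_analysis <- function(trials, neuron_id, modality = "visual",
                          n_boot = 1000, seed = NULL, alpha = 0.05) {
  p <- gain_test(trials, neuron_id, modality, n_boot, seed)
  evoked <- attr(p, "evoked_by_eye")
  category <- if (is.null(evoked) || length(evoked) != 3) "none"
              else classify_gain(evoked, as.numeric(p), alpha)
  structure(list(evoked_by_eye = evoked, p_gain = as.numeric(p),
                 untestable = isTRUE(attr(p, "untestable")),
                 category = category),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("Gain field: p = %s -> %s\n",
              format(x$p_gain, digits = 3), x$category))
  invisible(x)
}
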