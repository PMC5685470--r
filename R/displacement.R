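#' Circular linear interpolation of a tuning curve
#'
#' Linearly interpolates a tuning curve onto a dense grid over the full
#' circle, wrapping across the 360 -> 0 boundary.  Sampled headings are
#' reproduced exactly.
#'
#' @param curve a `tuning_curve`, or a list/data.frame with `headings_deg`
#'   and `mean_rate_hz`.
#' @param resolution_deg output resolution (default 1 degree).
#' @return list with `headings_deg` (`seq(0, 360 - res, res)`) and
#'   `values`.
#' @export
interpolate_circular <- function(curve, resolution_deg = 1) {
  h <- wrap360(curve$headings_deg)
  v <- curve$mean_rate_hz
  if (anyDuplicated(h)) {
    dup <- duplicated(h) | duplicated(h, fromLast = TRUE)
    if (any(tapply(v[dup], h[dup], function(x) max(x) - min(x)) > 1e-9))
      stop("duplicate headings with conflicting means")
    keep <- !duplicated(h)
    v <- v[keep]; h <- h[keep]
  }
  if (length(h) < 3)
    stop("need at least 3 distinct headings to interpolate")
  o <- order(h)
  list(headings_deg = seq(0, 360 - resolution_deg, by = resolution_deg),
       values = interp_circ_dense(h[o], v[o], resolution_deg))
}

# Minimal fast path shared with the bootstrap: h sorted, no class checks.
interp_circ_dense <- function(h, v, resolution_deg = 1) {
  n <- length(h)
  hx <- c(h[n] - 360, h, h[1] + 360)
  vx <- c(v[n], v, v[1])
  stats::approx(hx, vx,
                xout = seq(0, 360 - resolution_deg, by = resolution_deg),
                ties = "ordered")$y
}

# Circular cross-covariance over all integer lags via FFT.
# Returns c(k) = mean_theta x(theta) * y(theta + k) for k = 0 .. n-1
# on mean-subtracted inputs.
xcov_circular <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  Re(stats::fft(Conj(stats::fft(x)) * stats::fft(y), inverse = TRUE)) / n^2
}

# Argmax lag in [-180, 180]; ties broken toward smallest |k|, then
# negative before positive (conservative: biases toward no shift).
best_lag <- function(cc) {
  n <- length(cc)
  k <- seq_len(n) - 1
  k <- ifelse(k > n / 2, k - n, k)
  tol <- 1e-9 * (max(abs(cc)) + 1)
  cand <- k[cc >= max(cc) - tol]
  cand[order(abs(cand), cand)][1]
}

#' Displacement index for one pair of tuning curves
#'
#' Interpolates both curves to 1 degree, mean-subtracts them, and finds the
#' circular lag `k` in `[-180, 180]` that maximises the cross-covariance
#' `cov[R_i(theta), R_j(theta + k)]`.  The displacement index is the lag
#' divided by the eye-position difference, signed so that a tuning shift
#' equal to the gaze displacement gives +1 (eye-centered) and no shift
#' gives 0 (head-centered).
#'
#' @param curve_i,curve_j tuning curves (see [interpolate_circular()] for
#'   accepted forms).
#' @param P_i,P_j the eye positions (degrees) at which the curves were
#'   measured; must differ.
#' @param resolution_deg interpolation resolution.
#' @return list with `di`, `lag_deg` (the maximising lag) and
#'   `pair = c(P_i, P_j)`.
#' @export
pairwise_di <- function(curve_i, curve_j, P_i, P_j, resolution_deg = 1) {
  if (P_i == P_j) stop("P_i and P_j must differ")
  xi <- interpolate_circular(curve_i, resolution_deg)$values
  xj <- interpolate_circular(curve_j, resolution_deg)$values
  if (stats::var(xi) < 1e-12 || stats::var(xj) < 1e-12)
    stop("undefined DI: flat tuning curve (zero variance)")
  k <- best_lag(xcov_circular(xi, xj)) * resolution_deg
  list(di = k / (P_j - P_i), lag_deg = k, pair = c(P_i = P_i, P_j = P_j))
}

#' Displacement index of one neuron (point estimate)
#'
#' Evaluates [pairwise_di()] for every pair of significantly tuned curves
#' and averages the pair values (unweighted).  With all three eye positions
#' significant this averages three pair DIs.
#'
#' @param curves list of tuning curves; eye positions are taken from
#'   `label$eye_pos_deg` unless `eye_positions` is given.
#' @param eye_positions optional numeric vector of eye positions.
#' @param p_values optional pre-computed tuning p-values; by default
#'   [tuning_significance()] is applied to each curve.  Curves flagged
#'   `single_rep` (ANOVA non-testable) are treated as significant and the
#'   result is flagged `untested_significance`.
#' @param alpha significance level for including a curve (default 0.05).
#' @return a `di_result`: `di`, `pair_dis` (data.frame of per-pair values),
#'   `n_pairs`, `eye_positions` used; `ci95` and `category` are `NA` until
#'   [bootstrap_ci()] / [classify_frame()] are applied.
#' @export
neuron_di <- function(curves, eye_positions = NULL, p_values = NULL,
                      alpha = 0.05) {
  if (is.null(eye_positions))
    eye_positions <- vapply(curves, function(cv) cv$label$eye_pos_deg, 0)
  stopifnot(length(curves) == length(eye_positions))
  untested <- FALSE
  if (is.null(p_values)) {
    p_values <- vapply(curves, function(cv) {
      if (isTRUE(attr(cv, "single_rep"))) return(NA_real_)
      as.numeric(tuning_significance(cv))
    }, 0)
  }
  untested <- anyNA(p_values)
  sig <- is.na(p_values) | p_values < alpha
  if (sum(sig) < 2)
    stop("excluded: fewer than 2 significantly tuned curves")
  idx <- which(sig)
  pairs <- utils::combn(idx, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    pd <- pairwise_di(curves[[i1]], curves[[i2]],
                      eye_positions[i1], eye_positions[i2])
    data.frame(P_i = eye_positions[i1], P_j = eye_positions[i2],
               di = pd$di, lag_deg = pd$lag_deg)
  })
  pair_dis <- do.call(rbind, rows)
  res <- structure(list(di = mean(pair_dis$di), pair_dis = pair_dis,
                        n_pairs = nrow(pair_dis),
                        eye_positions = eye_positions[idx],
                        ci95 = c(NA_real_, NA_real_),
                        category = NA_character_,
                        boot_reps = NA_integer_, seed = NA_integer_),
                   class = "di_result")
  if (untested) attr(res, "untested_significance") <- TRUE
  res
}

# Extract, for one neuron/modality, a list (per eye position) of
# rate matrices [heading x rep-slot] as ragged lists, for fast resampling.
di_boot_data <- function(trials, neuron_id, modality, eye_positions) {
  df <- as.data.frame(trials)
  df <- df[df$neuron_id == neuron_id & df$modality == modality &
             df$protocol == "eccentric_fixation" &
             df$eye_pos_deg %in% eye_positions, , drop = FALSE]
  headings <- sort(unique(df$heading_deg))
  cells <- lapply(eye_positions, function(P) {
    sub <- df[df$eye_pos_deg == P, , drop = FALSE]
    lapply(headings, function(h) sub$rate_hz[sub$heading_deg == h])
  })
  list(headings = headings, cells = cells)
}

#' Bootstrap confidence interval for a neuron's displacement index
#'
#' Resamples repetitions with replacement independently within every
#' (eye position x heading) cell, rebuilds the tuning curves, recomputes
#' the averaged DI, and returns the 2.5/97.5 percentiles of the bootstrap
#' distribution.  Replicates producing a flat curve are dropped and
#' counted; more than 20% drops raises a warning.
#'
#' @param trials a [trial_table()] holding the neuron's fixation block.
#' @param neuron_id,modality select the neuron.
#' @param eye_positions eye positions entering the DI (default: those of
#'   the point estimate, i.e. all with >= 2 significant curves is the
#'   caller's responsibility; by default all present).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed; identical seeds give identical intervals.
#' @return list with `ci95 = c(low, high)`, `boot_dis` (the replicate
#'   DIs), `n_dropped`, `n_boot`, `seed`.
#' @export
bootstrap_ci <- function(trials, neuron_id, modality = "visual",
                         eye_positions = NULL, n_boot = 1000,
                         seed = NULL) {
  df <- as.data.frame(trials)
  if (is.null(eye_positions)) {
    eye_positions <- sort(unique(
      df$eye_pos_deg[df$neuron_id == neuron_id & df$modality == modality]))
  }
  bd <- di_boot_data(trials, neuron_id, modality, eye_positions)
  nh <- length(bd$headings)
  ne <- length(eye_positions)
  if (nh < 3 || ne < 2) stop("insufficient data for a bootstrap DI")
  pair_idx <- utils::combn(ne, 2)
  denom <- eye_positions[pair_idx[2, ]] - eye_positions[pair_idx[1, ]]
  h <- bd$headings
  reps_per_cell <- lapply(bd$cells, lengths)

  boot_dis <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      dense <- matrix(0, 360, ne)
      for (e in seq_len(ne)) {
        m <- vapply(seq_len(nh), function(i) {
          v <- bd$cells[[e]][[i]]
          mean(v[sample.int(length(v), replace = TRUE)])
        }, 0)
        dense[, e] <- interp_circ_dense(h, m)
      }
      if (any(apply(dense, 2, stats::var) < 1e-12)) return(NA_real_)
      dis <- vapply(seq_len(ncol(pair_idx)), function(j) {
        best_lag(xcov_circular(dense[, pair_idx[1, j]],
                               dense[, pair_idx[2, j]])) / denom[j]
      }, 0)
      mean(dis)
    }, 0)
  })
  n_dropped <- sum(is.na(boot_dis))
  if (n_dropped > 0.2 * n_boot)
    warning(sprintf("%d of %d bootstrap replicates dropped (flat curves)",
                    n_dropped, n_boot))
  keep <- boot_dis[!is.na(boot_dis)]
  list(ci95 = unname(stats::quantile(keep, c(0.025, 0.975), type = 7)),
       boot_dis = boot_dis, n_dropped = n_dropped,
       n_boot = n_boot, seed = seed)
}

#' Classify a reference frame from a DI confidence interval
#'
#' * head-centered: CI includes 0 but not 1
#' * eye-centered: CI includes 1 but not 0
#' * intermediate: CI strictly inside (0, 1)
#' * unclassified: anything else (e.g. CI covering both 0 and 1)
#'
#' @param di the point estimate (stored, not used by the rules).
#' @param ci95 numeric length-2 confidence interval.
#' @return one of `"head"`, `"eye"`, `"intermediate"`, `"unclassified"`.
#' @export
classify_frame <- function(di, ci95) {
  stopifnot(length(ci95) == 2, ci95[1] <= ci95[2])
  has0 <- ci95[1] <= 0 && ci95[2] >= 0
  has1 <- ci95[1] <= 1 && ci95[2] >= 1
  if (has0 && !has1) "head"
  else if (has1 && !has0) "eye"
  else if (!has0 && !has1 && ci95[1] > 0 && ci95[2] < 1) "intermediate"
  else "unclassified"
}

#' Displacement index for one neuron, end to end
#'
#' Convenience wrapper: builds the per-eye-position tuning curves, computes
#' the averaged DI over significant pairs, bootstraps the 95% CI and
#' classifies the frame.
#'
#' @inheritParams bootstrap_ci
#' @param alpha tuning-significance level.
#' @return a `di_result` with `ci95` and `category` filled in.
#' @export
displacement_index <- function(trials, neuron_id, modality = "visual",
                               n_boot = 1000, seed = NULL, alpha = 0.05) {
  df <- as.data.frame(trials)
  eyes <- sort(unique(
    df$eye_pos_deg[df$neuron_id == neuron_id & df$modality == modality &
                     df$protocol == "eccentric_fixation"]))
  curves <- lapply(eyes, function(P)
    build_tuning(trials, neuron_id, modality,
                 list(protocol = "eccentric_fixation", eye_pos_deg = P)))
  res <- neuron_di(curves, eye_positions = eyes, alpha = alpha)
  bc <- bootstrap_ci(trials, neuron_id, modality,
                     eye_positions = res$eye_positions,
                     n_boot = n_boot, seed = seed)
  res$ci95 <- bc$ci95
  res$boot_reps <- bc$n_boot
  res$seed <- if (is.null(seed)) NA_integer_ else seed
  res$category <- classify_frame(res$di, res$ci95)
  res
}

#' @export
print.di_result <- function(x, ...) {
  cat(sprintf("DI = %.3f over %d pair(s)", x$di, x$n_pairs))
  if (!anyNA(x$ci95))
    cat(sprintf(", 95%% CI [%.3f, %.3f] -> %s", x$ci95[1], x$ci95[2],
                x$category))
  cat("\n")
  invisible(x)
}

#' Displacement index as a function of fixation eccentricity
#'
#' For each eccentricity magnitude present (10, 20, 30 degrees), computes
#' pair DIs between the central-fixation curve and the curves at +/- that
#' eccentricity, and averages them.  Used to check that the frame estimate
#' does not depend on the gaze amplitude.
#'
#' @param curves list of tuning curves labelled with `eye_pos_deg` drawn
#'   from 0, +/-10, +/-20, +/-30.
#' @param eye_positions optional numeric vector overriding the labels.
#' @param alpha tuning-significance level.
#' @return data.frame of `eccentricity_deg`, `di`, `n_pairs`; eccentricities
#'   with no significant pairing are omitted and listed in attribute
#'   `omitted`.
#' @export
di_by_eccentricity <- function(curves, eye_positions = NULL, alpha = 0.05) {
  if (is.null(eye_positions))
    eye_positions <- vapply(curves, function(cv) cv$label$eye_pos_deg, 0)
  if (!0 %in% eye_positions)
    stop("need a central-fixation (0 deg) curve")
  p_values <- vapply(curves, function(cv) {
    if (isTRUE(attr(cv, "single_rep"))) return(NA_real_)
    as.numeric(tuning_significance(cv))
  }, 0)
  sig <- is.na(p_values) | p_values < alpha
  centre <- which(eye_positions == 0)[1]
  if (!sig[centre]) stop("central-fixation curve not significantly tuned")
  omitted <- numeric(0)
  rows <- list()
  for (m in c(10, 20, 30)) {
    idx <- which(abs(eye_positions) == m & sig)
    if (length(idx) == 0) {
      if (any(abs(eye_positions) == m)) omitted <- c(omitted, m)
      next
    }
    dis <- vapply(idx, function(i) {
      pairwise_di(curves[[centre]], curves[[i]], 0, eye_positions[i])$di
    }, 0)
    rows[[length(rows) + 1]] <-
      data.frame(eccentricity_deg = m, di = mean(dis),
                 n_pairs = length(dis))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(eccentricity_deg = numeric(0), di = numeric(0),
                         n_pairs = integer(0))
  if (length(omitted)) attr(out, "omitted") <- omitted
  out
}
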