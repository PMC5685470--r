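#' Scale a pursuit tuning curve to a reference
#'
#' Linearly rescales the pursuit curve about its mean so its peak-to-trough
#' modulation matches the no-pursuit reference, removing multiplicative
#' gain differences before shifts are measured.
#'
#' @param pursuit_curve,reference_curve tuning curves (or dense lists with
#'   `mean_rate_hz`/`values`).
#' @return list with `curve` (the scaled pursuit curve, same structure as
#'   the input) and `scale` (the factor applied).
#' @export
scale_to_reference <- function(pursuit_curve, reference_curve) {
  get_vals <- function(cv) if (!is.null(cv$values)) cv$values else cv$mean_rate_hz
  vp <- get_vals(pursuit_curve)
  vr <- get_vals(reference_curve)
  amp_p <- max(vp) - min(vp)
  amp_r <- max(vr) - min(vr)
  if (amp_p < 1e-12)
    stop("undefined scaling: pursuit curve has zero peak-to-trough")
  scale <- amp_r / amp_p
  scaled <- mean(vp) + (vp - mean(vp)) * scale
  out <- pursuit_curve
  if (!is.null(out$values)) out$values <- scaled else out$mean_rate_hz <- scaled
  list(curve = out, scale = scale)
}

#' Split a dense tuning curve into half heading ranges
#'
#' Half A covers `[0, 180)`, half B `[180, 360)` (half-open, so the two
#' halves partition the circle and concatenate back to the full curve).
#'
#' @param dense a dense curve from [interpolate_circular()].
#' @return list with `A` and `B`, each a list of `headings_deg`, `values`.
#' @export
split_halves <- function(dense) {
  inA <- dense$headings_deg < 180
  list(A = list(headings_deg = dense$headings_deg[inA],
                values = dense$values[inA]),
       B = list(headings_deg = dense$headings_deg[!inA],
                values = dense$values[!inA]))
}

#' Half-range tuning shift
#'
#' Circularly shifts the reference half-curve (within its 180-degree
#' support) in 1-degree steps over `[-max_shift, max_shift]` and returns
#' the shift maximising the Pearson correlation with the pursuit half.
#' Ties are broken toward the smallest magnitude, negative first.
#'
#' @param reference_half,pursuit_half dense half-curves (lists with
#'   `values`, or plain numeric vectors) of equal length.
#' @param max_shift search bound in degrees (default 90; larger shifts
#'   would leave the half's support).
#' @return the shift in degrees (positive = reference must move toward
#'   larger headings to match the pursuit half), or `NA` with attribute
#'   `dropped = TRUE` if either half is flat.
#' @export
half_shift <- function(reference_half, pursuit_half, max_shift = 90) {
  r <- if (is.list(reference_half)) reference_half$values else reference_half
  p <- if (is.list(pursuit_half)) pursuit_half$values else pursuit_half
  stopifnot(length(r) == length(p))
  n <- length(r)
  if (stats::sd(r) < 1e-12 || stats::sd(p) < 1e-12) {
    out <- NA_real_
    attr(out, "dropped") <- TRUE
    return(out)
  }
  ks <- -max_shift:max_shift
  cors <- vapply(ks, function(k) {
    shifted <- r[((seq_len(n) - 1 - k) %% n) + 1]
    stats::cor(shifted, p)
  }, 0)
  tol <- 1e-9
  cand <- ks[cors >= max(cors) - tol]
  cand[order(abs(cand), cand)][1]
}

# Predicted sign of the uncompensated half shift for each
# (pursuit direction, half) combination, fixed by the flow-geometry
# convention of the generator: leftward pursuit pushes the [0,180) half
# toward larger and the [180,360) half toward smaller headings.
pursuit_sign_table <- c(leftward.A = 1, leftward.B = -1,
                        rightward.A = -1, rightward.B = 1)

#' Pursuit displacement index (3-step partial-shift analysis)
#'
#' Quantifies tuning shift under smooth pursuit: (1) the pursuit curves'
#' peak-to-trough modulation is linearly scaled to match the no-pursuit
#' curve; (2) each curve is interpolated to 1 degree and split into the
#' `[0,180)` and `[180,360)` halves, each required to be significantly
#' tuned; (3) within each half the no-pursuit curve is circularly shifted
#' in 1-degree steps to maximise the correlation with the pursuit half.
#' The up-to-four shifts (2 pursuit directions x 2 halves) are sign-aligned
#' so that shifts consistent with uncompensated resultant flow are
#' positive, averaged, and divided by the predicted full shift
#' (`predicted_shift_deg`, default 30).  DI = 0 means unchanged tuning
#' (complete compensation); DI = 1 means complete shift.
#'
#' @param no_pursuit,leftward,rightward tuning curves for the three
#'   pursuit conditions (either pursuit curve may be `NULL`).
#' @param predicted_shift_deg DI denominator (default 30).
#' @param alpha significance level for the half-range ANOVA gates; halves
#'   whose underlying trials are single-repetition are not testable and
#'   pass with a flag.
#' @param max_shift half-shift search bound.
#' @return a `pursuit_di_result`: `di`, `half_shifts_deg` (named raw
#'   shifts), `aligned_shifts_deg`, `scale_factors`, `n_valid_halves`,
#'   `category` (`NA` until [classify_pursuit()]).
#' @export
pursuit_di <- function(no_pursuit, leftward = NULL, rightward = NULL,
                       predicted_shift_deg = 30, alpha = 0.05,
                       max_shift = 90) {
  if (is.null(leftward) && is.null(rightward))
    stop("need at least one pursuit condition")
  half_sig <- function(curve, inA) {
    # ANOVA on the raw trials restricted to the half; untestable halves
    # (single rep) pass with a flag
    idx <- if (inA) which(curve$headings_deg < 180)
           else which(curve$headings_deg >= 180)
    groups <- curve$trials[idx]
    if (length(groups) < 2) return(FALSE)
    if (any(lengths(groups) < 2)) return(NA)
    sub <- tuning_curve(curve$headings_deg[idx], groups)
    as.numeric(tuning_significance(sub)) < alpha
  }

  ref_dense <- interpolate_circular(no_pursuit)
  ref_halves <- split_halves(ref_dense)
  shifts <- c(leftward.A = NA_real_, leftward.B = NA_real_,
              rightward.A = NA_real_, rightward.B = NA_real_)
  scales <- c(leftward = NA_real_, rightward = NA_real_)
  untested <- FALSE

  for (dir in c("leftward", "rightward")) {
    pcurve <- if (dir == "leftward") leftward else rightward
    if (is.null(pcurve)) next
    sc <- scale_to_reference(pcurve, no_pursuit)
    scales[dir] <- sc$scale
    p_dense <- interpolate_circular(sc$curve)
    p_halves <- split_halves(p_dense)
    for (half in c("A", "B")) {
      ok_ref <- half_sig(no_pursuit, half == "A")
      ok_pur <- half_sig(pcurve, half == "A")
      if (is.na(ok_ref) || is.na(ok_pur)) untested <- TRUE
      else if (!ok_ref || !ok_pur) next
      s <- half_shift(ref_halves[[half]], p_halves[[half]], max_shift)
      if (!is.na(s)) shifts[paste(dir, half, sep = ".")] <- s
    }
  }

  valid <- !is.na(shifts)
  aligned <- shifts[valid] * pursuit_sign_table[names(shifts)[valid]]
  if (length(aligned) == 0) {
    res <- structure(list(di = NA_real_, half_shifts_deg = shifts,
                          aligned_shifts_deg = aligned,
                          scale_factors = scales, n_valid_halves = 0L,
                          ci95 = c(NA_real_, NA_real_),
                          category = "unclassified",
                          predicted_shift_deg = predicted_shift_deg),
                     class = "pursuit_di_result")
    attr(res, "diagnostic") <- "no valid half-range shifts"
    return(res)
  }
  res <- structure(list(di = mean(aligned) / predicted_shift_deg,
                        half_shifts_deg = shifts,
                        aligned_shifts_deg = aligned,
                        scale_factors = scales,
                        n_valid_halves = sum(valid),
                        ci95 = c(NA_real_, NA_real_),
                        category = NA_character_,
                        predicted_shift_deg = predicted_shift_deg),
                   class = "pursuit_di_result")
  if (untested) attr(res, "untested_significance") <- TRUE
  res
}

#' Classify pursuit compensation from a DI confidence interval
#'
#' * complete_compensation: CI includes 0 but not 1
#' * complete_shift: CI includes 1 but not 0
#' * partial: CI strictly inside (0, 1)
#' * unclassified: anything else
#'
#' @param di point estimate (stored, not used by the rules).
#' @param ci95 numeric length-2 bootstrap confidence interval.
#' @return one of `"complete_compensation"`, `"complete_shift"`,
#'   `"partial"`, `"unclassified"`.
#' @export
classify_pursuit <- function(di, ci95) {
  switch(classify_frame(di, ci95),
         head = "complete_compensation",
         eye = "complete_shift",
         intermediate = "partial",
         "unclassified")
}

#' Pursuit displacement index for one neuron, end to end
#'
#' Builds the three pursuit-condition tuning curves from a trial table and
#' applies either the 3-step partial-shift procedure (default) or, for
#' comparison, the same cross-covariance method as the eccentric-fixation
#' DI (lag of maximal covariance between pursuit and no-pursuit curves,
#' sign-aligned over directions, divided by the predicted shift).
#' Optionally bootstraps a 95% CI by resampling repetitions within each
#' (pursuit direction x heading) cell.
#'
#' @param trials a [trial_table()] holding the pursuit block.
#' @param neuron_id neuron identifier.
#' @param method `"partial_shift"` or `"xcov"`.
#' @param predicted_shift_deg DI denominator (default 30).
#' @param n_boot bootstrap replicates (0 to skip).
#' @param seed RNG seed for the bootstrap.
#' @param alpha significance level for the half gates.
#' @return a `pursuit_di_result`, with `ci95` and `category` filled in
#'   when `n_boot > 0`.
#' @export
pursuit_displacement <- function(trials, neuron_id,
                                 method = c("partial_shift", "xcov"),
                                 predicted_shift_deg = 30, n_boot = 0,
                                 seed = NULL, alpha = 0.05) {
  method <- match.arg(method)
  get_curves <- function(tab) {
    dirs <- c("none", "leftward", "rightward")
    stats::setNames(lapply(dirs, function(d) {
      tryCatch(build_tuning(tab, neuron_id, "visual",
                            list(protocol = "pursuit", pursuit_dir = d)),
               error = function(e) NULL)
    }), dirs)
  }
  compute <- function(cv) {
    if (is.null(cv$none)) stop("no-pursuit condition missing")
    if (method == "partial_shift") {
      pursuit_di(cv$none, cv$leftward, cv$rightward,
                 predicted_shift_deg, alpha)
    } else {
      dense0 <- interpolate_circular(cv$none)$values
      lags <- c()
      for (dir in c("leftward", "rightward")) {
        if (is.null(cv[[dir]])) next
        dp <- interpolate_circular(cv[[dir]])$values
        lag <- best_lag(xcov_circular(dense0, dp))
        lags[dir] <- lag * if (dir == "leftward") 1 else -1
      }
      structure(list(di = mean(lags) / predicted_shift_deg,
                     half_shifts_deg = lags, aligned_shifts_deg = lags,
                     scale_factors = NULL, n_valid_halves = length(lags),
                     ci95 = c(NA_real_, NA_real_),
                     category = NA_character_,
                     predicted_shift_deg = predicted_shift_deg),
                class = "pursuit_di_result")
    }
  }
  res <- compute(get_curves(trials))
  if (n_boot > 0) {
    df <- as.data.frame(trials)
    df <- df[df$neuron_id == neuron_id & df$protocol == "pursuit", ,
             drop = FALSE]
    boot_dis <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      rs <- do.call(rbind, lapply(split(df, list(df$pursuit_dir,
                                                 df$heading_deg),
                                        drop = TRUE), function(cell) {
        cell[sample.int(nrow(cell), replace = TRUE), , drop = FALSE]
      }))
      rs$repetition <- stats::ave(seq_len(nrow(rs)),
                                  rs$pursuit_dir, rs$heading_deg,
                                  FUN = seq_along)
      tryCatch(compute(get_curves(trial_table(rs)))$di,
               error = function(e) NA_real_)
    }, 0))
    keep <- boot_dis[!is.na(boot_dis)]
    if (length(keep) > 0) {
      res$ci95 <- unname(stats::quantile(keep, c(0.025, 0.975)))
      res$category <- classify_pursuit(res$di, res$ci95)
    }
  }
  res
}

#' @export
print.pursuit_di_result <- function(x, ...) {
  cat(sprintf("Pursuit DI = %.3f from %d half-shift(s)",
              x$di, x$n_valid_halves))
  if (!anyNA(x$ci95))
    cat(sprintf(", 95%% CI [%.3f, %.3f] -> %s",
                x$ci95[1], x$ci95[2], x$category))
  cat("\n")
  invisible(x)
}
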