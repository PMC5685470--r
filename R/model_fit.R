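#' Modified wrapped-Gaussian tuning function
#'
#' Evaluates
#' \deqn{R(\theta) = A_1 [ e^{-2(1-\cos(\theta-\theta_p))/(\sigma^2 \kappa)}
#'   + A_2\, e^{-2(1-\cos(\theta-\theta_p-180^\circ))/\sigma^2} ] + R_0}
#' a 360-degree-periodic bell with an optional second peak 180 degrees out
#' of phase.  `kappa` scales the width of the first peak only, so the
#' relative widths of the two peaks are set by `kappa`.
#'
#' @param heading_deg heading angle(s) in degrees.
#' @param params named list or vector with `theta_p_deg`, `sigma`, `A1`,
#'   `A2`, `kappa`, `R0`.
#' @return firing rate(s) in spikes/s.
#' @export
wrapped_gaussian <- function(heading_deg, params) {
  p <- as.list(params)
  d <- (heading_deg - p$theta_p_deg) * pi / 180
  p$A1 * (exp(-2 * (1 - cos(d)) / (p$sigma^2 * p$kappa)) +
            p$A2 * exp(-2 * (1 - cos(d - pi)) / p$sigma^2)) + p$R0
}

# Predicted rates of the 16-parameter joint model.
# p = c(theta0, then per eye position: A1, sigma, kappa, A2, R0)
joint_predict <- function(p, headings, eye_positions, model) {
  lapply(seq_along(eye_positions), function(e) {
    base <- 1 + (e - 1) * 5
    peak <- p[1] + if (model == "eye") eye_positions[e] else 0
    wrapped_gaussian(headings[[e]],
                     list(theta_p_deg = peak, A1 = p[base + 1],
                          sigma = p[base + 2], kappa = p[base + 3],
                          A2 = p[base + 4], R0 = p[base + 5]))
  })
}

#' Joint wrapped-Gaussian fit across eye positions
#'
#' Fits the tuning curves measured at the three eye positions
#' simultaneously with a single 16-parameter model: one shared preferred
#' direction `theta0` plus per-eye-position `A1, sigma, kappa, A2, R0`.
#' Under the eye-centered model the peak at eye position *P* is
#' `theta0 + P`; under the head-centered model it is `theta0` at every eye
#' position.  Least squares with bounded quasi-Newton optimisation and
#' multi-start: `theta0` is initialised at each curve's best heading and
#' its antipode, plus seeded random restarts.
#'
#' @param curves list of `tuning_curve`s whose `label$eye_pos_deg` give the
#'   eye positions (or pass `eye_positions`).
#' @param model `"eye"` or `"head"`.
#' @param eye_positions optional numeric vector overriding the labels.
#' @param n_restarts total number of optimisation starts (default 20).
#' @param seed seed for the random restarts.
#' @return a `joint_fit` object: `model`, `theta0_deg` (wrapped),
#'   `params` (3 x 5 matrix, rows = eye positions), `r2` (squared Pearson
#'   correlation between fitted and observed mean rates), `sse`,
#'   `predictions` (fitted values at the data headings), `converged`.
#' @export
fit_joint <- function(curves, model = c("eye", "head"),
                      eye_positions = NULL, n_restarts = 20, seed = NULL) {
  model <- match.arg(model)
  if (is.null(eye_positions))
    eye_positions <- vapply(curves, function(cv) cv$label$eye_pos_deg, 0)
  stopifnot(length(curves) == length(eye_positions))
  headings <- lapply(curves, `[[`, "headings_deg")
  if (any(lengths(headings) < 5))
    stop("need at least 5 headings per curve for a joint fit")
  obs_list <- lapply(curves, `[[`, "mean_rate_hz")
  obs <- unlist(obs_list)
  max_rate <- max(obs)
  if (max_rate <= 0 || stats::var(obs) == 0)
    stop("fit failure: flat tuning curves")

  ne <- length(eye_positions)
  lower <- c(-90, rep(c(1e-3, 0.1, 0.1, 0, 0), ne))
  upper <- c(450, rep(c(3 * max_rate, 10, 10, 1, max_rate), ne))

  objective <- function(p) {
    pred <- unlist(joint_predict(p, headings, eye_positions, model))
    sum((pred - obs)^2)
  }
  # analytic gradient of the SSE; keeps L-BFGS-B iterations cheap
  gradient <- function(p) {
    g <- numeric(length(p))
    for (e in seq_len(ne)) {
      base <- 1 + (e - 1) * 5
      A1 <- p[base + 1]; sg <- p[base + 2]; kp <- p[base + 3]
      A2 <- p[base + 4]
      peak <- p[1] + if (model == "eye") eye_positions[e] else 0
      d <- (headings[[e]] - peak) * pi / 180
      E1 <- exp(-2 * (1 - cos(d)) / (sg^2 * kp))
      E2 <- exp(-2 * (1 + cos(d)) / sg^2)   # cos(d - pi) = -cos(d)
      pred <- A1 * (E1 + A2 * E2) + p[base + 5]
      r2e <- 2 * (pred - obs_list[[e]])
      dE1_dd <- E1 * (-2 * sin(d) / (sg^2 * kp))
      dE2_dd <- E2 * (2 * sin(d) / sg^2)
      g[1] <- g[1] + sum(r2e * A1 * (dE1_dd + A2 * dE2_dd)) * (-pi / 180)
      g[base + 1] <- sum(r2e * (E1 + A2 * E2))
      g[base + 2] <- sum(r2e * A1 *
                           (E1 * 4 * (1 - cos(d)) / (sg^3 * kp) +
                              A2 * E2 * 4 * (1 + cos(d)) / sg^3))
      g[base + 3] <- sum(r2e * A1 * E1 * 2 * (1 - cos(d)) / (sg^2 * kp^2))
      g[base + 4] <- sum(r2e * A1 * E2)
      g[base + 5] <- sum(r2e)
    }
    g
  }

  per_curve_init <- function(theta0) {
    unlist(lapply(seq_len(ne), function(e) {
      v <- obs_list[[e]]
      amp <- max(1e-2, max(v) - min(v))
      c(amp, 1.5, 1, 0.01, max(0, min(v)))
    }))
  }
  # theta0 starts: each curve's argmax mapped back to the shared frame,
  # plus antipodes
  starts <- unlist(lapply(seq_len(ne), function(e) {
    pk <- headings[[e]][which.max(obs_list[[e]])]
    th <- pk - if (model == "eye") eye_positions[e] else 0
    c(th, th + 180)
  }))
  starts <- unique(wrap360(starts))
  extra <- max(0, n_restarts - length(starts))
  if (extra > 0)
    starts <- c(starts, with_seed(seed, stats::runif(extra, 0, 360)))
  starts <- starts[seq_len(min(length(starts), max(n_restarts, 1)))]

  best <- NULL
  for (th0 in starts) {
    p0 <- pmin(pmax(c(th0, per_curve_init(th0)), lower), upper)
    fit <- tryCatch(
      stats::optim(p0, objective, gradient, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e5)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("fit failure: no optimisation start converged")

  pred <- unlist(joint_predict(best$par, headings, eye_positions, model))
  r2 <- if (stats::sd(pred) < 1e-12) 0 else stats::cor(pred, obs)^2
  params <- matrix(best$par[-1], nrow = ne, byrow = TRUE,
                   dimnames = list(paste0("eye_", eye_positions),
                                   c("A1", "sigma", "kappa", "A2", "R0")))
  structure(list(model = model, theta0_deg = wrap360(best$par[1]),
                 params = params, eye_positions = eye_positions,
                 r2 = r2, sse = best$value, predictions = pred,
                 converged = best$convergence == 0, n_free = 1 + 5 * ne),
            class = "joint_fit")
}

#' Goodness-of-fit filter
#'
#' Data whose best model explains the tuning poorly are excluded from the
#' model comparison.
#'
#' @param r2 squared correlation of the best-fitting model.
#' @param threshold exclusion threshold (default 0.6, boundary inclusive:
#'   `r2 = 0.6` is kept).
#' @return `TRUE` to keep, `FALSE` to exclude.
#' @export
goodness_filter <- function(r2, threshold = 0.6) {
  r2 >= threshold
}

#' Partial correlations between data and two competing models
#'
#' Removes the component of each model's fit that is explained by the
#' competing model:
#' \deqn{R_e = (r_e - r_h r_{eh}) / \sqrt{(1 - r_h^2)(1 - r_{eh}^2)}}
#' and symmetrically for \eqn{R_h}.
#'
#' @param data observed mean rates (all conditions concatenated).
#' @param eye_pred,head_pred model predictions at the same conditions.
#' @return list with `R_e`, `R_h` and the plain correlations `r_e`, `r_h`,
#'   `r_eh`.
#' @export
partial_correlations <- function(data, eye_pred, head_pred) {
  stopifnot(length(data) == length(eye_pred),
            length(data) == length(head_pred))
  r_e <- stats::cor(data, eye_pred)
  r_h <- stats::cor(data, head_pred)
  r_eh <- stats::cor(eye_pred, head_pred)
  if (!is.finite(r_eh) || abs(r_eh) >= 1 - 1e-12)
    stop("degenerate models: eye and head predictions are collinear")
  partial <- function(num, den2) {
    # algebraic limit: data equal to one prediction makes the competing
    # partial 0/0, which resolves to 0
    if (den2 < 1e-24) return(if (abs(num) < 1e-9) 0 else sign(num))
    num / sqrt(den2)
  }
  R_e <- partial(r_e - r_h * r_eh, (1 - r_h^2) * (1 - r_eh^2))
  R_h <- partial(r_h - r_e * r_eh, (1 - r_e^2) * (1 - r_eh^2))
  list(R_e = R_e, R_h = R_h, r_e = r_e, r_h = r_h, r_eh = r_eh)
}

#' Fisher r-to-Z transform
#'
#' `Z = atanh(R) * sqrt(n - 3)`, so Z-scores are comparable across fits
#' with different numbers of points and 1.645 corresponds to one-tailed
#' p = 0.05 under the normal approximation.  Set `scaled = FALSE` for the
#' raw `atanh` variant.
#'
#' @param R (partial) correlation coefficient.
#' @param n_points number of data points (must exceed 3 when `scaled`).
#' @param scaled apply the `sqrt(n - 3)` factor (default TRUE).
#' @return the Z-score; out-of-range `|R| >= 1` is clipped to
#'   `1 - 1e-6` with attribute `clipped = TRUE`.
#' @export
fisher_z <- function(R, n_points, scaled = TRUE) {
  clipped <- FALSE
  if (abs(R) >= 1) {
    R <- sign(R) * (1 - 1e-6)
    clipped <- TRUE
  }
  if (scaled && n_points <= 3)
    stop("fisher_z with scaling requires n_points > 3")
  z <- atanh(R) * if (scaled) sqrt(n_points - 3) else 1
  if (clipped) attr(z, "clipped") <- TRUE
  z
}

#' Classify a neuron's reference frame from model Z-scores
#'
#' @param Z_e,Z_h Fisher-Z-transformed partial correlations of the eye- and
#'   head-centered fits.
#' @param criterion Z-difference criterion; the default 1.645 is the
#'   one-tailed normal 95% point (p = 0.05).
#' @return `"eye"`, `"head"` or `"unclassified"`.
#' @export
classify_model <- function(Z_e, Z_h, criterion = 1.645) {
  if (Z_e - Z_h >= criterion) "eye"
  else if (Z_h - Z_e >= criterion) "head"
  else "unclassified"
}

#' Full eye- vs head-centered model comparison for one neuron
#'
#' Fits both joint models, computes partial correlations of each fit with
#' the concatenated mean rates, Fisher-Z transforms them, applies the
#' goodness-of-fit exclusion and the Z-difference criterion.
#'
#' @inheritParams fit_joint
#' @param r2_threshold exclusion threshold for the best model's fit.
#' @param criterion classification criterion on `Z_e - Z_h`.
#' @return a `model_comparison` object: both `joint_fit`s, `R_e`, `R_h`,
#'   `Z_e`, `Z_h`, `z_diff`, `category`, `excluded` (+ `exclude_reason`).
#' @export
compare_models <- function(curves, eye_positions = NULL, n_restarts = 20,
                           seed = NULL, r2_threshold = 0.6,
                           criterion = 1.645) {
  fit_e <- fit_joint(curves, "eye", eye_positions, n_restarts,
                     derive_seed(seed, 1))
  fit_h <- fit_joint(curves, "head", eye_positions, n_restarts,
                     derive_seed(seed, 2))
  data <- unlist(lapply(curves, `[[`, "mean_rate_hz"))
  pc <- partial_correlations(data, fit_e$predictions, fit_h$predictions)
  n <- length(data)
  Z_e <- fisher_z(pc$R_e, n)
  Z_h <- fisher_z(pc$R_h, n)
  best_r2 <- max(fit_e$r2, fit_h$r2)
  excluded <- !goodness_filter(best_r2, r2_threshold)
  structure(list(fit_eye = fit_e, fit_head = fit_h,
                 r_e = pc$r_e, r_h = pc$r_h, r_eh = pc$r_eh,
                 R_e = pc$R_e, R_h = pc$R_h,
                 Z_e = as.numeric(Z_e), Z_h = as.numeric(Z_h),
                 z_diff = as.numeric(Z_e) - as.numeric(Z_h),
                 n_points = n, best_r2 = best_r2, excluded = excluded,
                 exclude_reason = if (excluded)
                   sprintf("best r2 %.3f < %.2f", best_r2, r2_threshold)
                 else NA_character_,
                 category = if (excluded) "excluded"
                 else classify_model(as.numeric(Z_e), as.numeric(Z_h),
                                     criterion)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "Model comparison: Z_e = %.2f, Z_h = %.2f (diff %.2f) -> %s%s\n",
    x$Z_e, x$Z_h, x$z_diff, x$category,
    if (x$excluded) paste0(" [", x$exclude_reason, "]") else ""))
  invisible(x)
}
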