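#' Generative parameters for a synthetic heading-tuned neuron
#'
#' Describes a wrapped-Gaussian-tuned neuron whose preferred direction at
#' eye position *P* is `theta_p_deg + lambda_frame * P`: `lambda_frame = 0`
#' yields head-centered and `lambda_frame = 1` eye-centered tuning, with
#' intermediate (and modestly over-shifting) frames in between.  Responses
#' can be multiplicatively gain-modulated by eye position and corrupted by
#' trial noise; under pursuit the two half-range curves shift by
#' `(1 - pursuit_comp) * 30` degrees in opposite directions.
#'
#' @param theta_p_deg preferred heading at central fixation (deg).
#' @param sigma tuning width of the wrapped Gaussian (dimensionless; ~1
#'   corresponds to a half-width of roughly 60 deg).
#' @param A1 response amplitude (spikes/s), > 0.
#' @param A2 relative weight of the second peak 180 deg out of phase, in
#'   `[0, 1]`.
#' @param kappa relative width of the first peak, > 0.
#' @param R0 baseline rate (spikes/s), >= 0.
#' @param lambda_frame frame parameter in `[-0.5, 1.5]`.
#' @param gain list `(kind, strength, center)`: `kind` one of `"none"`,
#'   `"monotonic"`, `"nonmonotonic"`; `strength` is the fractional
#'   modulation per 20 deg of eye displacement; `center` (`"max"`/`"min"`)
#'   selects whether a non-monotonic field peaks or dips at central
#'   fixation.
#' @param noise list `(kind, fano)`: `kind` one of `"none"`,
#'   `"gaussian_fano"` (Gaussian with variance `fano * mean`, clipped at
#'   0), `"poisson"` (1 s spike counts).
#' @param pursuit_comp pursuit compensation `c` in `[0, 1]`; 1 = complete
#'   compensation (tuning unchanged by pursuit).
#' @return a `neuron_spec` object.
#' @export
neuron_spec <- function(theta_p_deg = 90, sigma = 1.2, A1 = 50, A2 = 0,
                        kappa = 1, R0 = 10, lambda_frame = 1,
                        gain = list(kind = "none", strength = 0,
                                    center = "max"),
                        noise = list(kind = "gaussian_fano", fano = 1.5),
                        pursuit_comp = 1) {
  stopifnot(A1 > 0, sigma > 0, kappa > 0, R0 >= 0,
            A2 >= 0, A2 <= 1,
            lambda_frame >= -0.5, lambda_frame <= 1.5,
            pursuit_comp >= 0, pursuit_comp <= 1)
  gain <- utils::modifyList(list(kind = "none", strength = 0,
                                 center = "max"), gain)
  noise <- utils::modifyList(list(kind = "gaussian_fano", fano = 1.5), noise)
  stopifnot(gain$kind %in% c("none", "monotonic", "nonmonotonic"),
            gain$center %in% c("max", "min"),
            noise$kind %in% c("none", "gaussian_fano", "poisson"))
  structure(list(theta_p_deg = wrap360(theta_p_deg), sigma = sigma,
                 A1 = A1, A2 = A2, kappa = kappa, R0 = R0,
                 lambda_frame = lambda_frame, gain = gain, noise = noise,
                 pursuit_comp = pursuit_comp),
            class = "neuron_spec")
}

# Multiplicative gain factor for one eye position (floored at 0).
gain_factor <- function(gain, eye_pos_deg) {
  f <- switch(gain$kind,
              none = rep(1, length(eye_pos_deg)),
              monotonic = 1 + gain$strength * eye_pos_deg / 20,
              nonmonotonic = {
                s <- if (gain$center == "max") -1 else 1
                1 + s * gain$strength * abs(eye_pos_deg) / 20
              })
  pmax(f, 0)
}

#' Noiseless mean firing rate of a synthetic neuron
#'
#' Wrapped-Gaussian tuning with the preferred direction displaced by
#' `lambda_frame * eye_pos_deg` and multiplied by the eye-position gain
#' factor.
#'
#' @param spec a [neuron_spec()].
#' @param heading_deg heading(s) in degrees.
#' @param eye_pos_deg static eye position in degrees.
#' @return mean rate(s) in spikes/s.
#' @export
mean_rate <- function(spec, heading_deg, eye_pos_deg = 0) {
  p <- list(theta_p_deg = spec$theta_p_deg +
              spec$lambda_frame * eye_pos_deg,
            sigma = spec$sigma, A1 = spec$A1, A2 = spec$A2,
            kappa = spec$kappa, R0 = spec$R0)
  wrapped_gaussian(heading_deg, p) * gain_factor(spec$gain, eye_pos_deg)
}

# Draw noisy trial rates around a vector of means.
apply_noise <- function(mu, noise) {
  switch(noise$kind,
         none = mu,
         gaussian_fano = pmax(0, stats::rnorm(length(mu), mu,
                                              sqrt(noise$fano * mu))),
         poisson = stats::rpois(length(mu), mu))
}

#' Simulate an eccentric-fixation recording block
#'
#' Emits a trial table with `reps` noisy repetitions of every
#' heading-by-eye-position condition of the grid.
#'
#' @param spec a [neuron_spec()].
#' @param grid a [condition_grid()].
#' @param reps repetitions per condition (>= 1).
#' @param seed RNG seed; identical seeds give identical tables.
#' @param neuron_id,modality identifiers written into the table.
#' @return a [trial_table()] with protocol `"eccentric_fixation"`.
#' @export
simulate_fixation_block <- function(spec, grid = condition_grid(),
                                    reps = 5, seed = NULL,
                                    neuron_id = "syn1",
                                    modality = "visual") {
  stopifnot(reps >= 1)
  cells <- expand.grid(heading_deg = grid$headings_deg,
                       eye_pos_deg = grid$eye_positions_deg,
                       repetition = seq_len(reps),
                       KEEP.OUT.ATTRS = FALSE)
  mu <- mean_rate(spec, cells$heading_deg, cells$eye_pos_deg)
  rate <- with_seed(seed, apply_noise(mu, spec$noise))
  trial_table(data.frame(neuron_id = neuron_id, modality = modality,
                         protocol = "eccentric_fixation",
                         eye_pos_deg = cells$eye_pos_deg,
                         pursuit_dir = "none",
                         heading_deg = cells$heading_deg,
                         repetition = cells$repetition,
                         rate_hz = rate,
                         stringsAsFactors = FALSE))
}

# Pursuit-condition mean: the no-pursuit mean restricted to each half
# heading range ([0,180) / [180,360)) is circularly shifted within that
# half by `shift_A` / `shift_B` degrees.
pursuit_mean <- function(spec, heading_deg, shift_A, shift_B) {
  h <- wrap360(heading_deg)
  inA <- h < 180
  out <- numeric(length(h))
  out[inA] <- mean_rate(spec, (h[inA] - shift_A) %% 180, 0)
  out[!inA] <- mean_rate(spec, 180 + (h[!inA] - 180 - shift_B) %% 180, 0)
  out
}

#' Simulate a smooth-pursuit recording block
#'
#' Generates three interleaved conditions: no-pursuit (central fixation),
#' leftward and rightward pursuit.  The pursuit distortion is produced
#' directly as the quantity the partial-shift analysis measures: the two
#' half-range curves (`[0,180)` and `[180,360)`) of the no-pursuit tuning
#' are circularly shifted within their half by `(1 - pursuit_comp) *
#' predicted_shift_deg` degrees, with opposite signs for the two halves and
#' for the two pursuit directions.  The default 1-degree heading grid
#' represents that construct exactly; pass a coarser grid (e.g. 45-degree
#' steps) to emulate a realistic session, at the cost of
#' interpolation-induced distortion that the analysis then inherits.
#'
#' @param spec a [neuron_spec()] (uses `pursuit_comp`).
#' @param headings_deg heading grid (default 1-degree resolution).
#' @param reps repetitions per condition.
#' @param seed RNG seed.
#' @param predicted_shift_deg predicted full shift of resultant optic flow
#'   (default 30).
#' @param neuron_id identifier written into the table.
#' @return a [trial_table()] with protocol `"pursuit"`, modality
#'   `"visual"`, and `pursuit_dir` in none/leftward/rightward.
#' @export
simulate_pursuit_block <- function(spec, headings_deg = 0:359, reps = 5,
                                   seed = NULL, predicted_shift_deg = 30,
                                   neuron_id = "syn1") {
  stopifnot(reps >= 1)
  delta <- (1 - spec$pursuit_comp) * predicted_shift_deg
  mu_by_dir <- list(
    none = mean_rate(spec, headings_deg, 0),
    leftward = pursuit_mean(spec, headings_deg, delta, -delta),
    rightward = pursuit_mean(spec, headings_deg, -delta, delta))
  rows <- do.call(rbind, lapply(names(mu_by_dir), function(dir) {
    expand.grid(heading_idx = seq_along(headings_deg),
                repetition = seq_len(reps), pursuit_dir = dir,
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  mu <- unlist(lapply(names(mu_by_dir), function(dir)
    rep(mu_by_dir[[dir]], times = reps)))
  rate <- with_seed(seed, apply_noise(mu, spec$noise))
  trial_table(data.frame(neuron_id = neuron_id, modality = "visual",
                         protocol = "pursuit", eye_pos_deg = 0,
                         pursuit_dir = rows$pursuit_dir,
                         heading_deg = headings_deg[rows$heading_idx],
                         repetition = rows$repetition,
                         rate_hz = rate,
                         stringsAsFactors = FALSE))
}

#' Gaussian motion-velocity profile
#'
#' The translational stimulus follows a smooth trajectory with a
#' Gaussian-shaped velocity bell.  By default the bell's width is derived
#' from the stated peak velocity via the closed form
#' `V = D / (sigma * sqrt(2*pi))`; alternatively fix the truncation at
#' `truncation_sigmas` standard deviations within the window.
#'
#' @param duration_s stimulus duration (default 2 s).
#' @param distance_m travel distance (default 0.11 m).
#' @param peak_velocity_mps peak velocity used to derive the bell width
#'   (default 0.25 m/s); ignored when `truncation_sigmas` is given.
#' @param truncation_sigmas optional half-width of the window in SD units.
#' @param n number of samples of the velocity trace.
#' @return a `motion_profile`: `t_s`, `velocity_mps`, `duration_s`,
#'   `distance_m`, `peak_velocity_mps`, `peak_accel_mps2`.
#' @export
gaussian_velocity_profile <- function(duration_s = 2, distance_m = 0.11,
                                      peak_velocity_mps = 0.25,
                                      truncation_sigmas = NULL, n = 2001) {
  stopifnot(duration_s > 0, distance_m > 0, n > 10)
  sigma <- if (!is.null(truncation_sigmas)) {
    stopifnot(truncation_sigmas > 0)
    duration_s / (2 * truncation_sigmas)
  } else {
    stopifnot(peak_velocity_mps > 0)
    distance_m / (peak_velocity_mps * sqrt(2 * pi))
  }
  t <- seq(0, duration_s, length.out = n)
  centre <- duration_s / 2
  # mass lost to truncation is renormalised so the integral equals distance
  mass <- 2 * stats::pnorm(centre / sigma) - 1
  v <- distance_m * stats::dnorm(t, centre, sigma) / mass
  dt <- t[2] - t[1]
  structure(list(t_s = t, velocity_mps = v,
                 duration_s = duration_s, distance_m = distance_m,
                 peak_velocity_mps = max(v),
                 peak_accel_mps2 = max(abs(diff(v)) / dt)),
            class = "motion_profile")
}

#' Simulate heading-estimation behaviour
#'
#' Reported heading = true heading + `bias_deg_per_eye * eye_pos_deg` +
#' wrapped Gaussian noise.  A bias gain of 1 reproduces a fully
#' eye-referenced reporter (20-degree error at 20-degree fixation); trained
#' animals retain a residual gain of roughly 0.1-0.2.  Saccade endpoints on
#' the choice ring (centred on the fixation) are emitted alongside the
#' reported heading so the endpoint-decoding path can be exercised.
#'
#' @param bias_deg_per_eye eye-position bias gain (degrees of report error
#'   per degree of fixation eccentricity).
#' @param noise_sd_deg SD of the circular report noise (default 10).
#' @param grid estimation schedule grid (see [estimation_schedule()]).
#' @param reps repetitions per condition (default 5).
#' @param seed RNG seed.
#' @param ring_diameter_deg choice-ring diameter (default 20).
#' @return data.frame of `true_heading_deg`, `eye_pos_deg`, `repetition`,
#'   `reported_heading_deg`, `endpoint_x_deg`, `endpoint_y_deg`.
#' @export
simulate_behavior <- function(bias_deg_per_eye = 0.15, noise_sd_deg = 10,
                              grid = condition_grid(seq(0, 340, by = 20),
                                                    c(-20, 0, 20)),
                              reps = 5, seed = NULL,
                              ring_diameter_deg = 20) {
  sched <- estimation_schedule(grid)
  cells <- sched[rep(seq_len(nrow(sched)), each = reps), ]
  cells$repetition <- rep(seq_len(reps), times = nrow(sched))
  noise <- with_seed(seed,
                     if (noise_sd_deg > 0)
                       stats::rnorm(nrow(cells), 0, noise_sd_deg)
                     else numeric(nrow(cells)))
  reported <- wrap360(cells$heading_deg +
                        bias_deg_per_eye * cells$eye_pos_deg + noise)
  radius <- ring_diameter_deg / 2
  ang <- reported * pi / 180
  data.frame(true_heading_deg = cells$heading_deg,
             eye_pos_deg = cells$eye_pos_deg,
             repetition = cells$repetition,
             reported_heading_deg = reported,
             endpoint_x_deg = cells$eye_pos_deg + radius * cos(ang),
             endpoint_y_deg = radius * sin(ang),
             row.names = NULL)
}

#' Generate a population of synthetic neurons
#'
#' Draws neuron specs with preferred headings uniform on the circle and
#' mild heterogeneity in width, amplitude and baseline, then simulates an
#' eccentric-fixation block per neuron.  Used for distribution-level
#' validation (noise-robustness of the displacement index, model-recovery
#' rates).
#'
#' @param n_neurons number of neurons (0 allowed).
#' @param lambda_frame frame parameter: scalar, vector of length
#'   `n_neurons`, or a function `n -> numeric(n)`.
#' @param fano Fano factor of the Gaussian trial noise (0 for noiseless).
#' @param grid a [condition_grid()].
#' @param reps repetitions per condition.
#' @param seed RNG seed (drives both the spec draws and the trial noise).
#' @param modality modality label.
#' @return list with `specs` (list of [neuron_spec()]) and `trials`
#'   (one combined [trial_table()]; `NULL` when `n_neurons = 0`).
#' @export
generate_population <- function(n_neurons, lambda_frame = 1, fano = 1.5,
                                grid = condition_grid(), reps = 5,
                                seed = NULL, modality = "visual") {
  if (n_neurons == 0) return(list(specs = list(), trials = NULL))
  lam <- if (is.function(lambda_frame)) {
    with_seed(derive_seed(seed, 99), lambda_frame(n_neurons))
  } else rep_len(lambda_frame, n_neurons)
  noise <- if (fano > 0) list(kind = "gaussian_fano", fano = fano)
           else list(kind = "none")
  specs <- with_seed(derive_seed(seed, 1), {
    lapply(seq_len(n_neurons), function(i)
      neuron_spec(theta_p_deg = stats::runif(1, 0, 360),
                  sigma = stats::runif(1, 0.9, 1.8),
                  A1 = stats::runif(1, 30, 80),
                  A2 = if (stats::runif(1) < 0.15)
                         stats::runif(1, 0.2, 0.6) else 0,
                  kappa = stats::runif(1, 0.7, 1.4),
                  R0 = stats::runif(1, 0, 15),
                  lambda_frame = lam[i], noise = noise))
  })
  ids <- sprintf("syn%04d", seq_len(n_neurons))
  tabs <- lapply(seq_len(n_neurons), function(i)
    simulate_fixation_block(specs[[i]], grid, reps,
                            seed = derive_seed(seed, 1000 + i),
                            neuron_id = ids[i], modality = modality))
  trials <- do.call(rbind, lapply(tabs, as.data.frame))
  list(specs = stats::setNames(specs, ids), trials = trial_table(trials))
}
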