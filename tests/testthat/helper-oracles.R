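# Independent brute-force oracles, kept deliberately naive so they cannot
# share code paths (or bugs) with the package implementation.

# Direct term-by-term evaluation of the modified wrapped Gaussian.
oracle_wg <- function(th, thp, sigma, A1, A2, kappa, R0) {
  sapply(th, function(t) {
    d <- (t - thp) * pi / 180
    e1 <- exp(-2 * (1 - cos(d)) / (sigma^2 * kappa))
    e2 <- exp(-2 * (1 - cos(d - pi)) / sigma^2)
    A1 * (e1 + A2 * e2) + R0
  })
}

# Exhaustive-search circular cross-covariance argmax on dense curves,
# lag in [-180, 180], ties -> smallest |k| then negative first.
oracle_best_lag <- function(x, y) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  ks <- -(n / 2 - 1):(n / 2)
  cc <- sapply(ks, function(k) {
    idx <- ((seq_len(n) - 1 + k) %% n) + 1
    sum(x * y[idx])
  })
  tol <- 1e-9 * (max(abs(cc)) + 1)
  cand <- ks[cc >= max(cc) - tol]
  cand[order(abs(cand), cand)][1]
}

# Exhaustive half-range shift search (correlation, shift ref right by k).
oracle_half_shift <- function(r, p, max_shift = 90) {
  n <- length(r)
  ks <- -max_shift:max_shift
  cors <- sapply(ks, function(k) {
    shifted <- r[((seq_len(n) - 1 - k) %% n) + 1]
    suppressWarnings(cor(shifted, p))
  })
  cand <- ks[cors >= max(cors) - 1e-9]
  cand[order(abs(cand), cand)][1]
}

# Partial correlation via regression residuals (independent of the
# closed-form route used by the package).
oracle_partial_cor <- function(data, pred, other) {
  rd <- resid(lm(data ~ other))
  rp <- resid(lm(pred ~ other))
  cor(rd, rp)
}

# Circular SD from the resultant length, step by step.
oracle_circ_sd <- function(deg) {
  r <- deg * pi / 180
  C <- sum(cos(r)) / length(r)
  S <- sum(sin(r)) / length(r)
  sqrt(-2 * log(sqrt(C^2 + S^2))) * 180 / pi
}

# Random smooth tuning samples on a grid (wrapped Gaussian + optional
# roughness) for property tests.
random_curve_values <- function(grid, rough = 0) {
  v <- oracle_wg(grid, runif(1, 0, 360), runif(1, 0.8, 2),
                 runif(1, 20, 80), ifelse(runif(1) < 0.3, runif(1), 0),
                 runif(1, 0.5, 2), runif(1, 0, 20))
  if (rough > 0) v <- v + rnorm(length(v), 0, rough)
  v
}

make_curve <- function(grid, values, eye_pos = 0) {
  tuning_curve(grid, as.list(values), label = list(eye_pos_deg = eye_pos))
}

# Small deterministic per-id seed for parameterised loops.
derive_seed_for_test <- function(base, id) {
  (base * 1009 + sum(utf8ToInt(as.character(id)))) %% 2000000000
}
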