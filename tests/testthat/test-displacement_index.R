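grid8 <- seq(0, 315, by = 45)

test_that("interpolate_circular wraps the circle and preserves samples", {
  v <- oracle_wg(grid8, 100, 1.3, 50, 0, 1, 5)
  dense <- interpolate_circular(make_curve(grid8, v))
  expect_equal(dense$values[grid8 + 1], v)
  expect_equal(length(dense$values), 360)

  # circular midpoint across the 360 -> 0 seam
  cv <- make_curve(c(10, 180, 350), c(20, 7, 10))
  expect_equal(interpolate_circular(cv)$values[1], 15)

  expect_error(interpolate_circular(make_curve(c(0, 90), c(1, 2))),
               "at least 3")
  dup <- list(headings_deg = c(0, 0, 90, 180), mean_rate_hz = c(1, 2, 3, 4))
  expect_error(interpolate_circular(dup), "conflicting")

  # interpolation error against dense evaluation is bounded for a smooth
  # wrapped Gaussian sampled at 45 degrees
  truth <- oracle_wg(0:359, 100, 1.3, 50, 0, 1, 5)
  expect_lt(max(abs(dense$values - truth)), 0.1 * diff(range(truth)))
})

test_that("pairwise_di calibrates to 0, 1 and fractional shifts", {
  for (thp in c(90, 37, 260)) {
    f <- function(shift) make_curve(grid8,
                                    oracle_wg(grid8, thp + shift, 1.2,
                                              50, 0, 1, 10))
    expect_equal(pairwise_di(f(0), f(0), -20, 0)$di, 0)
    expect_equal(pairwise_di(f(0), f(20), 0, 20)$di, 1)
    # half-displacement: exact up to the 1-degree lag grid under coarse
    # 45-degree sampling (the exhaustive oracle lands on the same lag)
    expect_lte(abs(pairwise_di(f(0), f(10), 0, 20)$di - 0.5), 0.05)
  }
  flat <- make_curve(grid8, rep(5, 8))
  expect_error(pairwise_di(flat, flat, 0, 20), "flat")
  expect_error(pairwise_di(flat, flat, 20, 20), "must differ")
})

test_that("pairwise_di lag matches the exhaustive-search oracle", {
  set.seed(31)
  for (i in 1:100) {
    xi <- random_curve_values(grid8, rough = runif(1, 0, 5))
    xj <- random_curve_values(grid8, rough = runif(1, 0, 5))
    ci <- make_curve(grid8, xi); cj <- make_curve(grid8, xj)
    di <- pairwise_di(ci, cj, 0, 20)
    ref <- oracle_best_lag(interpolate_circular(ci)$values,
                           interpolate_circular(cj)$values)
    expect_equal(di$lag_deg, as.numeric(ref))
  }
})

test_that("pairwise_di is symmetric and invariant to affine rescaling", {
  set.seed(17)
  for (i in 1:25) {
    ci <- make_curve(grid8, random_curve_values(grid8, rough = 2))
    cj <- make_curve(grid8, random_curve_values(grid8, rough = 2))
    expect_equal(pairwise_di(ci, cj, -20, 20)$di,
                 pairwise_di(cj, ci, 20, -20)$di)
    a <- runif(1, 0.2, 5); b <- runif(1, -10, 10)
    cj2 <- make_curve(grid8, a * cj$mean_rate_hz + b)
    expect_equal(pairwise_di(ci, cj2, -20, 20)$di,
                 pairwise_di(ci, cj, -20, 20)$di)
  }
})

test_that("neuron_di averages significant pairs and recovers lambda", {
  # noiseless lambda = 0.63 neuron: DI within the 1-degree shift grid
  spec <- neuron_spec(theta_p_deg = 77, lambda_frame = 0.63,
                      noise = list(kind = "none"))
  tab <- simulate_fixation_block(spec, reps = 2, seed = 1)
  curves <- lapply(c(-20, 0, 20), function(P)
    build_tuning(tab, "syn1", "visual", list(eye_pos_deg = P)))
  res <- neuron_di(curves, eye_positions = c(-20, 0, 20))
  expect_equal(res$n_pairs, 3)
  expect_lt(abs(res$di - 0.63), 0.05)
  expect_equal(res$di, mean(res$pair_dis$di))

  # noiseless recovery sweep over the frame parameter
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    s <- neuron_spec(theta_p_deg = 203, lambda_frame = lam,
                     noise = list(kind = "none"))
    tb <- simulate_fixation_block(s, reps = 2, seed = 1)
    cvs <- lapply(c(-20, 0, 20), function(P)
      build_tuning(tb, "syn1", "visual", list(eye_pos_deg = P)))
    expect_lte(abs(neuron_di(cvs, eye_positions = c(-20, 0, 20))$di - lam),
               0.05)
  }

  # only two of three curves significant -> a single pair
  flat_trials <- rep(list(rnorm(5, 20, 5)), 8)   # untuned
  set.seed(4)
  curves2 <- list(curves[[1]], curves[[2]],
                  tuning_curve(grid8, flat_trials,
                               label = list(eye_pos_deg = 20)))
  res2 <- neuron_di(curves2, eye_positions = c(-20, 0, 20))
  expect_equal(res2$n_pairs, 1)

  expect_error(neuron_di(list(curves[[1]],
                              tuning_curve(grid8, flat_trials,
                                           label = list(eye_pos_deg = 0))),
                         eye_positions = c(-20, 0)),
               "fewer than 2")
})

test_that("bootstrap_ci is deterministic under a seed and degenerate without noise", {
  spec <- neuron_spec(lambda_frame = 0.5, noise = list(kind = "none"))
  tab <- simulate_fixation_block(spec, reps = 3, seed = 1)
  bc <- bootstrap_ci(tab, "syn1", n_boot = 100, seed = 2)
  expect_equal(diff(bc$ci95), 0)

  noisy <- simulate_fixation_block(neuron_spec(lambda_frame = 0.5),
                                   reps = 5, seed = 3)
  b1 <- bootstrap_ci(noisy, "syn1", n_boot = 200, seed = 11)
  b2 <- bootstrap_ci(noisy, "syn1", n_boot = 200, seed = 11)
  expect_identical(b1$ci95, b2$ci95)
  b3 <- bootstrap_ci(noisy, "syn1", n_boot = 200, seed = 12)
  expect_false(identical(b1$boot_dis, b3$boot_dis))
})

test_that("classify_frame applies the four CI rules", {
  expect_equal(classify_frame(0.1, c(-0.1, 0.3)), "head")
  expect_equal(classify_frame(0.9, c(0.7, 1.2)), "eye")
  expect_equal(classify_frame(0.5, c(0.2, 0.8)), "intermediate")
  expect_equal(classify_frame(0.5, c(-0.2, 1.2)), "unclassified")
  expect_equal(classify_frame(0.5, c(0, 1)), "unclassified")  # touches both
  expect_equal(classify_frame(1.6, c(1.4, 1.9)), "unclassified")
})

test_that("bootstrap CIs cover the generating frame parameter (scaled run)", {
  # scaled-down version of the full coverage check in test-acceptance.R:
  # 40 neurons x 200 replicates, wider accepted band
  n_neurons <- 40
  pop <- generate_population(n_neurons, lambda_frame = 0.5, fano = 1.5,
                             reps = 5, seed = 21)
  cover <- vapply(names(pop$specs), function(id) {
    ci <- bootstrap_ci(pop$trials, id, n_boot = 200,
                       seed = derive_seed_for_test(21, id))$ci95
    ci[1] <= 0.5 && ci[2] >= 0.5
  }, TRUE)
  expect_gte(mean(cover), 0.8)
})

test_that("di_by_eccentricity is flat for a homogeneous frame parameter", {
  spec <- neuron_spec(theta_p_deg = 145, lambda_frame = 0.5,
                      noise = list(kind = "none"))
  grid7 <- condition_grid(eye_positions_deg = c(-30, -20, -10, 0,
                                                10, 20, 30))
  tab <- simulate_fixation_block(spec, grid7, reps = 2, seed = 1)
  curves <- lapply(grid7$eye_positions_deg, function(P)
    build_tuning(tab, "syn1", "visual", list(eye_pos_deg = P)))
  res <- di_by_eccentricity(curves,
                            eye_positions = grid7$eye_positions_deg)
  expect_equal(res$eccentricity_deg, c(10, 20, 30))
  expect_true(all(abs(res$di - 0.5) <= 0.1))

  # lambda = 1: exactly 1 at every eccentricity
  spec1 <- neuron_spec(theta_p_deg = 145, lambda_frame = 1,
                       noise = list(kind = "none"))
  tab1 <- simulate_fixation_block(spec1, grid7, reps = 2, seed = 1)
  curves1 <- lapply(grid7$eye_positions_deg, function(P)
    build_tuning(tab1, "syn1", "visual", list(eye_pos_deg = P)))
  res1 <- di_by_eccentricity(curves1,
                             eye_positions = grid7$eye_positions_deg)
  # the 1-degree lag grid limits precision to 0.1 DI at 10 deg eccentricity
  expect_true(all(abs(res1$di - 1) <= 0.1))
})
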