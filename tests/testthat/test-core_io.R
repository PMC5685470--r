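grid8 <- seq(0, 315, by = 45)

test_that("trial table round-trips through CSV and validates input", {
  tab <- simulate_fixation_block(neuron_spec(), reps = 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tab, f)
  back <- load_trial_table(f)
  expect_s3_class(back, "trial_table")
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$rate_hz, tab$rate_hz, tolerance = 1e-12)
  expect_equal(sort(names(back)), sort(names(tab)))

  # headings outside [0, 360) are normalised with a warning
  df <- as.data.frame(tab)
  df$heading_deg[1] <- 370
  expect_warning(tt <- trial_table(df), "normalised")
  expect_equal(tt$heading_deg[1], 10)

  # missing required column is a format error
  expect_error(trial_table(df[setdiff(names(df), "heading_deg")]),
               "missing required column")
  # column-mapping dialect for third-party files
  df2 <- as.data.frame(tab)
  names(df2)[names(df2) == "rate_hz"] <- "FR"
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, f2, row.names = FALSE)
  remapped <- load_trial_table(f2, dialect = list(rate_hz = "FR"))
  expect_equal(remapped$rate_hz, tab$rate_hz, tolerance = 1e-12)
})

test_that("trial tables carry spike times that convert to rates", {
  df <- data.frame(neuron_id = "n1", modality = "visual",
                   heading_deg = c(0, 90), repetition = 1)
  df$spike_times_s <- list(c(0.1, 0.6, 1.4, 1.9), numeric(0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(trial_table(df), f)
  back <- load_trial_table(f)
  expect_equal(back$spike_times_s[[1]], c(0.1, 0.6, 1.4, 1.9))
  cv <- build_tuning(back, "n1", "visual")
  expect_equal(cv$mean_rate_hz, c(2, 0))
})

test_that("firing_rate_from_spikes counts half-open windows", {
  expect_equal(firing_rate_from_spikes(c(0.1, 0.6, 1.4, 1.9)), 2)
  expect_equal(firing_rate_from_spikes(numeric(0)), 0)
  expect_equal(firing_rate_from_spikes(seq(0.5, 1.5, length.out = 31)[-31],
                                       c(0.5, 1.5)), 30)
  # boundary ownership: spike exactly at end is excluded, at start included
  expect_equal(firing_rate_from_spikes(c(0.5, 1.5), c(0.5, 1.5)), 1)
  expect_error(firing_rate_from_spikes(1, c(1.5, 0.5)), "end > start")

  # additive over disjoint windows covering [0, 2]
  set.seed(42)
  for (i in 1:20) {
    spikes <- runif(rpois(1, 30), 0, 2)
    cut <- runif(1, 0.2, 1.8)
    whole <- firing_rate_from_spikes(spikes, c(0, 2)) * 2
    parts <- firing_rate_from_spikes(spikes, c(0, cut)) * cut +
      firing_rate_from_spikes(spikes, c(cut, 2)) * (2 - cut)
    expect_equal(whole, parts)
  }
})

test_that("build_tuning computes means/sems and is row-order invariant", {
  df <- data.frame(neuron_id = "n1", modality = "visual",
                   heading_deg = rep(grid8, each = 3),
                   repetition = rep(1:3, 8),
                   rate_hz = rep(c(10, 12, 14), 8))
  cv <- build_tuning(trial_table(df), "n1", "visual")
  expect_equal(cv$mean_rate_hz, rep(12, 8))
  expect_equal(cv$sem_hz, rep(sd(c(10, 12, 14)) / sqrt(3), 8))
  expect_equal(sapply(cv$trials, mean), cv$mean_rate_hz)

  shuffled <- df[sample(nrow(df)), ]
  cv2 <- build_tuning(trial_table(shuffled), "n1", "visual")
  expect_equal(cv2, cv)

  # single repetition: sem 0 and the non-testable flag
  one <- build_tuning(trial_table(df[df$repetition == 1, ]), "n1", "visual")
  expect_equal(one$sem_hz, rep(0, 8))
  expect_true(attr(one, "single_rep"))
  expect_error(tuning_significance(one), "non-testable")

  # grid headings absent from the data are named in the error
  expect_error(
    build_tuning(trial_table(df[df$heading_deg != 90, ]), "n1", "visual",
                 grid = condition_grid()),
    "missing data for grid heading")
})

test_that("noiseless synthetic tuning equals the generator mean function", {
  spec <- neuron_spec(theta_p_deg = 135, lambda_frame = 0.5, A2 = 0.3,
                      noise = list(kind = "none"))
  tab <- simulate_fixation_block(spec, reps = 2, seed = 1)
  for (P in c(-20, 0, 20)) {
    cv <- build_tuning(tab, "syn1", "visual", list(eye_pos_deg = P))
    expect_equal(cv$mean_rate_hz, mean_rate(spec, cv$headings_deg, P),
                 tolerance = 1e-12)
  }
})

test_that("tuning_significance matches an independent ANOVA and flags degenerate data", {
  set.seed(7)
  spec <- neuron_spec(A1 = 40, R0 = 10,
                      noise = list(kind = "gaussian_fano", fano = 1.5))
  tab <- simulate_fixation_block(spec, condition_grid(eye_positions_deg = 0),
                                 reps = 5, seed = 7)
  cv <- build_tuning(tab, "syn1", "visual", list(eye_pos_deg = 0))
  p <- tuning_significance(cv)
  expect_lt(as.numeric(p), 0.05)
  # oracle: stats::oneway.test with pooled variance on the same data
  vals <- unlist(cv$trials)
  grp <- factor(rep(cv$headings_deg, lengths(cv$trials)))
  ref <- stats::oneway.test(vals ~ grp, var.equal = TRUE)
  expect_equal(as.numeric(p), ref$p.value, tolerance = 1e-12)
  expect_equal(attr(p, "F"), unname(ref$statistic), tolerance = 1e-12)

  flat <- tuning_curve(grid8, rep(list(c(5, 5, 5)), 8))
  pf <- tuning_significance(flat)
  expect_equal(as.numeric(pf), 1)
  expect_true(attr(pf, "degenerate"))
})

test_that("tuning_significance holds its nominal type-I error", {
  set.seed(2024)
  n_sim <- 1000
  rej <- mean(replicate(n_sim, {
    cv <- tuning_curve(grid8, replicate(8, rnorm(5, 20, 4),
                                        simplify = FALSE))
    as.numeric(tuning_significance(cv)) < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("estimation_schedule enumerates the condition set", {
  sched <- estimation_schedule()
  expect_equal(attr(sched, "n_conditions"), 54)   # 18 headings x 3 eyes
  expect_gte(attr(sched, "min_trials"), 270)      # >= 5 reps each
  sched2 <- estimation_schedule(condition_grid(grid8, c(-20, 0, 20)))
  expect_equal(nrow(sched2), 24)
  expect_error(estimation_schedule(list(headings_deg = numeric(0),
                                        eye_positions_deg = 0)),
               "empty")
})
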