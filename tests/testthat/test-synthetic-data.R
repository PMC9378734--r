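test_that("latent states are stationary AR(1) with the configured moments", {
  cfg0 <- state_config(ar_coeff = 0)
  s0 <- sample_latent_states(cfg0, 10000, seed = 1)
  expect_lt(abs(cor(s0$s1[-1], s0$s1[-10000])), 3 / sqrt(10000))

  cfg9 <- state_config(ar_coeff = 0.9, state_sd = c(1.5, 0.5))
  s9 <- sample_latent_states(cfg9, 10000, seed = 2)
  expect_lt(abs(cor(s9$s1[-1], s9$s1[-10000]) - 0.9), 0.03)
  expect_lt(abs(cor(s9$s2[-1], s9$s2[-10000]) - 0.9), 0.03)
  expect_lt(abs(sd(s9$s1) - 1.5), 0.15)
  expect_lt(abs(sd(s9$s2) - 0.5), 0.05)
  # states mutually independent
  expect_lt(abs(cor(s9$s1, s9$s2)), 0.1)

  # determinism
  again <- sample_latent_states(cfg9, 10000, seed = 2)
  expect_identical(s9$s1, again$s1)
  expect_identical(s9$eps, again$eps)
})

test_that("state_config rejects invalid dynamics", {
  expect_error(state_config(ar_coeff = 1), "ar_coeff")
  expect_error(state_config(ar_coeff = -0.1), "ar_coeff")
  expect_error(state_config(state_sd = 0), "state_sd")
  expect_error(state_config(beta_ta = NaN), "beta_ta")
})

test_that("outcome model reduces to the symmetric and degenerate limits", {
  task <- task_config()
  # fully symmetric three-way link: equal outcome frequencies
  cfg <- state_config(beta_ta = 0, beta_s1_miss = 0, beta_s1_fa = 0,
                      beta_s2 = 0, intercept_hit = 0, intercept_miss = 0,
                      intercept_fa = 0)
  st <- sample_latent_states(cfg, 30000, seed = 3)
  beh <- sample_attention_and_outcomes(task, st, cfg, seed = 3)
  freqs <- prop.table(table(droplevels(beh$trial_table$outcome)))
  expect_true(all(abs(freqs - 1 / 3) < 0.02))

  # jitter 0, huge TA slope: at TA = 0 everything is a hit
  cfg2 <- state_config(beta_ta = 50, beta_s1_miss = 0, beta_s1_fa = 0,
                       beta_s2 = 0, attention_jitter_sd = 0,
                       intercept_hit = 25)
  st2 <- sample_latent_states(cfg2, 2000, seed = 4)
  beh2 <- sample_attention_and_outcomes(task, st2, cfg2, seed = 4)
  expect_true(all(beh2$trial_table$outcome == "hit"))
  # true spotlight exactly at the cued landmark
  expect_equal(beh2$states$true_as_xy[, 1], beh2$trial_table$cue_x,
               ignore_attr = TRUE)
})

test_that("planted TA slope yields decreasing hit rate over true TA bins", {
  task <- task_config()
  cfg <- state_config(beta_ta = 0.12, attention_jitter_sd = 8)
  st <- sample_latent_states(cfg, 20000, seed = 5)
  beh <- sample_attention_and_outcomes(task, st, cfg, seed = 5)
  tt <- beh$trial_table
  ta <- compute_ta(beh$states$true_as_xy, cbind(tt$target_x, tt$target_y))
  hm <- as.character(tt$outcome) %in% c("hit", "miss")
  acc <- vapply(list(c(0, 6), c(6, 12), c(12, 18)), function(b) {
    i <- hm & ta > b[1] & ta <= b[2]
    mean(tt$outcome[i] == "hit")
  }, numeric(1))
  expect_true(acc[1] > acc[2] && acc[2] > acc[3])

  # beta_ta = 0: flat accuracy profile
  cfg0 <- state_config(beta_ta = 0, attention_jitter_sd = 8)
  beh0 <- sample_attention_and_outcomes(
    task, sample_latent_states(cfg0, 20000, seed = 6), cfg0, seed = 6)
  tt0 <- beh0$trial_table
  ta0 <- compute_ta(beh0$states$true_as_xy,
                    cbind(tt0$target_x, tt0$target_y))
  hm0 <- as.character(tt0$outcome) %in% c("hit", "miss")
  acc0 <- vapply(list(c(0, 6), c(6, 12), c(12, 18)), function(b) {
    i <- hm0 & ta0 > b[1] & ta0 <= b[2]
    mean(tt0$outcome[i] == "hit")
  }, numeric(1))
  expect_lt(max(acc0) - min(acc0), 0.03)
})

test_that("spike counts are Poisson at baseline when all modulation is off", {
  task <- task_config()
  pop <- uniform_population(n_units = 12, rate = 25)
  cfg <- state_config()
  st <- sample_latent_states(cfg, 5000, seed = 7)
  beh <- sample_attention_and_outcomes(task, st, cfg, seed = 7)
  ses <- generate_spike_counts(pop, beh$states, beh$trial_table, task,
                               seed = 7)
  expect_true(all(ses$counts >= 0))
  expect_true(all(ses$counts == round(ses$counts)))
  # pre-stimulus bins: mean count per bin = rate * dt within 3 SE
  bins <- window_bins(ses, c(-400, 0))
  m <- 25 * 0.01
  for (i in seq_len(12)) {
    x <- ses$counts[, i, bins]
    se <- sqrt(m / length(x))
    expect_lt(abs(mean(x) - m), 3 * se)
  }
})

test_that("noise correlations vanish without state loadings and match the shared-gain closed form with them", {
  task <- task_config()
  cfg <- state_config(ar_coeff = 0)  # iid states for clean conditioning
  st <- sample_latent_states(cfg, 2000, seed = 8)
  beh <- sample_attention_and_outcomes(task, st, cfg, seed = 8)

  # no loadings: conditional independence
  pop0 <- uniform_population(n_units = 24, rate = 30)
  ses0 <- generate_spike_counts(pop0, beh$states, beh$trial_table, task,
                                seed = 8)
  z0 <- trial_responses(ses0, "pre_target")
  r0 <- cor(z0)
  expect_lt(abs(mean(r0[upper.tri(r0)])), 0.01)

  # common multiplicative coupling to the optimality-state magnitude:
  # with per-bin mean m = rate*dt, nb bins averaged and gain variance
  # w^2 * Var(|s1| - E|s1|), the pairwise correlation is
  # r = 1 / (1 + 1/(nb * m * w^2 * V))   [law of total covariance]
  w <- 0.3
  pop1 <- uniform_population(n_units = 24, rate = 30, w_s1 = w)
  ses1 <- generate_spike_counts(pop1, beh$states, beh$trial_table, task,
                                seed = 9)
  z1 <- trial_responses(ses1, "pre_target")
  r1 <- cor(z1)
  V <- 1 - 2 / pi
  nb <- 20; m <- 30 * 0.01
  r_expected <- 1 / (1 + 1 / (nb * m * w^2 * V))
  expect_lt(abs(mean(r1[upper.tri(r1)]) - r_expected), 0.05)
})

test_that("an implausible configuration engages the rate floor with a warning", {
  task <- task_config()
  pop <- uniform_population(n_units = 6, rate = 5, w_s2 = 40)
  cfg <- state_config()
  st <- sample_latent_states(cfg, 200, seed = 10)
  beh <- sample_attention_and_outcomes(task, st, cfg, seed = 10)
  expect_warning(
    generate_spike_counts(pop, beh$states, beh$trial_table, task,
                          seed = 10),
    "rate floor")
})

test_that("multi-session simulation is deterministic with distinct sessions", {
  a <- simulate_sessions(n_sessions = 2, n_trials = 60, seed = 5)
  b <- simulate_sessions(n_sessions = 2, n_trials = 60, seed = 5)
  expect_identical(a[[1]]$session$counts, b[[1]]$session$counts)
  expect_identical(a[[2]]$states$s1, b[[2]]$states$s1)
  expect_false(identical(a[[1]]$session$counts, a[[2]]$session$counts))
})

test_that("session directories round-trip through write/read", {
  sim <- simulate_session(n_trials = 40, seed = 12)
  dir <- file.path(tempdir(), "ses_roundtrip")
  write_session(sim$session, dir)
  back <- read_session(dir)
  expect_identical(back$counts, sim$session$counts)
  expect_equal(back$trial_table$outcome, sim$session$trial_table$outcome)
  expect_equal(back$task$landmark_positions,
               sim$session$task$landmark_positions,
               ignore_attr = TRUE)
  expect_error(read_session(file.path(tempdir(), "nope_missing")),
               "not found")
  unlink(dir, recursive = TRUE)
})
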