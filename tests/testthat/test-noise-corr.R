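test_that("trial responses are exactly z-scored and exclude flat channels", {
  sim <- small_session(n_trials = 60, seed = 51)
  ses <- sim$session
  z <- trial_responses(ses, "pre_target")
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))

  ses2 <- ses
  ses2$counts[, 3, ] <- 5L  # constant channel
  expect_warning(z2 <- trial_responses(ses2, "pre_target"),
                 "zero-variance")
  expect_false(3L %in% attr(z2, "channels"))
  expect_error(trial_responses(ses, "pre_target", 1:2), "at least 3")
})

test_that("noise_correlation has the matrix invariants and filters as documented", {
  set.seed(52)
  x <- matrix(rnorm(200 * 6), 200, 6)
  x <- cbind(x, x[, 1] + rnorm(200, sd = 1e-8))  # near-duplicated channel
  nc <- noise_correlation(scale(x))
  expect_equal(nc$r, t(nc$r))
  expect_equal(unname(diag(nc$r)), rep(1, 7))
  expect_gt(min(eigen(nc$r, only.values = TRUE)$values), -1e-10)
  expect_gt(nc$r[1, 7], 0.999)

  # invariance to channel order and affine rescaling of raw inputs
  y <- x[, c(3, 1, 2, 4:7)]
  y[, 2] <- y[, 2] * 12 + 100
  nc2 <- noise_correlation(scale(y))
  expect_equal(nc2$mean, nc$mean, tolerance = 1e-12)
})

test_that("independent data match the positive-truncation null oracle", {
  # brute-force Monte-Carlo oracle for the mean positive-significant r
  # of independent channels
  set.seed(53)
  n <- 200; p <- 48
  oracle_draws <- replicate(40, {
    z <- matrix(rnorm(n * p), n, p)
    noise_correlation(z)$mean
  })
  oracle <- mean(oracle_draws, na.rm = TRUE)

  task <- task_config()
  pop <- null_population(n_units = p, seed = 53)
  cfg <- state_config()
  st <- sample_latent_states(cfg, n, seed = 53)
  beh <- sample_attention_and_outcomes(task, st, cfg, seed = 53)
  ses <- generate_spike_counts(pop, beh$states, beh$trial_table, task,
                               seed = 53)
  z <- trial_responses(ses, "pre_target")
  got <- noise_correlation(z)$mean
  expect_lt(abs(got - oracle), 0.02)
})

test_that("shared gain raises the summary towards its analytic expectation", {
  task <- task_config()
  cfg <- state_config(ar_coeff = 0)
  st <- sample_latent_states(cfg, 400, seed = 54)
  beh <- sample_attention_and_outcomes(task, st, cfg, seed = 54)
  w <- 0.3
  pop <- uniform_population(n_units = 24, rate = 30, w_s1 = w)
  ses <- generate_spike_counts(pop, beh$states, beh$trial_table, task,
                               seed = 54)
  z <- trial_responses(ses, "pre_target")
  nc <- noise_correlation(z)
  V <- 1 - 2 / pi
  r_expected <- 1 / (1 + 1 / (20 * 0.3 * w^2 * V))
  expect_lt(abs(nc$mean - r_expected), 0.05)
  expect_gt(nc$n_pairs, 0)
})

test_that("trial-type noise correlations show the planted ordering", {
  sim <- simulate_session(n_trials = 800, seed = 55)
  est <- rolling_decode(sim$session)
  nc <- noise_corr_by_outcome(sim$session, seed = 55)
  g <- function(ep) {
    v <- nc[nc$epoch == ep, ]
    setNames(v$nc_mean, as.character(v$trial_type))
  }
  pt <- g("pre_target"); pc <- g("pre_cue")
  expect_true(pt["hit"] < pt["miss"])
  expect_true(pc["hit"] < pc["miss"])

  # TA equalization: matched TA-bin profiles across types
  nce <- noise_corr_by_outcome(sim$session, equalize_ta = TRUE,
                               estimates = est, seed = 55)
  expect_true(all(!is.na(nce$nc_mean)))
})

test_that("TA matching equalizes the TA-bin profiles across trial types", {
  sim <- simulate_session(n_trials = 800, seed = 56)
  est <- rolling_decode(sim$session)
  tt <- sim$session$trial_table
  types <- c("hit", "miss", "fa")
  rows_of <- lapply(types, function(ty)
    which(as.character(tt$outcome) == ty))
  names(rows_of) <- types
  sel <- attnstate:::ta_matched_rows(rows_of, tt, est, seed = 1)
  props <- sapply(types, function(ty) {
    b <- est$ta_bin[match(tt$trial_id[sel[[ty]]], est$trial_id)]
    prop.table(table(b))
  })
  # profiles agree within a few percent despite unequal totals
  expect_lt(max(abs(props[, "hit"] - props[, "miss"])), 0.05)
  expect_lt(max(abs(props[, "hit"] - props[, "fa"])), 0.05)
})

test_that("a missing trial type is reported as NA with a warning", {
  sim <- small_session(n_trials = 60, seed = 57)
  ses <- sim$session
  ses$trial_table$outcome[ses$trial_table$outcome == "fa"] <- "miss"
  expect_warning(nc <- noise_corr_by_outcome(ses, epochs = "pre_target"),
                 "missing")
  expect_true(is.na(nc$nc_mean[nc$trial_type == "fa"]))
})
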