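test_that("fit_regole matches the normal-equation oracle for all penalties", {
  set.seed(21)
  R <- matrix(rnorm(20 * 5), 20, 5)
  C <- cbind(sign(rnorm(20)), sign(rnorm(20)))
  for (lambda in c(0.01, 1, 100)) {
    fit <- fit_regole(R, C, lambda = lambda)
    orc <- ridge_oracle(R, C, lambda)
    expect_lt(max(abs(fit$W - orc$W)), 1e-8)
    expect_lt(max(abs(fit$intercept - orc$intercept)), 1e-8)
  }
})

test_that("fit_regole interpolates at lambda 0 and shrinks at huge lambda", {
  set.seed(22)
  # noiseless linear targets: lambda 0 recovers the generating map
  R <- matrix(rnorm(100), 20, 5)
  W0 <- matrix(rnorm(10), 5, 2)
  Cc <- sweep(R, 2, colMeans(R)) %*% W0
  fit0 <- fit_regole(R, Cc, lambda = 0)
  expect_lt(max(abs(fit0$W - W0)), 1e-6)

  Rs <- scale(matrix(rnorm(200), 50, 4))
  Cs <- cbind(sign(Rs[, 1]), sign(Rs[, 2]))
  fit_big <- fit_regole(Rs, Cs, lambda = 1e9)
  expect_lt(sqrt(sum(fit_big$W^2)), 1e-3)
})

test_that("collinear channels at lambda 0 raise an informative error", {
  R <- matrix(rnorm(30), 10, 3)
  R <- cbind(R, R[, 1])  # exact collinearity
  C <- cbind(sign(rnorm(10)), sign(rnorm(10)))
  expect_error(fit_regole(R, C, lambda = 0), "lambda > 0")
})

test_that("GCV selects a finite penalty that tracks the noise level", {
  set.seed(23)
  R <- matrix(rnorm(400), 100, 4)
  C <- cbind(sign(R[, 1] + rnorm(100, sd = 2)),
             sign(R[, 2] + rnorm(100, sd = 2)))
  lam <- select_lambda_gcv(R, C)
  expect_true(is.finite(lam) && lam > 0)
})

test_that("compute_ta is the Euclidean distance with metric properties", {
  expect_equal(compute_ta(c(0, 0), c(0, 0)), 0)
  expect_equal(compute_ta(c(3, 4), c(0, 0)), 5)
  expect_equal(compute_ta(c(10, 10), c(14, 14)), 5.6569, tolerance = 1e-4)
  set.seed(24)
  for (i in 1:20) {
    a <- rnorm(2); b <- rnorm(2); c <- rnorm(2)
    expect_equal(compute_ta(a, b), compute_ta(b, a))
    expect_lte(compute_ta(a, c), compute_ta(a, b) + compute_ta(b, c) + 1e-12)
  }
})

test_that("bin_ta applies the half-open bin edges exactly", {
  expect_equal(as.character(bin_ta(c(0, 6, 6.0001, 12, 12.0001, 17.99, 18, 18.5))),
               c("close", "close", "medium", "medium", "far", "far",
                 "out_of_range", "out_of_range"))
  expect_error(bin_ta(-1), "TA")
})

test_that("rolling schedule retrains every 20 correct trials and never sees the tested trial", {
  # session engineered so hit count and ordering are known
  sim <- simulate_session(n_trials = 900, seed = 31)
  ses <- sim$session
  n_hits <- sum(ses$trial_table$outcome == "hit")
  est <- rolling_decode(ses, lambda = 1)
  # bookkeeping: first fit after 200 hits, retrain each further 20 hits
  # (a retraining happens only if a later trial is decoded)
  hit_pos <- which(ses$trial_table$outcome == "hit")
  ks <- seq(220, n_hits, by = 20)
  # a retraining at the (200 + 20k)-th hit happens only if some later
  # trial remains to be decoded
  exp_retrain <- sum(hit_pos[ks] < nrow(ses$trial_table))
  expect_equal(attr(est, "n_retrainings"), exp_retrain)
  # tested trials start strictly after the 200th hit
  expect_gt(min(est$trial_id), hit_pos[200])

  # leakage probe: corrupting responses of trials after the last
  # retraining leaves earlier decoded estimates identical
  ses2 <- ses
  last_block <- est$trial_id[est$trial_id > hit_pos[200 + 20]]
  ses2$counts[max(last_block), , ] <- 0L
  est2 <- rolling_decode(ses2, lambda = 1)
  shared <- est$trial_id < max(last_block)
  expect_equal(est$x_as[shared], est2$x_as[est2$trial_id < max(last_block)])
})

test_that("too few correct trials yields an empty estimate with a warning", {
  sim <- simulate_session(n_trials = 120, seed = 32)
  expect_warning(est <- rolling_decode(sim$session), "fewer correct")
  expect_equal(nrow(est), 0L)
})

test_that("decoded TA tracks the planted spotlight and hit rates fall with TA", {
  sim <- simulate_session(n_trials = 800, seed = 33)
  tt <- sim$session$trial_table
  est <- rolling_decode(sim$session)
  ta_true <- compute_ta(sim$states$true_as_xy,
                        cbind(tt$target_x, tt$target_y))
  rows <- match(est$trial_id, tt$trial_id)
  expect_gt(cor(est$ta, ta_true[rows], method = "spearman"), 0.5)

  hr <- hit_rate_by_ta(est, tt)
  acc <- hr$accuracy[match(c("close", "far"), hr$ta_bin)]
  expect_gt(acc[1], acc[2])
})

test_that("hit_rate_by_ta handles degenerate and equalized inputs", {
  est <- data.frame(trial_id = 1:30, x_as = 0, y_as = 0,
                    ta = rep(c(3, 9, 15), 10),
                    ta_bin = bin_ta(rep(c(3, 9, 15), 10)))
  tt <- data.frame(trial_id = 1:30,
                   outcome = factor(rep("hit", 30),
                                    levels = c("hit", "miss", "fa", "cr")))
  hr <- hit_rate_by_ta(est, tt)
  expect_true(all(hr$accuracy == 1))

  tt2 <- tt
  tt2$outcome[seq(1, 30, 2)] <- "miss"
  hr2 <- hit_rate_by_ta(est, tt2, equalize = TRUE, seed = 1)
  expect_equal(sum(hr2$n_hit), sum(hr2$n_miss))
})

test_that("permuted cue labels reduce decoding to four-class chance", {
  sim <- simulate_session(n_trials = 800, seed = 34)
  ses <- sim$session
  # permute the cue/target geometry across trials before decoding
  set.seed(99)
  perm <- sample(nrow(ses$trial_table))
  ses$trial_table[, c("cue_landmark", "cue_x", "cue_y", "target_x",
                      "target_y")] <-
    ses$trial_table[perm, c("cue_landmark", "cue_x", "cue_y", "target_x",
                            "target_y")]
  est <- rolling_decode(ses)
  rows <- match(est$trial_id, ses$trial_table$trial_id)
  agree <- mean(sign(est$x_as) == sign(ses$trial_table$cue_x[rows]) &
                  sign(est$y_as) == sign(ses$trial_table$cue_y[rows]))
  expect_lt(abs(agree - 0.25), 0.06)
})
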