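test_that("marginalization matches the nested-loop oracle and conserves the tensor", {
  set.seed(61)
  X <- array(rnorm(4 * 3 * 2 * 5), dim = c(4, 3, 2, 5))
  marg <- marginalize(X, factor_names = c("f1", "f2"))
  orc <- marginalize_oracle(X)
  expect_lt(max(abs(marg$f1 - orc$f1)), 1e-12)
  expect_lt(max(abs(marg$f2 - orc$f2)), 1e-12)
  expect_lt(max(abs(marg$interaction - orc$int)), 1e-12)
  expect_lt(max(abs(marg$condition_independent - orc$ci)), 1e-12)
  # conservation: pieces sum exactly to the centred tensor
  recon <- Reduce(`+`, marg)
  expect_lt(max(abs(recon - attr(marg, "centered"))), 1e-12)
})

test_that("structure-free marginals vanish identically", {
  set.seed(62)
  # constant across the second factor: its marginal and the interaction are 0
  base <- array(rnorm(5 * 3 * 6), dim = c(5, 3, 6))
  X <- array(0, dim = c(5, 3, 2, 6))
  X[, , 1, ] <- base; X[, , 2, ] <- base
  marg <- marginalize(X, c("a", "b"))
  expect_lt(max(abs(marg$b)), 1e-12)
  expect_lt(max(abs(marg$interaction)), 1e-12)

  # additive structure: interaction exactly 0
  a_eff <- rnorm(3); b_eff <- rnorm(2)
  X2 <- array(0, dim = c(1, 3, 2, 4))
  for (i in 1:3) for (j in 1:2) X2[1, i, j, ] <- a_eff[i] + b_eff[j]
  marg2 <- marginalize(X2, c("a", "b"))
  expect_lt(max(abs(marg2$interaction)) / max(abs(X2)), 1e-10)
})

test_that("dPCA recovers planted structure in limiting cases", {
  set.seed(63)
  # data lying entirely in one marginalization: first dPC equals the
  # first PC of the data
  n <- 12; A <- 3; Tt <- 10
  ax <- rnorm(n); ax <- ax / sqrt(sum(ax^2))
  cond_eff <- c(-1, 0, 1)
  X <- array(0, dim = c(n, A, Tt))
  for (a in 1:A) X[, a, ] <- outer(ax * cond_eff[a] * 5, rep(1, Tt))
  X <- X + array(rnorm(length(X), sd = 1e-4), dim = dim(X))
  model <- fit_dpca(X, n_components = 3)
  pca <- pca_baseline(X)
  marg_name <- names(model$marginalizations)[1]
  f1 <- model$marginalizations[[marg_name]]$F[, 1]
  expect_gt(abs(cor(f1, pca$rotation[, 1])), 0.999)
  expect_gt(abs(sum(f1 * ax)), 0.999)

  # two planted orthogonal axes, one per marginalization, high SNR
  n <- 20; A <- 3; B <- 2; Tt <- 8
  a1 <- c(1, rep(0, n - 1)); a2 <- c(0, 1, rep(0, n - 2))
  X2 <- array(rnorm(n * A * B * Tt, sd = 1e-3), dim = c(n, A, B, Tt))
  for (a in 1:A) for (b in 1:B) {
    X2[, a, b, ] <- X2[, a, b, ] +
      outer(a1 * (a - 2) * 10 + a2 * (b - 1.5) * 10, rep(1, Tt))
  }
  m2 <- fit_dpca(X2, n_components = 2)
  ang <- function(u, v) acos(pmin(abs(sum(u * v)), 1)) * 180 / pi
  expect_lt(ang(m2$marginalizations[[1]]$D[1, ], a1), 5)
  expect_lt(ang(m2$marginalizations[[2]]$D[1, ], a2), 5)
})

test_that("explained variance accounting is coherent", {
  set.seed(64)
  # pure-attention data: attention share > 95%
  n <- 10; A <- 3; Tt <- 6
  X <- array(rnorm(n * A * Tt, sd = 0.01), dim = c(n, A, Tt))
  ax <- rnorm(n)
  for (a in 1:A) X[, a, ] <- X[, a, ] + outer(ax * (a - 2), rep(1, Tt))
  model <- fit_dpca(X)
  shares <- model$var_by_marginalization
  expect_gt(shares[[1]], 0.95)
  expect_true(all(shares >= 0))
  expect_lt(sum(shares), 1 + 1e-9)

  ev <- explained_variance(model, n_components = 5)
  expect_true(all(diff(ev$cumulative) > -1e-9))
})

test_that("pca_baseline matches an eigendecomposition oracle", {
  set.seed(65)
  X <- array(rnorm(8 * 3 * 2 * 7), dim = c(8, 3, 2, 7))
  pca <- pca_baseline(X, n_components = 8)
  marg <- marginalize(X, c("a", "b"))
  Xf <- matrix(attr(marg, "centered"), nrow = 8)
  ev <- eigen(tcrossprod(Xf), symmetric = TRUE)
  cum_oracle <- cumsum(ev$values) / sum(ev$values)
  expect_lt(max(abs(pca$cumvar - cum_oracle[1:8])), 1e-10)
  expect_true(all(diff(pca$cumvar) > -1e-12))
  expect_lte(max(pca$cumvar), 1 + 1e-12)

  # rank-1 data: one component explains everything
  r1 <- array(outer(rnorm(8), rnorm(42)), dim = c(8, 3, 2, 7))
  p1 <- pca_baseline(r1, n_components = 3)
  expect_gt(p1$cumvar[1], 1 - 1e-10)
})

test_that("dPCA cumulative variance never exceeds the PCA curve", {
  sim <- simulate_session(n_trials = 800, seed = 66)
  est <- rolling_decode(sim$session)
  tens <- build_condition_tensor(sim$session, est, "ta_x_outcome",
                                 seed = 1)
  model <- fit_dpca(tens, n_components = 20)
  ev <- explained_variance(model, n_components = 20)
  pca <- pca_baseline(tens, n_components = length(ev$cumulative))
  expect_true(all(ev$cumulative <= pca$cumvar[seq_along(ev$cumulative)] +
                    1e-9))
})

test_that("axis decoding separates planted classes and calibrates under the null", {
  sim <- small_session(n_trials = 800, seed = 67)
  est <- rolling_decode(sim$session)
  tens <- build_condition_tensor(sim$session, est, "trialtype",
                                 balanced = FALSE, seed = 1)
  model <- fit_dpca(tens)
  dec <- decode_with_axis(model, tens, "trial_type", 1, n_cv = 50,
                          n_shuffle = 30, seed = 2)
  expect_gt(dec$accuracy, 1 / 3)
  expect_true(dec$accuracy >= 0 && dec$accuracy <= 1)
  expect_lt(dec$chance_threshold, 1)
  expect_error(decode_with_axis(model, tens, "trial_type", 99),
               "unknown component")

  # perfectly separable classes decode at 100%
  n <- 6; Tt <- 4
  Xs <- array(0, dim = c(n, 2, Tt))
  Xs[1, 1, ] <- 5; Xs[1, 2, ] <- -5
  tens2 <- list(
    X = Xs,
    trials = array(c(rep(5, Tt * n), rep(-5, Tt * n)), dim = c(n, 20, Tt)),
    trial_cond = data.frame(outcome = factor(rep(c("hit", "miss"),
                                                 each = 10))),
    factor_names = "outcome",
    factor_levels = list(outcome = c("hit", "miss")))
  class(tens2) <- "condition_tensor"
  for (j in 1:20) {
    tens2$trials[, j, ] <- (if (j <= 10) 1 else -1) *
      matrix(5, n, Tt) + rnorm(n * Tt, sd = 0.01)
  }
  m2 <- fit_dpca(tens2)
  d2 <- decode_with_axis(m2, tens2, "outcome", 1, n_cv = 20,
                         n_shuffle = 20, seed = 3)
  expect_equal(d2$accuracy, 1)
  expect_lt(d2$chance_threshold, 1)
})

test_that("axis overlap reports dot, angle, and a Monte-Carlo null", {
  a <- c(1, 0, 0, 0); b <- c(0, 1, 0, 0)
  o1 <- axis_overlap(a, a)
  expect_equal(o1$dot, 1)
  expect_equal(o1$angle_deg, 0)
  o2 <- axis_overlap(a, b)
  expect_equal(o2$dot, 0)
  expect_equal(o2$angle_deg, 90)
  expect_error(axis_overlap(a, rep(0, 4)), "nonzero")
  # the null threshold shrinks with dimension
  hi <- axis_overlap(rnorm(100), rnorm(100), n_mc = 5000, seed = 1)
  lo <- axis_overlap(rnorm(10), rnorm(10), n_mc = 5000, seed = 1)
  expect_lt(hi$null_threshold, lo$null_threshold)
})

test_that("component removal is idempotent on the removed axis", {
  sim <- small_session(n_trials = 800, seed = 68)
  est <- rolling_decode(sim$session)
  tens <- build_condition_tensor(sim$session, est, "trialtype",
                                 balanced = FALSE, seed = 1)
  model <- fit_dpca(tens)
  cleaned <- remove_component_backproject(model, tens, "trial_type", 1)
  d1 <- model$marginalizations$trial_type$D[1, ]
  # re-projecting the cleaned data onto the removed decoder axis is ~0
  Xf <- matrix(cleaned$X, nrow = dim(cleaned$X)[1])
  expect_lt(sqrt(sum((d1 %*% Xf)^2)) / sqrt(sum(Xf^2)), 1e-8)
  Tf <- matrix(cleaned$trials, nrow = dim(cleaned$trials)[1])
  expect_lt(sqrt(sum((d1 %*% Tf)^2)) / sqrt(sum(Tf^2)), 1e-8)
  expect_error(remove_component_backproject(model, tens, "trial_type", 99),
               "unknown component")
})

test_that("decoder sign convention makes fits reproducible", {
  sim <- small_session(n_trials = 800, seed = 69)
  est <- rolling_decode(sim$session)
  tens <- build_condition_tensor(sim$session, est, "ta_x_outcome",
                                 seed = 7)
  m1 <- fit_dpca(tens)
  m2 <- fit_dpca(tens)
  expect_identical(m1$marginalizations$attention$D,
                   m2$marginalizations$attention$D)
  for (f in m1$marginalizations) {
    if (nrow(f$D) == 0) next
    picks <- apply(f$D, 1, function(d) d[which.max(abs(d))])
    expect_true(all(picks > 0))
  }
})
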