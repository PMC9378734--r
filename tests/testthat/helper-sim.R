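# Shared fixtures, built in code at test time.

# A small but analysis-ready session: enough correct trials for the
# rolling decoder at reduced train size.
small_session <- function(n_trials = 400L, seed = 11L, ...) {
  simulate_session(n_trials = n_trials, seed = seed, ...)
}

# A population with all attention tuning and state loadings switched
# off: pure Poisson noise at per-unit baseline rates.
null_population <- function(n_units = 48L, seed = 1L) {
  pop <- sample_population_config(n_units = n_units, seed = seed)
  pop$tuning_gain[] <- 0
  pop$focus_gain[] <- 0
  pop$w_s1[] <- 0
  pop$w_s2[] <- 0
  pop$v_s1[] <- 0
  pop$roles[] <- "none"
  pop
}

# Uniform population: identical baselines, no tuning, configurable
# state loadings; handy for closed-form checks.
uniform_population <- function(n_units = 24L, rate = 30, w_s1 = 0,
                               w_s2 = 0, v_s1 = 0) {
  population_config(
    baseline_rates = rep(rate, n_units),
    rf_centers = matrix(0, n_units, 2L),
    tuning_gain = rep(0, n_units),
    tuning_width = rep(8, n_units),
    w_s1 = rep(w_s1, n_units),
    w_s2 = rep(w_s2, n_units),
    v_s1 = rep(v_s1, n_units),
    focus_gain = rep(0, n_units))
}

# Brute-force ridge solve via augmented normal equations; independent
# of fit_regole's implementation.
ridge_oracle <- function(R, C, lambda) {
  Xc <- sweep(R, 2L, colMeans(R))
  W <- solve(t(Xc) %*% Xc + lambda * diag(ncol(R)), t(Xc) %*% C)
  list(W = W, intercept = colMeans(C))
}

# Nested-loop factorial marginalization oracle for a units x A x B x T
# tensor; deliberately naive.
marginalize_oracle <- function(X) {
  d <- dim(X)
  n <- d[1L]; A <- d[2L]; B <- d[3L]; Tt <- d[4L]
  out <- list(
    f1 = array(0, d), f2 = array(0, d), int = array(0, d),
    ci = array(0, d))
  for (i in seq_len(n)) {
    x <- X[i, , , ]
    mu <- mean(x)
    xa <- apply(x, 1L, mean) - mu
    xb <- apply(x, 2L, mean) - mu
    xt <- apply(x, 3L, mean) - mu
    for (a in seq_len(A)) for (b in seq_len(B)) for (t in seq_len(Tt)) {
      ab <- mean(x[a, b, ]) - mu - xa[a] - xb[b]
      at <- mean(x[a, , t]) - mu - xa[a] - xt[t]
      bt <- mean(x[, b, t]) - mu - xb[b] - xt[t]
      abt <- x[a, b, t] - mu - xa[a] - xb[b] - xt[t] - ab - at - bt
      out$f1[i, a, b, t] <- xa[a] + at
      out$f2[i, a, b, t] <- xb[b] + bt
      out$int[i, a, b, t] <- ab + abt
      out$ci[i, a, b, t] <- xt[t]
    }
  }
  out
}
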