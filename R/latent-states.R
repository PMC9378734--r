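#' Sample the latent behavioral states
#'
#' Draws the two per-trial latent states as independent stationary AR(1)
#' sequences: \eqn{s_t = a s_{t-1} + \epsilon_t} with
#' \eqn{\epsilon_t \sim N(0, \sigma^2 (1 - a^2))} and
#' \eqn{s_1 \sim N(0, \sigma^2)}, so that the marginal standard deviation
#' is the configured stationary SD at every trial. The AR coefficient
#' controls how slowly the states drift across trials ("low-frequency"
#' state dynamics spanning many trials).
#'
#' @param state_config A [state_config()].
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed; the same seed reproduces the sequences
#'   exactly.
#' @return An object of class `latent_states`: a list with numeric
#'   vectors `s1` (optimality) and `s2` (responsiveness) of length
#'   `n_trials`, plus `eps`, the fast trial-wise standard-normal shared
#'   gain factor whose amplitude is modulated by `|s1|` in the rate
#'   model. `true_as_xy` is filled in later by
#'   [sample_attention_and_outcomes()].
#' @export
#' @examples
#' st <- sample_latent_states(state_config(), n_trials = 100, seed = 1)
#' sd(st$s1)
sample_latent_states <- function(state_config, n_trials, seed = NULL) {
  stopifnot(inherits(state_config, "state_config"))
  assert_scalar_number(n_trials, "n_trials", lower = 1)
  n_trials <- as.integer(n_trials)
  with_seed(stream_seed(seed, "states"), {
    draw <- function(a, sd) {
      if (n_trials == 1L) return(stats::rnorm(1L, sd = sd))
      innov_sd <- sd * sqrt(1 - a^2)
      s <- numeric(n_trials)
      s[1L] <- stats::rnorm(1L, sd = sd)
      eps <- stats::rnorm(n_trials - 1L, sd = innov_sd)
      for (t in 2:n_trials) s[t] <- a * s[t - 1L] + eps[t - 1L]
      s
    }
    structure(
      list(s1 = draw(state_config$ar_coeff[1], state_config$state_sd[1]),
           s2 = draw(state_config$ar_coeff[2], state_config$state_sd[2]),
           eps = stats::rnorm(n_trials),
           true_as_xy = NULL),
      class = "latent_states")
  })
}

#' @export
print.latent_states <- function(x, ...) {
  cat(sprintf("Latent states over %d trials (s1 SD %.2f, s2 SD %.2f)\n",
              length(x$s1), stats::sd(x$s1), stats::sd(x$s2)))
  invisible(x)
}
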