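#' Sample per-trial attention positions and behavioral outcomes
#'
#' For each trial a cue landmark is drawn uniformly among the four
#' landmarks; with 100% cue validity the target appears at the cued
#' landmark. The true attentional spotlight is the cued landmark plus
#' isotropic Gaussian jitter (`attention_jitter_sd`). The behavioral
#' outcome (hit / miss / false alarm) is drawn from the multinomial
#' logistic model documented in [state_config()]: the hit log-odds fall
#' with the true target-to-attention distance, the miss log-odds rise
#' with the positive part of the optimality state s1 and with the
#' responsiveness state s2, and the false-alarm log-odds rise with the
#' negative part of s1 and fall with s2.
#'
#' @param task A [task_config()].
#' @param states A `latent_states` object from [sample_latent_states()].
#' @param state_config The [state_config()] holding the outcome model
#'   coefficients.
#' @param seed Integer seed.
#' @return A list with `trial_table` (data frame: `trial_id`,
#'   `cue_landmark`, `cue_x`, `cue_y`, `target_x`, `target_y`,
#'   `stim_onset_bin`, `outcome`) and `states`, the input states with
#'   `true_as_xy` (n x 2 matrix) filled in.
#' @export
sample_attention_and_outcomes <- function(task, states, state_config,
                                          seed = NULL) {
  stopifnot(inherits(task, "task_config"),
            inherits(states, "latent_states"),
            inherits(state_config, "state_config"))
  n <- length(states$s1)
  with_seed(stream_seed(seed, "outcomes"), {
    cue_lm <- sample.int(4L, n, replace = TRUE)
    cue_xy <- task$landmark_positions[cue_lm, , drop = FALSE]
    target_xy <- cue_xy  # 100% validity: target at cued landmark
    jitter <- matrix(stats::rnorm(2L * n, sd = state_config$attention_jitter_sd),
                     ncol = 2L)
    true_as <- cue_xy + jitter
    colnames(true_as) <- c("x", "y")
    ta_true <- sqrt(rowSums((true_as - target_xy)^2))

    eta_hit <- state_config$intercept_hit - state_config$beta_ta * ta_true
    eta_miss <- state_config$intercept_miss +
      state_config$beta_s1_miss * pmax(states$s1, 0) +
      state_config$beta_s2 * states$s2
    eta_fa <- state_config$intercept_fa +
      state_config$beta_s1_fa * pmax(-states$s1, 0) -
      state_config$beta_s2 * states$s2
    eta <- cbind(hit = eta_hit, miss = eta_miss, fa = eta_fa)
    eta <- eta - apply(eta, 1L, max)
    p <- exp(eta) / rowSums(exp(eta))
    u <- stats::runif(n)
    cp <- t(apply(p, 1L, cumsum))
    outcome_idx <- 1L + (u > cp[, 1L]) + (u > cp[, 2L])
    outcome <- factor(c("hit", "miss", "fa")[outcome_idx],
                      levels = c("hit", "miss", "fa", "cr"))

    n_pre <- (task$pre_cue_window_ms + task$pre_stim_window_ms) %/%
      task$bin_width_ms
    trial_table <- data.frame(
      trial_id = seq_len(n),
      cue_landmark = cue_lm,
      cue_x = cue_xy[, 1L], cue_y = cue_xy[, 2L],
      target_x = target_xy[, 1L], target_y = target_xy[, 2L],
      stim_onset_bin = n_pre + 1L,
      outcome = outcome)
    states$true_as_xy <- true_as
    list(trial_table = trial_table, states = states)
  })
}
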