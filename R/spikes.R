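#' Session container for spike counts and trial metadata
#'
#' @param counts Integer array, trials x units x time-bins, of
#'   non-negative spike counts.
#' @param trial_table Per-trial metadata data frame with columns
#'   `trial_id`, `cue_landmark`, `cue_x`, `cue_y`, `target_x`,
#'   `target_y`, `stim_onset_bin`, `outcome`.
#' @param task The [task_config()] the session was recorded/simulated
#'   under.
#' @param session_id Character label.
#' @return An object of class `session_data`. The `$time` element
#'   records the bin width and the three time-axis segments (pre-cue,
#'   cue-aligned; pre-stimulus and post-stimulus, stimulus-aligned).
#' @export
session_data <- function(counts, trial_table, task, session_id = "s1") {
  stopifnot(inherits(task, "task_config"), length(dim(counts)) == 3L)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("'counts' must be non-negative integers")
  }
  need <- c("trial_id", "cue_landmark", "cue_x", "cue_y", "target_x",
            "target_y", "stim_onset_bin", "outcome")
  if (!all(need %in% names(trial_table))) {
    stop("trial_table is missing columns: ",
         paste(setdiff(need, names(trial_table)), collapse = ", "))
  }
  if (nrow(trial_table) != dim(counts)[1L]) {
    stop("trial_table rows must match the first dimension of 'counts'")
  }
  if (!all(as.character(trial_table$outcome) %in%
           c("hit", "miss", "fa", "cr"))) {
    stop("outcomes must be one of hit, miss, fa, cr")
  }
  if (!all(trial_table$cue_landmark %in%
           seq_len(nrow(task$landmark_positions)))) {
    stop("cue_landmark must index a task landmark")
  }
  bw <- task$bin_width_ms
  n_pre_cue <- task$pre_cue_window_ms %/% bw
  n_pre_stim <- task$pre_stim_window_ms %/% bw
  n_post <- task$post_stim_window_ms %/% bw
  if (dim(counts)[3L] != n_pre_cue + n_pre_stim + n_post) {
    stop("third dimension of 'counts' does not match the task time axis")
  }
  structure(
    list(counts = counts, trial_table = trial_table, task = task,
         session_id = session_id,
         time = list(bin_width_ms = bw, n_pre_cue = n_pre_cue,
                     n_pre_stim = n_pre_stim, n_post = n_post,
                     alignment = "bins 1..n_pre_cue end at cue onset; the rest are stimulus-aligned with onset after bin n_pre_cue + n_pre_stim")),
    class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Session %s: %d trials x %d units x %d bins (%d ms)\n",
              x$session_id, d[1L], d[2L], d[3L], x$time$bin_width_ms))
  print(table(droplevels(x$trial_table$outcome)))
  invisible(x)
}

#' Map a time window to spike-count bins
#'
#' @param session A [session_data()].
#' @param window_ms Two-element window in ms. For `align = "stimulus"`,
#'   times are relative to stimulus onset (negative = before); for
#'   `align = "cue"` only non-positive times (the pre-cue segment) are
#'   available.
#' @param align `"stimulus"` or `"cue"`.
#' @return Integer vector of bin indices whose bins lie inside the
#'   window.
#' @export
window_bins <- function(session, window_ms, align = c("stimulus", "cue")) {
  align <- match.arg(align)
  stopifnot(length(window_ms) == 2L, diff(window_ms) > 0)
  tm <- session$time
  bw <- tm$bin_width_ms
  if (align == "stimulus") {
    idx <- tm$n_pre_cue + seq_len(tm$n_pre_stim + tm$n_post)
    starts <- seq(-tm$n_pre_stim * bw, by = bw, length.out = length(idx))
  } else {
    idx <- seq_len(tm$n_pre_cue)
    starts <- seq(-tm$n_pre_cue * bw, by = bw, length.out = length(idx))
  }
  keep <- starts >= window_ms[1L] & (starts + bw) <= window_ms[2L] + 1e-9
  if (!any(keep)) stop("window does not cover any complete bin")
  idx[keep]
}

#' Generate Poisson spike counts for a session
#'
#' Implements the population rate model. For trial \eqn{t} and unit
#' \eqn{i} the pre-stimulus firing rate is
#' \deqn{r_{it} = \max\{0,\; (b_i + w^{s2}_i s_{2,t}) \,
#'   (1 + g_i K(d_{it}/\sigma_i)) (1 + f_i K(TA_t/\omega_i)) \,
#'   (1 + w^{s1}_i \tilde{s}_{1,t} + v_i |s_{1,t}| \epsilon_t)\}}
#' with \eqn{b_i} the baseline rate, \eqn{K(u) = \exp(-u^2/2)} a
#' Gaussian kernel, \eqn{d_{it}} the distance between the true
#' attentional spotlight and the unit's receptive-field centre,
#' \eqn{TA_t} the true spotlight-to-target distance driving the
#' population-wide attentional-focus gain \eqn{f_i}, and
#' \eqn{\tilde{s}_1 = |s_1| - E|s_1|} the centred magnitude of the
#' optimality state. \eqn{\epsilon_t} is a fast trial-wise standard
#' normal factor shared by the whole population: units with
#' \eqn{v_i > 0} fluctuate together, and the amplitude of that common
#' fluctuation scales with the optimality-state magnitude
#' \eqn{|s_1|}, so the shared variance — hence the noise correlation —
#' is lowest on hits (small \eqn{|s_1|}) and progressively higher on
#' false alarms and misses. The mean-rate footprints are a U shape in
#' trial type from \eqn{w^{s1}} (hits apart from both error types) and
#' a monotone gradient from \eqn{w^{s2}} (responsiveness). In the pre-cue segment the attention term is absent
#' (attention not yet deployed); post-stimulus bins add a brief additive
#' evoked transient on responded (hit/false-alarm) and, more weakly,
#' missed trials. Counts are conditionally Poisson per bin given the
#' rate.
#'
#' @param pop A [population_config()] with as many units as channels.
#' @param states A `latent_states` object with `true_as_xy` populated.
#' @param trial_table Trial metadata from [sample_attention_and_outcomes()].
#' @param task A [task_config()].
#' @param seed Integer seed.
#' @param evoked_amp Relative amplitude of the post-stimulus transient.
#' @return A [session_data()] object.
#' @export
generate_spike_counts <- function(pop, states, trial_table, task,
                                  seed = NULL, evoked_amp = 0.5) {
  stopifnot(inherits(pop, "population_config"),
            inherits(states, "latent_states"),
            inherits(task, "task_config"))
  if (is.null(states$true_as_xy)) {
    stop("states$true_as_xy is empty; run sample_attention_and_outcomes() first")
  }
  n <- nrow(trial_table)
  nu <- pop$n_units
  stopifnot(nrow(states$true_as_xy) == n)

  # distance of the true spotlight to each unit's RF centre
  dx <- outer(states$true_as_xy[, 1L], pop$rf_centers[, 1L], "-")
  dy <- outer(states$true_as_xy[, 2L], pop$rf_centers[, 2L], "-")
  K <- exp(-(dx^2 + dy^2) / (2 * rep(pop$tuning_width^2, each = n)))
  rf_gain <- 1 + K * rep(pop$tuning_gain, each = n)           # trials x units
  ta_true <- sqrt((states$true_as_xy[, 1L] - trial_table$target_x)^2 +
                    (states$true_as_xy[, 2L] - trial_table$target_y)^2)
  Kf <- exp(-outer(ta_true^2, 2 * pop$focus_width^2, "/"))
  att_gain <- rf_gain * (1 + Kf * rep(pop$focus_gain, each = n))

  s1c <- abs(states$s1) - sqrt(2 / pi) * sqrt(mean(states$s1^2))
  eps <- states$eps
  if (is.null(eps)) eps <- stats::rnorm(n)  # fallback; normally preset
  shared <- s1c %o% pop$w_s1 + (abs(states$s1) * eps) %o% pop$v_s1
  gain_state <- 1 + shared                                     # trials x units
  base_state <- outer(states$s2, pop$w_s2) + rep(pop$baseline_rates, each = n)

  rate_pre_cue <- base_state * gain_state
  rate_pre_stim <- base_state * att_gain * gain_state
  floored <- mean(rate_pre_cue < 0 | rate_pre_stim < 0)
  if (floored > 0.05) {
    warning(sprintf(
      "rate floor engaged on %.1f%% of unit-trials; configuration implausible",
      100 * floored))
  }
  rate_pre_cue <- pmax(rate_pre_cue, 0)
  rate_pre_stim <- pmax(rate_pre_stim, 0)

  bw <- task$bin_width_ms
  n1 <- task$pre_cue_window_ms %/% bw
  n2 <- task$pre_stim_window_ms %/% bw
  n3 <- task$post_stim_window_ms %/% bw
  dt <- bw / 1000

  # evoked transient shape over post-stimulus bins (peak ~80 ms)
  t_post <- (seq_len(n3) - 0.5) * bw
  shape <- (t_post / 80) * exp(1 - t_post / 80)
  resp_amp <- evoked_amp *
    ifelse(as.character(trial_table$outcome) %in% c("hit", "fa"), 1,
           ifelse(as.character(trial_table$outcome) == "miss", 0.4, 0))

  with_seed(stream_seed(seed, "spikes"), {
    counts <- array(0L, dim = c(n, nu, n1 + n2 + n3))
    for (b in seq_len(n1)) {
      counts[, , b] <- stats::rpois(n * nu, rate_pre_cue * dt)
    }
    for (b in seq_len(n2)) {
      counts[, , n1 + b] <- stats::rpois(n * nu, rate_pre_stim * dt)
    }
    base_mat <- rep(pop$baseline_rates, each = n)
    for (b in seq_len(n3)) {
      rate_post <- rate_pre_stim + base_mat * resp_amp * shape[b]
      counts[, , n1 + n2 + b] <- stats::rpois(n * nu, rate_post * dt)
    }
    session_data(counts, trial_table, task)
  })
}
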