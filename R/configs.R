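#' Task geometry and timing configuration
#'
#' Describes the cued luminance-change detection task the simulator
#' emulates and the analyses assume: four landmarks at the corners of a
#' square with a ~28 degree diagonal (~14 degrees of eccentricity), 100%
#' valid cueing, and a binned spike-count time axis made of a pre-cue
#' segment, a pre-stimulus segment, and a short post-stimulus segment.
#'
#' @param landmark_positions 4 x 2 matrix of landmark (x, y) positions in
#'   degrees of visual angle. Default: corners of a square with a 28
#'   degree diagonal, i.e. eccentricity 14 degrees.
#' @param cue_validity Fraction of validly cued trials; the task is 100%
#'   valid and the analyses assume so.
#' @param cue_to_target_range_ms Two-element interval (ms) from which the
#'   cue-to-stimulus delay is drawn.
#' @param distractor_D_fraction,distractor_d_fraction Fractions of trials
#'   carrying a target-identical (D) or a low-level (d) distractor;
#'   recorded task metadata.
#' @param bin_width_ms Spike-count bin width in ms.
#' @param pre_stim_window_ms Length (ms) of the simulated pre-stimulus
#'   segment (stimulus = target, or distractor on false-alarm trials).
#' @param pre_cue_window_ms Length (ms) of the simulated pre-cue segment.
#' @param post_stim_window_ms Length (ms) of the simulated post-stimulus
#'   segment.
#' @return An object of class `task_config`.
#' @export
#' @examples
#' task <- task_config()
#' task$landmark_positions
task_config <- function(landmark_positions = default_landmarks(),
                        cue_validity = 1.0,
                        cue_to_target_range_ms = c(750, 3300),
                        distractor_D_fraction = 0.17,
                        distractor_d_fraction = 0.33,
                        bin_width_ms = 10L,
                        pre_stim_window_ms = 400L,
                        pre_cue_window_ms = 300L,
                        post_stim_window_ms = 200L) {
  landmark_positions <- as.matrix(landmark_positions)
  if (!is.numeric(landmark_positions) || ncol(landmark_positions) != 2L ||
      nrow(landmark_positions) != 4L || any(!is.finite(landmark_positions))) {
    stop("'landmark_positions' must be a finite 4 x 2 numeric matrix")
  }
  if (anyDuplicated(landmark_positions)) {
    stop("landmark positions must be distinct")
  }
  assert_scalar_number(cue_validity, "cue_validity", 0, 1)
  if (length(cue_to_target_range_ms) != 2L ||
      diff(cue_to_target_range_ms) < 0) {
    stop("'cue_to_target_range_ms' must be an increasing interval")
  }
  assert_scalar_number(distractor_D_fraction, "distractor_D_fraction", 0, 1)
  assert_scalar_number(distractor_d_fraction, "distractor_d_fraction", 0, 1)
  if (distractor_D_fraction + distractor_d_fraction >= 1) {
    stop("distractor fractions must sum to less than 1")
  }
  for (w in c("bin_width_ms", "pre_stim_window_ms", "pre_cue_window_ms",
              "post_stim_window_ms")) {
    assert_scalar_number(get(w), w, lower = 1)
  }
  if (pre_stim_window_ms %% bin_width_ms != 0 ||
      pre_cue_window_ms %% bin_width_ms != 0 ||
      post_stim_window_ms %% bin_width_ms != 0) {
    stop("window lengths must be multiples of 'bin_width_ms'")
  }
  structure(
    list(landmark_positions = landmark_positions,
         cue_validity = cue_validity,
         cue_to_target_range_ms = as.numeric(cue_to_target_range_ms),
         distractor_D_fraction = distractor_D_fraction,
         distractor_d_fraction = distractor_d_fraction,
         bin_width_ms = as.integer(bin_width_ms),
         pre_stim_window_ms = as.integer(pre_stim_window_ms),
         pre_cue_window_ms = as.integer(pre_cue_window_ms),
         post_stim_window_ms = as.integer(post_stim_window_ms)),
    class = "task_config")
}

#' Default landmark geometry
#'
#' Corners of a square with a 28-degree diagonal centred on fixation,
#' ordered up-right, up-left, down-left, down-right.
#'
#' @return A 4 x 2 numeric matrix in degrees of visual angle.
#' @export
default_landmarks <- function() {
  r <- 28 / 2 / sqrt(2)  # 14 deg eccentricity along the diagonals
  m <- rbind(c(r, r), c(-r, r), c(-r, -r), c(r, -r))
  colnames(m) <- c("x", "y")
  m
}

#' Neural population configuration
#'
#' Per-unit parameters of the Poisson population model. Each unit has a
#' baseline rate, a spatial receptive-field centre with a Gaussian
#' attention-tuning kernel, and loadings onto the two latent behavioral
#' states. `w_s1` couples the unit multiplicatively to the magnitude of
#' the optimality state (its sign sets whether error trials, which carry
#' large state magnitudes, raise or lower the rate); `v_s1` couples the
#' unit to a shared fast gain fluctuation whose amplitude scales with
#' the optimality-state magnitude, which is what moves trial-type noise
#' correlations; `w_s2` couples the unit additively to the
#' responsiveness state (baseline rate shifts).
#'
#' @param baseline_rates Per-unit baseline firing rates (spikes/s), > 0.
#' @param rf_centers n x 2 matrix of receptive-field centres (degrees).
#' @param tuning_gain Per-unit multiplicative attention gain (>= 0; 0 =
#'   untuned).
#' @param tuning_width Per-unit spatial tuning scale (degrees, > 0).
#' @param w_s1 Per-unit loading of the centred optimality-state
#'   magnitude onto multiplicative gain.
#' @param w_s2 Per-unit loading of the responsiveness state onto baseline
#'   rate (spikes/s per state unit).
#' @param v_s1 Per-unit loading onto the shared gain fluctuation whose
#'   amplitude follows the optimality-state magnitude (defaults to
#'   `|w_s1|`).
#' @param focus_gain Per-unit multiplicative gain of the attentional
#'   focus: a population-wide modulation that rises as the spotlight
#'   approaches the expected target location, regardless of where on the
#'   screen that is (distinct from the spatial receptive-field kernel).
#' @param focus_width Spatial scale (degrees) of the focus modulation.
#' @param roles Optional character vector of planted unit roles
#'   (`"attention"`, `"outcome"`, `"mixed"`, `"none"`); recorded ground
#'   truth for recovery tests.
#' @return An object of class `population_config`.
#' @seealso [sample_population_config()] for the study-default population.
#' @export
population_config <- function(baseline_rates, rf_centers, tuning_gain,
                              tuning_width, w_s1, w_s2, v_s1 = NULL,
                              focus_gain = NULL, focus_width = 12,
                              roles = NULL) {
  n <- length(baseline_rates)
  rf_centers <- as.matrix(rf_centers)
  if (is.null(focus_gain)) focus_gain <- 0.55 * tuning_gain
  if (is.null(v_s1)) v_s1 <- 0.6 * abs(w_s1)
  focus_width <- rep_len(as.numeric(focus_width), n)
  stopifnot(nrow(rf_centers) == n, ncol(rf_centers) == 2L,
            length(tuning_gain) == n, length(tuning_width) == n,
            length(w_s1) == n, length(w_s2) == n, length(v_s1) == n,
            length(focus_gain) == n)
  if (any(!is.finite(v_s1))) stop("'v_s1' must be finite")
  if (any(!is.finite(focus_gain)) || any(!is.finite(focus_width)) ||
      any(focus_width <= 0)) {
    stop("'focus_gain' must be finite and 'focus_width' positive")
  }
  if (any(!is.finite(baseline_rates)) || any(baseline_rates <= 0)) {
    stop("'baseline_rates' must be finite and > 0")
  }
  if (any(!is.finite(tuning_width)) || any(tuning_width <= 0)) {
    stop("'tuning_width' must be finite and > 0")
  }
  if (any(!is.finite(c(tuning_gain, w_s1, w_s2, rf_centers)))) {
    stop("population parameters must be finite")
  }
  if (is.null(roles)) {
    att <- tuning_gain != 0 | focus_gain != 0
    beh <- (w_s1 != 0) | (w_s2 != 0) | (v_s1 != 0)
    roles <- ifelse(att & beh, "mixed",
                    ifelse(att, "attention",
                           ifelse(beh, "outcome", "none")))
  }
  structure(
    list(n_units = n,
         baseline_rates = as.numeric(baseline_rates),
         rf_centers = rf_centers,
         tuning_gain = as.numeric(tuning_gain),
         tuning_width = as.numeric(tuning_width),
         w_s1 = as.numeric(w_s1),
         w_s2 = as.numeric(w_s2),
         v_s1 = as.numeric(v_s1),
         focus_gain = as.numeric(focus_gain),
         focus_width = focus_width,
         roles = roles,
         mixed_fraction = mean(roles == "mixed")),
    class = "population_config")
}

#' Sample the study-default population
#'
#' Draws a population of units emulating the recorded multi-unit
#' ensembles: receptive fields scattered around the four landmarks,
#' log-normal baseline rates, a majority of attention-tuned units and a
#' smaller set of behavioral-state-loaded units, with a configurable
#' `overlap` between the two groups. `overlap` is the correlation of the
#' Gaussian copula from which the attention and state memberships are
#' drawn: at 0 the two unit sets are independent; near 1 state loadings
#' concentrate on the attention-tuned units, which makes the attention
#' and outcome population axes overlap.
#'
#' @param n_units Number of units (default 48, two 24-contact probes).
#' @param overlap Copula correlation in (-1, 1) between attention tuning
#'   and state-loading membership; negative values push state loadings
#'   onto untuned units.
#' @param p_attention,p_state Marginal probabilities that a unit is
#'   attention-tuned / state-loaded.
#' @param task A [task_config()], used to place receptive fields.
#' @param seed Integer seed.
#' @return A [population_config()].
#' @export
sample_population_config <- function(n_units = 48L, overlap = 0.3,
                                     p_attention = 0.55, p_state = 0.45,
                                     task = task_config(), seed = 1L) {
  assert_scalar_number(overlap, "overlap", -0.999, 0.999)
  with_seed(stream_seed(seed, "population"), {
    base <- stats::rlnorm(n_units, meanlog = log(30), sdlog = 0.4)
    lm_idx <- rep_len(seq_len(4L), n_units)
    rf <- task$landmark_positions[lm_idx, , drop = FALSE] +
      matrix(stats::rnorm(2 * n_units, sd = 3), ncol = 2)
    # memberships with exact counts: the attention-tuned and
    # state-loaded unit counts, and their intersection, are fixed at the
    # expected values of a Gaussian copula with correlation `overlap`,
    # so the planted population overlap is not diluted by sampling noise
    n_att <- round(p_attention * n_units)
    n_beh <- round(p_state * n_units)
    a <- stats::qnorm(1 - p_attention)
    b <- stats::qnorm(1 - p_state)
    p_both <- stats::integrate(function(z) {
      stats::dnorm(z) *
        stats::pnorm((overlap * z - b) / sqrt(1 - overlap^2))
    }, a, Inf)$value
    n_both <- min(n_att, n_beh,
                  max(n_att + n_beh - n_units, round(p_both * n_units)))
    ord <- sample.int(n_units)
    att <- beh <- rep(FALSE, n_units)
    att[ord[seq_len(n_att)]] <- TRUE
    beh[ord[seq_len(n_both)]] <- TRUE
    if (n_beh > n_both) {
      beh[ord[n_att + seq_len(n_beh - n_both)]] <- TRUE
    }
    gain <- ifelse(att, stats::runif(n_units, 1, 2), 0)
    # each state unit carries either the optimality (s1, gain) or the
    # responsiveness (s2, additive) loading: the two latent axes then
    # live on separable unit subpopulations, as needed for the demixed
    # components to be identifiable; both enter with the same sign
    # convention (error trials lower the rate)
    has_s1 <- beh & (stats::runif(n_units) < 0.5)
    has_s2 <- beh & !has_s1
    w1 <- ifelse(has_s1, -stats::runif(n_units, 0.35, 0.55), 0)
    w2 <- ifelse(has_s2, -stats::runif(n_units, 5, 8), 0)
    population_config(
      baseline_rates = base, rf_centers = rf, tuning_gain = gain,
      tuning_width = stats::runif(n_units, 6, 9), w_s1 = w1, w_s2 = w2)
  })
}

#' Latent behavioral-state configuration
#'
#' Parameters of the two slowly drifting latent states and of the
#' trial-outcome model. State `s1` ("optimality") relates to outcome in a
#' U-shaped way: its positive extreme raises the odds of a miss
#' (distractibility), its negative extreme the odds of a false alarm
#' (impulsivity), and values near zero favour hits. State `s2`
#' ("responsiveness") relates to outcome linearly, ordering miss > hit >
#' false alarm. Outcomes are drawn from a multinomial logistic model with
#' linear predictors
#' \deqn{\eta_{hit} = b_{hit} - \beta_{TA} \cdot TA}
#' \deqn{\eta_{miss} = b_{miss} + \beta_{s1,miss} \max(s_1, 0) + \beta_{s2} s_2}
#' \deqn{\eta_{fa} = b_{fa} + \beta_{s1,fa} \max(-s_1, 0) - \beta_{s2} s_2}
#' where TA is the true target-to-attention distance in degrees.
#'
#' @param ar_coeff AR(1) coefficients of (s1, s2), each in [0, 1);
#'   scalars are recycled.
#' @param state_sd Stationary standard deviations of (s1, s2), > 0.
#' @param beta_ta Slope (per degree) of TA on the hit log-odds, >= 0.
#' @param beta_s1_miss,beta_s1_fa Coefficients mapping the positive /
#'   negative part of s1 to miss / false-alarm log-odds.
#' @param beta_s2 Coefficient mapping s2 to the miss-vs-false-alarm
#'   log-odds.
#' @param attention_jitter_sd Isotropic dispersion (degrees) of the true
#'   attentional spotlight around the cued landmark.
#' @param intercept_hit,intercept_miss,intercept_fa Outcome intercepts.
#' @return An object of class `state_config`.
#' @export
state_config <- function(ar_coeff = c(0.7, 0.7),
                         state_sd = c(1, 1),
                         beta_ta = 0.07,
                         beta_s1_miss = 2.0,
                         beta_s1_fa = 1.2,
                         beta_s2 = 1.0,
                         attention_jitter_sd = 8.5,
                         intercept_hit = 3.2,
                         intercept_miss = -0.7,
                         intercept_fa = 0.3) {
  ar_coeff <- rep_len(as.numeric(ar_coeff), 2L)
  state_sd <- rep_len(as.numeric(state_sd), 2L)
  if (any(!is.finite(ar_coeff)) || any(ar_coeff < 0) || any(ar_coeff >= 1)) {
    stop("'ar_coeff' must be in [0, 1)")
  }
  if (any(!is.finite(state_sd)) || any(state_sd <= 0)) {
    stop("'state_sd' must be finite and > 0")
  }
  for (nm in c("beta_ta", "beta_s1_miss", "beta_s1_fa", "beta_s2",
               "intercept_hit", "intercept_miss", "intercept_fa")) {
    assert_scalar_number(get(nm), nm)
  }
  assert_scalar_number(attention_jitter_sd, "attention_jitter_sd", lower = 0)
  structure(
    list(ar_coeff = ar_coeff, state_sd = state_sd, beta_ta = beta_ta,
         beta_s1_miss = beta_s1_miss, beta_s1_fa = beta_s1_fa,
         beta_s2 = beta_s2, attention_jitter_sd = attention_jitter_sd,
         intercept_hit = intercept_hit, intercept_miss = intercept_miss,
         intercept_fa = intercept_fa),
    class = "state_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat("Cued detection task: 4 landmarks at",
      sprintf("%.1f deg eccentricity,", sqrt(sum(x$landmark_positions[1, ]^2))),
      sprintf("cue validity %d%%\n", round(100 * x$cue_validity)))
  cat(sprintf("Time axis: %d ms pre-cue | %d ms pre-stimulus | %d ms post-stimulus, %d ms bins\n",
              x$pre_cue_window_ms, x$pre_stim_window_ms,
              x$post_stim_window_ms, x$bin_width_ms))
  invisible(x)
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf("Population of %d units: %d attention-tuned, %d state-loaded, %d mixed\n",
              x$n_units, sum(x$tuning_gain != 0),
              sum(x$w_s1 != 0 | x$w_s2 != 0), sum(x$roles == "mixed")))
  invisible(x)
}

#' @export
print.state_config <- function(x, ...) {
  cat(sprintf("Latent states: AR(1) coeff (%.2f, %.2f), SD (%.2f, %.2f)\n",
              x$ar_coeff[1], x$ar_coeff[2], x$state_sd[1], x$state_sd[2]))
  cat(sprintf("Outcome model: beta_ta %.3f/deg, beta_s1 (miss %.2f, fa %.2f), beta_s2 %.2f\n",
              x$beta_ta, x$beta_s1_miss, x$beta_s1_fa, x$beta_s2))
  invisible(x)
}
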