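#' Simulate one session
#'
#' Chains [sample_latent_states()], [sample_attention_and_outcomes()]
#' and [generate_spike_counts()] under one seed.
#'
#' @param n_trials Number of trials.
#' @param task,pop,states_cfg Configurations; defaults are the study
#'   conditions.
#' @param seed Integer seed.
#' @param session_id Character label.
#' @return A list with elements `session` ([session_data()]), `states`
#'   (`latent_states` ground truth) and `population`
#'   ([population_config()] ground truth).
#' @export
simulate_session <- function(n_trials = 800L, task = task_config(),
                             pop = NULL, states_cfg = state_config(),
                             seed = 1L, session_id = "s1") {
  if (is.null(pop)) pop <- sample_population_config(task = task, seed = seed)
  states <- sample_latent_states(states_cfg, n_trials, seed = seed)
  beh <- sample_attention_and_outcomes(task, states, states_cfg, seed = seed)
  session <- generate_spike_counts(pop, beh$states, beh$trial_table, task,
                                   seed = seed)
  session$session_id <- session_id
  list(session = session, states = beh$states, population = pop)
}

#' Simulate a multi-session study
#'
#' Generates independent sessions with per-session seeds derived
#' deterministically from the master seed. When `vary_overlap = TRUE`
#' the sessions plant a coupling between the overlap of the attention
#' and behavioral-state unit populations and the behavioral benefit of
#' attention: the population `overlap` parameter increases linearly
#' across sessions over `overlap_range` while the TA slope on hit
#' log-odds decreases over `beta_ta_range`. This emulates the
#' across-session relation in which a larger functional overlap between
#' attention- and outcome-coding populations goes with a smaller
#' behavioral gain of well-placed attention.
#'
#' @param n_sessions,n_trials Study size.
#' @param task,states_cfg Shared configurations.
#' @param seed Master seed.
#' @param vary_overlap Plant the overlap-vs-gain coupling?
#' @param overlap_range,beta_ta_range Endpoints of the per-session
#'   linear ramps used when `vary_overlap = TRUE`.
#' @return A list of per-session lists as returned by
#'   [simulate_session()].
#' @export
simulate_sessions <- function(n_sessions = 18L, n_trials = 800L,
                              task = task_config(),
                              states_cfg = state_config(),
                              seed = 1L, vary_overlap = FALSE,
                              overlap_range = c(-0.8, 0.9),
                              beta_ta_range = c(0.20, 0.02)) {
  assert_scalar_number(n_sessions, "n_sessions", lower = 1)
  n_sessions <- as.integer(n_sessions)
  out <- vector("list", n_sessions)
  for (k in seq_len(n_sessions)) {
    frac <- if (n_sessions == 1L) 0 else (k - 1) / (n_sessions - 1)
    cfg_k <- states_cfg
    pop_seed <- stream_seed(seed, "session", k)
    if (vary_overlap) {
      ov <- overlap_range[1L] + frac * diff(overlap_range)
      cfg_k$beta_ta <- beta_ta_range[1L] + frac * diff(beta_ta_range)
      pop_k <- sample_population_config(overlap = ov, task = task,
                                       seed = pop_seed)
    } else {
      pop_k <- sample_population_config(task = task, seed = pop_seed)
    }
    out[[k]] <- simulate_session(
      n_trials = n_trials, task = task, pop = pop_k, states_cfg = cfg_k,
      seed = derive_seed(seed, 11L, k), session_id = sprintf("s%02d", k))
  }
  out
}

#' Write / read a session directory
#'
#' `write_session()` stores a session as one directory: the count tensor
#' as an RDS array (`counts.rds`), the trial table as RFC-4180 CSV
#' (`trial_table.csv`), the task configuration as JSON and a manifest
#' recording dimensions, bin width and time-axis alignment.
#' `read_session()` restores the [session_data()] object.
#'
#' @param session A [session_data()].
#' @param dir Directory to create/read.
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   a [session_data()].
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(session$counts, file.path(dir, "counts.rds"))
  utils::write.csv(session$trial_table, file.path(dir, "trial_table.csv"),
                   row.names = FALSE)
  task <- session$task
  task$landmark_positions <- unclass(task$landmark_positions)
  jsonlite::write_json(unclass(task), file.path(dir, "task.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    c(list(session_id = session$session_id, dims = dim(session$counts)),
      session$time),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  if (!dir.exists(dir)) stop("session directory not found: ", dir)
  counts <- readRDS(file.path(dir, "counts.rds"))
  tt <- utils::read.csv(file.path(dir, "trial_table.csv"))
  tt$outcome <- factor(tt$outcome, levels = c("hit", "miss", "fa", "cr"))
  tj <- jsonlite::read_json(file.path(dir, "task.json"), simplifyVector = TRUE)
  task <- task_config(
    landmark_positions = matrix(unlist(tj$landmark_positions), ncol = 2,
                                byrow = FALSE,
                                dimnames = list(NULL, c("x", "y"))),
    cue_validity = tj$cue_validity,
    cue_to_target_range_ms = tj$cue_to_target_range_ms,
    distractor_D_fraction = tj$distractor_D_fraction,
    distractor_d_fraction = tj$distractor_d_fraction,
    bin_width_ms = tj$bin_width_ms,
    pre_stim_window_ms = tj$pre_stim_window_ms,
    pre_cue_window_ms = tj$pre_cue_window_ms,
    post_stim_window_ms = tj$post_stim_window_ms)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  session_data(counts, tt, task, session_id = mf$session_id)
}
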