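#' Identify the U-shaped and linear trial-type components
#'
#' Projects the per-type condition means (time-averaged) of a trial-type
#' condition tensor onto the first two demixed decoder axes and labels
#' the component whose projections set hits apart from both error types
#' as "U-shaped" and the one with a monotone miss > hit > fa gradient as
#' "linear".
#'
#' @param model A `dpca_model` fitted to a `"trialtype"` tensor.
#' @param tensor The tensor the model was fitted to.
#' @return List with `u_comp`, `linear_comp` (component indices within
#'   the `trial_type` marginalization) and `proj` (2 x 3 matrix of
#'   projections, columns miss/hit/fa).
#' @export
classify_trialtype_components <- function(model, tensor) {
  fit <- model$marginalizations[["trial_type"]]
  if (is.null(fit) || nrow(fit$D) < 2L) {
    stop("model has fewer than 2 trial-type components")
  }
  # time-averaged condition means in unit space (centred)
  Xc <- array(model$X, dim = model$tensor_dims)
  cm <- apply(Xc, c(1L, 2L), mean)               # units x 3 types
  proj <- fit$D[1:2, , drop = FALSE] %*% cm      # 2 x (miss, hit, fa)
  colnames(proj) <- tensor$factor_levels$trial_type
  # decompose each axis profile into the canonical U (hit apart from
  # both errors) and linear (miss-to-fa gradient) contrasts, then take
  # the assignment of axes to roles that explains most contrast overall
  pc <- proj - rowMeans(proj)
  pc <- pc / pmax(sqrt(rowSums(pc^2)), 1e-12)
  u0 <- c(1, -2, 1) / sqrt(6)
  l0 <- c(1, 0, -1) / sqrt(2)
  u_score <- abs(as.vector(pc %*% u0[match(colnames(proj),
                                           c("miss", "hit", "fa"))]))
  lin_score <- abs(as.vector(pc %*% l0[match(colnames(proj),
                                             c("miss", "hit", "fa"))]))
  u_comp <- if (u_score[1L] + lin_score[2L] >=
                u_score[2L] + lin_score[1L]) 1L else 2L
  list(u_comp = u_comp, linear_comp = 3L - u_comp, proj = proj)
}

#' Single-trial projections onto a demixed axis
#'
#' @param model A `dpca_model`.
#' @param tensor Its `condition_tensor`.
#' @param marginalization,component Axis selector.
#' @return Numeric vector: time-averaged projection per retained trial,
#'   in chronological order.
#' @export
axis_projections <- function(model, tensor, marginalization,
                             component = 1L) {
  d <- model$marginalizations[[marginalization]]$D[component, ]
  nu <- dim(tensor$trials)[1L]
  proj <- matrix(crossprod(matrix(tensor$trials, nrow = nu), d),
                 nrow = dim(tensor$trials)[2L])
  rowMeans(proj)
}

#' Trial-to-trial persistence of behavior-related activity
#'
#' Correlates the projection of trial t with that of trial t - 1 on the
#' behavior-related demixed axes, quantifying whether the underlying
#' state outlasts single trials.
#'
#' @param model A `dpca_model`.
#' @param tensor Its tensor (trials in chronological order).
#' @param marginalization Marginalization holding the axes.
#' @param components Component indices to test.
#' @return Data frame with `component`, `r` (lag-1 Pearson), `p`;
#'   `NA` with a warning for fewer than 20 trials.
#' @export
cross_trial_state_correlation <- function(model, tensor,
                                          marginalization = "trial_type",
                                          components = c(1L, 2L)) {
  n <- dim(tensor$trials)[2L]
  if (n < 20L) {
    warning("fewer than 20 trials; lag-1 correlation not estimated")
    return(data.frame(component = components, r = NA_real_, p = NA_real_))
  }
  adj <- which(diff(tensor$trial_ids) == 1L)  # consecutive trials only
  if (length(adj) < 10L) {
    warning("too few consecutive trial pairs; lag-1 correlation unreliable")
  }
  do.call(rbind, lapply(components, function(k) {
    pr <- axis_projections(model, tensor, marginalization, k)
    ct <- stats::cor.test(pr[adj + 1L], pr[adj])
    data.frame(component = k, r = unname(ct$estimate), p = ct$p.value)
  }))
}

#' Trial-type summaries before and after component removal
#'
#' For the original data and after removing the U-shaped or the linear
#' trial-type component, computes per trial type the positive-significant
#' noise-correlation summary and the population mean rate, from the
#' retained single trials of the tensor's analysis window.
#'
#' @param model A `dpca_model` fitted to a `"trialtype"` tensor.
#' @param tensor The tensor.
#' @return Data frame with columns `variant` (`original`, `remove_u`,
#'   `remove_linear`), `trial_type`, `nc_mean`, `rate_mean`, `n_trials`.
#' @export
component_removal_summary <- function(model, tensor) {
  cls <- classify_trialtype_components(model, tensor)
  variants <- list(
    original = tensor,
    remove_u = remove_component_backproject(model, tensor, "trial_type",
                                            cls$u_comp),
    remove_linear = remove_component_backproject(model, tensor,
                                                 "trial_type",
                                                 cls$linear_comp))
  types <- tensor$factor_levels$trial_type
  do.call(rbind, lapply(names(variants), function(v) {
    tr <- variants[[v]]$trials
    resp <- rowSums(aperm(tr, c(2L, 1L, 3L)), dims = 2L) / dim(tr)[3L]
    do.call(rbind, lapply(types, function(ty) {
      rows <- which(tensor$trial_cond[[1L]] == ty)
      nc <- if (length(rows) >= 3L) {
        sds <- apply(resp[rows, , drop = FALSE], 2L, stats::sd)
        z <- scale(resp[rows, sds > 0, drop = FALSE])
        noise_correlation(z)$mean
      } else NA_real_
      data.frame(variant = v, trial_type = ty, nc_mean = nc,
                 rate_mean = mean(resp[rows, ]),
                 n_trials = length(rows))
    }))
  }))
}

#' Analyze one session end to end
#'
#' Runs the full analysis chain on one session: rolling attentional
#' decoding, TA summaries, unit selectivity, trial-type noise
#' correlations (raw and TA-equalized), the joint (TA x outcome),
#' single-parameter (TA-only, outcome-only) and trial-type demixed
#' PCAs, axis decoding with permutation chance, component overlap, and
#' component-removal summaries.
#'
#' @param session A [session_data()].
#' @param lambda Ridge penalty for the attention decoder (`"auto"` =
#'   GCV).
#' @param dpca_lambda Demixed-PCA regularization fraction.
#' @param n_cv,n_shuffle Cross-validation repeats and label shuffles for
#'   axis decoding.
#' @param seed Integer seed for all stochastic steps.
#' @return An object of class `session_analysis`: a list of stage
#'   outputs plus a one-row `summary` data frame.
#' @export
analyze_session <- function(session, lambda = "auto", dpca_lambda = 1e-6,
                            n_cv = 100L, n_shuffle = 100L, seed = 1L) {
  stopifnot(inherits(session, "session_data"))
  estimates <- rolling_decode(session, lambda = lambda)
  if (nrow(estimates) == 0L) stop("no tested trials; session too short")
  hr <- hit_rate_by_ta(estimates, session$trial_table)
  hr_eq <- hit_rate_by_ta(estimates, session$trial_table, equalize = TRUE,
                          seed = seed)
  sel <- unit_selectivity(session, estimates)
  nc <- noise_corr_by_outcome(session, seed = seed)
  nc_eq <- noise_corr_by_outcome(session, equalize_ta = TRUE,
                                 estimates = estimates, seed = seed)

  tens_joint <- build_condition_tensor(session, estimates, "ta_x_outcome",
                                       seed = seed)
  model_joint <- fit_dpca(tens_joint, lambda = dpca_lambda)
  tens_ta <- build_condition_tensor(session, estimates, "ta_only",
                                    seed = seed)
  model_ta <- fit_dpca(tens_ta, lambda = dpca_lambda)
  tens_out <- build_condition_tensor(session, estimates, "outcome_only",
                                     seed = seed)
  model_out <- fit_dpca(tens_out, lambda = dpca_lambda)
  # trial-type analyses: unbalanced (all trials retained, preserving
  # consecutive-trial structure) but TA-equalized, so that trial-type
  # components cannot reflect attentional-focus differences
  tens_type <- build_condition_tensor(session, estimates, "trialtype",
                                      balanced = FALSE, equalize_ta = TRUE,
                                      seed = seed)
  model_type <- fit_dpca(tens_type, lambda = dpca_lambda)
  # pre-cue variant: behavioral states isolated from attention-related
  # variance (attention not yet deployed before the cue)
  tens_type_pc <- build_condition_tensor(session, estimates, "trialtype",
                                         window_ms = c(-300, 0),
                                         align = "cue", balanced = FALSE,
                                         equalize_ta = TRUE, seed = seed)
  model_type_pc <- fit_dpca(tens_type_pc, lambda = dpca_lambda)

  dec <- list(
    attention_joint = decode_with_axis(model_joint, tens_joint,
                                       "attention", 1L, n_cv, n_shuffle,
                                       seed),
    outcome_joint = decode_with_axis(model_joint, tens_joint, "outcome",
                                     1L, n_cv, n_shuffle, seed),
    interaction_joint = decode_with_axis(model_joint, tens_joint,
                                         "interaction", 1L, n_cv,
                                         n_shuffle, seed),
    attention_single = decode_with_axis(model_ta, tens_ta, "attention",
                                        1L, n_cv, n_shuffle, seed),
    outcome_single = decode_with_axis(model_out, tens_out, "outcome", 1L,
                                      n_cv, n_shuffle, seed),
    trialtype_1 = decode_with_axis(model_type, tens_type, "trial_type",
                                   1L, n_cv, n_shuffle, seed),
    trialtype_2 = decode_with_axis(model_type, tens_type, "trial_type",
                                   2L, n_cv, n_shuffle, seed))

  f_att <- model_joint$marginalizations$attention
  f_out <- model_joint$marginalizations$outcome
  # overlap between the first attention and outcome components; the
  # session estimate is the median |dot| over refits on resampled
  # near-balanced condition averages, which tames the estimation noise
  # of a single subsample
  dots <- vapply(seq_len(6L), function(r) {
    tr <- build_condition_tensor(session, estimates, "ta_x_outcome",
                                 equalize_ta = TRUE,
                                 seed = derive_seed(if (is.null(seed)) 0
                                                    else seed, 41L, r))
    mr <- fit_dpca(tr, lambda = dpca_lambda)
    c(abs(sum(mr$marginalizations$attention$F[, 1L] *
                mr$marginalizations$outcome$F[, 1L])),
      axis_overlap(mr$marginalizations$attention$D[1L, ],
                   mr$marginalizations$outcome$D[1L, ])$dot)
  }, numeric(2L))
  overlap_enc <- axis_overlap(f_att$F[, 1L], f_out$F[, 1L],
                              seed = stream_seed(seed, "shuffle"))
  overlap_enc$dot <- stats::median(dots[1L, ])
  overlap_enc$angle_deg <- acos(min(overlap_enc$dot, 1)) * 180 / pi
  overlap_dec <- axis_overlap(f_att$D[1L, ], f_out$D[1L, ],
                              seed = stream_seed(seed, "shuffle"))
  overlap_dec$dot <- stats::median(dots[2L, ])
  overlap_dec$angle_deg <- acos(min(overlap_dec$dot, 1)) * 180 / pi

  removal <- component_removal_summary(model_type, tens_type)
  lag1 <- cross_trial_state_correlation(model_type, tens_type)
  type_comps <- classify_trialtype_components(model_type, tens_type)

  gain <- function(h) {
    if (!all(c("close", "far") %in% h$ta_bin)) return(NA_real_)
    h$accuracy[h$ta_bin == "close"] - h$accuracy[h$ta_bin == "far"]
  }
  nc_pt <- nc[nc$epoch == "pre_target", ]
  summary <- data.frame(
    session_id = session$session_id,
    n_tested = nrow(estimates),
    behavioral_gain = gain(hr),
    behavioral_gain_equalized = gain(hr_eq),
    overlap = overlap_enc$dot,
    overlap_decoder = overlap_dec$dot,
    acc_attention_joint = dec$attention_joint$accuracy,
    acc_outcome_joint = dec$outcome_joint$accuracy,
    acc_interaction_joint = dec$interaction_joint$accuracy,
    acc_attention_single = dec$attention_single$accuracy,
    acc_outcome_single = dec$outcome_single$accuracy,
    acc_trialtype_1 = dec$trialtype_1$accuracy,
    acc_trialtype_2 = dec$trialtype_2$accuracy,
    nc_hit = nc_pt$nc_mean[nc_pt$trial_type == "hit"],
    nc_miss = nc_pt$nc_mean[nc_pt$trial_type == "miss"],
    nc_fa = nc_pt$nc_mean[nc_pt$trial_type == "fa"],
    u_comp = type_comps$u_comp,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed))

  structure(
    list(estimates = estimates, hit_rate = hr, hit_rate_equalized = hr_eq,
         selectivity = sel, noise_corr = nc, noise_corr_equalized = nc_eq,
         tensors = list(joint = tens_joint, ta = tens_ta,
                        outcome = tens_out, trialtype = tens_type,
                        trialtype_precue = tens_type_pc),
         models = list(joint = model_joint, ta = model_ta,
                       outcome = model_out, trialtype = model_type,
                       trialtype_precue = model_type_pc),
         decodings = dec, overlap = overlap_enc,
         overlap_decoder = overlap_dec, removal = removal,
         lag1 = lag1, trialtype_components = type_comps,
         summary = summary),
    class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat("Session analysis:", x$summary$session_id, "\n")
  print(x$summary[, c("behavioral_gain", "overlap", "acc_attention_joint",
                      "acc_outcome_joint")])
  invisible(x)
}

#' Demixing cost across sessions
#'
#' Compares, per session and parameter, the axis-decoding accuracy of
#' the single-parameter demixed PCA (variance demixed only from
#' condition-independent activity) with the joint demixed PCA (attention
#' and outcome demixed from each other). When the two parameters share
#' neural variance, forcing them apart costs accuracy.
#'
#' @param summaries The `summary` table of a [run_study()] result (one
#'   row per session).
#' @return List with per-parameter mean paired differences
#'   (single - joint) and two-sided Wilcoxon signed-rank p-values.
#' @export
demixing_cost <- function(summaries) {
  d_att <- summaries$acc_attention_single - summaries$acc_attention_joint
  d_out <- summaries$acc_outcome_single - summaries$acc_outcome_joint
  wt <- function(d) {
    if (length(d) < 2L || all(d == 0)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
  }
  list(attention = list(mean_diff = mean(d_att), p = wt(d_att),
                        per_session = d_att),
       outcome = list(mean_diff = mean(d_out), p = wt(d_out),
                      per_session = d_out))
}

#' Overlap versus behavioral gain across sessions
#'
#' Spearman correlation, across sessions, between the overlap of the
#' first attention and outcome demixed components and the behavioral
#' gain of attention (hit-rate difference between TA-close and TA-far
#' trials).
#'
#' @param summaries The `summary` table of a [run_study()] result
#'   (>= 5 sessions).
#' @return List with `rho`, `p`, `n` and the scatter data frame.
#' @export
overlap_vs_gain <- function(summaries) {
  ok <- stats::complete.cases(summaries[, c("overlap", "behavioral_gain")])
  s <- summaries[ok, ]
  if (nrow(s) < 5L) stop("need at least 5 sessions")
  if (stats::sd(s$overlap) == 0) {
    warning("constant overlap; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = nrow(s),
                data = s[, c("session_id", "overlap", "behavioral_gain")]))
  }
  ct <- suppressWarnings(stats::cor.test(s$overlap, s$behavioral_gain,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(s),
       data = s[, c("session_id", "overlap", "behavioral_gain")])
}

#' Run the full multi-session study
#'
#' Simulates (or accepts) sessions, analyzes each with
#' [analyze_session()], and aggregates the across-session statistics:
#' pooled hit rate by TA bin, noise-correlation ordering, demixing
#' cost, overlap-versus-gain correlation, component-removal contrasts
#' and state-recovery correlations against the planted ground truth.
#' Optionally writes a report (JSON summary, CSV tables, figures) to
#' `out_dir`.
#'
#' @param n_sessions,n_trials Study size.
#' @param seed Master seed for simulation and analysis.
#' @param vary_overlap Plant the across-session overlap-vs-gain coupling
#'   (the study default).
#' @param sessions Optional pre-simulated session list (as returned by
#'   [simulate_sessions()]); overrides simulation.
#' @param n_cv,n_shuffle Axis-decoding settings passed through.
#' @param out_dir Optional output directory for the report.
#' @param progress Print per-stage progress?
#' @return An object of class `attn_study`: per-session analyses,
#'   the pooled `summary` table, aggregate statistics, and the stage
#'   log.
#' @export
run_study <- function(n_sessions = 18L, n_trials = 800L, seed = 1L,
                      vary_overlap = TRUE, sessions = NULL,
                      n_cv = 100L, n_shuffle = 100L, out_dir = NULL,
                      progress = FALSE) {
  stages <- character(0)
  note <- function(s) {
    stages <<- c(stages, s)
    if (progress) message("[", format(Sys.time(), "%H:%M:%S"), "] ", s)
  }
  note("simulate")
  if (is.null(sessions)) {
    sessions <- simulate_sessions(n_sessions, n_trials, seed = seed,
                                  vary_overlap = vary_overlap)
  }
  note("decode+selectivity+noise_corr+dpca")
  analyses <- lapply(seq_along(sessions), function(k) {
    if (progress) message("  session ", k, "/", length(sessions))
    analyze_session(sessions[[k]]$session, n_cv = n_cv,
                    n_shuffle = n_shuffle,
                    seed = derive_seed(seed, 31L, k))
  })
  summaries <- do.call(rbind, lapply(analyses, `[[`, "summary"))

  note("pooled_behavior")
  hr_all <- do.call(rbind, lapply(analyses, function(a)
    a$hit_rate[, c("ta_bin", "n_hit", "n_miss")]))
  hr_pooled <- stats::aggregate(cbind(n_hit, n_miss) ~ ta_bin, hr_all, sum)
  hr_pooled$accuracy <- hr_pooled$n_hit / (hr_pooled$n_hit +
                                             hr_pooled$n_miss)
  hr_pooled <- hr_pooled[match(c("close", "medium", "far"),
                               as.character(hr_pooled$ta_bin)), ]

  note("selectivity_recovery")
  recovery <- vapply(seq_along(sessions), function(k) {
    planted <- sessions[[k]]$population$roles
    found <- as.character(analyses[[k]]$selectivity$selectivity_class)
    mean(found == planted)
  }, numeric(1L))

  note("state_recovery")
  state_rec <- do.call(rbind, lapply(seq_along(sessions), function(k) {
    a <- analyses[[k]]
    st <- sessions[[k]]$states
    tens <- a$tensors$trialtype_precue
    mod <- a$models$trialtype_precue
    rows <- match(tens$trial_ids,
                  sessions[[k]]$session$trial_table$trial_id)
    cmp <- classify_trialtype_components(mod, tens)
    pr_u <- axis_projections(mod, tens, "trial_type", cmp$u_comp)
    pr_l <- axis_projections(mod, tens, "trial_type", cmp$linear_comp)
    data.frame(
      session_id = a$summary$session_id,
      rho_u_s1 = stats::cor(pr_u, abs(st$s1[rows]), method = "spearman"),
      rho_linear_s2 = stats::cor(pr_l, st$s2[rows], method = "spearman"))
  }))

  note("aggregate")
  nc_order_frac <- mean(with(summaries, nc_hit < nc_fa & nc_fa < nc_miss),
                        na.rm = TRUE)
  ovg <- if (nrow(summaries) >= 5L) {
    overlap_vs_gain(summaries)
  } else {
    list(rho = NA_real_, p = NA_real_, n = nrow(summaries),
         data = summaries[, c("session_id", "overlap", "behavioral_gain")])
  }
  cost <- demixing_cost(summaries)
  removal <- do.call(rbind, lapply(analyses, function(a) {
    cbind(session_id = a$summary$session_id, a$removal)
  }))
  lag1 <- do.call(rbind, lapply(analyses, function(a) {
    cbind(session_id = a$summary$session_id, a$lag1)
  }))

  study <- structure(
    list(analyses = analyses, sessions = sessions, summary = summaries,
         hit_rate_pooled = hr_pooled, selectivity_recovery = recovery,
         state_recovery = state_rec, nc_order_frac = nc_order_frac,
         overlap_vs_gain = ovg, demixing_cost = cost, removal = removal,
         lag1 = lag1, seed = seed, stages = stages),
    class = "attn_study")
  if (!is.null(out_dir)) {
    note("report")
    write_study_report(study, out_dir)
    study$stages <- stages
  }
  study
}

#' @export
print.attn_study <- function(x, ...) {
  cat(sprintf("Study of %d sessions (seed %s)\n", nrow(x$summary),
              x$seed))
  cat("Hit rate by TA bin:",
      paste(sprintf("%s %.2f", x$hit_rate_pooled$ta_bin,
                    x$hit_rate_pooled$accuracy), collapse = ", "), "\n")
  cat(sprintf("Noise-correlation ordering hit < fa < miss in %.0f%% of sessions\n",
              100 * x$nc_order_frac))
  cat(sprintf("Overlap vs gain: Spearman rho = %.2f (p = %.3g)\n",
              x$overlap_vs_gain$rho, x$overlap_vs_gain$p))
  invisible(x)
}

#' Write the study report
#'
#' Writes a machine-readable JSON summary, CSV tables (per-session
#' summaries, pooled hit rates, component-removal contrasts, state
#' recovery) and static figures to a directory.
#'
#' @param study An `attn_study`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(study$summary, file.path(out_dir, "session_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(study$hit_rate_pooled,
                   file.path(out_dir, "hit_rate_by_ta.csv"),
                   row.names = FALSE)
  utils::write.csv(study$removal, file.path(out_dir, "component_removal.csv"),
                   row.names = FALSE)
  utils::write.csv(study$state_recovery,
                   file.path(out_dir, "state_recovery.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed,
         n_sessions = nrow(study$summary),
         stages = study$stages,
         hit_rate_by_ta = stats::setNames(
           as.list(study$hit_rate_pooled$accuracy),
           as.character(study$hit_rate_pooled$ta_bin)),
         nc_order_frac = study$nc_order_frac,
         overlap_vs_gain = study$overlap_vs_gain[c("rho", "p", "n")],
         demixing_cost = list(
           attention = study$demixing_cost$attention[c("mean_diff", "p")],
           outcome = study$demixing_cost$outcome[c("mean_diff", "p")]),
         selectivity_recovery = mean(study$selectivity_recovery),
         state_recovery = list(
           rho_u_s1 = mean(abs(study$state_recovery$rho_u_s1)),
           rho_linear_s2 = mean(abs(study$state_recovery$rho_linear_s2)))),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)

  grDevices::png(file.path(out_dir, "hit_rate_by_ta.png"), 600, 450)
  graphics::barplot(study$hit_rate_pooled$accuracy,
                    names.arg = as.character(study$hit_rate_pooled$ta_bin),
                    ylim = c(0, 1), ylab = "hit / (hit + miss)",
                    xlab = "TA bin", main = "Detection accuracy by TA")
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "noise_corr_by_type.png"), 600, 450)
  graphics::boxplot(study$summary[, c("nc_hit", "nc_fa", "nc_miss")],
                    names = c("hit", "fa", "miss"),
                    ylab = "mean positive-significant r",
                    main = "Pre-target noise correlation by trial type")
  grDevices::dev.off()
  grDevices::png(file.path(out_dir, "overlap_vs_gain.png"), 600, 450)
  graphics::plot(study$summary$overlap, study$summary$behavioral_gain,
                 xlab = "|dot| attention vs outcome component",
                 ylab = "behavioral gain (close - far)",
                 main = sprintf("Spearman rho = %.2f",
                                study$overlap_vs_gain$rho), pch = 19)
  grDevices::dev.off()
  invisible(out_dir)
}
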