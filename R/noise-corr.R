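#' Windowed, z-scored trial responses
#'
#' Average response of each channel over the analysis epoch (200 ms
#' before stimulus onset for `pre_target`, 200 ms before cue onset for
#' `pre_cue`), z-scored per channel across the trials of the subset
#' (sample SD, denominator n - 1). Channels with zero variance over the
#' subset are excluded with a warning.
#'
#' @param session A [session_data()].
#' @param epoch `"pre_target"` or `"pre_cue"`.
#' @param trial_subset Integer or logical trial selector (>= 3 trials).
#' @param window_ms Epoch length in ms.
#' @return Trials x channels matrix with per-channel mean 0 and SD 1;
#'   attribute `channels` gives the retained channel indices.
#' @export
trial_responses <- function(session, epoch = c("pre_target", "pre_cue"),
                            trial_subset = NULL, window_ms = 200) {
  epoch <- match.arg(epoch)
  stopifnot(inherits(session, "session_data"))
  if (is.null(trial_subset)) trial_subset <- seq_len(dim(session$counts)[1L])
  bins <- if (epoch == "pre_target") {
    window_bins(session, c(-window_ms, 0), "stimulus")
  } else {
    window_bins(session, c(-window_ms, 0), "cue")
  }
  x <- session$counts[trial_subset, , bins, drop = FALSE]
  if (dim(x)[1L] < 3L) stop("need at least 3 trials in the subset")
  resp <- rowSums(x, dims = 2L) / dim(x)[3L]
  sds <- apply(resp, 2L, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance channel(s) excluded")
  }
  z <- scale(resp[, keep, drop = FALSE])
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "channels") <- which(keep)
  z
}

#' Pairwise noise correlations with a positive-significant summary
#'
#' Pearson correlation matrix between the z-scored per-trial responses
#' of all channel pairs, with per-pair two-sided significance from the
#' t-distribution. The summary statistics (mean and median) are taken
#' over the pairs with r > 0 and p < `alpha` only.
#'
#' @param responses Trials x channels matrix (e.g. from
#'   [trial_responses()]).
#' @param alpha Per-pair significance level.
#' @return List with `r` (correlation matrix), `p` (p-value matrix),
#'   `mean`, `median` (over retained pairs; `NA` if none), `n_pairs`
#'   (retained) and `n_trials`.
#' @export
noise_correlation <- function(responses, alpha = 0.05) {
  responses <- as.matrix(responses)
  n <- nrow(responses)
  if (n < 3L) stop("need at least 3 trials")
  r <- stats::cor(responses)
  p <- pearson_p(r, n)
  diag(p) <- NA
  ut <- upper.tri(r)
  keep <- ut & r > 0 & p < alpha
  vals <- r[keep]
  list(r = r, p = p,
       mean = if (length(vals)) mean(vals) else NA_real_,
       median = if (length(vals)) stats::median(vals) else NA_real_,
       n_pairs = length(vals), n_trials = n)
}

#' Noise correlations by behavioral trial type
#'
#' Computes the positive-significant noise-correlation summary
#' separately for hit, miss and false-alarm trials, on the pre-target
#' and/or pre-cue epoch. With `equalize_ta = TRUE`, trial types are
#' first subsampled (seeded) to matching TA-bin distributions: the
#' TA-bin profile of the scarcest trial type is taken as the target and
#' every type is subsampled, bin by bin, to that profile (keeping as
#' many trials as the profile allows), so that differences between
#' types cannot be explained by attentional focus.
#'
#' @param session A [session_data()].
#' @param epochs Character vector among `"pre_target"`, `"pre_cue"`.
#' @param equalize_ta Equalize TA distributions across trial types?
#' @param estimates Attentional estimates (required when
#'   `equalize_ta = TRUE`; also restricts trials to tested ones).
#' @param window_ms Epoch length (ms).
#' @param seed Seed for the equalization subsample.
#' @return A data frame with one row per epoch x trial type:
#'   `epoch`, `trial_type`, `nc_mean`, `nc_median`, `n_pairs`,
#'   `n_trials`. Types absent from the session are reported with `NA`.
#' @export
noise_corr_by_outcome <- function(session,
                                  epochs = c("pre_target", "pre_cue"),
                                  equalize_ta = FALSE, estimates = NULL,
                                  window_ms = 200, seed = NULL) {
  stopifnot(inherits(session, "session_data"))
  tt <- session$trial_table
  types <- c("hit", "miss", "fa")
  rows_of <- lapply(types, function(ty) which(as.character(tt$outcome) == ty))
  names(rows_of) <- types

  if (equalize_ta) {
    if (is.null(estimates)) stop("'estimates' required for TA equalization")
    rows_of <- ta_matched_rows(rows_of, tt, estimates,
                               stream_seed(seed, "equalize"))
  }

  out <- do.call(rbind, lapply(epochs, function(ep) {
    do.call(rbind, lapply(types, function(ty) {
      rows <- rows_of[[ty]]
      if (length(rows) < 3L) {
        if (length(rows) > 0L || !(ty %in% as.character(tt$outcome))) {
          warning("trial type '", ty, "' missing or too small; reported NA")
        }
        return(data.frame(epoch = ep, trial_type = ty, nc_mean = NA_real_,
                          nc_median = NA_real_, n_pairs = 0L,
                          n_trials = length(rows)))
      }
      z <- suppressWarnings(trial_responses(session, ep, rows,
                                            window_ms = window_ms))
      nc <- noise_correlation(z)
      data.frame(epoch = ep, trial_type = ty, nc_mean = nc$mean,
                 nc_median = nc$median, n_pairs = nc$n_pairs,
                 n_trials = nc$n_trials)
    }))
  }))
  out$trial_type <- factor(out$trial_type, levels = types)
  rownames(out) <- NULL
  out
}
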