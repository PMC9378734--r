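#' Modulation index between two firing rates
#'
#' \eqn{MI = (FR_1 - FR_2) / (FR_1 + FR_2)}; antisymmetric in its
#' arguments and bounded in [-1, 1] for non-negative rates.
#'
#' @param fr1,fr2 Non-negative rates (vectorized).
#' @return The index; `NA` where `fr1 + fr2 == 0` (undefined).
#' @export
#' @examples
#' modulation_index(3, 1)  # 0.5
modulation_index <- function(fr1, fr2) {
  stopifnot(all(fr1 >= 0, na.rm = TRUE), all(fr2 >= 0, na.rm = TRUE))
  tot <- fr1 + fr2
  ifelse(tot > 0, (fr1 - fr2) / tot, NA_real_)
}

#' Per-unit attention and outcome selectivity
#'
#' For each unit, computes (i) an attention modulation index from the
#' median firing rates of TA-close versus TA-far correct trials and (ii)
#' a behavioral-outcome modulation index from hit versus miss trials
#' irrespective of TA, both on the pre-target `analysis_window_ms`.
#' Per-trial rate differences are tested with a two-sided Wilcoxon
#' rank-sum test at `alpha`; a unit is classed `mixed` if both indices
#' are significant, `attention`/`outcome` if exactly one is, `none`
#' otherwise.
#'
#' @param session A [session_data()].
#' @param estimates Attentional estimates from [rolling_decode()].
#' @param analysis_window_ms Pre-target analysis window (ms relative to
#'   stimulus onset).
#' @param alpha Significance level.
#' @param min_trials Minimum trials per class; units with fewer are
#'   flagged `reliable = FALSE`.
#' @param min_rate Minimum session-mean rate (spikes/s) for a unit to be
#'   considered task-related; others are flagged unreliable.
#' @return A data frame with one row per unit: `unit_id`,
#'   `mi_attention`, `mi_outcome`, `p_attention`, `p_outcome`,
#'   `selectivity_class`, `reliable`.
#' @export
unit_selectivity <- function(session, estimates,
                             analysis_window_ms = c(-250, -50),
                             alpha = 0.05, min_trials = 10L,
                             min_rate = 0.5) {
  stopifnot(inherits(session, "session_data"))
  tt <- session$trial_table
  dt <- session$time$bin_width_ms / 1000
  bins <- window_bins(session, analysis_window_ms, "stimulus")
  rates <- rowSums(session$counts[, , bins, drop = FALSE], dims = 2L) /
    (length(bins) * dt)

  m <- merge(estimates, tt[, c("trial_id", "outcome")], by = "trial_id")
  row_of <- match(m$trial_id, tt$trial_id)
  is_hit <- as.character(m$outcome) == "hit"
  att1 <- row_of[is_hit & m$ta_bin == "close"]
  att2 <- row_of[is_hit & m$ta_bin == "far"]
  out1 <- row_of[is_hit]
  out2 <- row_of[as.character(m$outcome) == "miss"]

  one_index <- function(rows1, rows2, r) {
    if (length(rows1) < 2L || length(rows2) < 2L) {
      return(c(mi = NA_real_, p = NA_real_))
    }
    mi <- modulation_index(stats::median(r[rows1]), stats::median(r[rows2]))
    p <- suppressWarnings(
      stats::wilcox.test(r[rows1], r[rows2], exact = FALSE)$p.value)
    c(mi = mi, p = p)
  }

  nu <- dim(session$counts)[2L]
  res <- t(vapply(seq_len(nu), function(i) {
    r <- rates[, i]
    c(one_index(att1, att2, r), one_index(out1, out2, r))
  }, numeric(4L)))
  colnames(res) <- c("mi_attention", "p_attention", "mi_outcome",
                     "p_outcome")

  sig_a <- !is.na(res[, "p_attention"]) & res[, "p_attention"] < alpha
  sig_o <- !is.na(res[, "p_outcome"]) & res[, "p_outcome"] < alpha
  cls <- ifelse(sig_a & sig_o, "mixed",
                ifelse(sig_a, "attention",
                       ifelse(sig_o, "outcome", "none")))
  reliable <- min(length(att1), length(att2), length(out1),
                  length(out2)) >= min_trials &
    colMeans(rates) >= min_rate
  data.frame(unit_id = seq_len(nu),
             mi_attention = res[, "mi_attention"],
             mi_outcome = res[, "mi_outcome"],
             p_attention = res[, "p_attention"],
             p_outcome = res[, "p_outcome"],
             selectivity_class = factor(cls, levels = c("attention",
                                                        "outcome", "mixed",
                                                        "none")),
             reliable = reliable)
}

#' Rank correlation of absolute modulation indices
#'
#' Spearman correlation between |attention MI| and |outcome MI| over a
#' subset of units, quantifying whether units that carry attention
#' information also tend to carry outcome information.
#'
#' @param records Output of [unit_selectivity()].
#' @param subset Optional logical/integer subset of rows (e.g. one
#'   selectivity class).
#' @return List with `rho`, `p`, `n`. `rho` is `NA` with a warning when
#'   either index vector is constant.
#' @export
mi_correlation <- function(records, subset = NULL) {
  if (!is.null(subset)) records <- records[subset, , drop = FALSE]
  ok <- stats::complete.cases(records[, c("mi_attention", "mi_outcome")])
  records <- records[ok, , drop = FALSE]
  if (nrow(records) < 3L) stop("need at least 3 units with both indices")
  a <- abs(records$mi_attention); b <- abs(records$mi_outcome)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant index vector; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = nrow(records)))
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(records))
}
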