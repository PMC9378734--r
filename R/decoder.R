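#' Fit the regularized optimal linear estimator (ridge decoder)
#'
#' Fits the decoder mapping population responses to the attended
#' location as two independent ridge regressions, one classifying the
#' x-axis (classes -1/+1) and one the y-axis, i.e. the exact minimizer
#' of \eqn{\|W(R + b) - C\|^2 + \lambda \|W\|^2} via the closed-form
#' ridge normal equations. The bias is handled by mean-centring the
#' responses and refitting an intercept, which is equivalent to the
#' `W (R + b)` parameterization up to reparameterization.
#'
#' @param R Trials x channels response matrix (finite).
#' @param C Trials x 2 class matrix with entries in -1/+1 (columns =
#'   x-axis, y-axis classes).
#' @param lambda Ridge penalty (>= 0), or `"auto"` to select by
#'   generalized cross-validation over a log grid \eqn{10^{-3} ... 10^3}
#'   (scaled by the mean squared response).
#' @return An object of class `decoder_weights`: list with `W`
#'   (channels x 2), `intercept` (length 2), `lambda`, and the column
#'   means used for centring.
#' @export
#' @examples
#' R <- matrix(rnorm(200), 50, 4)
#' C <- cbind(sign(R[, 1]), sign(R[, 2]))
#' w <- fit_regole(R, C, lambda = 1)
fit_regole <- function(R, C, lambda = "auto") {
  R <- as.matrix(R); C <- as.matrix(C)
  stopifnot(is.numeric(R), all(is.finite(R)), nrow(R) == nrow(C),
            ncol(C) == 2L)
  if (any(apply(C, 2L, function(v) length(unique(v))) < 2L)) {
    stop("each class axis needs at least 2 distinct classes")
  }
  if (identical(lambda, "auto")) lambda <- select_lambda_gcv(R, C)
  assert_scalar_number(lambda, "lambda", lower = 0)
  mu <- colMeans(R)
  Xc <- sweep(R, 2L, mu)
  G <- crossprod(Xc) + diag(lambda, ncol(R))
  W <- tryCatch(solve(G, crossprod(Xc, C)),
                error = function(e) {
                  stop("singular normal equations (collinear channels at ",
                       "lambda = 0); use lambda > 0", call. = FALSE)
                })
  intercept <- colMeans(C)  # Xc has zero column means
  structure(list(W = W, intercept = intercept, lambda = lambda,
                 center = mu),
            class = "decoder_weights")
}

#' @export
print.decoder_weights <- function(x, ...) {
  cat(sprintf("RegOLE decoder: %d channels, lambda = %.4g\n",
              nrow(x$W), x$lambda))
  invisible(x)
}

#' Predict continuous (x, y) readout from a fitted decoder
#'
#' @param object A `decoder_weights` from [fit_regole()].
#' @param newdata Trials x channels response matrix.
#' @param ... Unused.
#' @return Trials x 2 matrix of continuous class readouts.
#' @export
predict.decoder_weights <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  sweep(newdata, 2L, object$center) %*% object$W +
    rep(object$intercept, each = nrow(newdata))
}

#' Generalized cross-validation for the ridge penalty
#'
#' @param R Trials x channels responses.
#' @param C Trials x k targets.
#' @param grid Candidate penalties; defaults to a 13-point log grid
#'   \eqn{10^{-3}..10^3} scaled by the mean squared centred response.
#' @return The penalty minimizing the GCV score.
#' @export
select_lambda_gcv <- function(R, C, grid = NULL) {
  R <- as.matrix(R); C <- as.matrix(C)
  Xc <- sweep(R, 2L, colMeans(R))
  Yc <- sweep(C, 2L, colMeans(C))
  if (is.null(grid)) grid <- 10^seq(-3, 3, length.out = 13) *
      mean(Xc^2) * ncol(Xc)
  sv <- svd(Xc)
  n <- nrow(Xc)
  UtY <- crossprod(sv$u, Yc)
  scores <- vapply(grid, function(lam) {
    shrink <- sv$d^2 / (sv$d^2 + lam)
    fit <- sv$u %*% (shrink * UtY)
    edf <- sum(shrink)
    sum((Yc - fit)^2) / n / (1 - edf / n)^2
  }, numeric(1L))
  grid[which.min(scores)]
}

#' Rolling train/test decoding of the attentional spotlight
#'
#' Emulates the session-long decoding schedule: once `train_size`
#' correct (hit) trials have accumulated, a decoder is trained on those
#' trials and applied to each subsequent trial; after every `step`
#' further hits the decoder is retrained on the last `train_size` hits.
#' Training responses are averaged over `training_window_ms` and test
#' responses over `testing_window_ms` (both relative to stimulus onset).
#' A tested trial is never part of its own training set. Continuous
#' decoder readouts are rescaled to degrees by an affine calibration
#' mapping the -1/+1 class codes to the mean absolute training cue
#' coordinates.
#'
#' @param session A [session_data()].
#' @param lambda Ridge penalty or `"auto"` (GCV on the first training
#'   set, then kept fixed).
#' @param train_size Number of correct trials in the training database.
#' @param step Retraining period in correct trials.
#' @param training_window_ms,testing_window_ms Windows (ms, relative to
#'   stimulus onset).
#' @return A data frame of attentional estimates for tested trials:
#'   `trial_id`, `x_as`, `y_as`, `ta`, `ta_bin`; attribute
#'   `n_retrainings` counts retrainings after the initial fit. Trials
#'   before the warm-up are excluded. If fewer than `train_size` hits
#'   exist, an empty frame is returned with a warning.
#' @export
rolling_decode <- function(session, lambda = "auto", train_size = 200L,
                           step = 20L,
                           training_window_ms = c(-220, 30),
                           testing_window_ms = c(-150, 0)) {
  stopifnot(inherits(session, "session_data"))
  tt <- session$trial_table
  n <- nrow(tt)
  dt <- session$time$bin_width_ms / 1000
  train_bins <- window_bins(session, training_window_ms, "stimulus")
  test_bins <- window_bins(session, testing_window_ms, "stimulus")
  resp_train <- rowSums(session$counts[, , train_bins, drop = FALSE],
                        dims = 2L) / (length(train_bins) * dt)
  resp_test <- rowSums(session$counts[, , test_bins, drop = FALSE],
                       dims = 2L) / (length(test_bins) * dt)

  is_hit <- as.character(tt$outcome) == "hit"
  if (sum(is_hit) < train_size) {
    warning("fewer correct trials than 'train_size'; nothing decoded")
    out <- data.frame(trial_id = integer(), x_as = numeric(),
                      y_as = numeric(), ta = numeric(),
                      ta_bin = factor(character(),
                                      levels = c("close", "medium", "far",
                                                 "out_of_range")))
    attr(out, "n_retrainings") <- 0L
    return(out)
  }

  hit_idx <- which(is_hit)
  weights <- NULL
  cal <- NULL
  lam <- lambda
  n_retrain <- -1L  # first fit is the initial training, not a retraining
  hits_at_fit <- 0L
  est <- matrix(NA_real_, n, 2L)

  fit_on <- function(train_rows) {
    Rtr <- resp_train[train_rows, , drop = FALSE]
    Ctr <- cbind(sign(tt$cue_x[train_rows]), sign(tt$cue_y[train_rows]))
    if (identical(lam, "auto")) lam <<- select_lambda_gcv(Rtr, Ctr)
    weights <<- fit_regole(Rtr, Ctr, lambda = lam)
    cal <<- c(mean(abs(tt$cue_x[train_rows])),
              mean(abs(tt$cue_y[train_rows])))
    n_retrain <<- n_retrain + 1L
  }

  hits_seen <- 0L
  for (j in seq_len(n)) {
    if (hits_seen >= train_size &&
        (is.null(weights) || hits_seen - hits_at_fit >= step)) {
      fit_on(hit_idx[(hits_seen - train_size + 1L):hits_seen])
      hits_at_fit <- hits_seen
    }
    if (!is.null(weights)) {
      est[j, ] <- predict(weights, resp_test[j, , drop = FALSE]) * cal
    }
    if (is_hit[j]) hits_seen <- hits_seen + 1L
  }

  tested <- which(!is.na(est[, 1L]))
  ta <- compute_ta(est[tested, , drop = FALSE],
                   cbind(tt$target_x, tt$target_y)[tested, , drop = FALSE])
  out <- data.frame(trial_id = tt$trial_id[tested],
                    x_as = est[tested, 1L], y_as = est[tested, 2L],
                    ta = ta, ta_bin = bin_ta(ta))
  attr(out, "n_retrainings") <- max(n_retrain, 0L)
  out
}

#' Target-to-attention distance
#'
#' Euclidean distance between the decoded attentional spotlight and the
#' expected target location,
#' \eqn{TA = \sqrt{(x_{AS} - x_t)^2 + (y_{AS} - y_t)^2}}.
#'
#' @param as_xy,target_xy Points or n x 2 matrices (degrees).
#' @return Numeric vector of distances (degrees).
#' @export
#' @examples
#' compute_ta(c(3, 4), c(0, 0))  # 5
compute_ta <- function(as_xy, target_xy) {
  as_xy <- rbind(as_xy); target_xy <- rbind(target_xy)
  stopifnot(ncol(as_xy) == 2L, ncol(target_xy) == 2L,
            all(is.finite(as_xy)), all(is.finite(target_xy)))
  if (nrow(target_xy) == 1L && nrow(as_xy) > 1L) {
    target_xy <- target_xy[rep(1L, nrow(as_xy)), , drop = FALSE]
  }
  unname(sqrt(rowSums((as_xy - target_xy)^2)))
}

#' Bin target-to-attention distances
#'
#' Half-open bins: close (0 < TA <= 6), medium (6 < TA <= 12), far
#' (12 < TA < 18); TA = 0 is counted as close and TA >= 18 as
#' out_of_range.
#'
#' @param ta Non-negative distances (degrees).
#' @return Factor with levels `close`, `medium`, `far`, `out_of_range`.
#' @export
bin_ta <- function(ta) {
  if (any(!is.finite(ta)) || any(ta < 0)) stop("TA must be >= 0 and finite")
  lab <- ifelse(ta <= 6, "close",
                ifelse(ta <= 12, "medium",
                       ifelse(ta < 18, "far", "out_of_range")))
  factor(lab, levels = c("close", "medium", "far", "out_of_range"))
}

#' Hit rate as a function of target-to-attention distance
#'
#' Per-TA-bin detection accuracy hit/(hit + miss) over tested trials.
#' With `equalize = TRUE`, hit and miss trials are first randomly
#' subsampled (seeded) to equal session-level counts.
#'
#' @param estimates Attentional estimates from [rolling_decode()].
#' @param trial_table The session trial table.
#' @param equalize Equalize hit and miss counts before binning?
#' @param seed Seed for the equalization subsample.
#' @return Data frame with `ta_bin`, `n_hit`, `n_miss`, `accuracy`;
#'   empty bins are omitted with a warning.
#' @export
hit_rate_by_ta <- function(estimates, trial_table, equalize = FALSE,
                           seed = NULL) {
  m <- merge(estimates, trial_table[, c("trial_id", "outcome")],
             by = "trial_id")
  m <- m[as.character(m$outcome) %in% c("hit", "miss"), ]
  if (equalize) {
    hits <- which(as.character(m$outcome) == "hit")
    misses <- which(as.character(m$outcome) == "miss")
    k <- min(length(hits), length(misses))
    keep <- with_seed(stream_seed(seed, "equalize"),
                      c(sample(hits, k), sample(misses, k)))
    m <- m[sort(keep), ]
  }
  bins <- levels(m$ta_bin)[seq_len(3L)]  # out_of_range not summarized
  res <- do.call(rbind, lapply(bins, function(b) {
    sub <- m[m$ta_bin == b, ]
    data.frame(ta_bin = b, n_hit = sum(sub$outcome == "hit"),
               n_miss = sum(sub$outcome == "miss"))
  }))
  empty <- res$n_hit + res$n_miss == 0L
  if (any(empty)) {
    warning("empty TA bin(s) omitted: ",
            paste(res$ta_bin[empty], collapse = ", "))
    res <- res[!empty, ]
  }
  res$accuracy <- res$n_hit / (res$n_hit + res$n_miss)
  res
}
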