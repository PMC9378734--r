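#' Build a trial-averaged condition tensor
#'
#' Selects the analysis epoch, converts spike counts to rates, smooths
#' each unit's trace with a Gaussian kernel, assigns every retained
#' trial to a condition cell, and averages trials within each cell.
#' Condition grids: `"ta_x_outcome"` (3 TA bins x hit/miss on tested
#' trials), `"trialtype"` (hit/miss/false alarm), and the
#' single-parameter grids `"ta_only"` (3 TA bins, hit and miss trials
#' pooled) and `"outcome_only"` (hit vs miss). Single trials are
#' retained for axis decoding.
#'
#' @param session A [session_data()].
#' @param estimates Attentional estimates from [rolling_decode()];
#'   required for the `"ta_x_outcome"` grid and, when supplied for
#'   `"trialtype"`, restricts the analysis to tested trials.
#' @param grid `"ta_x_outcome"`, `"trialtype"`, `"ta_only"` or
#'   `"outcome_only"`.
#' @param window_ms Analysis window (ms, relative to the alignment
#'   event).
#' @param align `"stimulus"` or `"cue"` (pre-cue epoch).
#' @param smooth_sd_ms Gaussian smoothing kernel SD in ms (0 disables).
#' @param balanced Near-balanced averaging: subsample every cell
#'   (seeded) to the larger of the smallest cell count and
#'   `min_per_cell`, so one sparse cell cannot starve the whole fit.
#' @param min_per_cell Floor for the near-balanced cell size.
#' @param equalize_ta Subsample trial outcome classes (seeded) to
#'   matching TA distributions before analysis, so that outcome-related
#'   components cannot reflect attentional-focus differences between
#'   classes: the `"trialtype"` grid matches hit/miss/fa on the TA-bin
#'   profile; the TA grids match hit and miss within 2-degree TA
#'   sub-bins. Requires `estimates`.
#' @param normalize Soft-normalize each unit by `1 / (mean rate + 5)`
#'   (spikes/s) so that high-rate units do not dominate the population
#'   axes.
#' @param seed Seed for balanced subsampling.
#' @return An object of class `condition_tensor`: `X` (units x
#'   condition... x time array), `trials` (units x trials x time),
#'   `trial_cond` (data frame of per-trial condition labels),
#'   `factor_names`, `cell_counts`, plus window/smoothing metadata.
#' @export
build_condition_tensor <- function(session, estimates = NULL,
                                   grid = c("ta_x_outcome", "trialtype",
                                            "ta_only", "outcome_only"),
                                   window_ms = c(-300, 0),
                                   align = c("stimulus", "cue"),
                                   smooth_sd_ms = 30, balanced = TRUE,
                                   min_per_cell = 8L,
                                   equalize_ta = FALSE, normalize = TRUE,
                                   seed = NULL) {
  grid <- match.arg(grid)
  align <- match.arg(align)
  stopifnot(inherits(session, "session_data"))
  tt <- session$trial_table
  dt <- session$time$bin_width_ms / 1000

  if (grid %in% c("ta_x_outcome", "ta_only", "outcome_only")) {
    if (is.null(estimates)) stop("'estimates' required for the TA grids")
    m <- merge(estimates, tt[, c("trial_id", "outcome")], by = "trial_id")
    m <- m[as.character(m$outcome) %in% c("hit", "miss") &
             m$ta_bin %in% c("close", "medium", "far"), ]
    if (equalize_ta) {
      # match hit and miss TA profiles at 2-degree resolution so that
      # the outcome marginal cannot encode residual within-bin TA
      rows_of <- split(match(m$trial_id, tt$trial_id),
                       as.character(m$outcome))
      fine <- cut(estimates$ta, seq(0, 18, by = 2), include.lowest = TRUE)
      sel <- ta_matched_rows(rows_of, tt, estimates,
                             stream_seed(seed, "equalize"), bins = fine)
      keep_rows <- sort(unlist(sel))
      m <- m[match(tt$trial_id[keep_rows], m$trial_id), ]
    }
    trial_rows <- match(m$trial_id, tt$trial_id)
    att <- factor(as.character(m$ta_bin),
                  levels = c("close", "medium", "far"))
    outc <- factor(as.character(m$outcome), levels = c("hit", "miss"))
    if (grid == "ta_x_outcome") {
      cond <- data.frame(attention = att, outcome = outc)
      factor_names <- c("attention", "outcome")
    } else if (grid == "ta_only") {
      cond <- data.frame(attention = att)
      factor_names <- "attention"
    } else {
      cond <- data.frame(outcome = outc)
      factor_names <- "outcome"
    }
  } else {
    keep_ids <- if (is.null(estimates)) tt$trial_id else estimates$trial_id
    rows <- which(tt$trial_id %in% keep_ids &
                    as.character(tt$outcome) %in% c("hit", "miss", "fa"))
    if (equalize_ta) {
      if (is.null(estimates)) stop("'estimates' required for TA equalization")
      rows_of <- split(rows, as.character(tt$outcome[rows]))
      rows <- sort(unlist(ta_matched_rows(rows_of, tt, estimates,
                                          stream_seed(seed, "equalize"))))
    }
    trial_rows <- rows
    cond <- data.frame(
      trial_type = factor(as.character(tt$outcome[rows]),
                          levels = c("miss", "hit", "fa")))
    factor_names <- "trial_type"
  }

  lv <- lapply(cond, levels)
  cell_id <- interaction(cond, drop = FALSE)
  counts_per_cell <- table(cell_id)
  if (any(counts_per_cell == 0L)) {
    stop("empty condition cell(s): ",
         paste(names(counts_per_cell)[counts_per_cell == 0L], collapse = ", "))
  }
  if (any(counts_per_cell < 5L)) {
    warning("condition cell(s) with fewer than 5 trials: ",
            paste(names(counts_per_cell)[counts_per_cell < 5L],
                  collapse = ", "))
  }
  if (balanced) {
    k <- max(min(counts_per_cell), min_per_cell)
    keep <- with_seed(stream_seed(seed, "equalize"), {
      unlist(lapply(split(seq_along(trial_rows), cell_id),
                    function(ix) if (length(ix) > k) sample(ix, k) else ix))
    })
    keep <- sort(keep)
    trial_rows <- trial_rows[keep]
    cond <- cond[keep, , drop = FALSE]
    cell_id <- droplevels(interaction(cond, drop = FALSE))
    counts_per_cell <- table(cell_id)
  }

  bins <- window_bins(session, window_ms, align)
  nt <- length(bins)
  nu <- dim(session$counts)[2L]
  sd_bins <- smooth_sd_ms / session$time$bin_width_ms

  # units x trials x time, smoothed rates
  x <- session$counts[trial_rows, , bins, drop = FALSE] / dt
  trials_arr <- array(0, dim = c(nu, length(trial_rows), nt))
  for (j in seq_along(trial_rows)) {
    trials_arr[, j, ] <- gauss_smooth_rows(
      matrix(x[j, , ], nrow = nu), sd_bins)
  }
  norm_factors <- rep(1, nu)
  if (normalize) {
    norm_factors <- 1 / (apply(trials_arr, 1L, mean) + 5)
    trials_arr <- trials_arr * norm_factors
  }

  dims <- c(nu, vapply(lv, length, integer(1L)), nt)
  X <- array(0, dim = dims)
  idx_grid <- expand.grid(lapply(lv, function(z) seq_along(z)))
  for (g in seq_len(nrow(idx_grid))) {
    sel <- rep(TRUE, nrow(cond))
    for (f in seq_along(lv)) {
      sel <- sel & (as.integer(cond[[f]]) == idx_grid[g, f])
    }
    avg <- apply(trials_arr[, sel, , drop = FALSE], c(1L, 3L), mean)
    if (length(lv) == 1L) {
      X[, idx_grid[g, 1L], ] <- avg
    } else {
      X[, idx_grid[g, 1L], idx_grid[g, 2L], ] <- avg
    }
  }

  structure(
    list(X = X, trials = trials_arr, trial_cond = cond,
         trial_ids = tt$trial_id[trial_rows],
         factor_names = factor_names, factor_levels = lv,
         cell_counts = counts_per_cell, window_ms = window_ms,
         align = align, smooth_sd_ms = smooth_sd_ms,
         norm_factors = norm_factors,
         bin_width_ms = session$time$bin_width_ms),
    class = "condition_tensor")
}

#' @export
print.condition_tensor <- function(x, ...) {
  cat(sprintf("Condition tensor: %d units x (%s) x %d bins, %d single trials\n",
              dim(x$X)[1L],
              paste(vapply(x$factor_levels, length, integer(1L)),
                    collapse = " x "),
              dim(x$X)[length(dim(x$X))], dim(x$trials)[2L]))
  invisible(x)
}

#' Factorial marginalization of a condition tensor
#'
#' Decomposes the grand-mean-centred tensor into parameter-specific
#' marginalizations: for a two-factor grid (attention x outcome x time)
#' the pieces are the attention marginal (attention main effect plus its
#' interaction with time), the outcome marginal, the
#' attention-x-outcome interaction (plus its time interaction), and the
#' condition-independent (pure time) part; for a one-factor grid, the
#' factor marginal and the condition-independent part. The pieces are
#' the standard factorial (ANOVA-style) averages with lower-order terms
#' subtracted, and sum exactly to the centred tensor.
#'
#' @param tensor A `condition_tensor`, or a bare array (units x
#'   conditions... x time).
#' @param factor_names Names for the condition factors when `tensor` is
#'   a bare array.
#' @return Named list of arrays, each the same shape as the centred
#'   tensor; attribute `grand_mean` holds the per-unit mean that was
#'   subtracted.
#' @export
marginalize <- function(tensor, factor_names = NULL) {
  if (inherits(tensor, "condition_tensor")) {
    X <- tensor$X
    factor_names <- tensor$factor_names
  } else {
    X <- tensor
    if (is.null(factor_names)) {
      factor_names <- paste0("factor", seq_len(length(dim(X)) - 2L))
    }
  }
  nd <- length(dim(X))
  stopifnot(nd %in% c(3L, 4L), length(factor_names) == nd - 2L)
  n <- dim(X)[1L]

  mean_over <- function(A, dims_out) {
    # average over all dims not in dims_out, then broadcast back
    m <- apply(A, dims_out, mean)
    if (length(dims_out) == 1L) m <- array(m, dim = dim(X)[dims_out])
    sweep_back(m, dims_out)
  }
  sweep_back <- function(m, dims_out) {
    # expand an array defined over dims_out to the full shape of X
    perm <- c(dims_out, setdiff(seq_len(nd), dims_out))
    full <- array(m, dim = dim(X)[perm])
    aperm(full, order(perm))
  }

  gm <- apply(X, 1L, mean)
  Xc <- X - sweep_back(array(gm, dim = n), 1L)

  if (nd == 3L) {            # units x A x time
    A <- mean_over(Xc, c(1L, 2L))
    Tt <- mean_over(Xc, c(1L, 3L))
    AT <- Xc - A - Tt
    out <- list(A + AT, Tt)
    names(out) <- c(factor_names, "condition_independent")
  } else {                   # units x A x B x time
    A <- mean_over(Xc, c(1L, 2L))
    B <- mean_over(Xc, c(1L, 3L))
    Tt <- mean_over(Xc, c(1L, 4L))
    AB <- mean_over(Xc, c(1L, 2L, 3L)) - A - B
    AT <- mean_over(Xc, c(1L, 2L, 4L)) - A - Tt
    BT <- mean_over(Xc, c(1L, 3L, 4L)) - B - Tt
    ABT <- Xc - A - B - Tt - AB - AT - BT
    out <- list(A + AT, B + BT, AB + ABT, Tt)
    names(out) <- c(factor_names, "interaction", "condition_independent")
  }
  attr(out, "grand_mean") <- gm
  attr(out, "centered") <- Xc
  out
}

# flatten units x ... array to units x rest matrix
flatten_units <- function(A) {
  d <- dim(A)
  matrix(A, nrow = d[1L])
}

#' Fit demixed PCA
#'
#' For each marginalization \eqn{\phi}, finds the reduced-rank
#' regularized solution of
#' \eqn{\|X_\phi - F_\phi D_\phi X\|^2 + \mu \|F_\phi D_\phi\|^2}
#' where X is the centred data matrix (units x condition-time): the
#' full-rank ridge solution \eqn{X_\phi X^\top (X X^\top + \mu I)^{-1}}
#' is rank-reduced through the SVD of its image, yielding decoder axes
#' `D` (rows) and orthonormal encoder axes `F` (columns). The sign of
#' each component is fixed so that the largest-magnitude element of the
#' decoder axis is positive, making fits bit-reproducible.
#'
#' @param tensor A `condition_tensor` (or bare array).
#' @param lambda Regularization as a fraction of the total signal
#'   variance (`mu = lambda * ||X||^2`); must be >= 0.
#' @param n_components Maximum components per marginalization.
#' @param marginals Optional precomputed [marginalize()] output.
#' @return An object of class `dpca_model`: per-marginalization `F`,
#'   `D`, singular values, per-component explained-variance fractions;
#'   `var_by_marginalization` (fractions of total variance per
#'   marginalization); the centred data matrix `X`; and a ranked
#'   component table.
#' @export
fit_dpca <- function(tensor, lambda = 1e-6, n_components = 20L,
                     marginals = NULL) {
  assert_scalar_number(lambda, "lambda", lower = 0)
  if (is.null(marginals)) marginals <- marginalize(tensor)
  Xc <- attr(marginals, "centered")
  X <- flatten_units(Xc)
  n <- nrow(X)
  total_var <- sum(X^2)
  mu <- lambda * total_var
  XXt <- tcrossprod(X)
  Kinv <- solve(XXt + diag(mu, n))

  fits <- lapply(marginals, function(Mphi) {
    Mx <- flatten_units(Mphi)
    Wls <- Mx %*% crossprod(X, Kinv)  # == Mx X' (XX'+muI)^-1, symmetric Kinv
    img <- Wls %*% X
    sv <- svd(img)
    tol <- max(sv$d) * 1e-9
    q <- min(n_components, sum(sv$d > tol))
    if (q == 0L) {
      return(list(F = matrix(0, n, 0L), D = matrix(0, 0L, n),
                  d = numeric(0L), expl_var = numeric(0L),
                  var_frac = sum(Mx^2) / total_var))
    }
    Fm <- sv$u[, seq_len(q), drop = FALSE]
    D <- crossprod(Fm, Wls)
    for (k in seq_len(q)) {
      j <- which.max(abs(D[k, ]))
      if (D[k, j] < 0) {
        D[k, ] <- -D[k, ]
        Fm[, k] <- -Fm[, k]
      }
    }
    ev <- vapply(seq_len(q), function(k) {
      p <- D[k, , drop = FALSE] %*% X
      g <- crossprod(Fm[, k, drop = FALSE], X)
      (2 * sum(g * p) - sum(p^2)) / total_var
    }, numeric(1L))
    list(F = Fm, D = D, d = sv$d[seq_len(q)], expl_var = ev,
         var_frac = sum(Mx^2) / total_var)
  })

  comp_tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (!length(f$expl_var)) return(NULL)
    data.frame(marginalization = nm, component = seq_along(f$expl_var),
               expl_var = f$expl_var)
  }))
  comp_tab <- comp_tab[order(-comp_tab$expl_var), ]
  rownames(comp_tab) <- NULL

  structure(
    list(marginalizations = fits, lambda = lambda, mu = mu,
         total_var = total_var, X = X,
         var_by_marginalization = vapply(fits, `[[`, numeric(1L),
                                         "var_frac"),
         components = comp_tab,
         tensor_dims = dim(Xc),
         factor_names = if (inherits(tensor, "condition_tensor"))
           tensor$factor_names else NULL),
    class = "dpca_model")
}

#' @export
print.dpca_model <- function(x, ...) {
  cat("Demixed PCA model\n")
  v <- round(100 * x$var_by_marginalization, 1)
  cat("Variance by marginalization (%):\n")
  print(v)
  invisible(x)
}

#' Explained variance accounting for a fitted dPCA model
#'
#' @param model A `dpca_model`.
#' @param n_components Number of top components (ranked by explained
#'   variance across marginalizations) for the cumulative curve.
#' @return List with `by_marginalization` (pie fractions of total
#'   variance), `components` (ranked per-component fractions) and
#'   `cumulative` (joint-reconstruction cumulative explained-variance
#'   fractions for the top components).
#' @export
explained_variance <- function(model, n_components = 20L) {
  stopifnot(inherits(model, "dpca_model"))
  tab <- utils::head(model$components, n_components)
  X <- model$X
  Z <- matrix(0, nrow(X), ncol(X))
  cum <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- model$marginalizations[[tab$marginalization[i]]]
    k <- tab$component[i]
    Z <- Z + f$F[, k, drop = FALSE] %*% (f$D[k, , drop = FALSE] %*% X)
    cum[i] <- 1 - sum((X - Z)^2) / model$total_var
  }
  list(by_marginalization = model$var_by_marginalization,
       components = tab, cumulative = cum)
}

#' PCA baseline on the condition tensor
#'
#' Standard principal component analysis of the centred unit x
#' (condition x time) matrix, as the reference against which the
#' demixed decomposition's cumulative explained variance is compared.
#'
#' @param tensor A `condition_tensor` or bare array.
#' @param n_components Number of components to report.
#' @return List with `cumvar` (nondecreasing cumulative explained
#'   variance fractions), `sdev`, `rotation` (unit-space axes), and
#'   `scores` (component x condition-time projections).
#' @export
pca_baseline <- function(tensor, n_components = 20L) {
  marg <- if (inherits(tensor, "condition_tensor") || is.array(tensor)) {
    marginalize(tensor)
  } else stop("unsupported input")
  X <- flatten_units(attr(marg, "centered"))
  sv <- svd(X)
  q <- min(n_components, length(sv$d))
  ev <- sv$d^2 / sum(sv$d^2)
  list(cumvar = cumsum(ev)[seq_len(q)], sdev = sv$d[seq_len(q)],
       rotation = sv$u[, seq_len(q), drop = FALSE],
       scores = (t(sv$u) %*% X)[seq_len(q), , drop = FALSE])
}

#' Theoretical chance accuracy of a balanced classifier
#'
#' @param n_classes Number of classes.
#' @return Chance accuracy as a fraction (1 / n_classes).
#' @export
#' @examples
#' theoretical_chance(3)  # 0.333...
theoretical_chance <- function(n_classes) {
  assert_scalar_number(n_classes, "n_classes", lower = 1)
  1 / n_classes
}

# labels for decoding along an axis of a given marginalization
.decode_labels <- function(tensor, marginalization) {
  cond <- tensor$trial_cond
  if (marginalization %in% names(cond)) {
    return(cond[[marginalization]])
  }
  if (marginalization == "interaction") {
    return(droplevels(interaction(cond, drop = FALSE)))
  }
  stop("cannot decode along marginalization '", marginalization, "'")
}

#' Single-trial decoding along a demixed axis
#'
#' Uses the decoder axis of one demixed component as a linear
#' classifier: single trials are projected onto the axis and a held-out
#' trial is assigned to the class whose training-mean projection is
#' nearest, per time bin. Cross-validation holds out one trial per class
#' per repeat. Chance is estimated by shuffling the class labels across
#' trials `n_shuffle` times and taking the maximum time-averaged shuffle
#' accuracy as the significance threshold.
#'
#' @param model A `dpca_model`.
#' @param tensor The `condition_tensor` the model was fitted to (single
#'   trials retained).
#' @param marginalization Which marginalization's axis to use (e.g.
#'   `"attention"`, `"outcome"`, `"interaction"`, `"trial_type"`).
#' @param component Component index within the marginalization.
#' @param n_cv Cross-validation repeats.
#' @param n_shuffle Label shuffles for the chance distribution; `0`
#'   skips the chance estimate (accuracy only).
#' @param seed Integer seed.
#' @return An object of class `axis_decoding`: `accuracy_time` (per
#'   bin), `accuracy` (time-averaged), `chance_dist`, `chance_threshold`
#'   (max shuffle accuracy), `significant`, `n_classes`.
#' @export
decode_with_axis <- function(model, tensor, marginalization,
                             component = 1L, n_cv = 100L,
                             n_shuffle = 100L, seed = NULL) {
  stopifnot(inherits(model, "dpca_model"),
            inherits(tensor, "condition_tensor"))
  fit <- model$marginalizations[[marginalization]]
  if (is.null(fit) || nrow(fit$D) < component) {
    stop("unknown component ", component, " in marginalization '",
         marginalization, "'")
  }
  axis <- fit$D[component, ]
  labels <- .decode_labels(tensor, marginalization)
  cls <- levels(labels)
  ncl <- length(cls)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("every class needs at least 2 trials for cross-validation")
  }

  nu <- dim(tensor$trials)[1L]
  ntr <- dim(tensor$trials)[2L]
  nt <- dim(tensor$trials)[3L]
  proj <- matrix(crossprod(matrix(tensor$trials, nrow = nu), axis),
                 nrow = ntr, ncol = nt)

  run_cv <- function(lab, seed_cv) {
    idx <- split(seq_len(ntr), lab)
    ns <- lengths(idx)
    with_seed(seed_cv, {
      held <- vapply(idx, function(ix) sample(ix, n_cv, replace = TRUE),
                     integer(n_cv))           # n_cv x ncl
      acc_t <- numeric(nt)
      S <- vapply(idx, function(ix)
        colSums(proj[ix, , drop = FALSE]), numeric(nt))  # nt x ncl
      for (t in seq_len(nt)) {
        x_held <- matrix(proj[held, t], n_cv, ncl)
        m_train <- sweep(-x_held, 2L, S[t, ], "+")
        m_train <- sweep(m_train, 2L, ns - 1L, "/")      # n_cv x ncl
        # m_train excludes each class's own held trial, i.e. exactly the
        # training set of the repeat (one trial per class held out)
        correct <- 0L
        for (c in seq_len(ncl)) {
          d <- abs(matrix(x_held[, c], n_cv, ncl) - m_train)
          correct <- correct + sum(max.col(-d, ties.method = "first") == c)
        }
        acc_t[t] <- correct / (n_cv * ncl)
      }
      acc_t
    })
  }

  base_seed <- stream_seed(seed, "cv")
  acc_time <- run_cv(labels, base_seed)
  chance <- if (n_shuffle > 0L) {
    with_seed(stream_seed(seed, "shuffle"), {
      vapply(seq_len(n_shuffle), function(s) {
        mean(run_cv(sample(labels),
                    derive_seed(if (is.null(seed)) 0 else seed, 23L, s)))
      }, numeric(1L))
    })
  } else numeric(0L)
  acc <- mean(acc_time)
  thr <- if (length(chance)) max(chance) else NA_real_
  structure(
    list(marginalization = marginalization, component = component,
         accuracy_time = acc_time, accuracy = acc, chance_dist = chance,
         chance_threshold = thr,
         significant = if (length(chance)) acc > thr else NA,
         n_classes = ncl),
    class = "axis_decoding")
}

#' @export
print.axis_decoding <- function(x, ...) {
  cat(sprintf(
    "Axis decoding (%s, component %d): accuracy %.1f%% (chance threshold %.1f%%, theoretical %.1f%%)%s\n",
    x$marginalization, x$component, 100 * x$accuracy,
    100 * x$chance_threshold, 100 / x$n_classes,
    if (x$significant) " *" else ""))
  invisible(x)
}

#' Overlap between two population axes
#'
#' Absolute normalized dot product between two axes in unit space, the
#' corresponding angle in degrees, and a Monte-Carlo non-orthogonality
#' test against the null of independent random directions in the same
#' dimension (threshold = 97.5th percentile of the null |dot|).
#'
#' @param axis_a,axis_b Nonzero numeric vectors of equal length.
#' @param n_mc Monte-Carlo draws for the null.
#' @param seed Integer seed for the null draws.
#' @return List with `dot`, `angle_deg`, `null_threshold`,
#'   `significant`, `n_dim`.
#' @export
#' @examples
#' axis_overlap(c(1, 0, 0), c(0, 1, 0))$angle_deg  # 90
axis_overlap <- function(axis_a, axis_b, n_mc = 10000L, seed = 1L) {
  stopifnot(length(axis_a) == length(axis_b))
  na <- sqrt(sum(axis_a^2)); nb <- sqrt(sum(axis_b^2))
  if (na == 0 || nb == 0) stop("axes must be nonzero")
  dot <- abs(sum(axis_a * axis_b)) / (na * nb)
  dot <- min(dot, 1)
  n <- length(axis_a)
  null <- with_seed(seed, {
    a <- matrix(stats::rnorm(n * n_mc), n)
    b <- matrix(stats::rnorm(n * n_mc), n)
    abs(colSums(a * b)) /
      (sqrt(colSums(a^2)) * sqrt(colSums(b^2)))
  })
  thr <- stats::quantile(null, 0.975, names = FALSE)
  list(dot = dot, angle_deg = acos(dot) * 180 / pi, null_threshold = thr,
       significant = dot > thr, n_dim = n)
}

#' Remove a demixed component and back-project
#'
#' Applies the rank-one filter \eqn{x \mapsto x - F_k (D_k x)} in unit
#' space, removing the variance captured by one demixed component and
#' projecting the remainder back onto the original units. Accepts the
#' model's condition tensor (cleans both the averaged tensor and the
#' retained single trials), a bare array with units as the first
#' dimension, or a matrix with units in rows.
#'
#' @param model A `dpca_model`.
#' @param x A `condition_tensor`, array, or units-in-rows matrix.
#' @param marginalization,component Which component to remove.
#' @return The same type as `x` with the component's variance removed.
#' @export
remove_component_backproject <- function(model, x, marginalization,
                                         component = 1L) {
  stopifnot(inherits(model, "dpca_model"))
  fit <- model$marginalizations[[marginalization]]
  if (is.null(fit) || nrow(fit$D) < component) {
    stop("unknown component ", component, " in marginalization '",
         marginalization, "'")
  }
  f <- fit$F[, component]
  d <- fit$D[component, ]
  # scale the rank-one filter so the removed axis is exactly annihilated
  # (D_k F_k is ~1 by construction; the rescaling removes the residual)
  d <- d / sum(d * f)
  clean_mat <- function(m) m - f %*% (rbind(d) %*% m)
  if (inherits(x, "condition_tensor")) {
    Xf <- flatten_units(x$X)
    x$X <- array(clean_mat(Xf), dim = dim(x$X))
    Tf <- flatten_units(x$trials)
    x$trials <- array(clean_mat(Tf), dim = dim(x$trials))
    return(x)
  }
  if (is.array(x) && length(dim(x)) > 2L) {
    return(array(clean_mat(flatten_units(x)), dim = dim(x)))
  }
  clean_mat(as.matrix(x))
}
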