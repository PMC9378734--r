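# Internal helpers shared across modules.

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package route their `seed` argument
#' through this helper so that calling them never disturbs the caller's
#' random number stream.
#'
#' @param seed Integer seed, or `NULL` to use the current stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  base <- (as.double(seed) %% 2147483629) + 1
  h <- (base * 2654435761 + stream * 97561 + index * 7919) %% 2147483629
  as.integer(h) + 1L
}

# stream offsets used when deriving per-component seeds from a master seed
.seed_streams <- c(
  states = 1L, outcomes = 2L, spikes = 3L, population = 4L,
  session = 5L, decode = 6L, equalize = 7L, shuffle = 8L, cv = 9L
)

stream_seed <- function(seed, stream, index = 0L) {
  if (is.null(seed)) return(NULL)
  derive_seed(seed, .seed_streams[[stream]], index)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

#' Gaussian smoothing of a matrix along its columns (time axis)
#'
#' @param x Numeric matrix (rows = series, columns = time bins).
#' @param sd_bins Kernel standard deviation in units of bins; `0` returns
#'   `x` unchanged.
#' @return Matrix of the same dimension.
#' @keywords internal
gauss_smooth_rows <- function(x, sd_bins) {
  if (sd_bins <= 0) return(x)
  nt <- ncol(x)
  half <- max(1L, ceiling(3 * sd_bins))
  k <- stats::dnorm(seq(-half, half), sd = sd_bins)
  # convolution matrix with edge renormalization (kernel mass inside range)
  S <- matrix(0, nt, nt)
  for (t in seq_len(nt)) {
    idx <- (t - half):(t + half)
    ok <- idx >= 1L & idx <= nt
    w <- k[ok]
    S[idx[ok], t] <- w / sum(w)
  }
  x %*% S
}

# vectorized two-sided p-value for a Pearson correlation given n
pearson_p <- function(r, n) {
  df <- n - 2
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(abs(tval), df, lower.tail = FALSE)
}

# Subsample per-type trial rows to matching TA-bin distributions: the
# TA-bin profile of the scarcest type is the target; every type keeps as
# many trials as fit that profile. rows_of: named list of trial-table
# row indices per type; estimates: rolling_decode() output.
ta_matched_rows <- function(rows_of, trial_table, estimates, seed = NULL,
                            bins = NULL) {
  if (is.null(bins)) bins <- estimates$ta_bin
  bins <- as.factor(bins)
  ids <- estimates$trial_id
  types <- names(rows_of)
  with_seed(seed, {
    bl <- levels(bins)
    per_bin <- lapply(types, function(ty) {
      lapply(bl, function(b)
        intersect(match(ids[bins == b], trial_table$trial_id),
                  rows_of[[ty]]))
    })
    names(per_bin) <- types
    # profile restricted to bins populated by every type
    common <- Reduce(`&`, lapply(per_bin, function(pb) lengths(pb) > 0L))
    per_bin <- lapply(per_bin, function(pb) {
      pb[!common] <- list(integer(0L))
      pb
    })
    tot <- vapply(per_bin, function(pb) sum(lengths(pb)), numeric(1L))
    ref <- types[which.min(tot)]
    target <- lengths(per_bin[[ref]]) / max(tot[ref], 1L)
    sel <- lapply(types, function(ty) {
      nb <- lengths(per_bin[[ty]])
      n_keep <- floor(min(ifelse(target > 0, nb / target, Inf)))
      unlist(lapply(seq_along(bl), function(b) {
        k <- min(round(n_keep * target[b]), nb[b])
        if (k > 0L) sample(per_bin[[ty]][[b]], k) else integer(0L)
      }))
    })
    names(sel) <- types
    sel
  })
}
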