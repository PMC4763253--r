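# Covert-attention mixture model: with a fixed probability q of attending
# the tones in any 0.5-s window, the probability that attention has been
# continuously on the tones for exactly k windows at the switch point is
# geometric, w_k = (1-q) q^k for k < K and w_K = q^K. The switch-condition
# build-up curve is modeled as the w-weighted mixture of the attend curve
# advanced by k windows, and a q-grid scan flags the q values for which the
# modeled and observed switch curves do not differ significantly (SPM cluster
# test on the per-subject difference fields).

#' Attention run-length weights
#'
#' @param q Probability of attending the tones in any one 0.5-s window.
#' @param K Number of pre-switch windows (25 for a 12.5-s pre-switch period).
#' @return Numeric vector `w_0 ... w_K` summing to one.
#' @examples
#' attention_weights(0.5, 2) # 0.50 0.25 0.25
#' @export
attention_weights <- function(q, K) {
  assert_that(q >= 0 && q <= 1, "invalid_q", "q must lie in [0, 1]")
  assert_that(K >= 1 && K == round(K), "invalid_K",
              "K must be a positive integer")
  k <- 0:(K - 1)
  c((1 - q) * q^k, q^K)
}

# Attend curve as a function of time-since-attending: interior NA linearly
# interpolated, clamped (or linearly extrapolated) beyond its support.
attend_curve_fun <- function(times_s, values,
                             extend = c("clamp", "linear")) {
  extend <- match.arg(extend)
  ok <- !is.na(values)
  assert_that(any(ok), "undefined_attend_curve",
              "the attend curve is entirely undefined")
  x <- times_s[ok]
  y <- values[ok]
  if (length(x) == 1) return(function(t) rep(y, length(t)))
  function(t) {
    out <- stats::approx(x, y, xout = t, rule = 2)$y
    if (extend == "linear") {
      hi <- t > max(x)
      if (any(hi)) {
        slope <- (y[length(y)] - y[length(y) - 1]) /
          (x[length(x)] - x[length(x) - 1])
        out[hi] <- y[length(y)] + slope * (t[hi] - max(x))
      }
      lo <- t < min(x)
      if (any(lo)) {
        slope <- (y[2] - y[1]) / (x[2] - x[1])
        out[lo] <- y[1] + slope * (t[lo] - min(x))
      }
    }
    out
  }
}

#' Model the switch-condition build-up curve for a given q
#'
#' The modeled value at post-switch time t is `sum_k w_k A(t + k w)`, where
#' `A` is the attend build-up curve read as a function of time since
#' attending began and `w` the window length. With q = 0 this reproduces the
#' attend curve (full reset); with q = 1, the attend curve advanced by the
#' whole pre-switch duration.
#'
#' @param attend_times_s,attend_values The attend curve on the triplet grid
#'   (values may contain NA at undefined points).
#' @param q Attention probability per window.
#' @param K Number of pre-switch windows.
#' @param post_times_s Post-switch times (seconds since the switch) at which
#'   to evaluate the model.
#' @param window_s Window length (default 0.5 s).
#' @param extend Support extension: `"clamp"` (default) or `"linear"`.
#' @return Numeric vector of modeled proportions at `post_times_s`.
#' @export
model_switch_curve <- function(attend_times_s, attend_values, q, K,
                               post_times_s, window_s = TRIPLET_PERIOD_S,
                               extend = "clamp") {
  A <- attend_curve_fun(attend_times_s, attend_values, extend)
  w <- attention_weights(q, K)
  vals <- vapply(0:K, function(k) A(post_times_s + k * window_s),
                 numeric(length(post_times_s)))
  if (length(post_times_s) == 1) vals <- matrix(vals, nrow = 1)
  as.numeric(vals %*% w)
}

#' Scan the attention probability q
#'
#' For each q on the grid, the covert-attention mixture is applied to each
#' subject's attend curve to give that subject's modeled switch curve; the
#' per-subject difference fields (observed minus modeled) are tested with the
#' SPM cluster procedure, and the q values with no significant suprathreshold
#' cluster are returned as interval(s).
#'
#' @param attend_mat Subjects x time matrix of attend curves with a `times_s`
#'   attribute (absolute time from sequence start; see [curve_matrix()]).
#' @param switch_mat Subjects x time matrix of observed switch-aligned curves
#'   with a `times_s` attribute (time since the switch).
#' @param switch_time_s Pre-switch duration (default 12.5 s); must be an
#'   integer number of windows.
#' @param q_grid Grid of q values (default 0 to 1 in steps of 0.001).
#' @param alpha Family-wise level of the SPM test.
#' @param method `"rft"` or `"perm"`.
#' @param window_s Attention window length.
#' @param n_perm Sign flips when `method = "perm"`.
#' @param seed Seed for the permutation method.
#' @param extend Attend-curve support extension.
#' @return A `q_scan` list: `table` (per-q max |t|, cluster count, minimum
#'   cluster p, significance flag), `nonsignificant` (data.frame of interval
#'   bounds), `K`, `alpha`.
#' @export
scan_q <- function(attend_mat, switch_mat, switch_time_s = SWITCH_TIME_S,
                   q_grid = seq(0, 1, by = 0.001), alpha = 0.05,
                   method = c("rft", "perm"), window_s = TRIPLET_PERIOD_S,
                   n_perm = 1000, seed = NULL, extend = "clamp") {
  method <- match.arg(method)
  assert_that(nrow(attend_mat) >= 3 && nrow(switch_mat) >= 3,
              "too_few_subjects", "at least 3 subjects are required")
  assert_that(nrow(attend_mat) == nrow(switch_mat), "subject_mismatch",
              "attend and switch matrices must have the same subjects")
  K <- switch_time_s / window_s
  assert_that(abs(K - round(K)) < 1e-9, "invalid_K",
              "switch_time_s must be an integer number of windows")
  K <- as.integer(round(K))
  at_times <- attr(attend_mat, "times_s")
  post_times <- attr(switch_mat, "times_s")
  stopifnot(!is.null(at_times), !is.null(post_times))
  n_subj <- nrow(attend_mat)
  # Per subject: matrix of A(t + k w) for k = 0..K (precomputed once)
  lagged <- lapply(seq_len(n_subj), function(s) {
    A <- attend_curve_fun(at_times, attend_mat[s, ], extend)
    vapply(0:K, function(k) A(post_times + k * window_s),
           numeric(length(post_times)))
  })
  rows <- vector("list", length(q_grid))
  for (qi in seq_along(q_grid)) {
    w <- attention_weights(q_grid[qi], K)
    diffs <- t(vapply(seq_len(n_subj), function(s) {
      switch_mat[s, ] - as.numeric(lagged[[s]] %*% w)
    }, numeric(length(post_times))))
    spm <- spm_cluster_test(diffs, alpha = alpha, method = method,
                            n_perm = n_perm, seed = seed)
    rows[[qi]] <- data.frame(
      q = q_grid[qi],
      max_abs_t = max(abs(spm$t_field[is.finite(spm$t_field)])),
      n_clusters = nrow(spm$clusters),
      min_cluster_p = if (nrow(spm$clusters)) min(spm$clusters$cluster_p)
                      else NA_real_,
      significant = any(spm$clusters$significant)
    )
  }
  tab <- do.call(rbind, rows)
  ns <- !tab$significant
  intervals <- if (any(ns)) {
    r <- rle(ns)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    data.frame(q_lo = tab$q[starts[keep]], q_hi = tab$q[ends[keep]])
  } else data.frame(q_lo = numeric(0), q_hi = numeric(0))
  if (nrow(intervals) > 1) {
    warning("nonsignificant q set is not a single contiguous interval")
  }
  structure(list(table = tab, nonsignificant = intervals, K = K,
                 alpha = alpha, method = method),
            class = "q_scan")
}

#' @export
print.q_scan <- function(x, ...) {
  cat(sprintf("<q_scan %s> %d q values, alpha = %g\n", x$method,
              nrow(x$table), x$alpha))
  if (nrow(x$nonsignificant)) {
    for (i in seq_len(nrow(x$nonsignificant))) {
      cat(sprintf("  no significant model-data cluster for q in [%.3f, %.3f]\n",
                  x$nonsignificant$q_lo[i], x$nonsignificant$q_hi[i]))
    }
  } else cat("  model and data differ significantly for every q\n")
  invisible(x)
}
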