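# Random-intercept logistic models of per-deviant hit/miss outcomes, fitted
# by maximizing the marginal likelihood with fixed-order Gauss-Hermite
# quadrature, plus the likelihood-ratio model ladder and the adjusted count
# pseudo-R-squared.

# Gauss-Hermite nodes/weights rescaled for an N(0, 1) integral:
# E[f(Z)] = sum w_i f(sqrt(2) x_i) / sqrt(pi).
gh_nodes <- function(order) {
  assert_that(order >= 5, "invalid_quadrature",
              "quadrature order must be at least 5")
  g <- pracma::gaussHermite(order)
  list(z = sqrt(2) * g$x, logw = log(g$w) - 0.5 * log(pi))
}

# Marginal log likelihood (and analytic gradient) of a logistic model with a
# normal random intercept per subject. theta = c(beta, log_sigma).
ri_loglik <- function(theta, y, X, subj_idx, n_subj, gh, gradient = FALSE) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1])
  eta <- as.numeric(X %*% beta)
  a <- sigma * gh$z # node offsets
  s <- 2 * y - 1
  # N x Q matrix of per-observation log-likelihood contributions per node
  A <- outer(s * eta, rep(1, length(a))) + outer(s, a)
  M <- stats::plogis(A, log.p = TRUE)
  L <- rowsum(M, subj_idx, reorder = TRUE) # S x Q
  Lw <- sweep(L, 2, gh$logw, "+")
  logLs <- row_logsumexp(Lw)
  ll <- sum(logLs)
  if (!gradient) return(ll)
  post <- exp(Lw - logLs) # S x Q posterior node weights
  P <- stats::plogis(outer(eta, rep(1, length(a))) + outer(rep(1, length(eta)), a))
  R <- (y - P) * post[subj_idx, , drop = FALSE] # N x Q
  g_beta <- as.numeric(crossprod(X, rowSums(R)))
  g_logsigma <- sum(colSums(R) * a)
  list(ll = ll, grad = c(g_beta, g_logsigma))
}

#' Fit a logistic model with a random subject intercept
#'
#' Maximizes the marginal likelihood, integrating the normal subject
#' intercept by fixed-order Gauss-Hermite quadrature, with quasi-Newton
#' (BFGS) iteration and standard errors from the observed information
#' matrix. If the estimated intercept standard deviation exceeds 2 logits, a
#' refinement pass doubles the quadrature order.
#'
#' @param y 0/1 outcome vector.
#' @param X Model matrix of fixed effects (including the intercept column).
#' @param subject Subject identifier per row.
#' @param quad_order Gauss-Hermite order (default 20, minimum 5).
#' @return A `glmm_fit`: `coefficients` (estimate, se, z per fixed effect),
#'   `sigma_subj`, `loglik`, `n_obs`, `converged`, `fitted` (probabilities at
#'   the per-subject posterior-mode intercepts), `ranef` (those modes).
#' @export
fit_logistic_random_intercept <- function(y, X, subject, quad_order = 20) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), is.matrix(X), nrow(X) == length(y),
            length(subject) == length(y))
  assert_that(length(unique(y)) == 2, "separation",
              "all outcomes identical: model is degenerate (complete separation)")
  subj <- as.integer(factor(subject))
  n_subj <- max(subj)
  assert_that(n_subj >= 2, "too_few_subjects",
              "at least 2 subjects are required")
  gh <- gh_nodes(quad_order)
  start_glm <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  theta0 <- c(start_glm$coefficients, log(0.5))
  theta0[!is.finite(theta0)] <- 0
  negll <- function(th) -ri_loglik(th, y, X, subj, n_subj, gh)
  neggr <- function(th) -ri_loglik(th, y, X, subj, n_subj, gh,
                                   gradient = TRUE)$grad
  opt <- stats::optim(theta0, negll, neggr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  sigma <- exp(opt$par[ncol(X) + 1])
  if (sigma > 2 && quad_order < 40) {
    gh <- gh_nodes(2 * quad_order)
    opt <- stats::optim(opt$par, negll, neggr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    sigma <- exp(opt$par[ncol(X) + 1])
  }
  hess <- stats::optimHess(opt$par, negll, neggr)
  p <- ncol(X)
  se <- rep(NA_real_, p)
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  if (!is.null(vc) && all(diag(vc)[seq_len(p)] > 0)) {
    se <- sqrt(diag(vc)[seq_len(p)])
  } else {
    vc2 <- tryCatch(solve(hess[seq_len(p), seq_len(p), drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(vc2) && all(diag(vc2) > 0)) se <- sqrt(diag(vc2))
  }
  beta <- opt$par[seq_len(p)]
  separated <- any(abs(beta) > 15)
  converged <- opt$convergence == 0 && !separated && all(is.finite(beta))
  diagnostic <- if (separated) {
    "diverging coefficients suggest complete or quasi-complete separation"
  } else if (opt$convergence != 0) "optimizer did not converge" else NA_character_
  # posterior-mode intercept per subject, for fitted probabilities
  eta <- as.numeric(X %*% beta)
  ranef <- vapply(seq_len(n_subj), function(s) {
    rows <- subj == s
    obj <- function(b) {
      sum(stats::plogis((2 * y[rows] - 1) * (eta[rows] + b), log.p = TRUE)) -
        b^2 / (2 * max(sigma, 1e-8)^2)
    }
    stats::optimize(obj, c(-6, 6) * max(sigma, 0.5),
                    maximum = TRUE)$maximum
  }, numeric(1))
  if (sigma < 1e-6) ranef[] <- 0
  structure(list(
    coefficients = data.frame(term = colnames(X) %||% paste0("b", seq_len(p)),
                              estimate = beta, se = se, z = beta / se),
    sigma_subj = sigma,
    loglik = -opt$value,
    n_obs = length(y),
    df_model = p + 1L,
    converged = converged,
    diagnostic = diagnostic,
    fitted = stats::plogis(eta + ranef[subj]),
    ranef = ranef,
    subject_index = subj,
    quad_order = quad_order
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> logLik = %.2f, sigma_subj = %.3f, n = %d%s\n",
              x$loglik, x$sigma_subj, x$n_obs,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# Random intercept + one independent random slope, integrated on a 2D tensor
# Gauss-Hermite grid. Used only for likelihood-ratio screening of slopes.
fit_logistic_random_slope <- function(y, X, subject, slope, quad_order = 8) {
  y <- as.numeric(y)
  subj <- as.integer(factor(subject))
  gh <- gh_nodes(quad_order)
  grid <- expand.grid(i = seq_along(gh$z), j = seq_along(gh$z))
  z0 <- gh$z[grid$i]
  z1 <- gh$z[grid$j]
  logw <- gh$logw[grid$i] + gh$logw[grid$j]
  s <- 2 * y - 1
  negll <- function(th) {
    p <- ncol(X)
    beta <- th[seq_len(p)]
    s0 <- exp(th[p + 1])
    s1 <- exp(th[p + 2])
    eta <- as.numeric(X %*% beta)
    # N x Q2 contributions
    A <- outer(s * eta, rep(1, length(z0))) +
      outer(s, s0 * z0) + outer(s * slope, s1 * z1)
    L <- rowsum(stats::plogis(A, log.p = TRUE), subj, reorder = TRUE)
    -sum(row_logsumexp(sweep(L, 2, logw, "+")))
  }
  start_glm <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  theta0 <- c(start_glm$coefficients, log(0.5), log(0.25))
  theta0[!is.finite(theta0)] <- 0
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(loglik = -opt$value, converged = opt$convergence == 0,
       sigma_subj = exp(opt$par[ncol(X) + 1]),
       sigma_slope = exp(opt$par[ncol(X) + 2]))
}

# Numeric coding of the outcome table: delta_f -> indicator of 8 st,
# position -> 0/1/2 (early/middle/late), percept -> indicator of segregated.
code_outcomes <- function(outcomes, drop_unreported = TRUE) {
  stopifnot(all(c("subject", "delta_f", "position", "hit") %in%
                  names(outcomes)))
  d <- outcomes
  if ("percept" %in% names(d)) {
    unrep <- d$percept == "unreported" | is.na(d$percept)
    if (drop_unreported && any(unrep)) d <- d[!unrep, , drop = FALSE]
    d$percept_seg <- as.numeric(d$percept %in% c("two_streams", "segregated"))
  }
  d$delta_f8 <- as.numeric(d$delta_f == 8)
  d$position_num <- if (is.numeric(d$position)) d$position else
    match(d$position, c("early", "middle", "late")) - 1
  d
}

#' Likelihood-ratio model ladder for hit/miss outcomes
#'
#' Starting from a subject-only random-intercept model, candidate fixed
#' effects are added in order; each addition is retained only when the
#' chi-squared test on twice the log-likelihood increase (with the added
#' degrees of freedom) has p below `alpha`. Pairwise interactions of the
#' retained fixed effects, and then independent random slopes for them, can
#' be screened the same way. The adjusted count pseudo-R-squared is reported
#' cumulatively at each accepted step.
#'
#' @param outcomes Per-deviant table from [deviant_outcomes()] (columns
#'   `subject`, `delta_f`, `position`, `percept`, `hit`). Deviants with an
#'   unreported percept are dropped (with a message) whenever `percept` is a
#'   candidate.
#' @param terms Candidate fixed effects, in entry order. Any of
#'   `"delta_f"`, `"position"`, `"percept"`.
#' @param test_interactions Screen pairwise interactions of retained terms.
#' @param test_random_slopes Screen independent random slopes for retained
#'   terms.
#' @param exclude_early Re-run on middle/late deviants only (sensitivity
#'   analysis for the percept/position confound at early positions).
#' @param alpha Entry threshold (default 0.05).
#' @param quad_order Quadrature order for all fits.
#' @return A `model_ladder`: `ladder` (one row per tested addition: term,
#'   added df, loglik, chi2, p, accepted, cumulative pseudo-R2), `winning_terms`,
#'   `final_fit`, `n_obs`.
#' @export
lr_ladder <- function(outcomes, terms = c("delta_f", "position", "percept"),
                      test_interactions = FALSE, test_random_slopes = FALSE,
                      exclude_early = FALSE, alpha = 0.05, quad_order = 20) {
  stopifnot(all(terms %in% c("delta_f", "position", "percept")))
  d <- code_outcomes(outcomes, drop_unreported = "percept" %in% terms)
  if (exclude_early) d <- d[d$position_num > 0, , drop = FALSE]
  assert_that(nrow(d) > 0, "empty_outcomes", "no outcome rows to fit")
  col_of <- c(delta_f = "delta_f8", position = "position_num",
              percept = "percept_seg")
  y <- d$hit
  subject <- d$subject
  build_X <- function(fixed, inter) {
    X <- matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
    for (tm in fixed) {
      X <- cbind(X, d[[col_of[[tm]]]])
      colnames(X)[ncol(X)] <- tm
    }
    for (iv in inter) {
      X <- cbind(X, d[[col_of[[iv[1]]]]] * d[[col_of[[iv[2]]]]])
      colnames(X)[ncol(X)] <- paste(iv, collapse = ":")
    }
    X
  }
  fit_or_null <- function(X) {
    tryCatch(fit_logistic_random_intercept(y, X, subject, quad_order),
             error = function(e) NULL)
  }
  current_fixed <- character(0)
  current_inter <- list()
  fit <- fit_or_null(build_X(current_fixed, current_inter))
  assert_that(!is.null(fit), "baseline_failed",
              "the subject-only baseline model failed to fit")
  ladder <- data.frame(step = 0L, term = "subject (random)", df_added = NA_real_,
                       loglik = fit$loglik, chi2 = NA_real_, p = NA_real_,
                       accepted = TRUE,
                       pseudo_r2 = adjusted_count_pseudo_r2(fit$fitted, y))
  step <- 0L
  try_addition <- function(label, cand_fit, df_added) {
    step <<- step + 1L
    if (is.null(cand_fit) || !cand_fit$converged) {
      warning(sprintf("candidate '%s' did not converge; skipped", label))
      ladder <<- rbind(ladder, data.frame(
        step = step, term = label, df_added = df_added, loglik = NA_real_,
        chi2 = NA_real_, p = NA_real_, accepted = FALSE,
        pseudo_r2 = NA_real_))
      return(FALSE)
    }
    chi2 <- max(2 * (cand_fit$loglik - fit$loglik), 0)
    p <- stats::pchisq(chi2, df_added, lower.tail = FALSE)
    accepted <- p < alpha
    r2 <- adjusted_count_pseudo_r2(cand_fit$fitted, y)
    ladder <<- rbind(ladder, data.frame(
      step = step, term = label, df_added = df_added,
      loglik = cand_fit$loglik, chi2 = chi2, p = p, accepted = accepted,
      pseudo_r2 = r2))
    if (accepted) fit <<- cand_fit
    accepted
  }
  for (tm in terms) {
    cand <- fit_or_null(build_X(c(current_fixed, tm), current_inter))
    if (try_addition(tm, cand, 1)) current_fixed <- c(current_fixed, tm)
  }
  if (test_interactions && length(current_fixed) >= 2) {
    pairs <- utils::combn(current_fixed, 2, simplify = FALSE)
    for (iv in pairs) {
      cand <- fit_or_null(build_X(current_fixed, c(current_inter, list(iv))))
      if (try_addition(paste(iv, collapse = ":"), cand, 1)) {
        current_inter <- c(current_inter, list(iv))
      }
    }
  }
  retained_slopes <- character(0)
  if (test_random_slopes && length(current_fixed) >= 1) {
    X_now <- build_X(current_fixed, current_inter)
    for (tm in current_fixed) {
      step <- step + 1L
      sl <- tryCatch(
        fit_logistic_random_slope(y, X_now, subject, d[[col_of[[tm]]]],
                                  quad_order = max(8, quad_order %/% 2)),
        error = function(e) NULL)
      if (is.null(sl) || !sl$converged) {
        warning(sprintf("random slope for '%s' did not converge; skipped", tm))
        next
      }
      chi2 <- max(2 * (sl$loglik - fit$loglik), 0)
      p <- stats::pchisq(chi2, 1, lower.tail = FALSE)
      accepted <- p < alpha
      ladder <- rbind(ladder, data.frame(
        step = step, term = paste0("slope(", tm, ")"), df_added = 1,
        loglik = sl$loglik, chi2 = chi2, p = p, accepted = accepted,
        pseudo_r2 = NA_real_))
      if (accepted) retained_slopes <- c(retained_slopes, tm)
    }
  }
  structure(list(ladder = ladder, winning_terms = current_fixed,
                 winning_interactions = current_inter,
                 winning_slopes = retained_slopes,
                 final_fit = fit, n_obs = length(y), alpha = alpha),
            class = "model_ladder")
}

#' @export
print.model_ladder <- function(x, ...) {
  cat(sprintf("<model_ladder> n = %d, winning fixed effects: %s\n", x$n_obs,
              if (length(x$winning_terms))
                paste(x$winning_terms, collapse = ", ") else "(none)"))
  print(x$ladder, row.names = FALSE)
  invisible(x)
}

#' Adjusted count pseudo-R-squared
#'
#' Fitted probabilities are quantized at 0.5 (a value of exactly 0.5 counts
#' as a predicted miss); the statistic is the number of correct predictions
#' beyond the majority-class count, as a fraction of the predictions the
#' majority class gets wrong: `(n_correct - n_majority) / (n - n_majority)`.
#' Values below zero (a model beaten by the majority rule) are reported
#' as-is.
#'
#' @param fitted_probs Fitted probabilities in \[0, 1\].
#' @param outcomes 0/1 outcomes.
#' @return A value at most 1.
#' @export
adjusted_count_pseudo_r2 <- function(fitted_probs, outcomes) {
  stopifnot(length(fitted_probs) == length(outcomes))
  assert_that(all(fitted_probs >= 0 & fitted_probs <= 1), "invalid_probs",
              "fitted probabilities must lie in [0, 1]")
  n <- length(outcomes)
  n_majority <- max(table(factor(outcomes, levels = c(0, 1))))
  assert_that(n_majority < n, "degenerate_outcomes",
              "all outcomes identical: pseudo-R2 undefined")
  pred <- as.numeric(fitted_probs > 0.5)
  (sum(pred == outcomes) - n_majority) / (n - n_majority)
}

#' Per-subject criterion contrast between percepts
#'
#' From a percept-conditioned score table, the per-subject difference in
#' decision criterion (segregated minus integrated), pooled over frequency
#' separation and position; a positive mean indicates more conservative
#' responding during segregated phases.
#'
#' @param scores Percept-conditioned table from
#'   `score_session(..., by_percept = TRUE)`.
#' @return A `data.frame` with `subject`, `criterion_seg`, `criterion_int`,
#'   `difference`. Subjects missing either percept cell are excluded with a
#'   warning.
#' @export
criterion_contrast <- function(scores) {
  stopifnot(all(c("subject", "percept", "n_hits", "n_deviants", "n_fa",
                  "n_nonsignal") %in% names(scores)))
  rows <- list()
  for (s in unique(scores$subject)) {
    sub <- scores[scores$subject == s, ]
    cell <- function(pc) {
      x <- sub[sub$percept == pc, ]
      if (!nrow(x) || sum(x$n_deviants) == 0) return(NULL)
      agg <- data.frame(n_hits = sum(x$n_hits), n_deviants = sum(x$n_deviants),
                        n_fa = sum(x$n_fa), n_nonsignal = sum(x$n_nonsignal))
      aggregate_dprime(agg)$criterion
    }
    c_seg <- cell("two_streams")
    c_int <- cell("one_stream")
    if (is.null(c_seg) || is.null(c_int)) {
      warning(sprintf("subject %s lacks a percept cell; excluded", s))
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      subject = s, criterion_seg = c_seg, criterion_int = c_int,
      difference = c_seg - c_int)
  }
  if (!length(rows)) {
    return(data.frame(subject = integer(0), criterion_seg = numeric(0),
                      criterion_int = numeric(0), difference = numeric(0)))
  }
  do.call(rbind, rows)
}
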