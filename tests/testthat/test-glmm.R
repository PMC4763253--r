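test_that("with no subject variance the fit matches plain logistic ML", {
  withr::with_seed(1, {
    n <- 1200
    x <- rbinom(n, 1, 0.5)
    z <- runif(n)
    y <- rbinom(n, 1, plogis(0.4 - 0.9 * x + 0.6 * z))
    subj <- rep(1:12, each = n / 12) # intercepts all truly zero
    X <- cbind(1, x, z)
    fit <- fit_logistic_random_intercept(y, X, subj)
    ref <- glm(y ~ x + z, family = binomial())
  })
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ref))), 1e-2)
  expect_lt(fit$sigma_subj, 0.15)
  expect_gte(fit$loglik, as.numeric(logLik(ref)) - 0.01)
})

test_that("the marginal likelihood agrees with lme4 adaptive quadrature", {
  skip_if_not_installed("lme4")
  withr::with_seed(2, dat <- simulate_outcome_table())
  d <- streamscore:::code_outcomes(dat)
  X <- cbind(1, d$delta_f8, d$position_num, d$percept_seg)
  fit <- fit_logistic_random_intercept(d$hit, X, d$subject)
  g <- lme4::glmer(hit ~ delta_f8 + position_num + percept_seg +
                     (1 | subject),
                   data = d, family = binomial(), nAGQ = 20)
  expect_equal(fit$loglik, as.numeric(stats::logLik(g)), tolerance = 0.05)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(g)),
               tolerance = 0.02)
  expect_equal(fit$sigma_subj,
               sqrt(as.numeric(lme4::VarCorr(g)$subject[1])),
               tolerance = 0.05)
})

test_that("planted coefficients are recovered with correct signs", {
  withr::with_seed(3, {
    ok <- vapply(seq_len(20), function(i) {
      dat <- simulate_outcome_table(beta = c(intercept = 2, delta_f8 = -1,
                                             position = -0.6,
                                             percept_seg = -1.0))
      d <- streamscore:::code_outcomes(dat)
      X <- cbind(1, d$delta_f8, d$position_num, d$percept_seg)
      fit <- fit_logistic_random_intercept(d$hit, X, d$subject,
                                           quad_order = 12)
      est <- fit$coefficients$estimate
      all(sign(est[2:4]) == c(-1, -1, -1)) &&
        abs(est[4] - (-1.0)) < 0.6
    }, logical(1))
  })
  expect_gte(mean(ok), 0.9)
})

test_that("quadrature order barely changes the converged log likelihood", {
  withr::with_seed(4, dat <- simulate_outcome_table())
  d <- streamscore:::code_outcomes(dat)
  X <- cbind(1, d$delta_f8, d$position_num, d$percept_seg)
  f20 <- fit_logistic_random_intercept(d$hit, X, d$subject, quad_order = 20)
  f40 <- fit_logistic_random_intercept(d$hit, X, d$subject, quad_order = 40)
  expect_lt(abs(f20$loglik - f40$loglik), 1e-3)
  expect_lt(max(abs(f20$coefficients$estimate - f40$coefficients$estimate)),
            1e-3)
  expect_lt(abs(f20$sigma_subj - f40$sigma_subj), 1e-3)
  expect_error(fit_logistic_random_intercept(d$hit, X, d$subject,
                                             quad_order = 4),
               class = "invalid_quadrature")
})

test_that("degenerate and separated outcomes are flagged", {
  X <- cbind(1, rbinom(100, 1, 0.5))
  expect_error(fit_logistic_random_intercept(rep(1, 100), X, rep(1:5, 20)),
               class = "separation")
  withr::with_seed(5, {
    x <- rbinom(200, 1, 0.5)
    y <- x # perfectly separated by the covariate
    fit <- fit_logistic_random_intercept(y, cbind(1, x), rep(1:10, each = 20))
  })
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "separation")
})

test_that("the ladder retains planted effects and screens extras", {
  withr::with_seed(6, dat <- simulate_outcome_table())
  lad <- lr_ladder(dat, test_interactions = TRUE, test_random_slopes = TRUE)
  expect_setequal(lad$winning_terms, c("delta_f", "position", "percept"))
  expect_length(lad$winning_interactions, 0)
  acc <- lad$ladder[lad$ladder$accepted, ]
  expect_true(all(diff(acc$loglik[!is.na(acc$loglik)]) >= -1e-6))
  expect_true(all(lad$ladder$chi2 >= 0, na.rm = TRUE))
  # percept decision is invariant to the entry order
  lad_rev <- lr_ladder(dat, terms = c("percept", "position", "delta_f"))
  expect_true("percept" %in% lad_rev$winning_terms)
  expect_equal(sort(lad_rev$winning_terms), sort(lad$winning_terms))
})

test_that("excluding early deviants preserves the percept decision", {
  withr::with_seed(7, dat <- simulate_outcome_table())
  lad <- lr_ladder(dat, exclude_early = TRUE)
  expect_true("percept" %in% lad$winning_terms)
  expect_equal(lad$n_obs, sum(dat$position != "early"))
})

test_that("adjusted count pseudo-R2 follows its defining arithmetic", {
  y <- c(rep(1, 60), rep(0, 40))
  expect_equal(adjusted_count_pseudo_r2(y, y), 1) # perfect prediction
  expect_equal(adjusted_count_pseudo_r2(rep(0.9, 100), y), 0) # majority rule
  # n = 100, majority 60, model correct 80 -> 0.5
  p <- ifelse(y == 1, 0.9, 0.1)
  flip <- c(1:10, 61:70) # make exactly 20 predictions wrong
  p[flip] <- 1 - p[flip]
  expect_equal(adjusted_count_pseudo_r2(p, y), 0.5)
  # ties at exactly 0.5 quantize to a predicted miss
  expect_equal(adjusted_count_pseudo_r2(rep(0.5, 100), y),
               (40 - 60) / (100 - 60))
  expect_error(adjusted_count_pseudo_r2(rep(0.9, 5), rep(1, 5)),
               class = "degenerate_outcomes")
})

test_that("criterion contrast is positive when segregation suppresses false
           alarms", {
  d <- make_session("exp2", rng_seed = 8)
  logs <- simulate_session(d, sample_listener_params(6, seed = 9), seed = 10)
  sc <- score_session(logs, hit_window = 1.147, by_percept = TRUE)
  ct <- criterion_contrast(sc)
  expect_gt(nrow(ct), 0)
  expect_gt(mean(ct$difference), 0)
  # identical rates in both cells give a zero difference
  same <- data.frame(subject = 1, percept = c("one_stream", "two_streams"),
                     n_hits = c(5, 5), n_deviants = c(10, 10),
                     n_fa = c(2, 2), n_nonsignal = c(20, 20))
  expect_equal(criterion_contrast(same)$difference, 0)
})
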