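test_that("zero build-up hazard yields only one-stream reports", {
  trial <- make_trial("t1", 37L, 8, "attend", "early", seed = 1)
  p <- listener_params(buildup_rate_4 = 0, buildup_rate_8 = 0)
  traj <- simulate_percept_trajectory(trial, p, seed = 2)
  expect_true(all(traj$latent == "integrated"))
  expect_true(all(traj$percept_reports$label == "one_stream"))
  expect_equal(nrow(traj$percept_reports), 1) # the mandatory first report
})

test_that("full automaticity makes switch trials match attend trials in
           absolute time", {
  p <- listener_params(unattended_gain = 1, reset_fraction = 1)
  seg_at <- function(task, n = 2000) {
    mean(vapply(seq_len(n), function(i) {
      tr <- make_trial("x", 37L, 8, task, character(), seed = i)
      traj <- simulate_percept_trajectory(tr, p, seed = 10000 + i)
      traj$latent[31] == "segregated" # triplet at 15 s
    }, logical(1)))
  }
  withr::with_seed(42, {
    pa <- seg_at("attend")
    ps <- seg_at("switch")
    se <- sqrt(pa * (1 - pa) / 2000 + ps * (1 - ps) / 2000)
    expect_lt(abs(pa - ps), 4 * se + 1e-9)
  })
})

test_that("zero unattended gain restarts build-up at the switch", {
  p <- listener_params(unattended_gain = 0, seg_to_int_hazard = 0)
  # latent P(segregated) as a function of time since attending began
  prob_curve <- function(task, idx, n = 1500) {
    rowMeans(vapply(seq_len(n), function(i) {
      tr <- make_trial("x", 39L, 8, task, character(), seed = i)
      traj <- simulate_percept_trajectory(tr, p, seed = 5000 + i)
      traj$latent[idx] == "segregated"
    }, logical(length(idx))))
  }
  withr::with_seed(43, {
    attend <- prob_curve("attend", idx = c(5, 9, 13))     # 2, 4, 6 s
    sw <- prob_curve("switch", idx = c(30, 34, 38))       # switch + 2, 4, 6 s
    se <- sqrt(pmax(attend * (1 - attend), 0.25) / 1500) * 2
    expect_true(all(abs(attend - sw) < 4 * pmax(se, 0.01)))
  })
})

test_that("effective time accrues attended, scales unattended and resets by
           kappa at the switch", {
  p <- listener_params(unattended_gain = 0.4, reset_fraction = 0.25)
  tr <- make_trial("x", 37L, 4, "switch", character(), seed = 1)
  traj <- simulate_percept_trajectory(tr, p, seed = 2)
  e <- traj$effective_time_s
  # pre-switch accrual at 0.4 s/s: window 25 starts at 12.0 s
  expect_equal(e[25], 12 * 0.4)
  # at the switch (window 26, 12.5 s) the accrued 12.5 * 0.4 is cut to 25%
  expect_equal(e[26], 12.5 * 0.4 * 0.25)
  expect_equal(e[28], 12.5 * 0.4 * 0.25 + 2 * 0.5)
})

test_that("hit probabilities track percept and false alarms are Poisson", {
  # certain hits, no false alarms: presses exactly track deviants
  p_hit <- listener_params(hit_coefs = c(intercept = 50, delta_f8 = 0,
                                         position = 0, segregated = 0),
                           fa_rate_int = 0, fa_rate_seg = 0,
                           latency_sdlog = 1e-6, latency_meanlog = log(0.3))
  tr <- make_trial("x", 37L, 4, "attend", c("early", "middle", "late"),
                   seed = 3)
  latent <- rep("integrated", 37)
  presses <- simulate_detection_responses(tr, latent, p_hit, seed = 4)
  silences <- tr$triplets$onset_s[tr$triplets$is_deviant] + 0.125
  expect_equal(presses, silences + 0.3, tolerance = 1e-3)

  # integrated-percept advantage at matched stimulus
  p <- listener_params(fa_rate_int = 0, fa_rate_seg = 0)
  hit_rate <- function(latent_state, n = 2500) {
    mean(vapply(seq_len(n), function(i) {
      length(simulate_detection_responses(
        tr, rep(latent_state, 37), p, seed = 20000 + i)) >= 3
    }, logical(1)))
  }
  withr::with_seed(44, {
    h_int <- hit_rate("integrated")
    h_seg <- hit_rate("segregated")
    expect_gt(h_int, h_seg + 0.05)
  })

  # Poisson false-alarm total over 1000 sequences of 18.5 s at 0.01/s
  p_fa <- listener_params(hit_coefs = c(intercept = -50, delta_f8 = 0,
                                        position = 0, segregated = 0),
                          fa_rate_int = 0.01, fa_rate_seg = 0.01)
  withr::with_seed(45, {
    total <- sum(vapply(seq_len(1000), function(i) {
      length(simulate_detection_responses(tr, latent, p_fa, seed = 30000 + i))
    }, numeric(1)))
  })
  expect_lt(abs(total - 185), 3 * sqrt(185))
})

test_that("sessions are reproducible and emulate the noise-task accuracy
           range", {
  d <- make_session("exp1_objective", rng_seed = 1)
  params <- sample_listener_params(12, seed = 2)
  logs1 <- simulate_session(d, params, seed = 3)
  logs2 <- simulate_session(d, params, seed = 3)
  expect_identical(logs_to_df(logs1), logs_to_df(logs2))
  acc <- noise_label_accuracy(logs1)
  expect_true(all(acc >= 0.82 & acc <= 0.98))
  expect_gt(mean(acc), 0.88)
  # perfect labeler
  perfect <- lapply(params, function(p) { p$noise_task_acc <- 1; p })
  logs3 <- simulate_session(d, perfect[1], seed = 4)
  expect_equal(noise_label_accuracy(logs3), 1)
})

test_that("percept reports alternate labels and stay within the response
           window", {
  d <- make_session("exp1_subjective", rng_seed = 6)
  logs <- simulate_session(d, sample_listener_params(4, seed = 7), seed = 8)
  for (su in logs$subjects) {
    for (tr in su$trials) {
      rp <- tr$percept_reports
      if (nrow(rp) >= 2) {
        expect_true(all(diff(rp$time_s) > 0))
        expect_true(all(rp$label[-1] != rp$label[-nrow(rp)]))
      }
      if (nrow(rp) >= 1) {
        expect_true(all(rp$time_s >= 0 & rp$time_s <= 18.5 + 1.5))
      }
    }
  }
})

test_that("population build-up is nondecreasing when segregation is
           absorbing", {
  p <- listener_params(seg_to_int_hazard = 0)
  withr::with_seed(46, {
    states <- vapply(seq_len(4000), function(i) {
      tr <- make_trial("x", 37L, 8, "attend", character(), seed = i)
      simulate_percept_trajectory(tr, p, seed = 40000 + i)$latent == "segregated"
    }, logical(37))
  })
  curve <- rowMeans(states)
  expect_true(all(diff(curve) >= -0.02))
  expect_gt(curve[37], curve[1])
})
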