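test_that("hit window is a linear-interpolation percentile", {
  expect_equal(compute_hit_window(rep(0.9, 8)), 0.9)
  lat <- seq(0.1, 2.0, by = 0.1)
  expect_equal(compute_hit_window(lat),
               unname(stats::quantile(lat, 0.95, type = 7)))
  expect_equal(compute_hit_window(lat), 1.905) # 0.1 * (1 + 0.95 * 19)
  expect_error(compute_hit_window(numeric(0)), class = "empty_latencies")
})

test_that("section boundaries scale with length; late section is always 6 s", {
  b37 <- section_boundaries(37)
  expect_equal(b37$breaks, c(0, 6.25, 12.5, 18.5))
  expect_equal(unname(b37$durations), c(6.25, 6.25, 6))
  expect_equal(unname(section_boundaries(35)$durations), c(5.75, 5.75, 6))
  expect_equal(unname(section_boundaries(39)$durations), c(6.75, 6.75, 6))
})

test_that("presses classify into hits and section-labeled false alarms", {
  trial <- make_trial("c1", 37L, 4, "attend", c("early", "late"), seed = 1)
  dev_silence <- trial$triplets$onset_s[trial$triplets$is_deviant] + 0.125
  cls <- classify_responses(trial, dev_silence[1] + 1.0)
  expect_equal(nrow(cls$hits), 1)
  expect_equal(cls$hits$position, "early")
  expect_equal(cls$misses$position, "late")
  # a press 1.2 s after the silence onset exceeds the window: false alarm
  cls2 <- classify_responses(trial, dev_silence[1] + 1.2)
  expect_equal(nrow(cls2$hits), 0)
  expect_equal(cls2$fas$section, "early")
  # no presses at all: all deviants missed
  cls3 <- classify_responses(trial, numeric(0))
  expect_equal(nrow(cls3$misses), 2)
  expect_equal(nrow(cls3$fas), 0)
  # only the first press inside a window is the hit, the second a false alarm
  cls4 <- classify_responses(trial, dev_silence[1] + c(0.4, 0.8))
  expect_equal(nrow(cls4$hits), 1)
  expect_equal(cls4$hits$press_s, dev_silence[1] + 0.4)
  expect_equal(nrow(cls4$fas), 1)
  # late presses are dropped with a warning
  expect_warning(cls5 <- classify_responses(trial, trial$duration_s + 2),
                 "dropping")
  expect_equal(cls5$dropped, trial$duration_s + 2)
})

test_that("classification agrees with the brute-force matcher on random toy
           logs", {
  withr::with_seed(101, {
    for (i in seq_len(1000)) {
      toy <- random_toy_log()
      got <- classify_responses(toy$trial, toy$presses)
      want <- brute_force_classify(toy$trial, toy$presses)
      expect_identical(sort(got$hits$index), sort(want$hit_deviant_idx))
      expect_identical(sort(got$misses$index), sort(want$miss_deviant_idx))
      expect_equal(got$fas$time_s, want$fa_times)
      expect_identical(got$fas$section, want$fa_section)
      # conservation: every deviant is hit or missed, every press lands once
      n_dev <- nrow(got$hits) + nrow(got$misses)
      n_dev_expected <- if (identical(toy$trial$task, "switch")) {
        sum(toy$trial$triplets$is_deviant &
              toy$trial$triplets$onset_s + 0.125 >= 12.5)
      } else sum(toy$trial$triplets$is_deviant)
      expect_equal(n_dev, n_dev_expected)
      kept <- if (identical(toy$trial$task, "switch")) {
        sum(toy$presses >= 12.5 & toy$presses <= toy$trial$duration_s + 1.5)
      } else sum(toy$presses <= toy$trial$duration_s + 1.5)
      expect_equal(nrow(got$hits) + nrow(got$fas), kept)
    }
  })
})

test_that("nonsignal trial normalization divides duration by the window", {
  expect_equal(count_nonsignal_trials(6.0, 0), 6 / 1.147, tolerance = 1e-12)
  expect_equal(count_nonsignal_trials(6.0, 0), 5.231, tolerance = 1e-3)
  expect_equal(count_nonsignal_trials(6.25, 1), 6.25 / 1.147 - 1,
               tolerance = 1e-12)
  expect_equal(count_nonsignal_trials(6.25, 1), 4.449, tolerance = 1e-3)
  expect_equal(count_nonsignal_trials(6.0, 0, scoring_config(6.0)), 1.0)
  expect_error(count_nonsignal_trials(1.0, 1), class = "invalid_nonsignal_count")
})

test_that("d-prime and criterion come from corrected pooled rates", {
  cells <- data.frame(n_hits = c(6, 3), n_deviants = c(12, 6),
                      n_fa = c(10, 3), n_nonsignal = c(20, 6))
  out <- aggregate_dprime(cells)
  expect_equal(out$dprime[1], 0) # hit rate 0.5 = fa rate 0.5
  expect_equal(out$criterion[1], 0)
  expect_equal(out$dprime[2], 0)
  # perfect rates draw the 0.5 correction
  perf <- aggregate_dprime(data.frame(n_hits = 12, n_deviants = 12,
                                      n_fa = 0, n_nonsignal = 118.776))
  expect_equal(perf$hit_rate, 11.5 / 12)
  expect_equal(perf$fa_rate, 0.5 / 118.776)
  expect_equal(round(perf$dprime, 1), 4.4)
  expect_error(aggregate_dprime(data.frame(n_hits = 2, n_deviants = 1,
                                           n_fa = 0, n_nonsignal = 5)),
               class = "invalid_counts")
})

test_that("d-prime responds monotonically to hits and false alarms", {
  base <- data.frame(n_hits = 8, n_deviants = 12, n_fa = 4, n_nonsignal = 50)
  d0 <- aggregate_dprime(base)$dprime
  more_fa <- base; more_fa$n_fa <- 5
  expect_lt(aggregate_dprime(more_fa)$dprime, d0)
  more_hit <- base; more_hit$n_hits <- 9
  expect_gt(aggregate_dprime(more_hit)$dprime, d0)
})

test_that("percept lookup uses the latest report at or before the time", {
  reports <- data.frame(time_s = c(1.0, 5.0),
                        label = c("one_stream", "two_streams"))
  expect_equal(percept_at(4.9, reports), "one_stream")
  expect_equal(percept_at(5.0, reports), "two_streams")
  expect_equal(percept_at(0.5, reports), "unreported")
  expect_equal(percept_at(0.5, NULL), "unreported")
})

test_that("scored sessions recover the planted difficulty ordering", {
  d <- make_session("exp1_objective", rng_seed = 21)
  logs <- simulate_session(d, sample_listener_params(12, seed = 22),
                           seed = 23)
  scores <- score_session(logs, hit_window = "auto")
  hw <- attr(scores, "hit_window_s")
  expect_gt(hw, 1.0)
  expect_lt(hw, 1.3)
  att <- scores[scores$task == "attend", ]
  grp <- tapply(att$dprime, list(att$delta_f, att$position), mean)
  expect_gt(mean(grp["4", ]), mean(grp["8", ])) # small separation easier
  expect_gt(grp["4", "early"], grp["4", "late"]) # early deviants easier
  expect_gt(grp["8", "early"], grp["8", "late"])
  # switch cells carry only the late position
  expect_setequal(unique(scores$position[scores$task == "switch"]), "late")
})

test_that("percept-conditioned cells split occupancy time and deviants", {
  trial <- make_trial("p1", 37L, 4, "dual", "late", seed = 31)
  reports <- data.frame(time_s = c(0.8, 13.0),
                        label = c("one_stream", "two_streams"))
  occ <- streamscore:::percept_occupancy(reports, 12.5, 18.5)
  expect_equal(occ$one_stream, 0.5)
  expect_equal(occ$two_streams, 5.5)
  occ2 <- streamscore:::percept_occupancy(reports, 0, 6.25)
  expect_equal(occ2$one_stream, 6.25 - 0.8)
  expect_equal(occ2$two_streams, 0)
})
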