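# Synthetic listener: a generative model of percept reports and keypresses
# with the statistical structure the analyses assume, so that every stage of
# the pipeline can be validated against planted ground truth.
#
# Perception is a two-state (integrated/segregated) chain sampled once per
# 0.5-s triplet. The integrated-to-segregated hazard in a window at time t is
#   1 - exp(-rate_df * e(t)),
# where the "effective time" e accrues at 1 s/s while the tones are attended
# and at rho s/s while they are not, and is multiplied by kappa at the moment
# attention switches to the tones. rho = 0 encodes no streaming without
# attention; rho = 1, kappa = 1 encodes fully automatic streaming; an
# intermediate kappa encodes partial resetting.

#' Listener parameters
#'
#' @param subj_intercept Additive subject offset (logit units) applied to the
#'   hit-model intercept.
#' @param buildup_rate_4,buildup_rate_8 Hazard scale (per second of effective
#'   time) for 4- and 8-semitone separations.
#' @param unattended_gain Fraction of build-up accrued per second while the
#'   tones are unattended (rho, in \[0, 1\]).
#' @param reset_fraction Fraction of effective time retained at an attention
#'   switch (kappa, in \[0, 1\]).
#' @param seg_to_int_hazard Per-triplet probability of reverting from
#'   segregated to integrated.
#' @param hit_coefs Named numeric: `intercept`, `delta_f8` (effect of 8 vs 4
#'   semitones), `position` (per position step early->middle->late), and
#'   `segregated` (effect of a currently segregated percept), logit units.
#' @param fa_rate_int,fa_rate_seg False alarms per second while integrated /
#'   segregated; `fa_rate_int >= fa_rate_seg` encodes the more conservative
#'   criterion during segregated phases.
#' @param latency_meanlog,latency_sdlog Lognormal detection latency (seconds
#'   after the deviant's additional-silence onset).
#' @param report_delay_meanlog,report_delay_sdlog Lognormal motor delay for
#'   percept reports.
#' @param noise_task_acc Probability of labeling a noise burst correctly.
#' @return A `listener_params` list.
#' @export
listener_params <- function(subj_intercept = 0,
                            buildup_rate_4 = 0.002,
                            buildup_rate_8 = 0.005,
                            unattended_gain = 0.35,
                            reset_fraction = 0.5,
                            seg_to_int_hazard = 0.02,
                            hit_coefs = c(intercept = 2.5, delta_f8 = -1.2,
                                          position = -0.9, segregated = -1.8),
                            fa_rate_int = 0.015,
                            fa_rate_seg = 0.006,
                            latency_meanlog = log(0.55),
                            latency_sdlog = 0.45,
                            report_delay_meanlog = log(0.6),
                            report_delay_sdlog = 0.35,
                            noise_task_acc = 0.93) {
  p <- list(subj_intercept = subj_intercept,
            buildup_rate_4 = buildup_rate_4, buildup_rate_8 = buildup_rate_8,
            unattended_gain = unattended_gain, reset_fraction = reset_fraction,
            seg_to_int_hazard = seg_to_int_hazard, hit_coefs = hit_coefs,
            fa_rate_int = fa_rate_int, fa_rate_seg = fa_rate_seg,
            latency_meanlog = latency_meanlog, latency_sdlog = latency_sdlog,
            report_delay_meanlog = report_delay_meanlog,
            report_delay_sdlog = report_delay_sdlog,
            noise_task_acc = noise_task_acc)
  assert_that(all(c(p$unattended_gain, p$reset_fraction, p$noise_task_acc,
                    p$seg_to_int_hazard) >= 0) &&
                all(c(p$unattended_gain, p$reset_fraction, p$noise_task_acc,
                      p$seg_to_int_hazard) <= 1),
              "invalid_listener_params",
              "probabilities/fractions must lie in [0, 1]")
  assert_that(p$buildup_rate_4 >= 0 && p$buildup_rate_8 >= 0 &&
                p$fa_rate_int >= 0 && p$fa_rate_seg >= 0,
              "invalid_listener_params", "hazards and rates must be >= 0")
  assert_that(p$fa_rate_int >= p$fa_rate_seg, "invalid_listener_params",
              "fa_rate_int must be >= fa_rate_seg")
  structure(p, class = "listener_params")
}

#' Draw a cohort of listener parameter sets
#'
#' Subject heterogeneity: hit-model intercept offsets N(0, 0.5^2), build-up
#' rates scaled by a common lognormal factor (sdlog 0.25), and noise-task
#' accuracy N(0.925, 0.028^2) clipped to \[0.86, 0.96\].
#'
#' @param n_subjects Number of listeners (default 12).
#' @param seed Optional integer seed.
#' @param base Template `listener_params`.
#' @return List of `listener_params`, one per subject.
#' @export
sample_listener_params <- function(n_subjects = 12, seed = NULL,
                                   base = listener_params()) {
  with_seed_or_current(seed, {
    lapply(seq_len(n_subjects), function(s) {
      p <- base
      p$subj_intercept <- stats::rnorm(1, 0, 0.5)
      sc <- exp(stats::rnorm(1, 0, 0.25))
      p$buildup_rate_4 <- base$buildup_rate_4 * sc
      p$buildup_rate_8 <- base$buildup_rate_8 * sc
      p$noise_task_acc <- min(0.96, max(0.86, stats::rnorm(1, 0.925, 0.028)))
      p
    })
  })
}

# Attention indicator per triplet window: in switch trials the tones are
# unattended before switch_time_s; otherwise attended throughout.
attended_windows <- function(trial) {
  t0 <- trial$triplets$onset_s
  if (identical(trial$task, "switch")) t0 >= trial$switch_time_s
  else rep(TRUE, length(t0))
}

#' Simulate the latent percept trajectory and percept reports for one trial
#'
#' @param trial A `trial_spec`.
#' @param params A `listener_params`.
#' @param seed Optional integer seed.
#' @return List with `latent` (character vector, one state per triplet,
#'   `"integrated"`/`"segregated"`), `effective_time_s`, and
#'   `percept_reports` (a `data.frame` of `time_s`, `label` in
#'   `one_stream`/`two_streams`). Reports are emitted only while the tones are
#'   attended: at the first attended window and at each subsequent state
#'   change, plus a lognormal motor delay.
#' @export
simulate_percept_trajectory <- function(trial, params, seed = NULL) {
  stopifnot(inherits(trial, "trial_spec"), inherits(params, "listener_params"))
  with_seed_or_current(seed, {
    n <- trial$n_triplets
    t0 <- trial$triplets$onset_s
    att <- attended_windows(trial)
    rate <- if (trial$delta_f == 8) params$buildup_rate_8 else params$buildup_rate_4
    gain <- ifelse(att, 1, params$unattended_gain)
    # effective attended time at each window onset
    e <- numeric(n)
    acc <- 0
    switched <- FALSE
    for (i in seq_len(n)) {
      if (!switched && identical(trial$task, "switch") && att[i]) {
        acc <- acc * params$reset_fraction
        switched <- TRUE
      }
      e[i] <- acc
      acc <- acc + TRIPLET_PERIOD_S * gain[i]
    }
    state <- integer(n) # 0 integrated, 1 segregated
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      prev <- if (i == 1) 0L else state[i - 1]
      p_tr <- if (prev == 0L) 1 - exp(-rate * e[i]) else params$seg_to_int_hazard
      state[i] <- if (u[i] < p_tr) 1L - prev else prev
    }
    # report triggers: first attended window, then attended state changes
    trig_idx <- integer(0)
    first_att <- which(att)[1]
    if (!is.na(first_att)) {
      changes <- which(att & c(FALSE, diff(state) != 0))
      trig_idx <- sort(unique(c(first_att, changes[changes > first_att])))
      # keep alternation: drop triggers repeating the previous reported label
      keep <- logical(length(trig_idx))
      last_lab <- NA_integer_
      for (k in seq_along(trig_idx)) {
        lab <- state[trig_idx[k]]
        if (is.na(last_lab) || lab != last_lab) {
          keep[k] <- TRUE
          last_lab <- lab
        }
      }
      trig_idx <- trig_idx[keep]
    }
    if (length(trig_idx)) {
      delays <- stats::rlnorm(length(trig_idx), params$report_delay_meanlog,
                              params$report_delay_sdlog)
      times <- t0[trig_idx] + delays
      # enforce strictly increasing report times
      for (k in seq_along(times)[-1]) {
        times[k] <- max(times[k], times[k - 1] + 0.01)
      }
      lab <- ifelse(state[trig_idx] == 1L, "two_streams", "one_stream")
      ok <- times <= trial$duration_s + 1.5
      reports <- data.frame(time_s = times[ok], label = lab[ok])
    } else {
      reports <- data.frame(time_s = numeric(0), label = character(0))
    }
    list(latent = ifelse(state == 1L, "segregated", "integrated"),
         effective_time_s = e,
         percept_reports = reports)
  })
}

#' Simulate deviant-detection keypresses for one trial
#'
#' Each attended deviant elicits a press with probability
#' `plogis(intercept + subj_intercept + delta_f8 * [df = 8] + position * pos +
#' segregated * [latent segregated])`, at a lognormal latency after the
#' deviant's additional-silence onset. False alarms arise from an
#' inhomogeneous Poisson process whose rate depends on the current latent
#' percept; no presses are generated while the listener is attending the
#' noise task.
#'
#' @param trial A `trial_spec`.
#' @param latent Character vector of latent states per triplet (from
#'   [simulate_percept_trajectory()]).
#' @param params A `listener_params`.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of press times (seconds).
#' @export
simulate_detection_responses <- function(trial, latent, params, seed = NULL) {
  stopifnot(inherits(trial, "trial_spec"), length(latent) == trial$n_triplets)
  with_seed_or_current(seed, {
    att <- attended_windows(trial)
    tl <- trial$triplets
    presses <- numeric(0)
    dev_idx <- which(tl$is_deviant)
    pos_map <- deviant_positions(trial$n_triplets)
    for (i in dev_idx) {
      if (!att[i]) next
      pos_num <- match(i, pos_map) - 1 # early 0, middle 1, late 2
      eta <- params$hit_coefs[["intercept"]] + params$subj_intercept +
        params$hit_coefs[["delta_f8"]] * (trial$delta_f == 8) +
        params$hit_coefs[["position"]] * pos_num +
        params$hit_coefs[["segregated"]] * (latent[i] == "segregated")
      if (stats::runif(1) < stats::plogis(eta)) {
        silence_onset <- tl$onset_s[i] + B_OFFSET_STD_S
        presses <- c(presses,
                     silence_onset + stats::rlnorm(1, params$latency_meanlog,
                                                   params$latency_sdlog))
      }
    }
    # false alarms per attended window, rate by latent percept
    rates <- ifelse(latent == "segregated", params$fa_rate_seg,
                    params$fa_rate_int)
    for (i in seq_len(trial$n_triplets)) {
      if (!att[i]) next
      k <- stats::rpois(1, rates[i] * TRIPLET_PERIOD_S)
      if (k > 0) {
        presses <- c(presses,
                     tl$onset_s[i] + stats::runif(k, 0, TRIPLET_PERIOD_S))
      }
    }
    sort(presses[presses <= trial$duration_s + 1.5])
  })
}

# Noise labels for the pre-switch labeling task (switch trials only).
simulate_noise_labels <- function(trial, params) {
  if (!identical(trial$task, "switch") || length(trial$noise_onsets_s) == 0) {
    return(data.frame(time_s = numeric(0), label = character(0),
                      correct = logical(0)))
  }
  correct <- stats::runif(length(trial$noise_onsets_s)) < params$noise_task_acc
  truth <- trial$noise_tokens
  other <- ifelse(truth == "approach", "depart", "approach")
  data.frame(
    time_s = trial$noise_onsets_s + NOISE_DUR_S +
      stats::rlnorm(length(truth), log(0.4), 0.3),
    label = ifelse(correct, truth, other),
    correct = correct
  )
}

#' Simulate a full session for a cohort of listeners
#'
#' @param design A `session_design`.
#' @param params_list List of `listener_params`, one per subject (default: a
#'   12-subject cohort drawn with [sample_listener_params()]).
#' @param seed Integer seed; the entire session is reproducible from it.
#' @return A `session_logs` list: `design`, and `subjects`, each with
#'   `subject`, `params`, and `trials` -- per trial a `response_log` list of
#'   `trial_id`, `percept_reports`, `detection_presses`, `noise_labels` -- plus
#'   ground truth (`latent` states per trial).
#' @examples
#' d <- make_session("exp1_subjective", rng_seed = 1)
#' logs <- simulate_session(d, sample_listener_params(2, seed = 2), seed = 3)
#' @export
simulate_session <- function(design, params_list = NULL, seed = 1L) {
  stopifnot(inherits(design, "session_design"))
  with_seed_or_current(seed, {
    if (is.null(params_list)) params_list <- sample_listener_params(12)
    subjects <- lapply(seq_along(params_list), function(s) {
      p <- params_list[[s]]
      trials <- lapply(design$trials, function(tr) {
        traj <- simulate_percept_trajectory(tr, p)
        presses <- simulate_detection_responses(tr, traj$latent, p)
        structure(list(
          trial_id = tr$trial_id,
          percept_reports = traj$percept_reports,
          detection_presses = presses,
          noise_labels = simulate_noise_labels(tr, p),
          latent = traj$latent
        ), class = "response_log")
      })
      names(trials) <- vapply(design$trials, `[[`, "", "trial_id")
      list(subject = s, params = p, trials = trials)
    })
    structure(list(design = design, subjects = subjects, seed = seed),
              class = "session_logs")
  })
}

#' @export
print.session_logs <- function(x, ...) {
  cat(sprintf("<session_logs> %s: %d subjects x %d trials\n",
              x$design$stage, length(x$subjects),
              length(x$design$trials)))
  invisible(x)
}

#' Observed noise-labeling accuracy per subject
#'
#' @param logs A `session_logs`.
#' @return Numeric vector of per-subject proportions correct (NA when a
#'   subject produced no labels).
#' @export
noise_label_accuracy <- function(logs) {
  vapply(logs$subjects, function(su) {
    cc <- unlist(lapply(su$trials, function(tr) tr$noise_labels$correct))
    if (length(cc)) mean(cc) else NA_real_
  }, numeric(1))
}

#' Flatten session logs to a tidy event table
#'
#' One row per logged event: `subject`, `trial_id`, `stream`
#' (`percept`/`detect`/`noise`), `time_s`, `value`.
#'
#' @param logs A `session_logs`.
#' @return A `data.frame`.
#' @export
logs_to_df <- function(logs) {
  rows <- list()
  for (su in logs$subjects) {
    for (tr in su$trials) {
      if (nrow(tr$percept_reports)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = su$subject, trial_id = tr$trial_id, stream = "percept",
          time_s = tr$percept_reports$time_s, value = tr$percept_reports$label)
      }
      if (length(tr$detection_presses)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = su$subject, trial_id = tr$trial_id, stream = "detect",
          time_s = tr$detection_presses, value = "press")
      }
      if (nrow(tr$noise_labels)) {
        rows[[length(rows) + 1]] <- data.frame(
          subject = su$subject, trial_id = tr$trial_id, stream = "noise",
          time_s = tr$noise_labels$time_s, value = tr$noise_labels$label)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(subject = integer(0), trial_id = character(0),
                      stream = character(0), time_s = numeric(0),
                      value = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$subject, out$trial_id, out$time_s), , drop = FALSE]
}
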