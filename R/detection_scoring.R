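# Deviant-detection scoring: hit windows, section-wise false-alarm
# normalization, 0/1 rate correction, d-prime and criterion, with optional
# percept- and subposition-conditioned cells.

#' Scoring configuration
#'
#' @param hit_window_s Seconds after a deviant's additional-silence onset
#'   within which a press counts as a hit (default 1.147, the 95th percentile
#'   of deviant-locked response latencies).
#' @param switch_post_only Score only post-switch sections and deviants for
#'   switch-task trials (the listener is labeling noises before the switch).
#' @param max_response_lag_s Presses later than the sequence end plus this lag
#'   are dropped with a warning.
#' @return A `scoring_config` list.
#' @export
scoring_config <- function(hit_window_s = 1.147, switch_post_only = TRUE,
                           max_response_lag_s = 1.5) {
  assert_that(hit_window_s > 0, "invalid_hit_window",
              "hit_window_s must be positive")
  structure(list(hit_window_s = hit_window_s,
                 switch_post_only = switch_post_only,
                 max_response_lag_s = max_response_lag_s),
            class = "scoring_config")
}

#' Section boundaries for false-alarm labeling
#'
#' Sections partition the sequence so that the late section is always the
#' final 6 s and the early and middle sections split the remainder equally.
#' For a 37-triplet (18.5-s) sequence the boundaries are 6.25 and 12.5 s.
#'
#' @param n_triplets Sequence length in triplets.
#' @return List with `breaks` (length 4: 0, early/middle, middle/late, end)
#'   and `durations` (named: early, middle, late).
#' @export
section_boundaries <- function(n_triplets) {
  dur <- n_triplets * TRIPLET_PERIOD_S
  late_start <- dur - 6
  b1 <- late_start / 2
  list(breaks = c(0, b1, late_start, dur),
       durations = c(early = b1, middle = late_start - b1, late = 6))
}

#' Hit window from pooled deviant-locked latencies
#'
#' The latency within which 95% of responses to deviants were made, pooled
#' across conditions and subjects, computed as a linear-interpolation
#' percentile (quantile type 7).
#'
#' @param latencies_s Numeric vector of response latencies (seconds from
#'   additional-silence onset).
#' @param prob Percentile (default 0.95).
#' @return The window in seconds.
#' @export
compute_hit_window <- function(latencies_s, prob = 0.95) {
  assert_that(length(latencies_s) >= 1, "empty_latencies",
              "at least one latency is required")
  unname(stats::quantile(latencies_s, prob, type = 7))
}

# Silence onsets of deviants in a trial (seconds): where the standard B tone
# would have started.
deviant_silence_onsets <- function(trial) {
  tl <- trial$triplets
  idx <- which(tl$is_deviant)
  data.frame(index = idx,
             position = names(deviant_positions(trial$n_triplets))[
               match(idx, deviant_positions(trial$n_triplets))],
             onset_s = tl$onset_s[idx] + B_OFFSET_STD_S)
}

#' Classify presses of one trial as hits or false alarms
#'
#' A press within `hit_window_s` of a deviant's additional-silence onset is a
#' hit; only the first such press counts, later presses in the same window
#' are false alarms. Deviants are matched in time order and each press is
#' consumed by at most one deviant. All remaining presses are false alarms,
#' labeled by the section containing them. For switch-task trials with
#' `switch_post_only`, pre-switch deviants and presses are excluded.
#'
#' @param trial A `trial_spec`.
#' @param presses Sorted numeric vector of press times (seconds).
#' @param config A [scoring_config()].
#' @return List with `hits` (data.frame: deviant index, position, onset_s,
#'   press_s, latency_s), `misses` (data.frame: index, position, onset_s),
#'   `fas` (data.frame: time_s, section), and `dropped` (numeric vector).
#' @export
classify_responses <- function(trial, presses, config = scoring_config()) {
  stopifnot(inherits(trial, "trial_spec"))
  presses <- sort(presses)
  out_of_range <- presses < 0 |
    presses > trial$duration_s + config$max_response_lag_s
  if (any(out_of_range)) {
    warning(sprintf("dropping %d press(es) outside the response window",
                    sum(out_of_range)))
  }
  dropped <- presses[out_of_range]
  presses <- presses[!out_of_range]
  post_only <- identical(trial$task, "switch") && config$switch_post_only
  if (post_only) presses <- presses[presses >= trial$switch_time_s]

  devs <- deviant_silence_onsets(trial)
  if (post_only && nrow(devs)) {
    devs <- devs[devs$onset_s >= trial$switch_time_s, , drop = FALSE]
  }
  used <- rep(FALSE, length(presses))
  hit_rows <- vector("list", nrow(devs))
  miss <- rep(TRUE, nrow(devs))
  if (nrow(devs)) {
    for (d in seq_len(nrow(devs))) {
      cand <- which(!used & presses >= devs$onset_s[d] &
                      presses <= devs$onset_s[d] + config$hit_window_s)
      if (length(cand)) {
        j <- cand[1]
        used[j] <- TRUE
        miss[d] <- FALSE
        hit_rows[[d]] <- data.frame(
          index = devs$index[d], position = devs$position[d],
          onset_s = devs$onset_s[d], press_s = presses[j],
          latency_s = presses[j] - devs$onset_s[d])
      }
    }
  }
  hits <- do.call(rbind, hit_rows[!vapply(hit_rows, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(index = integer(0), position = character(0),
                       onset_s = numeric(0), press_s = numeric(0),
                       latency_s = numeric(0))
  }
  fa_times <- presses[!used]
  sec <- section_boundaries(trial$n_triplets)
  fa_sec <- if (length(fa_times)) {
    cut(pmin(pmax(fa_times, 0), trial$duration_s - 1e-9),
        breaks = sec$breaks, labels = c("early", "middle", "late"),
        include.lowest = TRUE, right = FALSE)
  } else factor(character(0), levels = c("early", "middle", "late"))
  list(hits = hits,
       misses = data.frame(index = devs$index[miss],
                           position = devs$position[miss],
                           onset_s = devs$onset_s[miss]),
       fas = data.frame(time_s = fa_times, section = as.character(fa_sec)),
       dropped = dropped)
}

#' Normalized count of nonsignal "trials" in a section
#'
#' The section duration is divided by the hit window to give an equivalent
#' number of detection opportunities, reduced by one when the section
#' contains a deviant.
#'
#' @param section_duration_s Section duration in seconds.
#' @param n_deviants_in_section 0 or 1.
#' @param config A [scoring_config()].
#' @return Real-valued nonsignal trial count.
#' @export
count_nonsignal_trials <- function(section_duration_s, n_deviants_in_section,
                                   config = scoring_config()) {
  assert_that(section_duration_s > 0, "invalid_section",
              "section duration must be positive")
  assert_that(n_deviants_in_section %in% c(0, 1), "invalid_deviant_count",
              "a section contains at most one deviant")
  out <- section_duration_s / config$hit_window_s - n_deviants_in_section
  assert_that(out > 0, "invalid_nonsignal_count",
              "nonsignal trial count must be positive")
  out
}

# Rate with the 0.5 numerator correction applied when the pooled rate is
# exactly 0 or 1.
corrected_rate <- function(numerator, denominator) {
  rate <- numerator / denominator
  if (rate == 0) rate <- 0.5 / denominator
  if (rate == 1) rate <- (numerator - 0.5) / denominator
  rate
}

#' Sensitivity and criterion from pooled cell counts
#'
#' Rates are formed from counts pooled over all instances of a cell; when a
#' pooled rate is exactly 0 or 1 its numerator is adjusted by 0.5 before the
#' z transform. `dprime = z(hit rate) - z(fa rate)`;
#' `criterion = -(z(hit rate) + z(fa rate)) / 2`.
#'
#' @param cells A `data.frame` with columns `n_hits`, `n_deviants`, `n_fa`,
#'   `n_nonsignal` (one row per cell), plus any label columns.
#' @return The input with `hit_rate`, `fa_rate`, `dprime`, `criterion` added.
#' @export
aggregate_dprime <- function(cells) {
  stopifnot(all(c("n_hits", "n_deviants", "n_fa", "n_nonsignal") %in%
                  names(cells)))
  assert_that(all(cells$n_nonsignal >= 1), "invalid_nonsignal_count",
              "each cell needs a nonsignal trial count of at least 1")
  assert_that(all(cells$n_hits <= cells$n_deviants), "invalid_counts",
              "hits cannot exceed deviants")
  hr <- fr <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    hr[i] <- if (cells$n_deviants[i] > 0)
      corrected_rate(cells$n_hits[i], cells$n_deviants[i]) else NA_real_
    fr[i] <- corrected_rate(cells$n_fa[i], cells$n_nonsignal[i])
  }
  cells$hit_rate <- hr
  cells$fa_rate <- fr
  cells$dprime <- stats::qnorm(hr) - stats::qnorm(fr)
  cells$criterion <- -(stats::qnorm(hr) + stats::qnorm(fr)) / 2
  cells
}

#' Percept in effect at a given time
#'
#' The label of the latest report at or before `time_s` (the report instant
#' itself counts as the new label), or `"unreported"` when no report precedes.
#'
#' @param time_s Time in seconds.
#' @param percept_reports `data.frame` of `time_s`, `label`, sorted by time.
#' @return `"one_stream"`, `"two_streams"` or `"unreported"`.
#' @export
percept_at <- function(time_s, percept_reports) {
  if (is.null(percept_reports) || nrow(percept_reports) == 0) {
    return("unreported")
  }
  k <- findInterval(time_s, percept_reports$time_s)
  if (k == 0) "unreported" else percept_reports$label[k]
}

#' Deviant-locked response latencies pooled over a session
#'
#' For auto-selection of the hit window: every press within `max_lag_s` after
#' a deviant's additional-silence onset is treated as a response to that
#' deviant and its latency collected, pooled across trials and subjects.
#'
#' @param logs A `session_logs`.
#' @param max_lag_s Pooling window (default 2 s).
#' @return Numeric vector of latencies in seconds.
#' @export
pooled_deviant_latencies <- function(logs, max_lag_s = 2) {
  lat <- numeric(0)
  for (su in logs$subjects) {
    for (tr in logs$design$trials) {
      log_tr <- su$trials[[tr$trial_id]]
      devs <- deviant_silence_onsets(tr)
      if (identical(tr$task, "switch")) {
        devs <- devs[devs$onset_s >= tr$switch_time_s, , drop = FALSE]
      }
      for (o in devs$onset_s) {
        hit <- log_tr$detection_presses[
          log_tr$detection_presses >= o &
            log_tr$detection_presses <= o + max_lag_s]
        if (length(hit)) lat <- c(lat, hit[1] - o)
      }
    }
  }
  lat
}

#' Score a simulated or recorded session
#'
#' Classifies every trial's presses, pools counts into cells and computes
#' d-prime and criterion per cell. Cells are defined by subject, frequency
#' separation, deviant position and task, optionally split by the percept in
#' effect at the deviant (or false alarm) and by deviant subposition.
#'
#' When conditioning on percept, the nonsignal trial count of a
#' percept-specific cell is the time spent in that reported percept within
#' the section, divided by the hit window, minus deviants occurring during
#' that percept; deviants occurring before any report are excluded from
#' percept-conditioned cells but retained in stimulus-conditioned ones.
#'
#' @param logs A `session_logs`.
#' @param hit_window `"auto"` (95th percentile of pooled deviant-locked
#'   latencies) or a number of seconds.
#' @param config A [scoring_config()]; its `hit_window_s` is overridden by
#'   `hit_window`.
#' @param by_percept Split cells by concurrent percept.
#' @param by_subposition Split cells by the deviant's absolute onset time.
#' @return A `data.frame` of scored cells (see [aggregate_dprime()]), with
#'   attribute `hit_window_s`.
#' @export
score_session <- function(logs, hit_window = "auto",
                          config = scoring_config(), by_percept = FALSE,
                          by_subposition = FALSE) {
  stopifnot(inherits(logs, "session_logs"))
  hw <- if (identical(hit_window, "auto")) {
    compute_hit_window(pooled_deviant_latencies(logs))
  } else as.numeric(hit_window)
  config$hit_window_s <- hw
  rows <- list()
  for (su in logs$subjects) {
    for (tr in logs$design$trials) {
      log_tr <- su$trials[[tr$trial_id]]
      cls <- classify_responses(tr, log_tr$detection_presses, config)
      sec <- section_boundaries(tr$n_triplets)
      post_only <- identical(tr$task, "switch") && config$switch_post_only
      positions <- if (post_only) "late" else c("early", "middle", "late")
      for (pos in positions) {
        pos_i <- match(pos, c("early", "middle", "late"))
        has_dev <- pos %in% tr$deviant_config
        dev_onset <- if (has_dev) {
          tl_idx <- deviant_positions(tr$n_triplets)[[pos]]
          tr$triplets$onset_s[tl_idx] + B_OFFSET_STD_S
        } else NA_real_
        hit <- has_dev && pos %in% cls$hits$position
        n_fa <- sum(cls$fas$section == pos)
        base <- data.frame(
          subject = su$subject, delta_f = tr$delta_f, position = pos,
          task = tr$task,
          subposition = if (by_subposition) dev_onset else NA_real_,
          n_hits = as.integer(hit), n_deviants = as.integer(has_dev),
          n_fa = n_fa,
          n_nonsignal = sec$durations[[pos]] / hw - as.integer(has_dev)
        )
        if (!by_percept) {
          rows[[length(rows) + 1]] <- cbind(base, percept = NA_character_)
        } else {
          reports <- log_tr$percept_reports
          occ <- percept_occupancy(reports, sec$breaks[pos_i],
                                   sec$breaks[pos_i + 1])
          for (pc in c("one_stream", "two_streams")) {
            dev_pc <- if (has_dev) percept_at(dev_onset, reports) else NA
            has_dev_pc <- isTRUE(dev_pc == pc)
            ns <- occ[[pc]] / hw - as.integer(has_dev_pc)
            if (ns < .Machine$double.eps && !has_dev_pc) next
            fa_pc <- if (nrow(cls$fas)) {
              sum(cls$fas$section == pos &
                    vapply(cls$fas$time_s, percept_at, "", reports) == pc)
            } else 0L
            row <- base
            row$n_hits <- as.integer(hit && has_dev_pc)
            row$n_deviants <- as.integer(has_dev_pc)
            row$n_fa <- fa_pc
            row$n_nonsignal <- ns
            rows[[length(rows) + 1]] <- cbind(row, percept = pc)
          }
        }
      }
    }
  }
  per_trial <- do.call(rbind, rows)
  keys <- c("subject", "delta_f", "position", "task",
            if (by_percept) "percept", if (by_subposition) "subposition")
  agg <- stats::aggregate(
    per_trial[c("n_hits", "n_deviants", "n_fa", "n_nonsignal")],
    by = per_trial[keys], FUN = sum)
  agg <- agg[agg$n_nonsignal >= 1, , drop = FALSE]
  out <- aggregate_dprime(agg)
  attr(out, "hit_window_s") <- hw
  out
}

# Time (seconds) spent in each reported percept within [from, to).
percept_occupancy <- function(reports, from, to) {
  out <- c(one_stream = 0, two_streams = 0)
  if (is.null(reports) || nrow(reports) == 0) return(as.list(out))
  times <- c(reports$time_s, Inf)
  for (k in seq_len(nrow(reports))) {
    a <- max(from, reports$time_s[k])
    b <- min(to, times[k + 1])
    if (b > a) out[[reports$label[k]]] <- out[[reports$label[k]]] + (b - a)
  }
  as.list(out)
}

#' Per-deviant outcome table for the logistic model ladder
#'
#' One row per attended deviant: subject, frequency separation, position,
#' subposition (absolute additional-silence onset), the percept in effect at
#' the deviant, and whether it was hit.
#'
#' @param logs A `session_logs`.
#' @param config A [scoring_config()].
#' @return A `data.frame` with columns `subject`, `delta_f`, `position`,
#'   `subposition_s`, `percept`, `hit`.
#' @export
deviant_outcomes <- function(logs, config = scoring_config()) {
  rows <- list()
  for (su in logs$subjects) {
    for (tr in logs$design$trials) {
      log_tr <- su$trials[[tr$trial_id]]
      cls <- classify_responses(tr, log_tr$detection_presses, config)
      devs <- deviant_silence_onsets(tr)
      if (identical(tr$task, "switch") && config$switch_post_only) {
        devs <- devs[devs$onset_s >= tr$switch_time_s, , drop = FALSE]
      }
      if (!nrow(devs)) next
      rows[[length(rows) + 1]] <- data.frame(
        subject = su$subject, delta_f = tr$delta_f,
        position = devs$position, subposition_s = devs$onset_s,
        percept = vapply(devs$onset_s, percept_at, "",
                         log_tr$percept_reports),
        hit = as.integer(devs$position %in% cls$hits$position)
      )
    }
  }
  do.call(rbind, rows)
}
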