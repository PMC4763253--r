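# Build-up curves: percept reports sampled on the triplet grid, proportion
# segregated with per-point denominators, first-report statistics and
# log-transformed phase durations.

#' Sample the reported percept at each triplet onset
#'
#' At each triplet onset the most recent report's label applies (a report at
#' exactly the onset counts); onsets before the first report are
#' `"unreported"`.
#'
#' @param trial A `trial_spec`.
#' @param percept_reports `data.frame` of `time_s`, `label`.
#' @return A `data.frame` with `time_s` (triplet onsets) and `label`.
#' @export
sample_percept_grid <- function(trial, percept_reports) {
  t0 <- trial$triplets$onset_s
  lab <- vapply(t0, percept_at, "", percept_reports)
  data.frame(time_s = t0, label = lab)
}

#' Proportion-segregated build-up curve
#'
#' At each grid time point the numerator is the number of trials labeled
#' `two_streams` and the denominator the number of trials for which any
#' report had been made by then; the proportion is undefined (NA) where the
#' denominator is zero. With `alignment = "switch"` the grid is re-zeroed at
#' the switch time and only post-switch points are returned.
#'
#' @param grids List of per-trial label grids from [sample_percept_grid()].
#' @param alignment `"sequence_start"` or `"switch"`.
#' @param switch_time_s Required for switch alignment.
#' @return A `data.frame` with `time_s`, `prop_seg`, `n_responding`.
#' @export
proportion_segregated <- function(grids, alignment = c("sequence_start",
                                                       "switch"),
                                  switch_time_s = SWITCH_TIME_S) {
  alignment <- match.arg(alignment)
  assert_that(length(grids) >= 1, "empty_grids",
              "at least one trial grid is required")
  if (alignment == "switch") {
    grids <- lapply(grids, function(g) {
      g <- g[g$time_s >= switch_time_s - 1e-9, , drop = FALSE]
      g$time_s <- g$time_s - switch_time_s
      g
    })
  }
  times <- sort(unique(unlist(lapply(grids, `[[`, "time_s"))))
  n_seg <- n_resp <- numeric(length(times))
  for (g in grids) {
    m <- match(round(g$time_s, 6), round(times, 6))
    responded <- g$label != "unreported"
    n_resp[m[responded]] <- n_resp[m[responded]] + 1
    seg <- g$label == "two_streams"
    n_seg[m[seg]] <- n_seg[m[seg]] + 1
  }
  data.frame(time_s = times,
             prop_seg = ifelse(n_resp >= 1, n_seg / n_resp, NA_real_),
             n_responding = n_resp)
}

#' Build-up curves for a whole session
#'
#' Per subject, frequency separation and task, with start-aligned curves for
#' attend/dual trials and both alignments for switch trials.
#'
#' @param logs A `session_logs`.
#' @return A `data.frame` with `subject`, `delta_f`, `task`, `alignment`,
#'   `time_s`, `prop_seg`, `n_responding`.
#' @export
buildup_curves <- function(logs) {
  stopifnot(inherits(logs, "session_logs"))
  rows <- list()
  for (su in logs$subjects) {
    trs <- logs$design$trials
    key <- vapply(trs, function(tr) paste(tr$delta_f, tr$task, sep = "|"), "")
    for (k in unique(key)) {
      sel <- trs[key == k]
      delta_f <- sel[[1]]$delta_f
      task <- sel[[1]]$task
      grids <- lapply(sel, function(tr) {
        sample_percept_grid(tr, su$trials[[tr$trial_id]]$percept_reports)
      })
      aligns <- if (identical(task, "switch")) c("sequence_start", "switch")
                else "sequence_start"
      for (al in aligns) {
        cv <- proportion_segregated(grids, al,
                                    switch_time_s = SWITCH_TIME_S)
        rows[[length(rows) + 1]] <- cbind(
          data.frame(subject = su$subject, delta_f = delta_f, task = task,
                     alignment = al), cv)
      }
    }
  }
  do.call(rbind, rows)
}

#' First-report statistics
#'
#' For each subject, separation and task: the proportion of first reports
#' that were `two_streams`, and the mean time to the first `two_streams`
#' report, counted only over trials where that report occurred within
#' `max_first_seg_s` of alignment zero (sequence start, or the switch for
#' switch trials). Subjects without qualifying trials are excluded from the
#' mean.
#'
#' @param logs A `session_logs`.
#' @param max_first_seg_s Qualification window (default 6 s).
#' @return A `data.frame` with `subject`, `delta_f`, `task`,
#'   `prop_first_seg`, `mean_time_first_seg_s`, `n_qualifying`.
#' @export
first_report_stats <- function(logs, max_first_seg_s = 6) {
  rows <- list()
  for (su in logs$subjects) {
    trs <- logs$design$trials
    key <- vapply(trs, function(tr) paste(tr$delta_f, tr$task, sep = "|"), "")
    for (k in unique(key)) {
      sel <- trs[key == k]
      delta_f <- sel[[1]]$delta_f
      task <- sel[[1]]$task
      zero <- if (identical(task, "switch")) SWITCH_TIME_S else 0
      first_lab <- character(0)
      t_first_seg <- numeric(0)
      for (tr in sel) {
        rep_df <- su$trials[[tr$trial_id]]$percept_reports
        if (nrow(rep_df) == 0) next
        first_lab <- c(first_lab, rep_df$label[1])
        seg <- rep_df$time_s[rep_df$label == "two_streams"] - zero
        seg <- seg[seg >= 0]
        if (length(seg) && seg[1] <= max_first_seg_s) {
          t_first_seg <- c(t_first_seg, seg[1])
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = su$subject, delta_f = delta_f, task = task,
        prop_first_seg = if (length(first_lab))
          mean(first_lab == "two_streams") else NA_real_,
        mean_time_first_seg_s = if (length(t_first_seg))
          mean(t_first_seg) else NA_real_,
        n_qualifying = length(t_first_seg))
    }
  }
  do.call(rbind, rows)
}

#' Log-transformed perceptual phase durations
#'
#' Durations between consecutive percept alternations, with the final
#' (censored) phase excluded, transformed to natural logarithms.
#'
#' @param percept_reports `data.frame` of `time_s`, `label`.
#' @param sequence_end_s Sequence end (used only to validate input times).
#' @return A `data.frame` with `label` (the percept occupying the phase) and
#'   `ln_duration`.
#' @export
phase_durations <- function(percept_reports, sequence_end_s) {
  if (nrow(percept_reports) < 2) {
    return(data.frame(label = character(0), ln_duration = numeric(0)))
  }
  d <- diff(percept_reports$time_s)
  assert_that(all(d > 0), "nonpositive_phase",
              "report times must be strictly increasing")
  data.frame(label = percept_reports$label[-nrow(percept_reports)],
             ln_duration = log(d))
}

#' Subject-by-time curve matrix
#'
#' Reshapes the tidy curve table from [buildup_curves()] into a subjects x
#' time matrix for one condition, as consumed by the covert-attention scan
#' and the SPM test.
#'
#' @param curves Output of [buildup_curves()].
#' @param delta_f,task,alignment Condition selectors.
#' @return Numeric matrix (subjects x time points) with `times_s` attribute.
#' @export
curve_matrix <- function(curves, delta_f, task,
                         alignment = "sequence_start") {
  sel <- curves[curves$delta_f == delta_f & curves$task == task &
                  curves$alignment == alignment, , drop = FALSE]
  assert_that(nrow(sel) > 0, "empty_condition",
              "no curve rows match the requested condition")
  times <- sort(unique(sel$time_s))
  subjects <- sort(unique(sel$subject))
  m <- matrix(NA_real_, length(subjects), length(times),
              dimnames = list(subjects, NULL))
  for (i in seq_along(subjects)) {
    s <- sel[sel$subject == subjects[i], ]
    m[i, match(round(s$time_s, 6), round(times, 6))] <- s$prop_seg
  }
  attr(m, "times_s") <- times
  m
}
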