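# Stimulus timelines: ABA- triplet sequences with rhythmic deviants, a
# contralateral noise-burst series, and the factorial session designs.
#
# All times are in seconds from sequence onset; triplet indices are 1-based;
# intervals are half-open [onset, onset + duration).

# Fixed stimulus geometry (seconds).
TRIPLET_PERIOD_S <- 0.5
TONE_DUR_S <- 0.05
B_OFFSET_STD_S <- 0.125 # A(0) + 50 ms tone + 75 ms gap
B_OFFSET_DEV_S <- 0.175 # B tone delayed by 50 ms in deviant triplets
A2_OFFSET_S <- 0.25
NOISE_DUR_S <- 0.4
SWITCH_TIME_S <- 12.5 # midpoint of mean middle (10 s) and late (15 s) onsets

#' Build the triplet timeline for one sequence
#'
#' Constructs an ordered table of ABA- triplets on a 0.5-s grid. Within a
#' triplet the A tones start at 0 and 250 ms and the B tone at 125 ms
#' (175 ms when the triplet is a deviant); all tones last 50 ms.
#'
#' @param n_triplets Number of triplets (the designs use 35, 37 or 39).
#' @param delta_f Frequency separation between A and B tones in semitones
#'   (4 or 8).
#' @param a_freq_hz A-tone frequency in Hz.
#' @return A `data.frame` with one row per triplet: `index`, `onset_s`,
#'   `is_deviant`, `a_freq_hz`, `b_freq_hz`, `b_offset_s`.
#' @examples
#' tl <- build_triplet_timeline(37, 8)
#' tail(tl$onset_s, 1) # 18.0
#' @export
build_triplet_timeline <- function(n_triplets, delta_f, a_freq_hz = 800) {
  assert_that(length(n_triplets) == 1 && is.finite(n_triplets) &&
                n_triplets >= 1 && n_triplets == round(n_triplets),
              "invalid_n_triplets", "n_triplets must be a positive integer")
  assert_that(length(delta_f) == 1 && delta_f %in% c(4, 8),
              "invalid_delta_f", "delta_f must be 4 or 8 semitones")
  assert_that(length(a_freq_hz) == 1 && is.finite(a_freq_hz) && a_freq_hz > 0,
              "invalid_a_freq", "a_freq_hz must be positive")
  idx <- seq_len(n_triplets)
  data.frame(
    index = idx,
    onset_s = (idx - 1) * TRIPLET_PERIOD_S,
    is_deviant = FALSE,
    a_freq_hz = a_freq_hz,
    b_freq_hz = a_freq_hz * 2^(delta_f / 12),
    b_offset_s = B_OFFSET_STD_S
  )
}

#' Deviant triplet indices for a sequence length
#'
#' The early deviant is the sixth triplet (onset 2.5 s). Counting from the
#' end of the sequence inclusively, the late deviant is the seventh-from-last
#' triplet (onsets 14/15/16 s for 35/37/39 triplets) and the middle deviant
#' the seventeenth-from-last (onsets 9/10/11 s), so that middle and late
#' onsets straddle the 12.5-s attention-switch point symmetrically.
#'
#' @param n_triplets Sequence length in triplets.
#' @return Named integer vector with elements `early`, `middle`, `late`.
#' @export
deviant_positions <- function(n_triplets) {
  pos <- c(early = 6L, middle = as.integer(n_triplets - 16L),
           late = as.integer(n_triplets - 6L))
  assert_that(all(pos >= 1) && !anyDuplicated(pos) && all(diff(pos) > 0),
              "invalid_deviant_positions",
              "sequence too short for distinct early/middle/late deviants")
  pos
}

#' Flag deviant triplets in a timeline
#'
#' Marks the triplets named by `deviant_config` as deviants; their B-tone
#' offset becomes 175 ms. All other events are unchanged.
#'
#' @param timeline Timeline from [build_triplet_timeline()].
#' @param deviant_config Character vector, a subset of
#'   `c("early", "middle", "late")` (possibly empty).
#' @param n_triplets Sequence length; defaults to `nrow(timeline)`.
#' @return The timeline with `is_deviant` and `b_offset_s` updated.
#' @export
place_deviants <- function(timeline, deviant_config,
                           n_triplets = nrow(timeline)) {
  assert_that(all(deviant_config %in% c("early", "middle", "late")),
              "invalid_deviant_config",
              "deviant_config must be a subset of early/middle/late")
  if (length(deviant_config) == 0) return(timeline)
  pos <- deviant_positions(n_triplets)[unique(deviant_config)]
  timeline$is_deviant[pos] <- TRUE
  timeline$b_offset_s[pos] <- B_OFFSET_DEV_S
  timeline
}

#' Schedule the contralateral noise-burst series
#'
#' Noise bursts (400 ms) start at time 0 and recur with gaps drawn i.i.d.
#' uniformly from \[0.75, 1.25\] s (mean rate 1/s, rectangular jitter of up to
#' +/- 250 ms). The series is truncated so that every burst ends at or before
#' `switch_time_s`.
#'
#' @param switch_time_s End of the noise series, seconds (default 12.5).
#' @param seed Optional integer seed; the schedule is reproducible given it.
#' @return Numeric vector of burst onsets in seconds.
#' @export
schedule_noises <- function(switch_time_s = SWITCH_TIME_S, seed = NULL) {
  assert_that(switch_time_s > 0, "invalid_switch_time",
              "switch_time_s must be positive")
  with_seed_or_current(seed, {
    # upper bound on the number of gaps needed: min gap 0.75 s
    n_max <- ceiling(switch_time_s / 0.75) + 2L
    gaps <- stats::runif(n_max, 0.75, 1.25)
    onsets <- c(0, cumsum(gaps))
    onsets[onsets + NOISE_DUR_S <= switch_time_s]
  })
}

#' Assemble a single trial specification
#'
#' @param trial_id Integer or character identifier.
#' @param n_triplets 35, 37 or 39.
#' @param delta_f 4 or 8 semitones.
#' @param task `"attend"`, `"switch"` or `"dual"`.
#' @param deviant_config Subset of `c("early", "middle", "late")`.
#' @param a_freq_hz A-tone frequency in Hz.
#' @param seed Optional seed for the noise schedule and token draw.
#' @return A `trial_spec` list: the deviant-flagged timeline, noise onsets and
#'   approach/depart tokens, the switch time (for switch trials), and labels.
#' @export
make_trial <- function(trial_id, n_triplets, delta_f, task,
                       deviant_config = character(), a_freq_hz = 800,
                       seed = NULL) {
  assert_that(n_triplets %in% c(35L, 37L, 39L), "invalid_n_triplets",
              "n_triplets must be 35, 37 or 39 for a standard trial")
  assert_that(task %in% c("attend", "switch", "dual"), "invalid_task",
              "task must be attend, switch or dual")
  tl <- build_triplet_timeline(n_triplets, delta_f, a_freq_hz)
  tl <- place_deviants(tl, deviant_config)
  with_seed_or_current(seed, {
    noise_onsets <- schedule_noises(SWITCH_TIME_S)
    noise_tokens <- sample(c("approach", "depart"), length(noise_onsets),
                           replace = TRUE)
    structure(list(
      trial_id = trial_id,
      n_triplets = as.integer(n_triplets),
      delta_f = delta_f,
      task = task,
      deviant_config = sort(unique(deviant_config)),
      switch_time_s = if (identical(task, "switch")) SWITCH_TIME_S else NA_real_,
      duration_s = n_triplets * TRIPLET_PERIOD_S,
      triplets = tl,
      noise_onsets_s = noise_onsets,
      noise_tokens = noise_tokens
    ), class = "trial_spec")
  })
}

#' @export
print.trial_spec <- function(x, ...) {
  cat(sprintf(
    "<trial_spec %s> %d triplets (%.1f s), delta_f = %d st, task = %s, deviants: %s\n",
    x$trial_id, x$n_triplets, x$duration_s, x$delta_f, x$task,
    if (length(x$deviant_config)) paste(x$deviant_config, collapse = "+")
    else "none"))
  invisible(x)
}

#' Build a full session design
#'
#' The objective stage of Experiment 1 crosses frequency separation (4, 8 st),
#' the eight deviant configurations, task (attend, switch) and sequence length
#' (35, 37, 39 triplets), each combination exactly once: 96 trials. The
#' subjective stage drops the length factor (all 37 triplets): 32 trials.
#' Experiment 2 uses the dual task throughout and crosses separation,
#' configuration and length: 48 trials. Trial order is randomized and the
#' A-tone frequency is drawn per trial from a log-uniform distribution over
#' one octave centered on 800 Hz.
#'
#' @param stage `"exp1_objective"`, `"exp1_subjective"` or `"exp2"`.
#' @param rng_seed Integer seed controlling trial order, A frequencies and
#'   noise schedules.
#' @return A `session_design` list with elements `stage`, `trials` (list of
#'   `trial_spec`), and `rng_seed`.
#' @examples
#' d <- make_session("exp2", rng_seed = 1)
#' length(d$trials) # 48
#' @export
make_session <- function(stage, rng_seed = 1L) {
  assert_that(stage %in% c("exp1_objective", "exp1_subjective", "exp2"),
              "unknown_stage", sprintf("unknown stage name: %s", stage))
  configs <- list(character(), "early", "middle", "late",
                  c("early", "middle"), c("early", "late"),
                  c("middle", "late"), c("early", "middle", "late"))
  grid <- switch(stage,
    exp1_objective = expand.grid(delta_f = c(4, 8), config = seq_along(configs),
                                 task = c("attend", "switch"),
                                 n_triplets = c(35L, 37L, 39L),
                                 stringsAsFactors = FALSE),
    exp1_subjective = expand.grid(delta_f = c(4, 8), config = seq_along(configs),
                                  task = c("attend", "switch"),
                                  n_triplets = 37L,
                                  stringsAsFactors = FALSE),
    exp2 = expand.grid(delta_f = c(4, 8), config = seq_along(configs),
                       task = "dual", n_triplets = c(35L, 37L, 39L),
                       stringsAsFactors = FALSE)
  )
  with_seed_or_current(rng_seed, {
    ord <- sample.int(nrow(grid))
    grid <- grid[ord, , drop = FALSE]
    a_freqs <- 800 * 2^stats::runif(nrow(grid), -0.5, 0.5)
    trials <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      trials[[i]] <- make_trial(
        trial_id = sprintf("%s_%03d", stage, i),
        n_triplets = grid$n_triplets[i],
        delta_f = grid$delta_f[i],
        task = grid$task[i],
        deviant_config = configs[[grid$config[i]]],
        a_freq_hz = a_freqs[i]
      )
    }
    structure(list(stage = stage, trials = trials, rng_seed = rng_seed),
              class = "session_design")
  })
}

#' @export
print.session_design <- function(x, ...) {
  cat(sprintf("<session_design %s> %d trials (seed %s)\n",
              x$stage, length(x$trials), x$rng_seed))
  invisible(x)
}

#' Event table for a trial or session
#'
#' Serializes schedules as one event per row, suitable for CSV export:
#' columns `trial_id`, `event_type` (`tone_A`, `tone_B`, `noise`,
#' `switch_cue`), `onset_s`, `duration_s`, `freq_hz`, `is_deviant`.
#'
#' @param x A `trial_spec` or `session_design`.
#' @return A `data.frame` of events ordered by onset within trial.
#' @export
trial_events <- function(x) {
  if (inherits(x, "session_design")) {
    return(do.call(rbind, lapply(x$trials, trial_events)))
  }
  stopifnot(inherits(x, "trial_spec"))
  tl <- x$triplets
  ev <- rbind(
    data.frame(trial_id = x$trial_id, event_type = "tone_A",
               onset_s = tl$onset_s, duration_s = TONE_DUR_S,
               freq_hz = tl$a_freq_hz, is_deviant = tl$is_deviant),
    data.frame(trial_id = x$trial_id, event_type = "tone_B",
               onset_s = tl$onset_s + tl$b_offset_s, duration_s = TONE_DUR_S,
               freq_hz = tl$b_freq_hz, is_deviant = tl$is_deviant),
    data.frame(trial_id = x$trial_id, event_type = "tone_A",
               onset_s = tl$onset_s + A2_OFFSET_S, duration_s = TONE_DUR_S,
               freq_hz = tl$a_freq_hz, is_deviant = tl$is_deviant),
    data.frame(trial_id = x$trial_id, event_type = "noise",
               onset_s = x$noise_onsets_s, duration_s = NOISE_DUR_S,
               freq_hz = NA_real_, is_deviant = FALSE)
  )
  if (!is.na(x$switch_time_s)) {
    ev <- rbind(ev, data.frame(trial_id = x$trial_id, event_type = "switch_cue",
                               onset_s = x$switch_time_s, duration_s = 0,
                               freq_hz = NA_real_, is_deviant = FALSE))
  }
  ev[order(ev$onset_s, ev$event_type), , drop = FALSE]
}

#' Serialize / restore a session design as JSON
#'
#' @param design A `session_design`.
#' @param path File path.
#' @return `design_from_json` returns the restored `session_design`.
#' @export
design_to_json <- function(design, path) {
  stopifnot(inherits(design, "session_design"))
  x <- list(stage = design$stage, rng_seed = design$rng_seed,
            trials = lapply(design$trials, function(tr) {
              tr$triplets <- as.list(tr$triplets)
              unclass(tr)
            }))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname design_to_json
#' @export
design_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  trials <- lapply(x$trials, function(tr) {
    out <- list(
      trial_id = tr$trial_id, n_triplets = as.integer(tr$n_triplets),
      delta_f = as.numeric(tr$delta_f), task = tr$task,
      deviant_config = as.character(unlist(tr$deviant_config)),
      switch_time_s = if (is.null(tr$switch_time_s)) NA_real_
                      else as.numeric(tr$switch_time_s),
      duration_s = as.numeric(tr$duration_s),
      triplets = data.frame(lapply(tr$triplets, unlist)),
      noise_onsets_s = as.numeric(unlist(tr$noise_onsets_s)),
      noise_tokens = as.character(unlist(tr$noise_tokens))
    )
    structure(out, class = "trial_spec")
  })
  structure(list(stage = x$stage, trials = trials, rng_seed = x$rng_seed),
            class = "session_design")
}
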