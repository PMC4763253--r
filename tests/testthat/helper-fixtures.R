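# Shared fixtures: smooth random fields, synthetic cohorts for the q scan,
# outcome-table simulators for the model ladder, and a brute-force
# press-deviant matcher used as the scoring oracle.

# Smooth Gaussian random fields: rows are subjects, columns time points;
# white noise convolved with a Gaussian kernel of the given FWHM (grid
# units), each kernel column renormalized to unit sum of squares.
smooth_fields <- function(n, T, fwhm) {
  sigma <- fwhm / sqrt(8 * log(2))
  K <- vapply(seq_len(T), function(j) {
    v <- stats::dnorm(seq_len(T), j, sigma)
    v / sqrt(sum(v^2))
  }, numeric(T))
  matrix(stats::rnorm(n * T), n, T) %*% K
}

# One smooth noise trace of length T (sd scaled), for curve perturbation.
smooth_trace <- function(T, sd = 0.05, fwhm = 3) {
  as.numeric(smooth_fields(1, T, fwhm)) * sd
}

# Synthetic cohort for the covert-attention scan: a logistic group attend
# curve, subject attend curves with smooth noise, and observed switch curves
# generated by the q* mixture of the clean curve plus independent noise.
make_q_cohort <- function(q_star, n_subj = 12, noise_sd = 0.05) {
  at_times <- seq(0, 18.5, by = 0.5)
  post_times <- seq(0, 6, by = 0.5)
  A <- function(t) 0.8 / (1 + exp(-(t - 9) / 3))
  K <- 25L
  attend_mat <- t(vapply(seq_len(n_subj), function(s) {
    A(at_times) + smooth_trace(length(at_times), noise_sd)
  }, numeric(length(at_times))))
  attr(attend_mat, "times_s") <- at_times
  clean_switch <- model_switch_curve(at_times, A(at_times), q_star, K,
                                     post_times)
  switch_mat <- t(vapply(seq_len(n_subj), function(s) {
    clean_switch + smooth_trace(length(post_times), noise_sd)
  }, numeric(length(post_times))))
  attr(switch_mat, "times_s") <- post_times
  list(attend = attend_mat, switch = switch_mat, K = K,
       at_times = at_times, post_times = post_times, A = A)
}

# Per-deviant outcome table mirroring the dual-task design: 12 deviants per
# subject x separation x position, percept prevalence rising with position,
# outcomes drawn from a random-intercept logistic model with the given
# coefficients.
simulate_outcome_table <- function(beta = c(intercept = 2, delta_f8 = -1,
                                            position = -0.6,
                                            percept_seg = -1.5),
                                   n_subj = 12, n_rep = 12,
                                   sigma_subj = 0.5) {
  pos_names <- c("early", "middle", "late")
  p_seg <- c(0.05, 0.45, 0.65)
  b <- stats::rnorm(n_subj, 0, sigma_subj)
  grid <- expand.grid(rep = seq_len(n_rep), pos = 0:2, delta_f = c(4, 8),
                      subject = seq_len(n_subj))
  seg <- stats::rbinom(nrow(grid), 1, p_seg[grid$pos + 1])
  eta <- beta[["intercept"]] + b[grid$subject] +
    beta[["delta_f8"]] * (grid$delta_f == 8) +
    beta[["position"]] * grid$pos + beta[["percept_seg"]] * seg
  data.frame(subject = grid$subject, delta_f = grid$delta_f,
             position = pos_names[grid$pos + 1],
             percept = ifelse(seg == 1, "two_streams", "one_stream"),
             hit = stats::rbinom(nrow(grid), 1, stats::plogis(eta)))
}

# Brute-force press-deviant matcher, written independently of
# classify_responses: walk presses in time order and hand each one to the
# earliest still-unmatched deviant whose window contains it; leftover
# presses become false alarms labeled by explicit boundary comparison.
brute_force_classify <- function(trial, presses, config = scoring_config()) {
  presses <- sort(presses)
  presses <- presses[presses >= 0 &
                       presses <= trial$duration_s + config$max_response_lag_s]
  post_only <- identical(trial$task, "switch") && config$switch_post_only
  if (post_only) presses <- presses[presses >= trial$switch_time_s]
  pos_all <- deviant_positions(trial$n_triplets)
  dev_idx <- which(trial$triplets$is_deviant)
  onsets <- trial$triplets$onset_s[dev_idx] + 0.125
  if (post_only) {
    keep <- onsets >= trial$switch_time_s
    dev_idx <- dev_idx[keep]
    onsets <- onsets[keep]
  }
  matched <- rep(NA_integer_, length(dev_idx))
  is_hit <- rep(FALSE, length(presses))
  for (j in seq_along(presses)) {
    for (d in seq_along(dev_idx)) {
      if (!is.na(matched[d])) next
      if (presses[j] >= onsets[d] &&
            presses[j] <= onsets[d] + config$hit_window_s) {
        matched[d] <- j
        is_hit[j] <- TRUE
        break
      }
    }
  }
  sec <- section_boundaries(trial$n_triplets)
  fa_times <- presses[!is_hit]
  fa_section <- vapply(fa_times, function(tt) {
    tt <- min(max(tt, 0), trial$duration_s - 1e-9)
    if (tt < sec$breaks[2]) "early"
    else if (tt < sec$breaks[3]) "middle"
    else "late"
  }, character(1))
  list(hit_deviant_idx = dev_idx[!is.na(matched)],
       miss_deviant_idx = dev_idx[is.na(matched)],
       fa_times = fa_times, fa_section = fa_section)
}

# A random toy trial + press log for the oracle-equivalence property.
random_toy_log <- function() {
  n_triplets <- sample(c(35L, 37L, 39L), 1)
  config <- list(character(), "early", "middle", "late",
                 c("early", "middle"), c("early", "late"),
                 c("middle", "late"), c("early", "middle", "late"))
  trial <- make_trial("toy", n_triplets, sample(c(4, 8), 1),
                      sample(c("attend", "switch"), 1),
                      deviant_config = config[[sample(8, 1)]])
  n_press <- sample(0:5, 1)
  # half the presses land near deviant windows, half anywhere
  near <- numeric(0)
  devs <- which(trial$triplets$is_deviant)
  if (length(devs) && n_press > 0) {
    k <- sample(0:n_press, 1)
    if (k > 0) {
      near <- trial$triplets$onset_s[sample(devs, k, replace = TRUE)] +
        0.125 + stats::runif(k, -0.3, 1.6)
    }
  }
  anywhere <- stats::runif(n_press - length(near), 0, trial$duration_s + 1.4)
  list(trial = trial, presses = sort(pmax(c(near, anywhere), 0)))
}
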