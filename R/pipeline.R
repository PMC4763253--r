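# End-to-end orchestration: design -> simulate -> score -> analyze, with
# reproducible seeds and optional artifact output.

#' Run configuration
#'
#' @param n_subjects Simulated cohort size (default 12).
#' @param design_seed,listener_seed,perm_seed Seeds for the three sources of
#'   randomness: trial designs, the synthetic listeners, and the sign-flip
#'   permutation draw.
#' @param alpha Family-wise / entry significance level.
#' @param q_step Grid step of the covert-attention scan.
#' @param hit_window `"auto"` or seconds.
#' @param spm_method `"rft"` or `"perm"`.
#' @param n_perm Sign flips for the permutation method.
#' @param exclude_early Sensitivity re-run of the ladder on middle/late
#'   deviants.
#' @param listener_params Template `listener_params` for the cohort.
#' @param out_dir Optional directory; when set, artifacts are written as CSV
#'   and JSON.
#' @return A `run_config` list.
#' @export
run_config <- function(n_subjects = 12, design_seed = 1L, listener_seed = 2L,
                       perm_seed = 3L, alpha = 0.05, q_step = 0.001,
                       hit_window = "auto", spm_method = "rft", n_perm = 1000,
                       exclude_early = FALSE,
                       listener_params = streamscore::listener_params(),
                       out_dir = NULL) {
  structure(list(n_subjects = n_subjects, design_seed = design_seed,
                 listener_seed = listener_seed, perm_seed = perm_seed,
                 alpha = alpha, q_step = q_step, hit_window = hit_window,
                 spm_method = spm_method, n_perm = n_perm,
                 exclude_early = exclude_early,
                 listener_params = listener_params, out_dir = out_dir),
            class = "run_config")
}

write_artifact <- function(x, config, name) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(config$out_dir, name)
  if (grepl("\\.csv$", name)) {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE)
  }
  invisible(path)
}

#' Run the full first experiment
#'
#' Builds the objective (96-trial) and subjective (32-trial) stage designs,
#' simulates the cohort, scores deviant detection, derives build-up curves
#' and first-report statistics, and runs the covert-attention q scan with
#' SPM cluster inference on the subject-level model-data difference fields.
#'
#' @param config A [run_config()].
#' @return List with `designs`, `logs`, `scores`, `hit_window_s`, `curves`,
#'   `first_reports`, `noise_accuracy`, and `q_scan` (per frequency
#'   separation).
#' @export
run_experiment1 <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  params <- sample_listener_params(config$n_subjects,
                                   seed = config$listener_seed,
                                   base = config$listener_params)
  design_obj <- make_session("exp1_objective", rng_seed = config$design_seed)
  design_subj <- make_session("exp1_subjective",
                              rng_seed = config$design_seed + 1L)
  logs_obj <- simulate_session(design_obj, params,
                               seed = config$listener_seed + 1L)
  logs_subj <- simulate_session(design_subj, params,
                                seed = config$listener_seed + 2L)
  scores <- score_session(logs_obj, hit_window = config$hit_window)
  hw <- attr(scores, "hit_window_s")
  curves <- buildup_curves(logs_subj)
  firsts <- first_report_stats(logs_subj)
  scans <- list()
  for (df in c(4, 8)) {
    attend_mat <- curve_matrix(curves, df, "attend", "sequence_start")
    switch_mat <- curve_matrix(curves, df, "switch", "switch")
    scans[[paste0("delta_f_", df)]] <- scan_q(
      attend_mat, switch_mat,
      q_grid = seq(0, 1, by = config$q_step), alpha = config$alpha,
      method = config$spm_method, n_perm = config$n_perm,
      seed = config$perm_seed)
  }
  write_artifact(scores, config, "exp1_scores.csv")
  write_artifact(curves, config, "exp1_buildup.csv")
  write_artifact(firsts, config, "exp1_first_reports.csv")
  for (nm in names(scans)) {
    write_artifact(scans[[nm]]$table, config,
                   sprintf("exp1_qscan_%s.csv", nm))
    write_artifact(scans[[nm]]$nonsignificant, config,
                   sprintf("exp1_qscan_%s_intervals.json", nm))
  }
  list(designs = list(objective = design_obj, subjective = design_subj),
       logs = list(objective = logs_obj, subjective = logs_subj),
       scores = scores, hit_window_s = hw, curves = curves,
       first_reports = firsts,
       noise_accuracy = noise_label_accuracy(logs_obj),
       q_scan = scans)
}

#' Run the full second experiment
#'
#' Builds the 48-trial dual-task design, simulates the cohort, scores
#' deviant detection conditioned on the concurrent percept, fits the
#' likelihood-ratio model ladder on the per-deviant outcome table, and
#' computes the criterion contrast and the dual-task sensitivity cost
#' against a supplied first-experiment attend-condition score table.
#'
#' @param config A [run_config()].
#' @param exp1_scores Optional score table from [run_experiment1()] for the
#'   cross-experiment d-prime comparison.
#' @return List with `design`, `logs`, `scores`, `scores_by_percept`,
#'   `outcomes`, `ladder`, `pseudo_r2`, `criterion_contrast`, `curves`, and
#'   (when `exp1_scores` is given) `dual_task_cost`.
#' @export
run_experiment2 <- function(config = run_config(), exp1_scores = NULL) {
  stopifnot(inherits(config, "run_config"))
  params <- sample_listener_params(config$n_subjects,
                                   seed = config$listener_seed,
                                   base = config$listener_params)
  design <- make_session("exp2", rng_seed = config$design_seed + 2L)
  logs <- simulate_session(design, params, seed = config$listener_seed + 3L)
  scores <- score_session(logs, hit_window = config$hit_window)
  hw <- attr(scores, "hit_window_s")
  scores_pc <- score_session(logs, hit_window = hw, by_percept = TRUE)
  outcomes <- deviant_outcomes(logs, scoring_config(hit_window_s = hw))
  ladder <- lr_ladder(outcomes, exclude_early = config$exclude_early,
                      alpha = config$alpha)
  contrast <- criterion_contrast(scores_pc)
  curves <- buildup_curves(logs)
  out <- list(design = design, logs = logs, scores = scores,
              scores_by_percept = scores_pc, outcomes = outcomes,
              ladder = ladder,
              pseudo_r2 = utils::tail(ladder$ladder$pseudo_r2[
                ladder$ladder$accepted & !is.na(ladder$ladder$pseudo_r2)], 1),
              criterion_contrast = contrast, curves = curves,
              hit_window_s = hw)
  if (!is.null(exp1_scores)) {
    e1 <- exp1_scores[exp1_scores$task == "attend", ]
    key <- c("subject", "delta_f", "position")
    merged <- merge(e1[c(key, "dprime")], scores[c(key, "dprime")],
                    by = key, suffixes = c("_exp1", "_exp2"))
    merged$drop <- merged$dprime_exp1 - merged$dprime_exp2
    out$dual_task_cost <- merged
  }
  write_artifact(scores, config, "exp2_scores.csv")
  write_artifact(outcomes, config, "exp2_outcomes.csv")
  write_artifact(ladder$ladder, config, "exp2_ladder.csv")
  write_artifact(contrast, config, "exp2_criterion_contrast.csv")
  out
}
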