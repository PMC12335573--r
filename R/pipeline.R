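#' Simulate the full four-group study on synthetic participants
#'
#' Runs the complete data-generating pipeline: build game batches for the
#' toward, away and unbiased conditions; collect a held-out calibration
#' cohort on toward-biased batches, filter it with its own attention-check
#' statistics and fit the realignment map on it; reuse the toward batches
#' (identical shown fractions) for the realigned condition with
#' multicalibrated displayed confidence; simulate the four deployed cohorts;
#' and apply the pooled attention-check exclusion rule across them.
#'
#' @param n_per_group Participants per deployed group.
#' @param n_calibration Participants in the held-out calibration cohort.
#' @param seed Optional integer; seeds the session RNG for a fully
#'   reproducible run.
#' @param cfg A [design_config()].
#' @param behavior A [behavior_params()].
#' @param realignment A [realignment_config()].
#' @return A list of class `study_sim`:
#'   `records` — deployed-group records with a logical `kept` column from the
#'   pooled exclusion rule; `calibration` — calibration-cohort records with
#'   `kept`; `map` — the fitted `realignment_map`; `filter`,
#'   `calibration_filter` — the [filter_participants()] outputs;
#'   `batches` — all batch tables; `config` — the inputs.
#' @export
simulate_study <- function(n_per_group = 100,
                           n_calibration = 302,
                           seed = NULL,
                           cfg = design_config(),
                           behavior = behavior_params(),
                           realignment = realignment_config()) {
  if (!is.null(seed)) set.seed(seed)

  batches <- list(
    toward = build_batches(cfg, "toward"),
    away = build_batches(cfg, "away"),
    unbiased = build_batches(cfg, "unbiased"),
    calibration = build_batches(cfg, "calibration")
  )
  batches$realigned <- realign_batches(batches$toward)

  calib <- simulate_cohort(batches$calibration, n_calibration,
    params = behavior, cfg = cfg
  )
  calib_filter <- filter_participants(calib)
  calib$kept <- calib$participant_id %in% calib_filter$kept
  map <- fit_realignment(dplyr::filter(calib, .data$kept), realignment)

  cohorts <- list(
    toward = simulate_cohort(batches$toward, n_per_group,
      params = behavior, cfg = cfg
    ),
    away = simulate_cohort(batches$away, n_per_group,
      params = behavior, cfg = cfg
    ),
    unbiased = simulate_cohort(batches$unbiased, n_per_group,
      params = behavior, cfg = cfg
    ),
    realigned = simulate_cohort(batches$realigned, n_per_group,
      params = behavior, cfg = cfg, map = map
    )
  )
  records <- dplyr::bind_rows(cohorts)
  pooled_filter <- filter_participants(records)
  records$kept <- records$participant_id %in% pooled_filter$kept

  structure(
    list(
      records = records,
      calibration = calib,
      map = map,
      filter = pooled_filter,
      calibration_filter = calib_filter,
      batches = batches,
      config = list(
        n_per_group = n_per_group, n_calibration = n_calibration,
        seed = seed, design = cfg, behavior = behavior,
        realignment = realignment
      )
    ),
    class = "study_sim"
  )
}

#' @export
print.study_sim <- function(x, ...) {
  cat("Simulated alignment study\n")
  cat(
    "  deployed participants:",
    length(unique(x$records$participant_id)),
    "| excluded:", length(x$filter$excluded), "\n"
  )
  cat(
    "  calibration participants:",
    length(unique(x$calibration$participant_id)),
    "| excluded:", length(x$calibration_filter$excluded), "\n"
  )
  invisible(x)
}

#' Per-group alignment errors
#'
#' Computes the expected and maximum alignment error for each group in a
#' record set (the analogue of the study's per-group alignment table).
#'
#' @param records Response records; pass filtered records (e.g.
#'   `dplyr::filter(sim$records, kept)`) to mirror the study analysis.
#' @param min_count Minimum records per (a, h) cell.
#' @return A tibble with one row per group: `group`, `mae`, `eae`,
#'   `n_pairs`, `n_cells`.
#' @export
analyze_alignment <- function(records, min_count = 1) {
  records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ alignment_summary(.x, min_count = min_count)) |>
    dplyr::ungroup()
}

#' Run the study's Bayesian A/B tests
#'
#' Mirrors the two-model analysis: one binomial mixed-effects fit for the
#' toward / away / unbiased groups and one for toward / realigned, followed
#' by the six one-sided hypotheses — theta_0 and theta_1 greater in away and
#' in unbiased than in toward, and greater in realigned than in toward.
#'
#' @param records Filtered, scored response records covering the four
#'   deployed groups.
#' @param seed Integer seed for the MCMC.
#' @param ... Passed to [fit_ab_model()] (chains, iterations, ...).
#' @return A list of class `ab_tests`: `fit_bias` (toward/away/unbiased),
#'   `fit_realign` (toward/realigned), and `hypotheses` (tibble of the six
#'   tests with estimate, error, posterior probability, evidence ratio).
#' @export
run_ab_tests <- function(records, seed = 1, ...) {
  counts <- aggregate_counts(records)
  fit_bias <- fit_ab_model(
    dplyr::filter(counts, .data$group %in% c("toward", "away", "unbiased")),
    seed = seed, ...
  )
  fit_realign <- fit_ab_model(
    dplyr::filter(counts, .data$group %in% c("toward", "realigned")),
    seed = seed + 1L, ...
  )
  hyps <- dplyr::bind_rows(
    hypothesis_evidence(fit_bias, "away", "toward", 0),
    hypothesis_evidence(fit_bias, "unbiased", "toward", 0),
    hypothesis_evidence(fit_bias, "away", "toward", 1),
    hypothesis_evidence(fit_bias, "unbiased", "toward", 1),
    hypothesis_evidence(fit_realign, "realigned", "toward", 0),
    hypothesis_evidence(fit_realign, "realigned", "toward", 1)
  )
  structure(
    list(fit_bias = fit_bias, fit_realign = fit_realign, hypotheses = hyps),
    class = "ab_tests"
  )
}

#' @export
print.ab_tests <- function(x, ...) {
  cat("Bayesian A/B tests on conditional matching rates\n")
  h <- x$hypotheses
  for (i in seq_len(nrow(h))) {
    cat(sprintf(
      "  %-38s est %+.3f +- %.3f  ER %s (p = %.3f)\n",
      h$hypothesis[i], h$estimate[i], h$est_error[i],
      h$evidence_label[i], h$post_prob[i]
    ))
  }
  invisible(x)
}

#' Accuracy of the initial guess and of the shown-cards optimum, per group
#'
#' The initial-guess accuracy is the fraction of scored games whose initial
#' guess matched the picked card. The observer optimum is the expected
#' accuracy of the Bayes-optimal guess given the cards shown (the design-
#' aware ideal observer of [bayes_observer_guess()]), i.e. the accuracy
#' ceiling participants could reach from the shown cards alone.
#'
#' @param records Filtered response records.
#' @param cfg The [design_config()] of the study.
#' @return A tibble per group: `accuracy_initial` (empirical) and
#'   `accuracy_optimal` (expected accuracy of the ideal observer, averaged
#'   over the games played), both as percentages.
#' @export
accuracy_by_group <- function(records, cfg = design_config()) {
  recs <- scored_records(records)
  recs |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      obs <- bayes_observer_guess(
        df$z_count, df$a,
        ifelse(key$group[1] == "realigned", "toward", key$group[1]),
        cfg
      )
      acc_opt <- mean(ifelse(obs$guess == "red", obs$p_red, 1 - obs$p_red))
      tibble::tibble(
        accuracy_initial = 100 * mean(
          (df$initial_guess == "red") == (df$outcome_is_red == 1)
        ),
        accuracy_optimal = 100 * acc_opt,
        n_games = nrow(df)
      )
    }) |>
    dplyr::ungroup()
}
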