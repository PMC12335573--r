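#' Behavioral parameters of synthetic participants
#'
#' The synthetic behavior model reproduces the two statistical regularities
#' the analysis relies on: initial confidence is approximately normally
#' distributed around the shown red percentage, and the final guess is, on
#' average, monotone in both the participant's own confidence and the
#' displayed AI confidence. The specific functional form (a logistic
#' combination of centered confidences with a lapse rate) is a modeling
#' choice; all parameters are exposed so alternative behavior models can be
#' swapped in.
#'
#' @param sigma_initial SD of the initial confidence around `100 * z`, on the
#'   0-100 scale.
#' @param w_h Weight on the participant's own confidence in the final
#'   decision, logit units per confidence point.
#' @param w_a Weight on the displayed AI confidence, logit units per point.
#' @param lapse Probability of a uniformly random final guess.
#' @param inattentive_rate Fraction of participants who answer attention
#'   checks with uniformly random confidence.
#' @param per_batch Participants assigned per game batch (round-robin).
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(sigma_initial = 12,
                            w_h = 0.08,
                            w_a = 0.08,
                            lapse = 0.02,
                            inattentive_rate = 0.05,
                            per_batch = 5) {
  stopifnot(
    sigma_initial > 0, w_h >= 0, w_a >= 0,
    lapse >= 0, lapse < 1, inattentive_rate >= 0, inattentive_rate < 1
  )
  structure(
    list(
      sigma_initial = sigma_initial, w_h = w_h, w_a = w_a, lapse = lapse,
      inattentive_rate = inattentive_rate, per_batch = per_batch
    ),
    class = "behavior_params"
  )
}

#' Draw initial confidence around the shown red percentage
#'
#' Initial confidence is normal around `100 * z` with SD `sigma_initial`,
#' clipped to `[0, 100]` and rounded to an integer (half up).
#'
#' @param z Shown red fraction(s) in `[0, 1]`.
#' @param params A [behavior_params()].
#' @return Integer vector of confidences in 0..100, same length as `z`.
#' @export
draw_initial_confidence <- function(z, params = behavior_params()) {
  stopifnot(all(z >= 0 & z <= 1))
  x <- stats::rnorm(length(z), 100 * z, params$sigma_initial)
  as.integer(floor(pmin(100, pmax(0, x)) + 0.5))
}

#' Initial guess implied by a stated confidence
#'
#' Red above 50, black below 50; a fair coin at exactly 50 (the tie rule for
#' discretizing recorded confidences is applied downstream, at binning time).
#'
#' @param conf Integer confidence(s) in 0..100.
#' @return Character vector, `"red"` or `"black"`.
#' @export
initial_guess_from_confidence <- function(conf) {
  stopifnot(all(conf >= 0 & conf <= 100))
  n <- length(conf)
  out <- ifelse(conf > 50, "red", "black")
  tie <- conf == 50
  if (any(tie)) {
    out[tie] <- ifelse(stats::runif(sum(tie)) < 0.5, "red", "black")
  }
  out
}

#' Final decision after seeing the AI confidence
#'
#' With probability `lapse` the final guess is a uniform coin; otherwise it is
#' red with probability `plogis(w_h * (conf - 50) + w_a * (a_shown - 50))`.
#' The decision probability is nondecreasing in both confidences, matching
#' the average monotone behavior observed in assisted decision studies.
#'
#' @param conf Participant's own confidence(s), 0..100.
#' @param a_shown Displayed AI confidence(s), 0..100.
#' @param params A [behavior_params()].
#' @return Character vector of final guesses, `"red"` or `"black"`.
#' @export
final_decision <- function(conf, a_shown, params = behavior_params()) {
  p <- final_decision_prob(conf, a_shown, params)
  ifelse(stats::runif(length(p)) < p, "red", "black")
}

#' @rdname final_decision
#' @return `final_decision_prob()` returns the probability the final guess is
#'   red, without sampling.
#' @export
final_decision_prob <- function(conf, a_shown, params = behavior_params()) {
  stopifnot(all(conf >= 0 & conf <= 100), all(a_shown >= 0 & a_shown <= 100))
  base <- stats::plogis(
    params$w_h * (conf - 50) + params$w_a * (a_shown - 50)
  )
  (1 - params$lapse) * base + params$lapse / 2
}

#' Bayes-optimal guess from the shown cards
#'
#' The ideal observer knows the design: given the AI confidence `a` the true
#' red fraction is one of `a - var_a` or `a + var_a` with equal prior
#' probability, and the shown red count is Wallenius-distributed with the
#' group's odds ratio (which depends on which `r` is true). The posterior over
#' the two hypotheses then yields `P(red) = sum_r post(r) * r`, and the guess
#' is red iff that exceeds 1/2 (ties broken toward the side of `a`).
#'
#' @param z_count Shown red-card count(s).
#' @param a AI confidence value(s) on the design grid.
#' @param group Study group (determines the odds ratio per hypothesis).
#' @param cfg A [design_config()].
#' @return A tibble with columns `p_red` (posterior probability the picked
#'   card is red) and `guess`.
#' @export
bayes_observer_guess <- function(z_count, a, group, cfg = design_config()) {
  stopifnot(length(a) == length(z_count) || length(a) == 1)
  if (length(a) == 1) a <- rep(a, length(z_count))
  p_red <- numeric(length(z_count))
  for (i in seq_along(z_count)) {
    r_cand <- c(a[i] - cfg$var_a, a[i] + cfg$var_a)
    lik <- vapply(r_cand, function(r) {
      n_red <- as.integer(round(cfg$pile_size * r))
      pmf <- wallenius_pmf_cached(
        cfg$n_shown, n_red, cfg$pile_size - n_red,
        odds_ratio(group, r, a[i])
      )
      k <- z_count[i]
      if (k < 0 || k > length(pmf) - 1) 0 else pmf[[k + 1]]
    }, numeric(1))
    if (sum(lik) == 0) {
      stop("shown count ", z_count[i], " impossible under both red fractions",
        call. = FALSE
      )
    }
    post <- lik / sum(lik)
    p_red[i] <- sum(post * r_cand)
  }
  guess <- ifelse(
    p_red > 0.5, "red",
    ifelse(p_red < 0.5, "black", ifelse(a > 0.5, "red", "black"))
  )
  tibble::tibble(p_red = p_red, guess = guess)
}

# memoized pmf lookups: the design reuses a handful of (n_red, omega) combos
the_pmf_cache <- new.env(parent = emptyenv())
wallenius_pmf_cached <- function(n_draws, n_red, n_black, omega) {
  key <- paste(n_draws, n_red, n_black, omega, sep = "|")
  got <- the_pmf_cache[[key]]
  if (is.null(got)) {
    got <- wallenius_pmf(n_draws, n_red, n_black, omega)
    the_pmf_cache[[key]] <- got
  }
  got
}

#' Simulate a cohort of participants playing their batches
#'
#' Participants are assigned round-robin to the group's batches (so each batch
#' is played by roughly `per_batch` participants when
#' `n_participants = per_batch * n_batches`). Each participant plays the 24
#' scored rounds of their batch in a random order plus the three attention
#' checks at their fixed positions. Initial confidence tracks the shown red
#' percentage; the final guess combines own and displayed AI confidence. A
#' fraction `inattentive_rate` of participants answers attention checks with
#' uniform confidence, which is what the exclusion rule is designed to catch.
#'
#' For the `realigned` group, the displayed AI confidence is the
#' multicalibrated value from `map`, computed from the participant's own
#' confidence bin, then display-rounded.
#'
#' @param batches Batches from [build_batches()] (or [realign_batches()]).
#' @param n_participants Cohort size.
#' @param params A [behavior_params()].
#' @param cfg The [design_config()] used to build the batches.
#' @param map A `realignment_map` (required iff the batches are for the
#'   `realigned` group).
#' @param id_prefix Prefix for participant identifiers.
#' @return A tibble of response records, one row per participant x round:
#'   `participant_id`, `group`, `batch_id`, `round_index`, `display_order`,
#'   `a_num`, `a_den`, `a_shown`, `r_num`, `r_den`, `z_count`,
#'   `initial_confidence`, `initial_guess`, `final_guess`, `outcome_is_red`,
#'   `is_attention_check`, plus numeric `a`, `r`, `z`.
#' @export
simulate_cohort <- function(batches, n_participants,
                            params = behavior_params(),
                            cfg = design_config(),
                            map = NULL,
                            id_prefix = NULL) {
  group <- unique(batches$group)
  if (length(group) != 1) {
    stop("`batches` must belong to a single group", call. = FALSE)
  }
  if (group == "realigned" && is.null(map)) {
    stop("the realigned group needs a fitted `realignment_map`",
      call. = FALSE
    )
  }
  if (is.null(id_prefix)) id_prefix <- group
  n_batches <- length(unique(batches$batch_id))
  assign <- tibble::tibble(
    participant_id = sprintf("%s_%03d", id_prefix, seq_len(n_participants)),
    batch_id = (seq_len(n_participants) - 1L) %% n_batches + 1L,
    inattentive = stats::runif(n_participants) < params$inattentive_rate
  )
  rec <- dplyr::inner_join(assign, batches, by = "batch_id",
    relationship = "many-to-many"
  )
  # random play order for the scored rounds, checks keep their fixed slots
  rec <- rec |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(display_order = ifelse(.data$is_attention_check,
      .data$round_index,
      sample(sum(!.data$is_attention_check))
    )) |>
    dplyr::ungroup()

  n <- nrow(rec)
  conf <- draw_initial_confidence(rec$z, params)
  random_check <- rec$is_attention_check & rec$inattentive
  if (any(random_check)) {
    conf[random_check] <- as.integer(floor(stats::runif(sum(random_check),
      0, 100.99999
    )))
  }
  initial_guess <- initial_guess_from_confidence(conf)
  if (group == "realigned") {
    scored <- !rec$is_attention_check
    a_shown <- integer(n)
    a_shown[!scored] <- display_confidence(rec$a[!scored])
    h <- discretize_confidence(conf[scored], initial_guess[scored])
    a_shown[scored] <- display_confidence(
      apply_realignment(map, h, rec$a[scored])
    )
  } else {
    a_shown <- display_confidence(rec$a)
  }
  final_guess <- final_decision(conf, a_shown, params)
  outcome <- pick_card(n, rec$r)

  rec |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      group = .data$group,
      batch_id = .data$batch_id,
      round_index = .data$round_index,
      display_order = .data$display_order,
      a_num = .data$a_num, a_den = .data$a_den,
      a_shown = a_shown,
      r_num = .data$r_num, r_den = .data$r_den,
      z_count = .data$z_count,
      initial_confidence = conf,
      initial_guess = initial_guess,
      final_guess = final_guess,
      outcome_is_red = as.integer(outcome),
      is_attention_check = .data$is_attention_check,
      a = .data$a, r = .data$r, z = .data$z
    ) |>
    dplyr::arrange(.data$participant_id, .data$round_index)
}

# scored (non-attention) records only
scored_records <- function(records) {
  dplyr::filter(records, !.data$is_attention_check)
}
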