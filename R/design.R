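#' Configuration of the card-game design
#'
#' Collects the design constants of the AI-assisted card game: a pile of
#' `pile_size` cards of which `n_shown` are revealed, AI confidence levels on
#' the grid `k / confidence_denominator`, and for each level two pile types
#' with true red fraction `a - var_a` and `a + var_a`. `var_a` must keep
#' `pile_size * r` integral for every level so that the AI confidence is
#' calibrated by construction.
#'
#' @param pile_size Cards per game pile.
#' @param n_shown Cards revealed to the participant each round.
#' @param confidence_denominator AI confidence grid denominator; levels are
#'   `1/confidence_denominator, ..., (confidence_denominator-1)/confidence_denominator`.
#' @param var_a Offset between the AI confidence and the true red fraction;
#'   `pile_size * var_a` must be a positive integer.
#' @param n_rounds Scored games per participant.
#' @param n_batches Game batches per group.
#' @param n_calibration_batches Batches used to collect held-out calibration
#'   data for realignment.
#' @param attention_fractions Red fractions of the three attention-check
#'   rounds (shown without bias and excluded from all statistics).
#' @param bonus_per_point Bonus compensation, in GBP, per point earned.
#' @return A list of class `design_config`.
#' @examples
#' cfg <- design_config()
#' pile_types(cfg)
#' @export
design_config <- function(pile_size = 65,
                          n_shown = 21,
                          confidence_denominator = 13,
                          var_a = 2 / 65,
                          n_rounds = 24,
                          n_batches = 20,
                          n_calibration_batches = 60,
                          attention_fractions = c(0, 0.75, 1),
                          bonus_per_point = 0.12) {
  var_num <- pile_size * var_a
  if (abs(var_num - round(var_num)) > 1e-9 || round(var_num) < 1) {
    stop("`pile_size * var_a` must be a positive integer", call. = FALSE)
  }
  if (n_shown >= pile_size) {
    stop("`n_shown` must be smaller than `pile_size`", call. = FALSE)
  }
  cfg <- list(
    pile_size = as.integer(pile_size),
    n_shown = as.integer(n_shown),
    confidence_denominator = as.integer(confidence_denominator),
    var_a = var_a,
    var_num = as.integer(round(var_num)),
    n_rounds = as.integer(n_rounds),
    n_batches = as.integer(n_batches),
    n_calibration_batches = as.integer(n_calibration_batches),
    attention_fractions = attention_fractions,
    bonus_per_point = bonus_per_point
  )
  class(cfg) <- "design_config"
  # validate the induced pile types eagerly so bad configs fail at creation
  pt <- pile_types(cfg)
  if (any(pt$r <= 0 | pt$r >= 1 | abs(pt$r - 0.5) < 1e-12)) {
    stop("`var_a` produces a pile with r <= 0, r >= 1 or r = 0.5",
      call. = FALSE
    )
  }
  cfg
}

#' Enumerate the pile types of a design
#'
#' One pile type per (AI confidence level, sign of the offset) pair: with the
#' default 13-denominator grid and `var_a = 2/65` this yields the 24 pile
#' types, two per level, whose true red fractions average exactly to the
#' level — the calibration-by-design identity `P(red | A = a) = a`.
#'
#' @param cfg A [design_config()].
#' @return A tibble with one row per pile type, ordered by `a` then `r`:
#'   integer numerators `a_num` (over `a_den`), `r_num` (over `r_den`), and
#'   the numeric values `a` and `r`.
#' @export
pile_types <- function(cfg = design_config()) {
  den <- cfg$confidence_denominator
  step <- cfg$pile_size / den # cards per confidence step, integer by design
  if (abs(step - round(step)) > 1e-9) {
    stop("`pile_size` must be a multiple of `confidence_denominator`",
      call. = FALSE
    )
  }
  step <- as.integer(round(step))
  tidyr::crossing(
    a_num = seq_len(den - 1L),
    offset = c(-cfg$var_num, cfg$var_num)
  ) |>
    dplyr::mutate(
      a_den = den,
      r_num = .data$a_num * step + .data$offset,
      r_den = cfg$pile_size,
      a = .data$a_num / .data$a_den,
      r = .data$r_num / .data$r_den
    ) |>
    dplyr::arrange(.data$a, .data$r) |>
    dplyr::select(
      "a_num", "a_den", "r_num", "r_den", "a", "r"
    )
}

#' Group-specific odds ratio for the biased card display
#'
#' The shown cards are drawn with a Wallenius odds ratio that steers the shown
#' red fraction relative to the AI confidence: the `toward` group pulls it
#' toward the AI confidence (odds 1/4 when `r > a`, 4 when `r < a`), the
#' `away` group pushes it away (4 when `r > a`, 1/4 when `r < a`), and the
#' `unbiased` (and `calibration`) condition uses odds 1. The `realigned`
#' condition reuses the `toward` draws, so it returns the `toward` value.
#'
#' @param group One of `"toward"`, `"away"`, `"unbiased"`, `"realigned"`,
#'   `"calibration"`.
#' @param r True red fraction(s); must differ from `a`.
#' @param a AI confidence value(s).
#' @return Numeric vector of odds ratios (1/4, 1 or 4).
#' @export
odds_ratio <- function(group, r, a) {
  group <- match.arg(group, study_groups())
  if (any(abs(r - a) < 1e-12)) {
    stop("odds ratio undefined when r = a", call. = FALSE)
  }
  switch(group,
    toward = ,
    realigned = ifelse(r > a, 1 / 4, 4),
    away = ifelse(r > a, 4, 1 / 4),
    unbiased = ,
    calibration = rep.int(1, length(r))
  )
}

study_groups <- function() {
  c("toward", "away", "unbiased", "realigned", "calibration")
}

#' Sample the fraction of red cards shown for one pile
#'
#' Draws the shown red-card count from the Wallenius distribution with the
#' group's odds ratio and returns it as a fraction of the shown cards.
#'
#' @param r,a True red fraction and AI confidence of the pile (numeric).
#' @param group Study group, see [odds_ratio()].
#' @param cfg A [design_config()].
#' @return The shown red fraction `z = count / n_shown`.
#' @export
sample_shown_fraction <- function(r, a, group, cfg = design_config()) {
  n_red <- as.integer(round(cfg$pile_size * r))
  k <- wallenius_sample(
    1, cfg$n_shown, n_red, cfg$pile_size - n_red,
    odds_ratio(group, r, a)
  )
  k / cfg$n_shown
}

#' Pick the outcome card from a pile
#'
#' The game picks one card uniformly at random from the full pile, so the
#' outcome is red with probability exactly `r` — this is what makes the AI
#' confidence calibrated by design.
#'
#' @param n Number of picks.
#' @param r True red fraction(s), length 1 or `n`.
#' @return Integer vector of 0/1 outcomes (1 = red).
#' @export
pick_card <- function(n, r) {
  stats::rbinom(n, 1L, r)
}

#' Displayed AI confidence
#'
#' Participants see the AI confidence rescaled to 0-100 and rounded to the
#' nearest integer (half rounds up).
#'
#' @param a AI confidence in `[0, 1]` (vectorized).
#' @return Integer vector in 0..100.
#' @examples
#' display_confidence(1 / 13) # 8
#' display_confidence(12 / 13) # 92
#' @export
display_confidence <- function(a) {
  stopifnot(all(a >= 0 & a <= 1))
  as.integer(floor(100 * a + 0.5))
}

#' Build game batches for a study group
#'
#' Each batch holds one game instance per pile type, with the shown red-card
#' count sampled under the group's bias, plus the three unbiased
#' attention-check rounds appended at fixed positions (round_index 25-27)
#' identical across batches and groups. Batches for the `realigned` group are
#' not sampled afresh: use [realign_batches()] on the `toward` batches so both
#' groups see identical shown fractions.
#'
#' Randomness comes from the session RNG; seed with [set.seed()].
#'
#' @param cfg A [design_config()].
#' @param group `"toward"`, `"away"`, `"unbiased"` or `"calibration"`
#'   (calibration batches use the `toward` bias, matching the held-out
#'   calibration data collection).
#' @param n_batches Number of batches; defaults to `cfg$n_batches`.
#' @return A tibble with one row per batch x round: `group`, `batch_id`,
#'   `round_index`, the pile columns of [pile_types()], `z_count` (red cards
#'   among the shown), `z`, and `is_attention_check`.
#' @export
build_batches <- function(cfg = design_config(), group = "unbiased",
                          n_batches = NULL) {
  group <- match.arg(group, c("toward", "away", "unbiased", "calibration"))
  if (is.null(n_batches)) {
    n_batches <- if (group == "calibration") {
      cfg$n_calibration_batches
    } else {
      cfg$n_batches
    }
  }
  piles <- pile_types(cfg)
  omega_group <- if (group == "calibration") "toward" else group
  scored <- tidyr::crossing(batch_id = seq_len(n_batches), piles) |>
    dplyr::group_by(.data$batch_id) |>
    dplyr::mutate(round_index = dplyr::row_number()) |>
    dplyr::ungroup()
  omega <- odds_ratio(omega_group, scored$r, scored$a)
  n_red <- as.integer(round(scored$r * cfg$pile_size))
  z_count <- integer(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    z_count[i] <- wallenius_sample(
      1, cfg$n_shown, n_red[i], cfg$pile_size - n_red[i], omega[i]
    )
  }
  scored$z_count <- z_count
  scored$is_attention_check <- FALSE
  att <- attention_check_rounds(cfg)
  out <- tidyr::crossing(batch_id = seq_len(n_batches), att) |>
    dplyr::bind_rows(scored) |>
    dplyr::arrange(.data$batch_id, .data$round_index) |>
    dplyr::mutate(
      group = group,
      z = .data$z_count / cfg$n_shown,
      .before = 1
    ) |>
    dplyr::relocate("group", "batch_id", "round_index")
  out
}

# The three attention checks: trivially answerable rounds with red fractions
# 0, 3/4, 1 shown with no bias and a fixed card configuration shared by all
# batches and groups. Their AI confidence equals the red fraction.
attention_check_rounds <- function(cfg) {
  fr <- cfg$attention_fractions
  frac <- function(x) {
    if (abs(x - round(x)) < 1e-9) c(as.integer(round(x)), 1L) else c(3L, 4L)
  }
  nums <- t(vapply(fr, frac, integer(2)))
  tibble::tibble(
    round_index = cfg$n_rounds + seq_along(fr),
    a_num = nums[, 1], a_den = nums[, 2],
    r_num = nums[, 1], r_den = nums[, 2],
    a = fr, r = fr,
    z_count = as.integer(round(cfg$n_shown * fr)),
    is_attention_check = TRUE
  )
}

#' Derive realigned-group batches from toward-group batches
#'
#' The realigned condition shows the same pile types with the same shown
#' fractions as the toward condition; only the displayed AI confidence is
#' post-processed at play time. This relabels a set of toward batches.
#'
#' @param toward_batches Output of [build_batches()] with `group = "toward"`.
#' @return The same tibble with `group = "realigned"`.
#' @export
realign_batches <- function(toward_batches) {
  if (!all(toward_batches$group == "toward")) {
    stop("`toward_batches` must come from the toward group", call. = FALSE)
  }
  dplyr::mutate(toward_batches, group = "realigned")
}

#' Check the calibration-by-design identity
#'
#' For each AI confidence level, averages the true red fraction over its pile
#' types. In the standard design the two piles sit at `a - var_a` and
#' `a + var_a`, so the mean equals `a` exactly (verified in integer
#' arithmetic).
#'
#' @param piles A tibble of pile types, as from [pile_types()].
#' @return A tibble with `a_num`, `a_den`, `a`, `mean_r`, `exact`
#'   (logical: does `mean_r` equal `a` in exact rational arithmetic).
#' @export
design_calibration_check <- function(piles) {
  counts <- dplyr::count(piles, .data$a_num)
  if (any(counts$n != 2)) {
    stop("incomplete design: every confidence level needs its two pile types",
      call. = FALSE
    )
  }
  piles |>
    dplyr::group_by(.data$a_num, .data$a_den) |>
    dplyr::summarise(
      a = .data$a_num[1] / .data$a_den[1],
      # exact: compare 2 * a_num * r_den == a_den * sum(r_num) in integers
      exact = (2 * .data$a_num[1] * .data$r_den[1]) ==
        (.data$a_den[1] * sum(.data$r_num)),
      mean_r = sum(.data$r_num) / (2 * .data$r_den[1]),
      .groups = "drop"
    ) |>
    dplyr::select("a_num", "a_den", "a", "mean_r", "exact")
}
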