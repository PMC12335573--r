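#' Discretize human confidence into four ordered bins
#'
#' The 0-100 confidence range is split into four equal regions: very_low
#' `[0, 25]`, low `[26, 49]`, high `[51, 75]`, very_high `[76, 100]`. A
#' confidence of exactly 50 is assigned to `high` when the initial guess is
#' red and `low` when it is black.
#'
#' @param conf Integer confidence(s) in 0..100.
#' @param guess Initial guess(es), `"red"` or `"black"`; used only at
#'   `conf == 50`.
#' @return An ordered factor with levels
#'   `very_low < low < high < very_high`.
#' @export
discretize_confidence <- function(conf, guess) {
  if (any(conf < 0 | conf > 100)) {
    stop("confidence must lie in [0, 100]", call. = FALSE)
  }
  out <- dplyr::case_when(
    conf <= 25 ~ "very_low",
    conf <= 49 ~ "low",
    conf == 50 & guess == "red" ~ "high",
    conf == 50 ~ "low",
    conf <= 75 ~ "high",
    TRUE ~ "very_high"
  )
  factor(out, levels = h_bin_levels(), ordered = TRUE)
}

h_bin_levels <- function() c("very_low", "low", "high", "very_high")

#' Empirical outcome table on the (AI confidence, human confidence) lattice
#'
#' Estimates `P(Y = red | A = a, H = h)` cellwise: records are grouped by the
#' displayed AI confidence level and the human-confidence bin, and the red
#' outcome rate is computed per cell. Cells with fewer than `min_count`
#' records are dropped. Attention-check rows are excluded.
#'
#' @param records A response-record tibble (see [simulate_cohort()]).
#' @param min_count Minimum records for a cell to be included.
#' @return A tibble `a_level` (displayed confidence, integer), `h_bin`
#'   (ordered factor), `estimate`, `count`, sorted by `a_level`, `h_bin`.
#' @export
outcome_table <- function(records, min_count = 1) {
  records <- scored_records(records)
  if (nrow(records) == 0) {
    stop("no scored records to tabulate", call. = FALSE)
  }
  records |>
    dplyr::mutate(h_bin = discretize_confidence(
      .data$initial_confidence, .data$initial_guess
    )) |>
    dplyr::group_by(a_level = .data$a_shown, h_bin = .data$h_bin) |>
    dplyr::summarise(
      estimate = mean(.data$outcome_is_red),
      count = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$count >= min_count) |>
    dplyr::arrange(.data$a_level, .data$h_bin)
}

# all ordered comparable cell pairs (a <= a', h <= h', identical included)
# and the signed violation estimate(low) - estimate(high) for each
comparable_pairs <- function(table) {
  idx <- tidyr::crossing(i = seq_len(nrow(table)), j = seq_len(nrow(table)))
  keep <- table$a_level[idx$i] <= table$a_level[idx$j] &
    table$h_bin[idx$i] <= table$h_bin[idx$j]
  idx <- idx[keep, ]
  tibble::tibble(
    i = idx$i, j = idx$j,
    violation = table$estimate[idx$i] - table$estimate[idx$j]
  )
}

#' Maximum alignment error
#'
#' The largest monotonicity violation of `P(Y = red | A, H)` over comparable
#' cell pairs: `max over (a <= a', h <= h')` of
#' `P(Y | a, h) - P(Y | a', h')`, floored at zero (the identical pair always
#' attains 0). A perfectly aligned AI/human confidence pair gives 0.
#'
#' @param table An [outcome_table()].
#' @return A single number in `[0, 1]`.
#' @export
max_alignment_error <- function(table) {
  if (nrow(table) == 0) stop("alignment table is empty", call. = FALSE)
  max(0, comparable_pairs(table)$violation)
}

#' Expected alignment error
#'
#' The mean positive-part violation over all comparable ordered cell pairs
#' (identical pairs included, contributing zero): with `N` the number of
#' comparable pairs among included cells,
#' `EAE = (1/N) * sum over (a <= a', h <= h') of
#' max(0, P(Y | a, h) - P(Y | a', h'))`.
#'
#' @param table An [outcome_table()].
#' @return A list with `eae` and `n_pairs` (the `N` used).
#' @export
expected_alignment_error <- function(table) {
  if (nrow(table) == 0) stop("alignment table is empty", call. = FALSE)
  pairs <- comparable_pairs(table)
  list(
    eae = sum(pmax(0, pairs$violation)) / nrow(pairs),
    n_pairs = nrow(pairs)
  )
}

#' Alignment summary of a set of records
#'
#' Convenience wrapper: builds the outcome table and returns both alignment
#' errors together with the lattice size used.
#'
#' @inheritParams outcome_table
#' @return A one-row tibble: `mae`, `eae`, `n_pairs`, `n_cells`.
#' @export
alignment_summary <- function(records, min_count = 1) {
  tab <- outcome_table(records, min_count = min_count)
  e <- expected_alignment_error(tab)
  tibble::tibble(
    mae = max_alignment_error(tab),
    eae = e$eae,
    n_pairs = e$n_pairs,
    n_cells = nrow(tab)
  )
}

#' Expected calibration error of the displayed AI confidence
#'
#' Weighted mean absolute gap between the displayed confidence level and the
#' empirical red-outcome rate at that level:
#' `sum_a (n_a / n) * |mean(Y | a_shown = a) - a / 100|`.
#'
#' @param records A response-record tibble; attention checks are excluded.
#' @return A single number in `[0, 1]`.
#' @export
calibration_error <- function(records) {
  records <- scored_records(records)
  if (nrow(records) == 0) stop("no scored records", call. = FALSE)
  records |>
    dplyr::group_by(.data$a_shown) |>
    dplyr::summarise(
      gap = abs(mean(.data$outcome_is_red) - .data$a_shown[1] / 100),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::summarise(ece = sum(.data$gap * .data$n) / sum(.data$n)) |>
    dplyr::pull(.data$ece)
}

#' Decision-probability heatmap table
#'
#' Fraction of red guesses stratified by human-confidence bin and displayed
#' AI confidence, for the initial and the final guess. Cells with `min_count`
#' or fewer records are omitted (strictly: a cell with exactly `min_count`
#' records is dropped, mirroring the "10 or less data points" display rule).
#'
#' @param records A response-record tibble; attention checks are excluded.
#' @param min_count Cells with `count <= min_count` are dropped.
#' @return A tibble `stage` (`"initial"`/`"final"`), `h_bin`, `a_level`,
#'   `p_red`, `count`.
#' @export
decision_heatmap <- function(records, min_count = 10) {
  records <- scored_records(records)
  if (nrow(records) == 0) stop("no scored records", call. = FALSE)
  long <- records |>
    dplyr::mutate(h_bin = discretize_confidence(
      .data$initial_confidence, .data$initial_guess
    )) |>
    tidyr::pivot_longer(
      c("initial_guess", "final_guess"),
      names_to = "stage", values_to = "guess"
    ) |>
    dplyr::mutate(stage = sub("_guess$", "", .data$stage))
  long |>
    dplyr::group_by(.data$stage, .data$h_bin, a_level = .data$a_shown) |>
    dplyr::summarise(
      p_red = mean(.data$guess == "red"),
      count = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$count > min_count) |>
    dplyr::arrange(.data$stage, .data$h_bin, .data$a_level)
}

#' Mass of isotonicity violations in a heatmap table
#'
#' Diagnostic for the "monotone on average" rationality check: over adjacent
#' ordered cells within each row (fixed `h_bin`, increasing `a_level`) and
#' each column (fixed `a_level`, increasing `h_bin`), sums the decreases in
#' `p_red` and normalizes by the number of adjacent pairs.
#'
#' @param heatmap A table from [decision_heatmap()] (a single `stage`).
#' @return Mean violation mass per adjacent pair (0 for a monotone table).
#' @export
isotonic_violation_mass <- function(heatmap) {
  stopifnot(length(unique(heatmap$stage)) <= 1)
  viol <- 0
  n_pairs <- 0
  by_row <- split(heatmap[order(heatmap$a_level), ], heatmap$h_bin[order(heatmap$a_level)])
  for (rw in by_row) {
    d <- diff(rw$p_red)
    viol <- viol + sum(pmax(0, -d))
    n_pairs <- n_pairs + length(d)
  }
  by_col <- split(heatmap[order(heatmap$h_bin), ], heatmap$a_level[order(heatmap$h_bin)])
  for (cl in by_col) {
    d <- diff(cl$p_red)
    viol <- viol + sum(pmax(0, -d))
    n_pairs <- n_pairs + length(d)
  }
  if (n_pairs == 0) {
    return(0)
  }
  viol / n_pairs
}
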