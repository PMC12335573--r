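#' Plot decision-probability heatmaps
#'
#' Probability of guessing red stratified by the participant's initial
#' confidence bin and the displayed AI confidence, faceted by stage (initial
#' vs final guess) and, when several groups are present, by group. Rational
#' average behavior shows as monotone color gradients in both coordinates.
#'
#' @param records A response-record tibble (one or more groups).
#' @param min_count Cells with `count <= min_count` are omitted.
#' @return A ggplot object.
#' @export
plot_decision_heatmap <- function(records, min_count = 10) {
  groups <- unique(records$group)
  hm <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ decision_heatmap(.x, min_count = min_count)) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(hm, ggplot2::aes(
    x = factor(.data$a_level), y = .data$h_bin, fill = .data$p_red
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "black", mid = "grey85", high = "red3",
      midpoint = 0.5, limits = c(0, 1), name = "P(guess red)"
    ) +
    ggplot2::labs(
      x = "AI confidence shown", y = "initial confidence bin"
    ) +
    ggplot2::theme_minimal()
  if (length(groups) > 1) {
    p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$group), cols = ggplot2::vars(.data$stage)
    )
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$stage))
  }
}

#' Plot shown red fraction against true red fraction per group
#'
#' Shows how each bias condition displaces the shown fraction `z` relative to
#' the pile's true red fraction `r` and the AI confidence: toward-bias pulls
#' `z` across `r` toward (and past) the AI confidence, away-bias pushes it
#' outward, and the unbiased condition centers `z` on `r`.
#'
#' @param records A response-record tibble; attention checks are dropped.
#' @return A ggplot object.
#' @export
plot_shown_fraction <- function(records) {
  sums <- scored_records(records) |>
    dplyr::group_by(.data$group, .data$r, .data$a) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop")
  ggplot2::ggplot(sums, ggplot2::aes(x = .data$r)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = .data$a), shape = 3, color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_z), color = "red3") +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(
      x = "true red fraction r",
      y = "mean shown fraction z (red) / AI confidence a (+)"
    ) +
    ggplot2::theme_minimal()
}

#' Posterior densities of the conditional matching rates
#'
#' @param object An [fit_ab_model()] object.
#' @param ... Unused.
#' @return A ggplot object: theta_0 and theta_1 posteriors by group.
#' @export
autoplot.ab_fit <- function(object, ...) {
  draws <- tibble::as_tibble(object$theta) |>
    tidyr::pivot_longer(
      dplyr::everything(),
      names_to = "term", values_to = "theta"
    ) |>
    dplyr::mutate(
      q = paste0("theta[", sub("^theta(\\d)_.*$", "\\1", .data$term), "]"),
      group = sub("^theta\\d_", "", .data$term)
    )
  ggplot2::ggplot(draws, ggplot2::aes(
    x = .data$theta, fill = .data$group, color = .data$group
  )) +
    ggplot2::geom_density(alpha = 0.3) +
    ggplot2::facet_wrap(
      ggplot2::vars(.data$q),
      scales = "free",
      labeller = ggplot2::label_parsed
    ) +
    ggplot2::labs(x = "conditional matching rate", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Plot stratified matching rates
#'
#' Final matching rate against initial matching rate per game type, split by
#' whether the initial guess agreed with the AI lean. Points above the
#' diagonal in the disagreement stratum are games where AI assistance
#' corrected initially sub-optimal participants.
#'
#' @param records Filtered response records for one group.
#' @param min_count Cells with `count <= min_count` are omitted.
#' @return A ggplot object.
#' @export
plot_stratified_matching <- function(records, min_count = 10) {
  strat <- stratified_matching(records, min_count = min_count)
  ggplot2::ggplot(strat, ggplot2::aes(
    x = .data$q_rate, y = .data$qprime_rate,
    color = .data$agrees, size = .data$count
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_manual(
      values = c(`TRUE` = "steelblue", `FALSE` = "orange3"),
      name = "initial guess\nagrees with AI"
    ) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "initial matching rate E[Q]",
      y = "final matching rate E[Q']"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
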