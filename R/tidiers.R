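#' Tidy the posterior of an A/B fit
#'
#' One row per conditional matching rate theta[q, group]: posterior mean,
#' SD and central 95% credible interval.
#'
#' @param x An [fit_ab_model()] object.
#' @param ... Unused.
#' @return A tibble `term`, `group`, `q`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @export
tidy.ab_fit <- function(x, ...) {
  terms <- colnames(x$theta)
  qs <- as.integer(sub("^theta(\\d)_.*$", "\\1", terms))
  grps <- sub("^theta\\d_", "", terms)
  tibble::tibble(
    term = terms,
    group = grps,
    q = qs,
    estimate = colMeans(x$theta),
    std.error = apply(x$theta, 2, stats::sd),
    conf.low = apply(x$theta, 2, stats::quantile, probs = 0.025),
    conf.high = apply(x$theta, 2, stats::quantile, probs = 0.975)
  ) |>
    dplyr::arrange(.data$q, .data$group)
}

#' Glance at an A/B fit
#'
#' @param x An [fit_ab_model()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n_draws`, `chains`, `n_participants`,
#'   `n_obs`, `max_rhat`, `sigma_participant` (posterior mean random-
#'   intercept SD).
#' @export
glance.ab_fit <- function(x, ...) {
  tibble::tibble(
    n_draws = x$n_draws,
    chains = x$chains,
    n_participants = x$n_participants,
    n_obs = x$n_obs,
    max_rhat = max(x$rhat),
    sigma_participant = mean(x$sigma)
  )
}

#' Tidy a realignment map
#'
#' @param x A [fit_realignment()] map.
#' @param ... Unused.
#' @return A tibble with one row per (human bin, confidence bin):
#'   `h_bin`, `bin`, `lower_edge`, `upper_edge`, `output`, `train_count`.
#' @export
tidy.realignment_map <- function(x, ...) {
  purrr::imap(x$h_bins, function(s, h) {
    nb <- length(s$outputs)
    tibble::tibble(
      h_bin = h,
      bin = seq_len(nb),
      lower_edge = c(-Inf, s$edges),
      upper_edge = c(s$edges, Inf),
      output = s$outputs,
      train_count = s$train_counts
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(h_bin = factor(.data$h_bin,
      levels = h_bin_levels(), ordered = TRUE
    )) |>
    dplyr::arrange(.data$h_bin, .data$bin)
}
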