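#' Exact Wallenius noncentral hypergeometric probability mass function
#'
#' Distribution of the number of red cards obtained by drawing `n_draws` cards
#' sequentially without replacement from a pile of `n_red` red and `n_black`
#' black cards, when at every draw the odds of taking any particular remaining
#' red card are multiplied by `omega` relative to a black card.
#'
#' The pmf is computed by exact dynamic programming over the sequential draw
#' process: from a state with `R` reds and `B` blacks remaining, the next card
#' is red with probability `omega * R / (omega * R + B)`. This is exact (up to
#' floating point) for the small piles used in card-game designs; no integral
#' approximation is involved, so the result can serve as a bit-reproducible
#' oracle for the sampler.
#'
#' @param n_draws Number of cards drawn (shown), a non-negative integer.
#' @param n_red Number of red cards in the pile.
#' @param n_black Number of black cards in the pile.
#' @param omega Odds ratio in favour of red at every draw; positive and finite.
#'   `omega = 1` recovers the central hypergeometric distribution.
#'
#' @return A numeric vector `p` of length `min(n_draws, n_red) + 1` with
#'   `p[k + 1] = P(K = k)` for `k = 0, ..., min(n_draws, n_red)` red draws,
#'   named by `k`. Entries outside the feasible support
#'   `max(0, n_draws - n_black) <= k` are exactly zero.
#' @seealso [wallenius_sample()]
#' @examples
#' wallenius_pmf(21, 33, 32, 1 / 4)
#' sum(wallenius_pmf(21, 33, 32, 4)) # 1
#' @export
wallenius_pmf <- function(n_draws, n_red, n_black, omega) {
  check_wallenius_params(n_draws, n_red, n_black, omega)
  # p[k+1] = P(k reds drawn after t draws); grow one draw at a time
  p <- 1
  if (n_draws > 0) {
    for (t in 0:(n_draws - 1)) {
      k <- 0:t
      R <- n_red - k
      B <- n_black - (t - k)
      pr <- ifelse(R <= 0, 0, ifelse(B <= 0, 1, omega * R / (omega * R + B)))
      p <- c(p * (1 - pr), 0) + c(0, p * pr)
    }
  }
  kmax <- min(n_draws, n_red)
  p <- p[seq_len(kmax + 1)]
  names(p) <- 0:kmax
  p
}

#' Sample red-draw counts from the Wallenius noncentral hypergeometric
#'
#' Simulates the generative definition of the distribution: cards are drawn
#' one at a time without replacement, each remaining red card's odds of being
#' taken multiplied by `omega`. The empirical distribution over many draws
#' converges to [wallenius_pmf()].
#'
#' Randomness comes from the R session RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param n Number of independent replicates to draw.
#' @inheritParams wallenius_pmf
#' @return An integer vector of length `n` of red-draw counts, each in
#'   `[max(0, n_draws - n_black), min(n_draws, n_red)]`.
#' @examples
#' set.seed(1)
#' mean(wallenius_sample(1e4, 21, 33, 32, 1)) # ~ 21 * 33/65
#' @export
wallenius_sample <- function(n, n_draws, n_red, n_black, omega) {
  check_wallenius_params(n_draws, n_red, n_black, omega)
  stopifnot(is.numeric(n), length(n) == 1, n >= 0)
  reds <- integer(n)
  if (n == 0 || n_draws == 0) {
    return(reds)
  }
  R <- rep.int(n_red, n)
  B <- rep.int(n_black, n)
  for (t in seq_len(n_draws)) {
    pr <- ifelse(R <= 0, 0, ifelse(B <= 0, 1, omega * R / (omega * R + B)))
    take_red <- stats::runif(n) < pr
    R <- R - take_red
    B <- B - !take_red
  }
  as.integer(n_red - R)
}

check_wallenius_params <- function(n_draws, n_red, n_black, omega) {
  is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x >= 0 && x == as.integer(x)
  if (!is_count(n_draws)) {
    stop("`n_draws` must be a single non-negative integer", call. = FALSE)
  }
  if (!is_count(n_red)) {
    stop("`n_red` must be a single non-negative integer", call. = FALSE)
  }
  if (!is_count(n_black)) {
    stop("`n_black` must be a single non-negative integer", call. = FALSE)
  }
  if (n_draws > n_red + n_black) {
    stop("`n_draws` must not exceed `n_red + n_black`", call. = FALSE)
  }
  if (!is.numeric(omega) || length(omega) != 1 || !is.finite(omega) ||
    omega <= 0) {
    stop("`omega` must be a single finite positive number", call. = FALSE)
  }
  invisible(TRUE)
}
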