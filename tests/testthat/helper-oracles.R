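# Independent oracles and small fixture builders used across test files.
# These deliberately avoid the package's own computational paths.

# Wallenius pmf by brute-force enumeration of color sequences: the
# probability of drawing a specific remaining red card is omega / (total
# remaining weight), of a black card 1 / (total weight). Recursion over the
# draw sequence, independent of the package's dynamic program.
brute_wallenius_pmf <- function(n_draws, n_red, n_black, omega) {
  out <- numeric(min(n_draws, n_red) + 1)
  recurse <- function(reds_drawn, R, B, draws_left, prob) {
    if (draws_left == 0) {
      out[reds_drawn + 1] <<- out[reds_drawn + 1] + prob
      return(invisible(NULL))
    }
    w <- omega * R + B
    if (R > 0) {
      recurse(reds_drawn + 1, R - 1, B, draws_left - 1, prob * omega * R / w)
    }
    if (B > 0) {
      recurse(reds_drawn, R, B - 1, draws_left - 1, prob * B / w)
    }
  }
  recurse(0, n_red, n_black, n_draws, 1)
  out
}

# MAE / EAE by exhaustive double loop over cells; independent of the
# package's pair-enumeration code.
brute_alignment_errors <- function(table) {
  mae <- 0
  pos_sum <- 0
  n_pairs <- 0
  for (i in seq_len(nrow(table))) {
    for (j in seq_len(nrow(table))) {
      if (table$a_level[i] <= table$a_level[j] &&
        table$h_bin[i] <= table$h_bin[j]) {
        d <- table$estimate[i] - table$estimate[j]
        n_pairs <- n_pairs + 1
        if (d > mae) mae <- d
        if (d > 0) pos_sum <- pos_sum + d
      }
    }
  }
  list(mae = mae, eae = pos_sum / n_pairs, n_pairs = n_pairs)
}

# Random alignment table on a lattice of up to n_a x n_h cells
random_alignment_table <- function(n_a, n_h, keep_prob = 0.8) {
  grid <- expand.grid(
    a_level = seq_len(n_a) * 10L,
    h_bin = factor(humalign:::h_bin_levels()[seq_len(n_h)],
      levels = humalign:::h_bin_levels(), ordered = TRUE
    )
  )
  grid <- grid[stats::runif(nrow(grid)) < keep_prob, , drop = FALSE]
  if (nrow(grid) == 0) grid <- expand.grid(a_level = 10L, h_bin = factor(
    "low", levels = humalign:::h_bin_levels(), ordered = TRUE
  ))
  tibble::tibble(
    a_level = grid$a_level,
    h_bin = grid$h_bin,
    estimate = stats::runif(nrow(grid)),
    count = sample(1:50, nrow(grid), replace = TRUE)
  )
}

# Mean of the rounded clipped normal via exact probability mass on 0..100
clipped_round_normal_mean <- function(mu, sd) {
  k <- 0:100
  lo <- ifelse(k == 0, -Inf, k - 0.5)
  hi <- ifelse(k == 100, Inf, k + 0.5)
  sum(k * (stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd)))
}

# Boschloo p-value, coded independently (explicit loops, direct binomial
# sums) with the same published convention: Fisher one-sided ordering
# statistic, supremum over a fixed uniform nuisance grid.
brute_boschloo <- function(xa, na, xb, nb, n_grid = 1001) {
  fisher_one <- function(x1, x2) {
    s <- x1 + x2
    sum(stats::dhyper(x1:min(s, na), s, na + nb - s, na))
  }
  fmat <- matrix(0, na + 1, nb + 1)
  for (x1 in 0:na) {
    for (x2 in 0:nb) fmat[x1 + 1, x2 + 1] <- fisher_one(x1, x2)
  }
  extreme <- fmat <= fmat[xa + 1, xb + 1] + 1e-12
  pmax_val <- 0
  for (th in seq(1e-6, 1 - 1e-6, length.out = n_grid)) {
    tot <- 0
    for (x1 in 0:na) {
      for (x2 in 0:nb) {
        if (extreme[x1 + 1, x2 + 1]) {
          tot <- tot + stats::dbinom(x1, na, th) * stats::dbinom(x2, nb, th)
        }
      }
    }
    if (tot > pmax_val) pmax_val <- tot
  }
  min(1, pmax_val)
}

# Minimal record tibble builder for metric tests
make_records <- function(a_shown, conf, initial_guess, final_guess = NULL,
                         outcome, r = NULL, a = NULL,
                         group = "unbiased", participant = NULL) {
  n <- length(a_shown)
  tibble::tibble(
    participant_id = participant %||% sprintf("p%02d", seq_len(n)),
    group = group,
    batch_id = 1L,
    round_index = seq_len(n),
    a_num = 1L, a_den = 13L,
    a_shown = as.integer(a_shown),
    r_num = 1L, r_den = 65L,
    z_count = 10L,
    initial_confidence = as.integer(conf),
    initial_guess = initial_guess,
    final_guess = final_guess %||% initial_guess,
    outcome_is_red = as.integer(outcome),
    is_attention_check = FALSE,
    a = a %||% (a_shown / 100),
    r = r %||% (0.5 + (outcome - 0.5) * 0.1),
    z = 10 / 21
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
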