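cfg <- design_config()

test_that("initial confidence is a clipped rounded normal around 100 z", {
  set.seed(31)
  conf <- draw_initial_confidence(rep(10 / 21, 1e4))
  expect_true(all(conf >= 0 & conf <= 100))
  target <- clipped_round_normal_mean(1000 / 21, 12)
  expect_lt(abs(mean(conf) - target), 3 * 12 / sqrt(1e4))
  # degenerate limit: tiny sigma returns the rounded percentage
  tight <- behavior_params(sigma_initial = 1e-9)
  expect_true(all(draw_initial_confidence(rep(10 / 21, 50), tight) == 48L))
  expect_true(all(draw_initial_confidence(rep(0, 50), tight) == 0L))
})

test_that("initial guess follows confidence with a fair coin at 50", {
  expect_equal(initial_guess_from_confidence(c(80, 51)), c("red", "red"))
  expect_equal(initial_guess_from_confidence(c(20, 49)), c("black", "black"))
  set.seed(4)
  g <- initial_guess_from_confidence(rep(50, 1e4))
  expect_lt(abs(mean(g == "red") - 0.5), 3 * 0.5 / sqrt(1e4))
})

test_that("final decision probability follows the lapse-logistic form", {
  bp <- behavior_params()
  expect_equal(final_decision_prob(50, 50, bp), 0.5)
  # direct evaluation of the stated formula
  manual <- (1 - bp$lapse) *
    stats::plogis(bp$w_h * (90 - 50) + bp$w_a * (8 - 50)) + bp$lapse / 2
  expect_equal(final_decision_prob(90, 8, bp), manual)
  # monotone in both arguments
  grid <- 0:100
  expect_true(all(diff(final_decision_prob(grid, 40, bp)) >= 0))
  expect_true(all(diff(final_decision_prob(40, grid, bp)) >= 0))
  # sampled frequencies agree with the probability
  set.seed(12)
  f <- final_decision(rep(70, 2e4), rep(30, 2e4), bp)
  p <- final_decision_prob(70, 30, bp)
  expect_lt(abs(mean(f == "red") - p), 3 * sqrt(p * (1 - p) / 2e4))
})

test_that("bayes observer computes the two-hypothesis posterior", {
  # unbiased, symmetric likelihoods at the midpoint count: P(red) = a
  # (a = 5/13 -> piles 23/65 and 27/65; the pmfs are symmetric around
  #  their means, so equal posterior mass at a z equidistant from both)
  obs <- bayes_observer_guess(8, 5 / 13, "unbiased", cfg)
  lik1 <- wallenius_pmf(21, 23, 42, 1)[["8"]]
  lik2 <- wallenius_pmf(21, 27, 38, 1)[["8"]]
  manual <- (lik1 * 23 / 65 + lik2 * 27 / 65) / (lik1 + lik2)
  expect_equal(obs$p_red, manual)
  # z only feasible under the larger r: posterior collapses onto it
  obs2 <- bayes_observer_guess(7, 1 / 13, "unbiased", cfg)
  expect_equal(obs2$p_red, 7 / 65)
  expect_equal(obs2$guess, "black")
  # infeasible under both hypotheses errors
  expect_error(
    bayes_observer_guess(21, 1 / 13, "unbiased", cfg),
    "impossible"
  )
})

test_that("bayes observer beats the majority-of-shown rule on toward games", {
  set.seed(17)
  piles <- pile_types(cfg)
  n <- 1e4
  idx <- sample(nrow(piles), n, replace = TRUE)
  r <- piles$r[idx]
  a <- piles$a[idx]
  z_count <- integer(n)
  for (i in seq_len(n)) {
    n_red <- piles$r_num[idx[i]]
    z_count[i] <- wallenius_sample(
      1, 21, n_red, 65 - n_red,
      odds_ratio("toward", r[i], a[i])
    )
  }
  obs <- bayes_observer_guess(z_count, a, "toward", cfg)
  # expected point score of a guess g on a pile r is 2 P(correct) - 1
  exp_score <- function(guess) {
    mean(ifelse(guess == "red", 2 * r - 1, 1 - 2 * r))
  }
  majority <- ifelse(z_count > 21 / 2, "red", "black")
  expect_gt(exp_score(obs$guess), exp_score(majority))
})

test_that("simulated cohorts have the declared shape and reuse batch draws", {
  set.seed(23)
  batches <- build_batches(cfg, "unbiased", n_batches = 5)
  rec <- simulate_cohort(batches, 20, cfg = cfg)
  expect_equal(nrow(rec), 20 * 27)
  expect_equal(sum(!rec$is_attention_check), 20 * 24)
  expect_equal(sum(rec$is_attention_check), 20 * 3)
  # every record's shown count equals its batch's stored draw
  joined <- dplyr::inner_join(
    rec, batches,
    by = c("batch_id", "round_index"), suffix = c("", ".batch")
  )
  expect_equal(joined$z_count, joined$z_count.batch)
  # round-robin assignment: 4 participants per batch
  expect_equal(
    dplyr::n_distinct(rec$batch_id), 5
  )
  per_batch <- dplyr::distinct(rec, participant_id, batch_id) |>
    dplyr::count(batch_id)
  expect_true(all(per_batch$n == 4))
  # scored rounds are permuted per participant, checks keep their slots
  one <- dplyr::filter(rec, participant_id == rec$participant_id[1])
  expect_equal(sort(one$display_order[!one$is_attention_check]), 1:24)
  expect_equal(one$display_order[one$is_attention_check], 25:27)
})

test_that("initial confidence tracks the shown percentage with unit slope", {
  set.seed(29)
  batches <- build_batches(cfg, "unbiased", n_batches = 20)
  rec <- simulate_cohort(batches, 100, cfg = cfg)
  scored <- dplyr::filter(rec, !is_attention_check)
  slope <- stats::coef(
    stats::lm(initial_confidence ~ I(100 * z), data = scored)
  )[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("decision probabilities are monotone on average in a large cohort", {
  set.seed(37)
  batches <- build_batches(cfg, "unbiased", n_batches = 20)
  rec <- simulate_cohort(batches, 450, cfg = cfg)
  hm <- decision_heatmap(rec, min_count = 10)
  expect_lt(
    isotonic_violation_mass(dplyr::filter(hm, stage == "final")), 0.02
  )
  expect_lt(
    isotonic_violation_mass(dplyr::filter(hm, stage == "initial")), 0.02
  )
})

test_that("the realigned group requires a fitted map", {
  set.seed(41)
  tow <- build_batches(cfg, "toward", n_batches = 2)
  expect_error(
    simulate_cohort(realign_batches(tow), 4, cfg = cfg),
    "realignment_map"
  )
})
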