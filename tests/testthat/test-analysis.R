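test_that("optimal guess is red above one half and undefined at one half", {
  expect_equal(optimal_guess(33 / 65), "red")
  expect_equal(optimal_guess(3 / 65), "black")
  expect_equal(optimal_guess(c(0.6, 0.4)), c("red", "black"))
  expect_error(optimal_guess(0.5), "0.5")
})

test_that("matching indicators compare guesses to the optimum", {
  rec <- make_records(
    a_shown = rep(54, 4), conf = c(80, 30, 80, 30),
    initial_guess = c("red", "black", "red", "black"),
    final_guess = c("red", "red", "black", "black"),
    outcome = rep(1, 4), r = rep(37 / 65, 4)
  )
  ind <- match_indicators(rec)
  expect_equal(ind$q, c(1L, 0L, 1L, 0L))
  expect_equal(ind$q_prime, c(1L, 1L, 0L, 0L))
})

test_that("scores and bonuses follow the point rule", {
  mk <- function(correct) {
    out <- rep(1L, 24)
    final <- ifelse(seq_len(24) <= correct, "red", "black")
    make_records(
      a_shown = rep(54, 24), conf = rep(80, 24),
      initial_guess = rep("red", 24), final_guess = final,
      outcome = out, r = rep(37 / 65, 24),
      participant = rep("p1", 24)
    )
  }
  all_right <- score_participants(mk(24))
  expect_equal(all_right$points, 24)
  expect_equal(all_right$bonus, 2.88)
  half <- score_participants(mk(12))
  expect_equal(half$points, 0)
  expect_equal(half$bonus, 0)
  none <- score_participants(mk(0))
  expect_equal(none$points, -24)
  expect_equal(none$bonus, 0)
})

attention_fixture <- function(confs) {
  # confs: named list participant -> length-3 confidence vector
  n <- length(confs)
  tibble::tibble(
    participant_id = rep(names(confs), each = 3),
    group = "unbiased",
    batch_id = 1L,
    round_index = rep(25:27, n),
    a_num = 1L, a_den = 1L, a_shown = 50L,
    r_num = 1L, r_den = 1L, z_count = 21L,
    initial_confidence = as.integer(unlist(confs)),
    initial_guess = "red", final_guess = "red",
    outcome_is_red = 1L, is_attention_check = TRUE,
    a = 1, r = 1, z = 1
  )
}

test_that("exclusion needs more than one out-of-band attention check", {
  # ten conforming participants anchor the means; p11 deviates on one
  # check only, p12 on two
  confs <- c(
    lapply(1:10, function(i) c(5, 75, 95) + (i %% 3)),
    list(p11 = c(60, 75, 95), p12 = c(60, 20, 95))
  )
  names(confs)[1:10] <- sprintf("p%02d", 1:10)
  res <- filter_participants(attention_fixture(confs))
  expect_true("p11" %in% res$kept)
  expect_equal(res$excluded, "p12")
  # order invariance and determinism
  rec <- attention_fixture(confs)
  res2 <- filter_participants(rec[sample(nrow(rec)), ])
  expect_equal(sort(res2$kept), sort(res$kept))
  expect_equal(res2$excluded, res$excluded)
})

test_that("identical attention answers exclude nobody and warn on zero SD", {
  confs <- lapply(1:6, function(i) c(0, 75, 100))
  names(confs) <- sprintf("p%02d", 1:6)
  expect_warning(res <- filter_participants(attention_fixture(confs)), "zero")
  expect_equal(length(res$excluded), 0)
})

test_that("aggregated counts split games by the initial-match level", {
  rec <- make_records(
    a_shown = rep(54, 24), conf = c(rep(30, 10), rep(80, 14)),
    initial_guess = c(rep("black", 10), rep("red", 14)),
    final_guess = c(rep("red", 7), rep("black", 3), rep("red", 14)),
    outcome = rep(1, 24), r = rep(37 / 65, 24),
    participant = rep("p1", 24)
  )
  counts <- aggregate_counts(rec)
  expect_equal(nrow(counts), 2)
  q0 <- dplyr::filter(counts, q == 0)
  expect_equal(q0$successes, 7L)
  expect_equal(q0$trials, 10L)
  q1 <- dplyr::filter(counts, q == 1)
  expect_equal(q1$successes, 14L)
  expect_equal(q1$trials, 14L)
  # an all-optimal participant yields a single q = 1 row
  all_opt <- make_records(
    a_shown = rep(54, 24), conf = rep(80, 24),
    initial_guess = rep("red", 24), final_guess = rep("red", 24),
    outcome = rep(1, 24), r = rep(37 / 65, 24),
    participant = rep("p2", 24)
  )
  expect_equal(aggregate_counts(all_opt)$q, 1L)
  expect_equal(nrow(aggregate_counts(rec[0, ])), 0)
})

test_that("stratified matching flags AI agreement and omits sparse cells", {
  rec <- make_records(
    a_shown = rep(c(54, 8), each = 12), conf = rep(c(80, 80), each = 12),
    initial_guess = rep("red", 24),
    final_guess = rep("red", 24),
    outcome = rep(1, 24),
    r = rep(c(37 / 65, 3 / 65), each = 12),
    a = rep(c(7 / 13, 1 / 13), each = 12)
  )
  strat <- stratified_matching(rec, min_count = 10)
  expect_equal(nrow(strat), 2)
  # a_shown = 54 leans red and the guess is red: agreement
  expect_equal(strat$agrees[strat$r > 0.5], TRUE)
  expect_equal(strat$agrees[strat$r < 0.5], FALSE)
  # exactly-min_count cells are omitted
  expect_equal(nrow(stratified_matching(rec, min_count = 12)), 0)
})

test_that("boschloo p-values match an independent brute-force oracle", {
  cases <- list(
    c(5, 10, 5, 10), c(10, 10, 0, 10), c(7, 8, 2, 9),
    c(3, 12, 9, 12), c(6, 7, 1, 5), c(0, 4, 4, 4)
  )
  for (cs in cases) {
    expect_equal(
      boschloo_test(cs[1], cs[2], cs[3], cs[4], "greater"),
      brute_boschloo(cs[1], cs[2], cs[3], cs[4]),
      tolerance = 1e-9
    )
  }
})

test_that("boschloo respects no-evidence and decisive-evidence benchmarks", {
  # identical proportions carry no evidence; reference value verified
  # against an independent implementation of the exact unconditional test
  expect_equal(boschloo_test(5, 10, 5, 10, "greater"), 0.4724636,
    tolerance = 1e-4
  )
  expect_equal(boschloo_test(7, 8, 2, 9, "greater"), 0.004477785,
    tolerance = 1e-4
  )
  expect_lt(boschloo_test(10, 10, 0, 10, "greater"), 0.001)
  # 'less' is the swapped comparison
  expect_equal(
    boschloo_test(2, 10, 8, 10, "less"),
    boschloo_test(8, 10, 2, 10, "greater")
  )
  expect_error(boschloo_test(1, 0, 0, 5), "trials")
})

test_that("boschloo is never less powerful than one-sided Fisher", {
  set.seed(109)
  for (i in 1:25) {
    na <- sample(3:12, 1)
    nb <- sample(3:12, 1)
    xa <- sample(0:na, 1)
    xb <- sample(0:nb, 1)
    fisher <- stats::fisher.test(
      matrix(c(xa, na - xa, xb, nb - xb), 2, byrow = TRUE),
      alternative = "greater"
    )$p.value
    expect_lte(boschloo_test(xa, na, xb, nb, "greater"), fisher + 1e-12)
  }
})

test_that("hypothesis evidence implements the posterior-odds identity", {
  set.seed(113)
  fake <- structure(
    list(
      theta = cbind(
        theta0_away = c(rep(0.6, 99), 0.1),
        theta0_toward = rep(0.5, 100)
      ),
      n_draws = 100
    ),
    class = "ab_fit"
  )
  h <- hypothesis_evidence(fake, "away", "toward", 0)
  expect_equal(h$post_prob, 0.99)
  expect_equal(h$evidence_ratio, 99)
  expect_equal(h$estimate, mean(fake$theta[, 1] - 0.5))
  # unanimous support reports the draw-count ceiling
  fake$theta[, 1] <- 0.7
  h2 <- hypothesis_evidence(fake, "away", "toward", 0)
  expect_equal(h2$post_prob, 1)
  expect_true(is.infinite(h2$evidence_ratio))
  expect_equal(h2$evidence_label, "> 100")
  expect_error(hypothesis_evidence(fake, "away", "unbiased", 0), "unbiased")
})
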