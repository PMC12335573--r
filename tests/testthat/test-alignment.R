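test_that("confidence discretization follows the four regions and tie rule", {
  expect_equal(as.character(discretize_confidence(10, "black")), "very_low")
  expect_equal(as.character(discretize_confidence(25, "red")), "very_low")
  expect_equal(as.character(discretize_confidence(26, "red")), "low")
  expect_equal(as.character(discretize_confidence(49, "red")), "low")
  expect_equal(as.character(discretize_confidence(50, "red")), "high")
  expect_equal(as.character(discretize_confidence(50, "black")), "low")
  expect_equal(as.character(discretize_confidence(51, "black")), "high")
  expect_equal(as.character(discretize_confidence(75, "red")), "high")
  expect_equal(as.character(discretize_confidence(76, "red")), "very_high")
  expect_error(discretize_confidence(101, "red"), "\\[0, 100\\]")
  # the result is an ordered factor with the full level order
  b <- discretize_confidence(c(10, 40, 60, 90), rep("red", 4))
  expect_true(is.ordered(b))
  expect_true(all(diff(as.integer(b)) > 0))
})

test_that("outcome tables count and filter cells as declared", {
  # 6 records over 2 cells: 4 reds of 4 in one, 1 red of 2 in the other
  rec <- make_records(
    a_shown = c(8, 8, 8, 8, 92, 92),
    conf = c(10, 10, 10, 10, 90, 90),
    initial_guess = c(rep("black", 4), "red", "red"),
    outcome = c(1, 1, 1, 1, 1, 0)
  )
  tab <- outcome_table(rec)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$estimate, c(1, 0.5))
  expect_equal(tab$count, c(4L, 2L))
  # min_count filtering
  expect_equal(nrow(outcome_table(rec, min_count = 3)), 1)
  expect_equal(nrow(outcome_table(rec, min_count = 5)), 0)
  expect_error(outcome_table(rec[0, ]), "no scored")
})

test_that("MAE and EAE match the hand-computed 2x2 lattice", {
  tab <- tibble::tibble(
    a_level = c(10L, 10L, 20L, 20L),
    h_bin = factor(c("low", "high", "low", "high"),
      levels = humalign:::h_bin_levels(), ordered = TRUE
    ),
    estimate = c(0.8, 0.6, 0.7, 0.5),
    count = 5L
  )
  expect_equal(max_alignment_error(tab), 0.3)
  e <- expected_alignment_error(tab)
  expect_equal(e$n_pairs, 9)
  # positive violations: (a1,h1) vs (a1,h2), (a2,h1), (a2,h2) give
  # 0.2, 0.1, 0.3; (a1,h2) vs (a2,h2) gives 0.1; (a2,h1) vs (a2,h2) 0.2
  expect_equal(e$eae, (0.2 + 0.1 + 0.3 + 0.1 + 0.2) / 9)
})

test_that("monotone and single-cell tables have zero alignment error", {
  mono <- tibble::tibble(
    a_level = c(10L, 10L, 20L, 20L),
    h_bin = factor(c("low", "high", "low", "high"),
      levels = humalign:::h_bin_levels(), ordered = TRUE
    ),
    estimate = c(0.1, 0.2, 0.3, 0.4),
    count = 5L
  )
  expect_equal(max_alignment_error(mono), 0)
  expect_equal(expected_alignment_error(mono)$eae, 0)
  single <- mono[1, ]
  expect_equal(max_alignment_error(single), 0)
  expect_equal(expected_alignment_error(single)$n_pairs, 1)
})

test_that("MAE/EAE equal exhaustive enumeration on random lattices", {
  set.seed(53)
  for (i in 1:40) {
    tab <- random_alignment_table(sample(2:5, 1), sample(2:4, 1))
    oracle <- brute_alignment_errors(tab)
    expect_equal(max_alignment_error(tab), oracle$mae)
    e <- expected_alignment_error(tab)
    expect_equal(e$eae, oracle$eae)
    expect_equal(e$n_pairs, oracle$n_pairs)
  }
})

test_that("EAE <= MAE <= 1 on fuzzed tables and under permutation", {
  set.seed(59)
  for (i in 1:1000) {
    tab <- random_alignment_table(sample(2:5, 1), sample(2:4, 1))
    mae <- max_alignment_error(tab)
    eae <- expected_alignment_error(tab)$eae
    expect_true(eae >= 0 && eae <= mae && mae <= 1)
  }
  tab <- random_alignment_table(5, 4)
  perm <- tab[sample(nrow(tab)), ]
  expect_equal(max_alignment_error(perm), max_alignment_error(tab))
  expect_equal(
    expected_alignment_error(perm)$eae,
    expected_alignment_error(tab)$eae
  )
})

test_that("record order never changes the alignment summary", {
  set.seed(61)
  rec <- make_records(
    a_shown = sample(c(8, 31, 69, 92), 200, replace = TRUE),
    conf = sample(0:100, 200, replace = TRUE),
    initial_guess = sample(c("red", "black"), 200, replace = TRUE),
    outcome = sample(0:1, 200, replace = TRUE)
  )
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(alignment_summary(rec), alignment_summary(shuffled))
})

test_that("calibration error matches its definition on degenerate inputs", {
  all_red_100 <- make_records(
    a_shown = rep(100, 10), conf = rep(90, 10),
    initial_guess = rep("red", 10), outcome = rep(1, 10)
  )
  expect_equal(calibration_error(all_red_100), 0)
  all_red_8 <- make_records(
    a_shown = rep(8, 10), conf = rep(90, 10),
    initial_guess = rep("red", 10), outcome = rep(1, 10)
  )
  expect_equal(calibration_error(all_red_8), 0.92)
})

test_that("calibration error is small when outcomes follow the levels", {
  set.seed(67)
  a_shown <- rep(display_confidence((1:12) / 13), length.out = 1e4)
  rec <- make_records(
    a_shown = a_shown,
    conf = rep(50, 1e4),
    initial_guess = rep("red", 1e4),
    outcome = stats::rbinom(1e4, 1, a_shown / 100)
  )
  expect_lt(calibration_error(rec), 0.02)
})

test_that("decision heatmap drops cells with min_count or fewer records", {
  rec <- make_records(
    a_shown = c(rep(8, 10), rep(92, 11)),
    conf = c(rep(10, 10), rep(90, 11)),
    initial_guess = c(rep("black", 10), rep("red", 11)),
    outcome = rep(1, 21)
  )
  hm <- decision_heatmap(rec, min_count = 10)
  # the 10-record cell is omitted, the 11-record cell kept
  expect_true(all(hm$count == 11))
  expect_equal(nrow(hm), 2) # initial and final stage of the kept cell
})

test_that("deterministic confidence-driven agents give step-function rows", {
  # near-infinite weight on own confidence: initial guess fully determines
  # the final guess, so every heatmap row is 0/1 in the h direction
  set.seed(71)
  cfg <- design_config()
  bp <- behavior_params(w_h = 1000, w_a = 0, lapse = 0)
  batches <- build_batches(cfg, "unbiased", n_batches = 5)
  rec <- simulate_cohort(batches, 50, params = bp, cfg = cfg) |>
    dplyr::filter(initial_confidence != 50) # ties resolve by a fair coin
  hm <- decision_heatmap(rec, min_count = 10) |>
    dplyr::filter(stage == "final")
  expect_true(all(hm$p_red[hm$h_bin > "low"] > 0.95))
  expect_true(all(hm$p_red[hm$h_bin <= "low"] < 0.05))
})
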