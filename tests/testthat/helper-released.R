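# Synthetic stand-in for a deposited per-game response table with its own
# column names and group labels; used by the adapter tests.
released_fixture <- function(path) {
  set.seed(157)
  cfg <- design_config()
  batches <- build_batches(cfg, "unbiased", n_batches = 2)
  rec <- simulate_cohort(batches, 6, cfg = cfg)
  src <- tibble::tibble(
    pid = rec$participant_id,
    condition = "control",
    batch = rec$batch_id,
    trial = rec$round_index,
    ai_conf_num = rec$a_num,
    ai_conf_den = rec$a_den,
    ai_conf_shown = rec$a_shown,
    reds_num = rec$r_num,
    reds_den = rec$r_den,
    reds_shown = rec$z_count,
    conf_initial = rec$initial_confidence,
    guess_initial = rec$initial_guess,
    guess_final = rec$final_guess,
    card_red = rec$outcome_is_red,
    attention = as.integer(rec$is_attention_check)
  )
  readr::write_csv(src, path)
  rec
}

released_mapping <- function() {
  list(
    columns = c(
      participant_id = "pid", group = "condition", batch_id = "batch",
      round_index = "trial", a_num = "ai_conf_num", a_den = "ai_conf_den",
      a_shown = "ai_conf_shown", r_num = "reds_num", r_den = "reds_den",
      z_count = "reds_shown", initial_confidence = "conf_initial",
      initial_guess = "guess_initial", final_guess = "guess_final",
      outcome_is_red = "card_red", is_attention_check = "attention"
    ),
    group_labels = c(control = "unbiased")
  )
}
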