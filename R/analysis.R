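#' Optimal guess for a pile
#'
#' The optimal policy depends only on the true red fraction: guess red iff
#' `r > 0.5`. The design contains no pile with `r = 0.5`, where the optimum
#' would be undefined.
#'
#' @param r True red fraction(s).
#' @return Character vector, `"red"` or `"black"`.
#' @export
optimal_guess <- function(r) {
  if (any(abs(r - 0.5) < 1e-12)) {
    stop("optimal guess undefined at r = 0.5", call. = FALSE)
  }
  ifelse(r > 0.5, "red", "black")
}

#' Matching indicators Q and Q' per scored record
#'
#' `q = 1` when the initial guess equals the optimal guess for the pile,
#' `q_prime = 1` when the final guess does. The conditional matching rates
#' theta_0 = E[Q' | Q = 0] and theta_1 = E[Q' | Q = 1] measure how AI
#' assistance moves participants toward the optimal decision, conditioned on
#' their initial performance.
#'
#' @param records A response-record tibble; attention checks are dropped.
#' @return The scored records with integer columns `q` and `q_prime` added.
#' @export
match_indicators <- function(records) {
  records <- scored_records(records)
  opt <- optimal_guess(records$r)
  dplyr::mutate(records,
    q = as.integer(.data$initial_guess == opt),
    q_prime = as.integer(.data$final_guess == opt)
  )
}

#' Points and bonus earned per participant
#'
#' A point is won for each correct final guess and lost for each incorrect
#' one; the bonus pays `bonus_per_point` GBP per point, floored at zero.
#'
#' @param records A response-record tibble; attention checks are dropped.
#' @param bonus_per_point Bonus per point, GBP.
#' @return A tibble `participant_id`, `group`, `points`, `bonus`.
#' @export
score_participants <- function(records, bonus_per_point = 0.12) {
  scored_records(records) |>
    dplyr::group_by(.data$participant_id, .data$group) |>
    dplyr::summarise(
      points = sum(
        (.data$final_guess == "red") == (.data$outcome_is_red == 1)
      ) - sum(
        (.data$final_guess == "red") != (.data$outcome_is_red == 1)
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(bonus = pmax(.data$points, 0) * bonus_per_point)
}

#' Attention-check exclusion of inattentive participants
#'
#' For each of the three attention checks, the mean and SD of the stated
#' initial confidence are computed over the reference population (all records
#' passed in — pool all deployed groups, or pass the calibration cohort alone
#' to filter it against itself). A participant is flagged on a check when
#' their confidence lies more than one SD from the check mean, and excluded
#' when flagged on more than one check.
#'
#' @param records A response-record tibble containing attention-check rows
#'   for every participant.
#' @return A list: `kept` and `excluded` (participant id vectors),
#'   `check_stats` (per-check mean/SD), `flags` (per participant x check).
#' @export
filter_participants <- function(records) {
  att <- dplyr::filter(records, .data$is_attention_check)
  if (nrow(att) == 0) {
    stop("no attention-check records found", call. = FALSE)
  }
  stats_tbl <- att |>
    dplyr::group_by(.data$round_index) |>
    dplyr::summarise(
      mean_conf = mean(.data$initial_confidence),
      sd_conf = stats::sd(.data$initial_confidence),
      .groups = "drop"
    )
  if (any(stats_tbl$sd_conf == 0)) {
    warning("attention check with zero confidence SD; ",
      "any nonzero deviation flags on that check",
      call. = FALSE
    )
  }
  flags <- att |>
    dplyr::left_join(stats_tbl, by = "round_index") |>
    dplyr::mutate(flagged = abs(.data$initial_confidence - .data$mean_conf) >
      .data$sd_conf) |>
    dplyr::select(
      "participant_id", "round_index", "initial_confidence", "flagged"
    )
  per_part <- flags |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_flagged = sum(.data$flagged), .groups = "drop")
  list(
    kept = per_part$participant_id[per_part$n_flagged <= 1],
    excluded = per_part$participant_id[per_part$n_flagged > 1],
    check_stats = stats_tbl,
    flags = flags
  )
}

#' Aggregate matching counts for the binomial model
#'
#' One row per participant and initial-match level `q`: `successes` counts
#' games with `q_prime = 1`, `trials` counts games at that `q`. Rows with
#' zero trials are omitted.
#'
#' @param records Filtered, scored response records.
#' @return A tibble `participant_id`, `group`, `q`, `successes`, `trials`.
#' @export
aggregate_counts <- function(records) {
  match_indicators(records) |>
    dplyr::group_by(.data$participant_id, .data$group, .data$q) |>
    dplyr::summarise(
      successes = sum(.data$q_prime),
      trials = dplyr::n(),
      .groups = "drop"
    )
}

#' Fit the Bayesian binomial mixed-effects A/B model
#'
#' Fits, by MCMC (JAGS), the binomial-logit model for the matching rate with
#' one fixed-effect coefficient per (group, initial-match) cell — no global
#' intercept, so no group is singled out as reference — and a random
#' intercept per participant:
#' `logit(theta_ij) = beta[group_i, q_i] + u[participant_i]`,
#' `beta ~ N(0, prior_sd^2)`, `u ~ N(0, sigma^2)`, `sigma ~ half-N(1)`.
#' The conditional matching rates theta_0 and theta_1 per group are recovered
#' as `plogis(beta[g, q])` (the population-median participant, random
#' intercept 0).
#'
#' Convergence is assessed by split-R-hat on the fixed effects; if any
#' exceeds `rhat_limit` the chains are extended (up to `max_extensions`
#' times) before a diagnostic error is raised.
#'
#' @param counts A counts tibble from [aggregate_counts()], covering at
#'   least two groups.
#' @param prior_sd SD of the normal prior on the fixed effects.
#' @param chains,n_adapt,n_burn,n_iter MCMC settings per chain; total
#'   retained draws are `chains * n_iter`.
#' @param seed Integer seed; per-chain RNG seeds are derived from it.
#' @param rhat_limit Split-R-hat threshold for the fixed effects.
#' @param max_extensions Extra sampling rounds allowed before erroring.
#' @return An object of class `ab_fit`: `theta` (draws matrix, one column
#'   per `theta[group, q]`), `sigma` draws, `groups`, `rhat`, `n_draws`.
#' @export
fit_ab_model <- function(counts, prior_sd = 1,
                         chains = 4, n_adapt = 1000, n_burn = 2000,
                         n_iter = 2500, seed = 1,
                         rhat_limit = 1.01, max_extensions = 2) {
  groups <- sort(unique(counts$group))
  if (length(groups) < 2) {
    stop("`counts` must cover at least two groups", call. = FALSE)
  }
  parts <- sort(unique(counts$participant_id))
  dat <- list(
    succ = counts$successes,
    trials = counts$trials,
    g = match(counts$group, groups),
    q = counts$q + 1L,
    part = match(counts$participant_id, parts),
    nobs = nrow(counts),
    ngroup = length(groups),
    npart = length(parts),
    beta_prec = 1 / prior_sd^2
  )
  model_str <- "model {
  for (i in 1:nobs) {
    succ[i] ~ dbin(theta[i], trials[i])
    logit(theta[i]) <- beta[g[i], q[i]] + u[part[i]]
  }
  for (j in 1:ngroup) { for (k in 1:2) { beta[j, k] ~ dnorm(0, beta_prec) } }
  for (p in 1:npart) { u[p] ~ dnorm(0, tau) }
  sigma ~ dnorm(0, 1) T(0,)
  tau <- pow(sigma, -2)
  }"
  inits <- lapply(seq_len(chains), function(i) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (seed * 1000L + i) %% .Machine$integer.max
    )
  })
  model <- rjags::jags.model(textConnection(model_str),
    data = dat, n.chains = chains, n.adapt = n_adapt,
    inits = inits, quiet = TRUE
  )
  stats::update(model, n_burn, progress.bar = "none")
  draws <- rjags::coda.samples(model, c("beta", "sigma"), n_iter,
    progress.bar = "none"
  )
  fixed_cols <- grep("^beta", coda::varnames(draws), value = TRUE)
  rhat <- split_rhat(draws, fixed_cols)
  ext <- 0
  while (max(rhat) >= rhat_limit && ext < max_extensions) {
    draws <- rjags::coda.samples(model, c("beta", "sigma"), n_iter,
      progress.bar = "none"
    )
    rhat <- split_rhat(draws, fixed_cols)
    ext <- ext + 1
  }
  if (max(rhat) >= rhat_limit) {
    stop(
      "MCMC did not converge: max split-R-hat = ",
      sprintf("%.4f", max(rhat)), " (",
      paste(sprintf("%s=%.3f", names(rhat), rhat), collapse = ", "), ")",
      call. = FALSE
    )
  }
  mat <- as.matrix(draws)
  theta <- stats::plogis(mat[, fixed_cols, drop = FALSE])
  # beta[j,k]: j indexes groups, k = q + 1
  nice <- function(nm) {
    ij <- as.integer(strsplit(gsub("beta\\[|\\]", "", nm), ",")[[1]])
    sprintf("theta%d_%s", ij[2] - 1L, groups[ij[1]])
  }
  colnames(theta) <- vapply(fixed_cols, nice, character(1))
  structure(
    list(
      theta = theta,
      sigma = mat[, "sigma"],
      groups = groups,
      rhat = rhat,
      n_draws = nrow(mat),
      chains = chains,
      n_participants = length(parts),
      n_obs = nrow(counts)
    ),
    class = "ab_fit"
  )
}

# split-R-hat: each chain halved, potential scale reduction over the 2C parts
split_rhat <- function(mcmc_list, cols) {
  per_col <- function(col) {
    halves <- unlist(lapply(mcmc_list, function(ch) {
      x <- as.numeric(ch[, col])
      n2 <- floor(length(x) / 2)
      list(x[seq_len(n2)], x[n2 + seq_len(n2)])
    }), recursive = FALSE)
    m <- length(halves)
    n <- length(halves[[1]])
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    b <- n * stats::var(means)
    w <- mean(vars)
    sqrt(((n - 1) / n * w + b / n) / w)
  }
  out <- vapply(cols, per_col, numeric(1))
  names(out) <- cols
  out
}

#' @export
print.ab_fit <- function(x, ...) {
  cat("Bayesian binomial mixed-effects A/B fit (", x$n_draws,
    " draws, ", x$chains, " chains)\n",
    sep = ""
  )
  cat(
    "  groups:", paste(x$groups, collapse = ", "),
    "| participants:", x$n_participants, "\n"
  )
  cat("  max split-R-hat:", sprintf("%.4f", max(x$rhat)), "\n")
  est <- colMeans(x$theta)
  for (nm in names(est)) cat(sprintf("  %-22s %.3f\n", nm, est[nm]))
  invisible(x)
}

#' Evidence for a one-sided hypothesis about conditional matching rates
#'
#' Tests `theta_q(group_a) > theta_q(group_b)` on the posterior draws:
#' the estimate is the posterior mean difference, the estimation error its
#' posterior SD, the posterior probability is the fraction of draws
#' satisfying the inequality, and the evidence ratio is the posterior odds
#' `p / (1 - p)`. When every draw satisfies the hypothesis the ratio is
#' infinite and is reported as exceeding the draw count
#' (`evidence_label = "> <n_draws>"`).
#'
#' @param fit An [fit_ab_model()] object.
#' @param group_a,group_b Group labels present in the fit.
#' @param q Initial-match level, 0 or 1.
#' @return A one-row tibble: `hypothesis`, `q`, `estimate`, `est_error`,
#'   `post_prob`, `evidence_ratio`, `evidence_label`.
#' @export
hypothesis_evidence <- function(fit, group_a, group_b, q) {
  stopifnot(inherits(fit, "ab_fit"), q %in% c(0, 1))
  ca <- sprintf("theta%d_%s", q, group_a)
  cb <- sprintf("theta%d_%s", q, group_b)
  if (!all(c(ca, cb) %in% colnames(fit$theta))) {
    stop("groups not present in the fit: ", group_a, ", ", group_b,
      call. = FALSE
    )
  }
  d <- fit$theta[, ca] - fit$theta[, cb]
  p <- mean(d > 0)
  er <- p / (1 - p)
  tibble::tibble(
    hypothesis = sprintf("theta%d(%s) > theta%d(%s)", q, group_a, q, group_b),
    q = q,
    estimate = mean(d),
    est_error = stats::sd(d),
    post_prob = p,
    evidence_ratio = er,
    evidence_label = if (is.infinite(er)) {
      paste(">", fit$n_draws)
    } else {
      sprintf("%.2f", er)
    }
  )
}

#' Matching rate stratified by initial performance and AI agreement
#'
#' For each game type (pile) and each agreement stratum — whether the initial
#' guess agrees with the AI lean (`a_shown > 50` means the AI leans red) —
#' computes the empirical initial matching rate `E[Q]` and final matching
#' rate `E[Q']`. Cells with `min_count` or fewer records are omitted.
#'
#' @param records Filtered response records; attention checks are dropped.
#' @param min_count Cells with `count <= min_count` are dropped.
#' @return A tibble `a`, `r`, `agrees`, `count`, `q_rate`, `qprime_rate`.
#' @export
stratified_matching <- function(records, min_count = 10) {
  match_indicators(records) |>
    dplyr::mutate(
      agrees = (.data$initial_guess == "red") == (.data$a_shown > 50)
    ) |>
    dplyr::group_by(.data$a, .data$r, .data$agrees) |>
    dplyr::summarise(
      count = dplyr::n(),
      q_rate = mean(.data$q),
      qprime_rate = mean(.data$q_prime),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$count > min_count)
}

#' Boschloo's exact unconditional test for two binomial proportions
#'
#' Tests `p_A > p_B` (or `<`) for successes/trials pairs
#' `(successes_a, trials_a)` vs `(successes_b, trials_b)`. The ordering
#' statistic is Fisher's one-sided conditional p-value; the reported p-value
#' is the supremum over the common nuisance success probability of the
#' chance of observing an ordering statistic at least as extreme, evaluated
#' on a fine fixed grid of nuisance values. Boschloo's test is uniformly at
#' least as powerful as Fisher's exact test.
#'
#' @param successes_a,trials_a,successes_b,trials_b Nonnegative counts with
#'   `successes <= trials` and `trials > 0`.
#' @param alternative `"greater"` tests `p_A > p_B`, `"less"` tests
#'   `p_A < p_B`.
#' @param n_grid Number of nuisance-parameter grid points.
#' @return The p-value.
#' @export
boschloo_test <- function(successes_a, trials_a, successes_b, trials_b,
                          alternative = c("greater", "less"),
                          n_grid = 1001) {
  alternative <- match.arg(alternative)
  stopifnot(
    trials_a > 0, trials_b > 0,
    successes_a >= 0, successes_a <= trials_a,
    successes_b >= 0, successes_b <= trials_b
  )
  if (alternative == "less") {
    # p_A < p_B is p_B > p_A with the samples swapped
    return(boschloo_test(successes_b, trials_b, successes_a, trials_a,
      alternative = "greater", n_grid = n_grid
    ))
  }
  fp <- fisher_p_grid(trials_a, trials_b)
  f0 <- fp[successes_a + 1, successes_b + 1]
  extreme <- fp <= f0 + 1e-12
  theta <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  pa <- vapply(
    theta,
    function(th) {
      da <- stats::dbinom(0:trials_a, trials_a, th)
      db <- stats::dbinom(0:trials_b, trials_b, th)
      sum(outer(da, db) * extreme)
    },
    numeric(1)
  )
  min(1, max(pa))
}

# Fisher one-sided (greater) p-values for every (x_a, x_b) outcome:
# conditional on the success total s, P(X >= x_a), X hypergeometric.
fisher_p_grid <- function(trials_a, trials_b) {
  out <- matrix(NA_real_, trials_a + 1, trials_b + 1)
  for (xa in 0:trials_a) {
    for (xb in 0:trials_b) {
      s <- xa + xb
      out[xa + 1, xb + 1] <- stats::phyper(
        xa - 1, s, trials_a + trials_b - s, trials_a,
        lower.tail = FALSE
      )
    }
  }
  out
}
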