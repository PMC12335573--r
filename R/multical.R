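#' Configuration of the realignment (multicalibration) post-processing
#'
#' Realignment multicalibrates the AI confidence with respect to the human
#' confidence: within every human-confidence bin, AI confidence values are
#' split into `n_bins` uniform-mass (equal-count) bins and replaced by the
#' empirical mean true red fraction of the calibration instances in the bin.
#' A tiny uniform noise (bounded by `noise_high`) is added to the discrete AI
#' confidence levels, during both fitting and deployment, so the
#' uniform-mass binning is well defined on a discrete grid.
#'
#' @param n_bins Uniform-mass bins per human-confidence subspace.
#' @param noise_high Upper bound of the additive uniform tie-breaking noise.
#' @return A list of class `realignment_config`.
#' @export
realignment_config <- function(n_bins = 5,
                               noise_high = 1e-10 / (1 + 1e-10)) {
  stopifnot(n_bins >= 1, noise_high > 0, noise_high < 1e-9)
  structure(list(n_bins = as.integer(n_bins), noise_high = noise_high),
    class = "realignment_config"
  )
}

#' Fit a realignment map from calibration records
#'
#' For each human-confidence bin present in the calibration data: adds
#' seeded uniform noise in `[0, noise_high]` to the AI confidence values,
#' places bin edges at the empirical `k / n_bins` quantiles
#' (`k = 1..n_bins - 1`), and stores as the bin's output the mean *true* red
#' fraction `r` of the calibration instances in the bin (the true fraction
#' gives a lower-variance estimate than the Bernoulli outcomes at these
#' sample sizes).
#'
#' Randomness (the tie-breaking noise) comes from the session RNG; seed with
#' [set.seed()] for a bit-identical map.
#'
#' @param calib_records Calibration response records (attention checks are
#'   dropped); needs `initial_confidence`, `initial_guess`, `a`, `r`.
#' @param cfg A [realignment_config()].
#' @return An object of class `realignment_map`: per human bin the noised-
#'   confidence bin `edges`, the bin `outputs`, and `train_counts`.
#' @export
fit_realignment <- function(calib_records, cfg = realignment_config()) {
  recs <- scored_records(calib_records)
  recs$h_bin <- discretize_confidence(
    recs$initial_confidence, recs$initial_guess
  )
  subspaces <- split(recs, recs$h_bin, drop = TRUE)
  fit_one <- function(sub, h) {
    n <- nrow(sub)
    if (n < cfg$n_bins) {
      stop("human-confidence bin '", h, "' has ", n,
        " calibration records, fewer than n_bins = ", cfg$n_bins,
        call. = FALSE
      )
    }
    a_noised <- sub$a + stats::runif(n, 0, cfg$noise_high)
    edges <- stats::quantile(a_noised,
      probs = seq_len(cfg$n_bins - 1) / cfg$n_bins,
      names = FALSE, type = 7
    )
    bin <- findInterval(a_noised, edges) + 1L
    outputs <- vapply(
      seq_len(cfg$n_bins),
      function(b) mean(sub$r[bin == b]), numeric(1)
    )
    counts <- tabulate(bin, nbins = cfg$n_bins)
    if (anyNA(outputs)) {
      stop("empty uniform-mass bin in human-confidence bin '", h,
        "'; reduce n_bins or provide more calibration data",
        call. = FALSE
      )
    }
    list(edges = edges, outputs = outputs, train_counts = counts)
  }
  hs <- names(subspaces)
  map <- purrr::map2(subspaces, hs, fit_one)
  structure(list(h_bins = map, config = cfg), class = "realignment_map")
}

#' Apply a realignment map to new game instances
#'
#' Adds fresh deployment noise to the AI confidence, locates its uniform-mass
#' bin within the instance's human-confidence subspace (bins are left-closed,
#' right-open; values beyond the extreme edges clamp to the first/last bin),
#' and returns the bin's stored output — the realigned AI confidence.
#'
#' @param map A fitted [fit_realignment()] map.
#' @param h Human-confidence bin(s), as from [discretize_confidence()].
#' @param a AI confidence value(s), same length as `h`.
#' @return Numeric vector of realigned confidences in `[0, 1]`.
#' @export
apply_realignment <- function(map, h, a) {
  stopifnot(inherits(map, "realignment_map"), length(h) == length(a))
  h <- as.character(h)
  missing <- setdiff(unique(h), names(map$h_bins))
  if (length(missing) > 0) {
    stop("human-confidence bin(s) absent from the fitted map: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  a_noised <- a + stats::runif(length(a), 0, map$config$noise_high)
  out <- numeric(length(a))
  for (hb in unique(h)) {
    sel <- h == hb
    sub <- map$h_bins[[hb]]
    bin <- findInterval(a_noised[sel], sub$edges) + 1L
    out[sel] <- sub$outputs[bin]
  }
  out
}

#' Serialize / read a realignment map as JSON
#'
#' @param map A `realignment_map`.
#' @param path File path.
#' @return `write_realignment_map()` returns `path` invisibly;
#'   `read_realignment_map()` returns the `realignment_map`.
#' @export
write_realignment_map <- function(map, path) {
  stopifnot(inherits(map, "realignment_map"))
  payload <- list(
    h_bins = lapply(map$h_bins, function(s) {
      list(
        edges = s$edges, outputs = s$outputs,
        train_counts = s$train_counts
      )
    }),
    config = list(
      n_bins = map$config$n_bins,
      noise_high = map$config$noise_high
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_realignment_map
#' @export
read_realignment_map <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- realignment_config(
    n_bins = payload$config$n_bins,
    noise_high = payload$config$noise_high
  )
  h_bins <- lapply(payload$h_bins, function(s) {
    list(
      edges = as.numeric(s$edges),
      outputs = as.numeric(s$outputs),
      train_counts = as.integer(s$train_counts)
    )
  })
  structure(list(h_bins = h_bins, config = cfg), class = "realignment_map")
}

#' @export
print.realignment_map <- function(x, ...) {
  cat("Realignment map (uniform-mass multicalibration)\n")
  cat("  bins per human-confidence subspace:", x$config$n_bins, "\n")
  for (h in names(x$h_bins)) {
    s <- x$h_bins[[h]]
    cat(sprintf(
      "  %-9s outputs: %s\n", h,
      paste(sprintf("%.3f", s$outputs), collapse = " ")
    ))
  }
  invisible(x)
}
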