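response_header <- function() {
  c(
    "participant_id", "group", "batch_id", "round_index",
    "a_num", "a_den", "a_shown", "r_num", "r_den", "z_count",
    "initial_confidence", "initial_guess", "final_guess",
    "outcome_is_red", "is_attention_check"
  )
}

#' Write / read response-record tables as CSV
#'
#' The on-disk schema is fixed: one record per row with columns
#' `participant_id, group, batch_id, round_index, a_num, a_den, a_shown,
#' r_num, r_den, z_count, initial_confidence, initial_guess, final_guess,
#' outcome_is_red, is_attention_check`; colors are `"red"`/`"black"`,
#' binaries 0/1. Reading validates ranges and recomputes the numeric
#' convenience columns `a`, `r` and `z` (so writing then reading reproduces
#' the records exactly).
#'
#' @param records A response-record tibble.
#' @param path CSV file path.
#' @param n_shown Shown-card count used to recompute `z` on read.
#' @return `write_responses()` returns `path` invisibly; `read_responses()`
#'   returns the record tibble.
#' @export
write_responses <- function(records, path) {
  missing <- setdiff(response_header(), names(records))
  if (length(missing) > 0) {
    stop("records lack required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- records[, response_header()]
  out$is_attention_check <- as.integer(out$is_attention_check)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, n_shown = 21) {
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      batch_id = readr::col_integer(),
      round_index = readr::col_integer(),
      a_num = readr::col_integer(),
      a_den = readr::col_integer(),
      a_shown = readr::col_integer(),
      r_num = readr::col_integer(),
      r_den = readr::col_integer(),
      z_count = readr::col_integer(),
      initial_confidence = readr::col_integer(),
      initial_guess = readr::col_character(),
      final_guess = readr::col_character(),
      outcome_is_red = readr::col_integer(),
      is_attention_check = readr::col_integer()
    )
  )
  missing <- setdiff(response_header(), names(raw))
  if (length(missing) > 0) {
    stop("response file lacks required column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  validate_records(raw)
  raw |>
    dplyr::mutate(
      is_attention_check = .data$is_attention_check == 1L,
      a = .data$a_num / .data$a_den,
      r = .data$r_num / .data$r_den,
      z = .data$z_count / n_shown
    )
}

validate_records <- function(raw) {
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0) {
      stop("invalid response record(s): ", what, " at row ",
        paste(utils::head(rows, 5), collapse = ", "),
        call. = FALSE
      )
    }
  }
  bad(
    raw$initial_confidence < 0 | raw$initial_confidence > 100,
    "initial_confidence outside [0, 100]"
  )
  bad(raw$a_shown < 0 | raw$a_shown > 100, "a_shown outside [0, 100]")
  bad(
    !raw$initial_guess %in% c("red", "black"),
    "initial_guess not red/black"
  )
  bad(!raw$final_guess %in% c("red", "black"), "final_guess not red/black")
  bad(!raw$outcome_is_red %in% c(0L, 1L), "outcome_is_red not 0/1")
  bad(
    !raw$is_attention_check %in% c(0L, 1L),
    "is_attention_check not 0/1"
  )
  invisible(TRUE)
}

#' Adapt an externally released study dataset to the internal schema
#'
#' Maps a deposited per-game response table onto the internal record schema.
#' The mapping is declared, not guessed: `mapping$columns` is a named
#' character vector from internal column names to source column names, and
#' `mapping$group_labels` is a named character vector from source group
#' labels to the internal labels (`toward`, `away`, `unbiased`, `realigned`,
#' `calibration`). Adapted records are range-validated like
#' [read_responses()] output.
#'
#' @param path CSV file with the released per-game records.
#' @param mapping A list with elements `columns` and `group_labels`; an
#'   optional `n_shown` (default 21) for recomputing `z`.
#' @return A response-record tibble in the internal schema.
#' @export
adapt_released_dataset <- function(path, mapping) {
  required <- response_header()
  cols <- mapping$columns
  missing <- setdiff(required, names(cols))
  if (length(missing) > 0) {
    stop("mapping does not name source column(s) for: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  src <- readr::read_csv(path, show_col_types = FALSE)
  absent <- setdiff(unname(cols), names(src))
  if (length(absent) > 0) {
    stop("source file lacks mapped column(s): ",
      paste(absent, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(stats::setNames(src[, unname(cols)], names(cols)))
  labels <- mapping$group_labels
  if (!is.null(labels)) {
    unknown <- setdiff(unique(out$group), names(labels))
    if (length(unknown) > 0) {
      stop("unmapped group label(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    out$group <- unname(labels[out$group])
  }
  if (!all(out$group %in% study_groups())) {
    stop("group labels must map onto: ",
      paste(study_groups(), collapse = ", "),
      call. = FALSE
    )
  }
  out <- dplyr::mutate(out,
    dplyr::across(
      c(
        "batch_id", "round_index", "a_num", "a_den", "a_shown",
        "r_num", "r_den", "z_count", "initial_confidence",
        "outcome_is_red"
      ),
      as.integer
    ),
    is_attention_check = as.integer(.data$is_attention_check)
  )
  validate_records(out)
  n_shown <- mapping$n_shown %||% 21
  dplyr::mutate(out,
    is_attention_check = .data$is_attention_check == 1L,
    a = .data$a_num / .data$a_den,
    r = .data$r_num / .data$r_den,
    z = .data$z_count / n_shown
  )
}

#' Write / read game batches as JSON
#'
#' @param batches A batch tibble from [build_batches()].
#' @param path JSON file path.
#' @return `write_batches()` returns `path` invisibly; `read_batches()`
#'   returns the batch tibble.
#' @export
write_batches <- function(batches, path) {
  jsonlite::write_json(batches, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_batches
#' @export
read_batches <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE)) |>
    dplyr::mutate(dplyr::across(
      c("batch_id", "round_index", "a_num", "a_den", "r_num", "r_den",
        "z_count"),
      as.integer
    ))
}
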