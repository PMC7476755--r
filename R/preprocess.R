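#' Trial-table CSV schema
#'
#' The canonical on-disk format is a UTF-8, comma-separated file with a
#' header and one row per trial, columns exactly:
#' `participant_id`, `group`, `experiment`, `modality_left`,
#' `modality_right`, `soa_side` (signed ms, negative = left side first),
#' `response_side` (`left`/`right`), `rt` (ms, may be empty on
#' experimenter-entered rows), `experimenter_entered` (logical), `block`.
#'
#' @name trial-schema
#' @keywords internal
NULL

trial_columns <- c(
  "participant_id", "group", "experiment", "modality_left", "modality_right",
  "soa_side", "response_side", "rt", "experimenter_entered", "block"
)

modality_levels <- c("visual", "auditory", "tactile")

#' Validate a trial table
#'
#' Checks column presence and types, modality and response labels, RT
#' missingness, and that every `|soa_side|` belongs to the design SOA set.
#' Violations are collected and reported together, with row numbers.
#'
#' @param trials A data frame following the trial schema.
#' @param soa_set Allowed absolute SOA magnitudes (ms).
#' @return The validated table, invisibly as a tibble.
#' @export
validate_trials <- function(trials, soa_set = c(30, 90, 135, 400)) {
  if (nrow(trials) == 0) stop("trial table is empty")
  missing_cols <- setdiff(trial_columns, names(trials))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  problems <- character()
  offend <- function(bad, what) {
    if (any(bad)) {
      rows <- which(bad)
      problems <<- c(problems, sprintf(
        "%s in row(s) %s", what,
        paste(head(rows, 5), collapse = ", ")
      ))
    }
  }
  offend(!trials$modality_left %in% modality_levels, "unknown modality_left")
  offend(!trials$modality_right %in% modality_levels, "unknown modality_right")
  offend(!trials$response_side %in% c("left", "right"), "invalid response_side")
  offend(!abs(trials$soa_side) %in% soa_set, sprintf(
    "soa_side outside the design set +/-{%s}", paste(soa_set, collapse = ",")
  ))
  offend(is.na(trials$rt) & !trials$experimenter_entered,
         "missing rt on a non-experimenter row")
  offend(!is.na(trials$rt) & trials$rt < 0, "negative rt")
  if (length(problems)) {
    stop("trial table validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  invisible(tibble::as_tibble(trials))
}

#' Read a trial CSV
#'
#' Reads and validates a trial table in the canonical schema (see
#' [validate_trials()] for the checks performed).
#'
#' @param path Path to a CSV file.
#' @param soa_set Allowed absolute SOA magnitudes.
#' @return A validated tibble.
#' @export
load_trials <- function(path, soa_set = c(30, 90, 135, 400)) {
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      group = readr::col_character(),
      experiment = readr::col_character(),
      modality_left = readr::col_character(),
      modality_right = readr::col_character(),
      soa_side = readr::col_double(),
      response_side = readr::col_character(),
      rt = readr::col_double(),
      experimenter_entered = readr::col_logical(),
      block = readr::col_integer()
    )
  )
  validate_trials(trials, soa_set = soa_set)
  trials
}

#' Write a trial table to CSV
#'
#' @param trials A trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' Exclude trials by reaction time
#'
#' Applies the two RT exclusion rules per participant (and per experiment,
#' when a participant was tested in both): first, trials with RT shorter
#' than `fast_ms` are removed; then trials with RT more than `outlier_sd`
#' standard deviations above that participant's mean RT are removed, with
#' the mean and (n-1) SD computed over the participant's remaining
#' non-experimenter trials pooled across conditions. Experimenter-entered
#' responses are never filtered. Thresholds are computed once, on the raw
#' data: re-running the filter on its own output removes nothing further.
#'
#' @param trials A validated trial table.
#' @param fast_ms Fast-RT cutoff in ms (default 100).
#' @param outlier_sd Upper cutoff in SDs above the participant mean
#'   (default 2.5).
#' @return An object of class `toj_filter_result`: list with `retained` and
#'   `excluded` tibbles (the latter with a `reason` column among
#'   `rt_missing`, `rt_too_fast`, `rt_outlier`), `exclusion_fraction`
#'   (over non-experimenter rows), and a `summary` list.
#' @examples
#' tr <- simulate_participant(observer_params(), toj_design(), seed = 1)
#' f <- filter_trials(tr)
#' f$exclusion_fraction
#' @export
filter_trials <- function(trials, fast_ms = 100, outlier_sd = 2.5) {
  stopifnot(fast_ms > 0, outlier_sd > 0)
  trials <- tibble::as_tibble(trials)
  n0 <- nrow(trials)
  trials$.row <- seq_len(n0)
  reason <- rep(NA_character_, n0)

  exempt <- trials$experimenter_entered
  reason[!exempt & is.na(trials$rt)] <- "rt_missing"
  reason[!exempt & !is.na(trials$rt) & trials$rt < fast_ms] <- "rt_too_fast"

  key <- paste(trials$participant_id, trials$experiment, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k & !exempt & is.na(reason))
    rts <- trials$rt[idx]
    if (length(rts) < 2) {
      if (length(idx)) {
        warning("participant ", trials$participant_id[idx[1]],
                ": fewer than 2 usable RTs; outlier rule skipped")
      }
      next
    }
    cutoff <- mean(rts) + outlier_sd * sd(rts)
    reason[idx[rts > cutoff]] <- "rt_outlier"
  }

  excluded <- trials[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  retained <- trials[is.na(reason), , drop = FALSE]
  retained$.row <- NULL
  excluded$.row <- NULL
  n_nonexp <- sum(!exempt)
  res <- list(
    retained = retained,
    excluded = excluded,
    exclusion_fraction = if (n_nonexp) nrow(excluded) / n_nonexp else 0,
    summary = list(
      n_input = n0,
      n_excluded_missing = sum(excluded$reason == "rt_missing"),
      n_excluded_fast = sum(excluded$reason == "rt_too_fast"),
      n_excluded_outlier = sum(excluded$reason == "rt_outlier"),
      exclusion_fraction = if (n_nonexp) nrow(excluded) / n_nonexp else 0
    )
  )
  class(res) <- "toj_filter_result"
  res
}

#' @export
print.toj_filter_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "RT filter: %d trials in, %d excluded (%.1f%% of non-experimenter rows: %d fast, %d outlier, %d missing)\n",
    s$n_input, nrow(x$excluded), 100 * s$exclusion_fraction,
    s$n_excluded_fast, s$n_excluded_outlier, s$n_excluded_missing
  ))
  invisible(x)
}

#' Export a filter result
#'
#' Writes the retained and excluded trials as two CSVs plus a JSON summary.
#'
#' @param x A `toj_filter_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_filter_result <- function(x, dir) {
  stopifnot(inherits(x, "toj_filter_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(x$retained, file.path(dir, "trials_retained.csv"))
  readr::write_csv(x$excluded, file.path(dir, "trials_excluded.csv"))
  jsonlite::write_json(x$summary, file.path(dir, "filter_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Recode side responses into analysis variables
#'
#' Adds the derived columns the analysis works with:
#' * `condition` -- `"bimodal"` for cross-modal rows, else
#'   `"visual-visual"`, `"auditory-auditory"`, `"tactile-tactile"`;
#' * `right_first` -- 1 if the response was `right`;
#' * `correct` -- 1 if the reported side matches the sign of `soa_side`;
#' * `soa_visual` -- bimodal rows only: the SOA re-signed so that positive
#'   means the visual stimulus came first (`soa_side` if the visual stimulus
#'   was on the right, `-soa_side` otherwise);
#' * `visual_first` -- bimodal rows only: 1 if the reported side carried the
#'   visual stimulus.
#'
#' @param trials A validated trial table.
#' @return The input tibble with the derived columns appended; `soa_visual`
#'   and `visual_first` are `NA` on unimodal rows.
#' @export
recode_trials <- function(trials) {
  trials <- tibble::as_tibble(trials)
  bimodal <- trials$modality_left != trials$modality_right
  if (any(bimodal & !(trials$modality_left == "visual" |
                        trials$modality_right == "visual"))) {
    stop("bimodal rows must include a visual stimulus")
  }
  trials$condition <- ifelse(
    bimodal, "bimodal",
    paste(trials$modality_left, trials$modality_right, sep = "-")
  )
  trials$right_first <- as.integer(trials$response_side == "right")
  trials$correct <- as.integer(
    (trials$soa_side > 0) == (trials$response_side == "right")
  )
  visual_right <- trials$modality_right == "visual"
  trials$soa_visual <- ifelse(
    bimodal, ifelse(visual_right, trials$soa_side, -trials$soa_side), NA_real_
  )
  trials$visual_first <- ifelse(
    bimodal,
    as.integer((trials$response_side == "right") == visual_right),
    NA_integer_
  )
  trials
}
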