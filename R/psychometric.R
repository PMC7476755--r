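#' Probit-transformed response proportions per SOA
#'
#' Aggregates binary responses per SOA level and applies the probit
#' (inverse-normal) transform, after clamping each proportion into
#' `[1/(2n), 1 - 1/(2n)]` (n = trials at that SOA) so that perfect
#' performance still yields a finite probit.
#'
#' @param trials Recoded trials (see [recode_trials()]), already restricted
#'   to the rows of interest (e.g. one participant's bimodal trials, or one
#'   unimodal condition).
#' @param coding `"visual_first"` (response = `visual_first`, SOA =
#'   `soa_visual`; bimodal rows only) or `"right_first"` (response =
#'   `right_first`, SOA = `soa_side`).
#' @return A tibble of class `toj_probit_points` with columns `soa`,
#'   `n_trials`, `k_first`, `proportion`, `probit`.
#' @examples
#' tr <- recode_trials(simulate_participant(observer_params(), toj_design(), 1))
#' probit_points(dplyr::filter(tr, condition == "bimodal"))
#' @export
probit_points <- function(trials, coding = c("visual_first", "right_first")) {
  coding <- match.arg(coding)
  if (coding == "visual_first") {
    trials <- trials[trials$condition == "bimodal", , drop = FALSE]
    soa <- trials$soa_visual
    y <- trials$visual_first
  } else {
    soa <- trials$soa_side
    y <- trials$right_first
  }
  ok <- !is.na(soa) & !is.na(y)
  soa <- soa[ok]
  y <- y[ok]
  if (length(unique(soa)) < 2) {
    stop("need at least 2 distinct SOA levels to form probit points")
  }
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(soa = soa, y = y), soa),
    n_trials = dplyr::n(), k_first = sum(y), .groups = "drop"
  )
  agg$proportion <- agg$k_first / agg$n_trials
  clamped <- pmin(pmax(agg$proportion, 1 / (2 * agg$n_trials)),
                  1 - 1 / (2 * agg$n_trials))
  agg$probit <- qnorm(clamped)
  agg <- agg[order(agg$soa), ]
  structure(agg, class = c("toj_probit_points", class(agg)),
            coding = coding)
}

#' Proportion correct by absolute SOA
#'
#' Pools both signs of each SOA magnitude; used by the asymptote rule of
#' [fit_probit_line()].
#'
#' @param trials Recoded trials restricted to the rows of interest.
#' @return A tibble with `abs_soa` and `prop_correct`.
#' @export
accuracy_by_abs_soa <- function(trials) {
  dplyr::summarise(
    dplyr::group_by(tibble::tibble(abs_soa = abs(trials$soa_side),
                                   correct = trials$correct), abs_soa),
    prop_correct = mean(correct), .groups = "drop"
  )
}

#' Fit the probit line and derive PSS and JND
#'
#' Ordinary (unweighted) least squares of the probit-transformed response
#' proportions on SOA. Before fitting, the asymptote rule is applied: if
#' performance (pooled proportion correct) at the longest |SOA| has not
#' improved over the second-longest |SOA|, both points at the longest |SOA|
#' are dropped, since a saturated tail only flattens the line. The PSS is
#' the zero crossing of the line, `-intercept/slope`, clipped into
#' `[-pss_bound, +pss_bound]`; the JND is the SOA at which the line predicts
#' 75% correct order reports, `qnorm(0.75)/slope`.
#'
#' @param points A [probit_points()] table.
#' @param accuracy Optional output of [accuracy_by_abs_soa()] on the same
#'   trials; if `NULL`, the asymptote rule is skipped.
#' @param asymptote_rule `"lte"` (default) drops the longest |SOA| whenever
#'   accuracy there is less than or equal to accuracy at the second-longest;
#'   `"eq"` only on exact equality; `"never"` disables the rule.
#' @param pss_bound Bound (ms) applied to the PSS by clipping (default 150).
#' @return An object of class `toj_psychometric_fit`: a one-row tibble with
#'   `slope`, `intercept`, `pss_raw`, `pss`, `pss_bounded`, `jnd`,
#'   `dropped_longest`, `n_trials_used`, `identifiable`, `coding`, plus the
#'   SOAs used as an attribute. A non-positive slope is flagged
#'   non-identifiable and PSS/JND are returned as `NA`.
#' @examples
#' pts <- tibble::tibble(soa = c(-135, -90, -30, 30, 90, 135),
#'                       n_trials = 10, k_first = 5)
#' pts$proportion <- pts$k_first / pts$n_trials
#' pts$probit <- pts$soa / 90
#' fit_probit_line(structure(pts, class = c("toj_probit_points", class(pts))))
#' @export
fit_probit_line <- function(points, accuracy = NULL,
                            asymptote_rule = c("lte", "eq", "never"),
                            pss_bound = 150) {
  asymptote_rule <- match.arg(asymptote_rule)
  stopifnot(pss_bound > 0)
  pts <- tibble::as_tibble(points)
  dropped <- FALSE
  if (!is.null(accuracy) && asymptote_rule != "never" && nrow(accuracy) >= 2) {
    acc <- accuracy[order(accuracy$abs_soa), ]
    a_top <- acc$prop_correct[nrow(acc)]
    a_2nd <- acc$prop_correct[nrow(acc) - 1]
    hit <- if (asymptote_rule == "lte") a_top <= a_2nd else a_top == a_2nd
    if (hit) {
      longest <- max(abs(pts$soa))
      pts <- pts[abs(pts$soa) < longest, , drop = FALSE]
      dropped <- TRUE
    }
  }
  if (nrow(pts) < 2) stop("fewer than 2 SOA points left to fit")
  fit <- lm(probit ~ soa, data = pts)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  identifiable <- is.finite(slope) && slope > 0
  if (identifiable) {
    pss_raw <- -intercept / slope
    pss <- min(max(pss_raw, -pss_bound), pss_bound)
    jnd <- qnorm(0.75) / slope
  } else {
    warning("non-positive slope: PSS and JND not identifiable")
    pss_raw <- pss <- jnd <- NA_real_
  }
  out <- tibble::tibble(
    slope = slope, intercept = intercept,
    pss_raw = pss_raw, pss = pss,
    pss_bounded = identifiable && !is.na(pss_raw) && abs(pss_raw) > pss_bound,
    jnd = jnd,
    dropped_longest = dropped,
    n_trials_used = sum(pts$n_trials),
    identifiable = identifiable,
    coding = attr(points, "coding") %||% NA_character_
  )
  structure(out, class = c("toj_psychometric_fit", class(out)),
            soas_used = pts$soa)
}

#' Fit one participant x condition psychometric function
#'
#' Convenience wrapper: forms the probit points and the pooled accuracy
#' profile from recoded trials and calls [fit_probit_line()].
#'
#' @inheritParams probit_points
#' @inheritParams fit_probit_line
#' @return A `toj_psychometric_fit` (see [fit_probit_line()]).
#' @export
fit_psychometric <- function(trials, coding = c("visual_first", "right_first"),
                             asymptote_rule = c("lte", "eq", "never"),
                             pss_bound = 150) {
  coding <- match.arg(coding)
  if (coding == "visual_first") {
    trials <- trials[trials$condition == "bimodal", , drop = FALSE]
  }
  pts <- probit_points(trials, coding)
  acc <- accuracy_by_abs_soa(trials)
  fit_probit_line(pts, acc, asymptote_rule = asymptote_rule,
                  pss_bound = pss_bound)
}

#' Per-participant behavioural summary
#'
#' Computes, from one participant's retained and recoded trials, the
#' proportion correct per modality condition, the overall proportion of
#' 'visual first' responses across all bimodal trials (the criterion-like
#' bias measure, robust to outliers along the psychometric function), and
#' the bias size `|p_visual_first - 0.5|`.
#'
#' @param trials One participant's recoded, filtered trials.
#' @return A list with `accuracy` (tibble: condition, n, proportion_correct),
#'   `p_visual_first`, and `bias`.
#' @export
summarize_participant <- function(trials) {
  acc <- dplyr::summarise(
    dplyr::group_by(trials, .data$condition),
    n = dplyr::n(), proportion_correct = mean(.data$correct),
    .groups = "drop"
  )
  bi <- trials$visual_first[trials$condition == "bimodal"]
  p_vf <- if (length(bi)) mean(bi) else NA_real_
  if (!length(bi)) warning("no bimodal trials: p_visual_first missing")
  list(
    accuracy = acc,
    p_visual_first = p_vf,
    bias = if (is.na(p_vf)) NA_real_ else abs(p_vf - 0.5)
  )
}

#' Summary table for many participants
#'
#' Applies [summarize_participant()] and [fit_psychometric()] per
#' participant and binds the results into one table.
#'
#' @param trials Recoded, filtered trials for any number of participants.
#' @inheritParams fit_probit_line
#' @return A tibble, one row per participant, with group, bimodal PSS/JND
#'   and fit diagnostics, `p_visual_first`, `bias`, and per-condition
#'   accuracy spread into columns `accuracy_<condition>`.
#' @export
summarize_participants <- function(trials, asymptote_rule = "lte",
                                   pss_bound = 150) {
  parts <- split(trials, trials$participant_id)
  rows <- lapply(parts, function(tr) {
    s <- summarize_participant(tr)
    fit <- tryCatch(
      suppressWarnings(fit_psychometric(tr, "visual_first",
                                        asymptote_rule = asymptote_rule,
                                        pss_bound = pss_bound)),
      error = function(e) NULL
    )
    acc <- tidyr::pivot_wider(
      s$accuracy[, c("condition", "proportion_correct")],
      names_from = "condition", values_from = "proportion_correct",
      names_prefix = "accuracy_"
    )
    base <- tibble::tibble(
      participant_id = tr$participant_id[1],
      group = tr$group[1],
      experiment = tr$experiment[1],
      n_trials = nrow(tr),
      p_visual_first = s$p_visual_first,
      bias = s$bias,
      slope = if (is.null(fit)) NA_real_ else fit$slope,
      pss_raw = if (is.null(fit)) NA_real_ else fit$pss_raw,
      pss = if (is.null(fit)) NA_real_ else fit$pss,
      pss_bounded = if (is.null(fit)) NA else fit$pss_bounded,
      jnd = if (is.null(fit)) NA_real_ else fit$jnd,
      dropped_longest = if (is.null(fit)) NA else fit$dropped_longest,
      identifiable = if (is.null(fit)) FALSE else fit$identifiable
    )
    dplyr::bind_cols(base, acc)
  })
  dplyr::bind_rows(rows)
}

#' @importFrom rlang .data
NULL
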