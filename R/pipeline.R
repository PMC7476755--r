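#' Default synthetic study specification
#'
#' A four-group study mirroring the sample structure of a sight-recovery
#' TOJ experiment: a congenital-cataract group (CC, n = 10) and a
#' developmental-cataract group (DC, n = 9), each with an age-matched
#' sighted control group (MCC n = 10, MDC n = 9), all run on the full
#' 32-cell x 10-repetition design. Generative parameters reproduce the
#' qualitative result pattern (CC negative mean PSS -- vision perceived
#' as earlier; controls and DC positive mean PSS; poorer resolution and a
#' higher lapse rate in the cataract groups); see the methods vignette for
#' the rationale behind each value.
#'
#' @param experiment `"visual-auditory"` or `"visual-tactile"` (sets the
#'   non-visual modality of the design).
#' @return A [study_spec()].
#' @export
default_study_spec <- function(experiment = c("visual-auditory",
                                              "visual-tactile")) {
  experiment <- match.arg(experiment)
  other <- sub("visual-", "", experiment)
  design <- toj_design(modalities = c("visual", other))
  study_spec(
    groups = list(
      group_spec("CC", 10, pss_mean = -40, pss_sd = 50,
                 sigma_mean = 150, sigma_sd = 40, lapse = 0.05,
                 unimodal_sigma = 120),
      group_spec("MCC", 10, pss_mean = 40, pss_sd = 40,
                 sigma_mean = 80, sigma_sd = 25, lapse = 0.02,
                 unimodal_sigma = 70),
      group_spec("DC", 9, pss_mean = 70, pss_sd = 60,
                 sigma_mean = 170, sigma_sd = 50, lapse = 0.05,
                 unimodal_sigma = 120),
      group_spec("MDC", 9, pss_mean = 35, pss_sd = 40,
                 sigma_mean = 80, sigma_sd = 25, lapse = 0.02,
                 unimodal_sigma = 70)
    ),
    design = design,
    fraction_experimenter_entered = 0.05,
    completion_rate = 0.97
  )
}

#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline. The defaults are the
#' standard analysis constants: 100 ms fast-RT cutoff, 2.5 SD RT outlier
#' cutoff, +/-150 ms PSS bound, 75% JND criterion (implied by the probit
#' line), 2.5 SD leverage exclusion for the bias-resolution correlation.
#'
#' @param mode `"simulate"` (generate data from `study`) or `"load"`
#'   (read trial CSVs from `paths`).
#' @param study A [study_spec()] (simulate mode).
#' @param paths Character vector of trial CSV paths (load mode).
#' @param fast_ms,outlier_sd RT exclusion thresholds ([filter_trials()]).
#' @param pss_bound PSS clipping bound in ms.
#' @param asymptote_rule Asymptote rule variant ([fit_probit_line()]).
#' @param n_perm Monte-Carlo permutation count.
#' @param seed Master seed for every stochastic step.
#' @param tails_planned Tails for the planned, directional comparisons
#'   (group PSS vs zero, cataract group vs matched control); default one.
#' @param tails_other Tails for the remaining tests; default two.
#' @param link,nagq GLMM link and quadrature nodes ([fit_binomial_glmm()]).
#' @param corr_exclusion_sd Leverage cutoff for
#'   [bias_accuracy_correlation()].
#' @param control_pairs Named character vector mapping each experimental
#'   group to its matched control group; only these pairs are ever
#'   compared directly.
#' @return A `toj_config` list.
#' @export
toj_config <- function(mode = c("simulate", "load"),
                       study = default_study_spec(), paths = NULL,
                       fast_ms = 100, outlier_sd = 2.5, pss_bound = 150,
                       asymptote_rule = "lte",
                       n_perm = 10000, seed = 1,
                       tails_planned = "one", tails_other = "two",
                       link = "logit", nagq = 15,
                       corr_exclusion_sd = 2.5,
                       control_pairs = c(CC = "MCC", DC = "MDC")) {
  mode <- match.arg(mode)
  stopifnot(fast_ms > 0, outlier_sd > 0, pss_bound > 0, n_perm > 0,
            corr_exclusion_sd > 0, nagq >= 1)
  if (mode == "load" && is.null(paths)) stop("load mode requires paths")
  structure(
    list(
      mode = mode, study = study, paths = paths,
      fast_ms = fast_ms, outlier_sd = outlier_sd, pss_bound = pss_bound,
      asymptote_rule = asymptote_rule,
      n_perm = n_perm, seed = as.integer(seed),
      tails_planned = tails_planned, tails_other = tails_other,
      link = link, nagq = nagq, corr_exclusion_sd = corr_exclusion_sd,
      control_pairs = control_pairs
    ),
    class = "toj_config"
  )
}

test_row <- function(id, t) {
  tibble::tibble(
    test_id = id, method = t$method, statistic = t$statistic,
    df1 = t$df[1], df2 = if (length(t$df) > 1) t$df[2] else NA_real_,
    p_perm = t$p_perm, tails = t$tails, n_perm = t$n_perm,
    exhaustive = t$exhaustive, r_equiv = t$r_equiv,
    seed = t$seed, note = t$note %||% NA_character_
  )
}

# Fit the per-group 'response probability vs chance' LRT: intercept-present
# vs intercept-fixed-at-zero random-intercept model, on the logit scale
# (0 = probability 0.5).
glmm_vs_chance <- function(trials, response, link, nagq) {
  full <- fit_binomial_glmm(trials, response, ~1, link = link, nagq = nagq)
  reduced <- fit_binomial_glmm(trials, response, ~0, link = link, nagq = nagq)
  lrt_group_effect(full, reduced,
                   r_equiv_df = full$n_participants - 1)
}

#' Run the full TOJ analysis pipeline
#'
#' Executes the stages in order: obtain trials (simulate or load), RT
#' filtering, response recoding, per-participant psychometric fits and
#' summaries, group-level permutation tests (each group's PSS against zero,
#' one-way ANOVA over groups, planned matched-pair comparisons), binomial
#' random-intercept GLMMs for the 'visual first' probability (per-group
#' chance tests and matched-pair likelihood-ratio tests) and for accuracy
#' (matched-pair tests across and within modality conditions), the
#' bias-resolution correlation, and the RT-peak analysis. Deterministic
#' given the configuration and its seed.
#'
#' @param config A [toj_config()].
#' @return An object of class `toj_report`: list with `participant_fits`,
#'   `group_summary`, `tests`, `rt_peaks`, `filter_summary`, `truth`
#'   (simulate mode only), and `provenance`.
#' @examples
#' \donttest{
#' cfg <- toj_config(n_perm = 500, seed = 7)
#' rep <- run_analysis(cfg)
#' rep$tests
#' }
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "toj_config"))
  truth <- NULL
  if (config$mode == "simulate") {
    sim <- simulate_study(config$study, seed = config$seed)
    trials <- sim$trials
    truth <- sim$truth
  } else {
    trials <- dplyr::bind_rows(lapply(config$paths, load_trials))
  }
  validate_trials(trials, soa_set = unique(abs(
    if (config$mode == "simulate") config$study$design$soas
    else trials$soa_side
  )))

  filt <- filter_trials(trials, fast_ms = config$fast_ms,
                        outlier_sd = config$outlier_sd)
  coded <- recode_trials(filt$retained)

  fits <- summarize_participants(coded,
                                 asymptote_rule = config$asymptote_rule,
                                 pss_bound = config$pss_bound)

  acc_cols <- grep("^accuracy_", names(fits), value = TRUE)
  group_summary <- dplyr::summarise(
    dplyr::group_by(fits, .data$group),
    n = dplyr::n(),
    mean_pss = mean(.data$pss, na.rm = TRUE),
    mean_p_visual_first = mean(.data$p_visual_first, na.rm = TRUE),
    mean_bias = mean(.data$bias, na.rm = TRUE),
    mean_jnd = mean(.data$jnd, na.rm = TRUE),
    dplyr::across(dplyr::all_of(acc_cols), ~mean(.x, na.rm = TRUE)),
    .groups = "drop"
  )

  tests <- list()
  groups <- unique(fits$group)
  pss_by_group <- split(fits$pss, fits$group)

  # each group's PSS against zero (directional planned test)
  for (g in groups) {
    v <- pss_by_group[[g]]
    v <- v[is.finite(v)]
    if (length(v) >= 3) {
      tests[[paste0("pss_vs_zero_", g)]] <- perm_t_one_sample(
        v, 0, tails = config$tails_planned,
        n_perm = config$n_perm, seed = derive_seed(config$seed, 11L)
      )
    }
  }

  # omnibus group effect on PSS
  usable <- lapply(pss_by_group, function(v) v[is.finite(v)])
  usable <- usable[lengths(usable) >= 2]
  if (length(usable) >= 2) {
    tests[["pss_anova"]] <- perm_anova_oneway(
      usable, n_perm = config$n_perm, seed = derive_seed(config$seed, 12L)
    )
  }

  pairs <- config$control_pairs[names(config$control_pairs) %in% groups &
                                  config$control_pairs %in% groups]
  k <- 20L
  for (g in names(pairs)) {
    ctrl <- pairs[[g]]
    pair_id <- paste0(g, "_vs_", ctrl)
    k <- k + 1L
    tests[[paste0("pss_", pair_id)]] <- perm_t_two_sample(
      usable[[g]], usable[[ctrl]], tails = config$tails_planned,
      n_perm = config$n_perm, seed = derive_seed(config$seed, k)
    )

    pair_trials <- coded[coded$group %in% c(g, ctrl), , drop = FALSE]
    bi <- pair_trials[pair_trials$condition == "bimodal", , drop = FALSE]
    # 'visual first' probability: matched-pair group effect
    full <- fit_binomial_glmm(bi, "visual_first", ~group,
                              link = config$link, nagq = config$nagq)
    reduced <- fit_binomial_glmm(bi, "visual_first", ~1,
                                 link = config$link, nagq = config$nagq)
    tests[[paste0("visual_first_", pair_id)]] <-
      lrt_group_effect(full, reduced,
                       r_equiv_df = full$n_participants - 2)
    # accuracy: group effect across modality conditions, then per condition
    full_a <- fit_binomial_glmm(pair_trials, "correct", ~group + condition,
                                link = config$link, nagq = config$nagq)
    red_a <- fit_binomial_glmm(pair_trials, "correct", ~condition,
                               link = config$link, nagq = config$nagq)
    tests[[paste0("accuracy_all_", pair_id)]] <-
      lrt_group_effect(full_a, red_a, r_equiv_df = full_a$n_participants - 2)
    for (cond in sort(unique(pair_trials$condition))) {
      sub <- pair_trials[pair_trials$condition == cond, , drop = FALSE]
      fc <- fit_binomial_glmm(sub, "correct", ~group,
                              link = config$link, nagq = config$nagq)
      rc <- fit_binomial_glmm(sub, "correct", ~1,
                              link = config$link, nagq = config$nagq)
      tests[[paste0("accuracy_", cond, "_", pair_id)]] <-
        lrt_group_effect(fc, rc, r_equiv_df = fc$n_participants - 2)
    }
  }

  # per-group 'visual first' probability against chance
  for (g in groups) {
    bi_g <- coded[coded$group == g & coded$condition == "bimodal", ,
                  drop = FALSE]
    if (length(unique(bi_g$participant_id)) >= 2) {
      tests[[paste0("visual_first_vs_chance_", g)]] <-
        glmm_vs_chance(bi_g, "visual_first", config$link, config$nagq)
    }
  }

  # bias-resolution correlation across all participants
  corr_in <- tibble::tibble(
    participant_id = fits$participant_id, group = fits$group,
    bias = fits$bias, accuracy = fits$accuracy_bimodal
  )
  tests[["bias_accuracy_correlation"]] <- tryCatch(
    bias_accuracy_correlation(
      corr_in, exclusion_sd = config$corr_exclusion_sd,
      tails = config$tails_other, n_perm = config$n_perm,
      seed = derive_seed(config$seed, 13L)
    ),
    error = function(e) NULL
  )

  # RT-peak analysis
  rt_peaks <- suppressWarnings(fit_rt_peaks(coded))
  if (nrow(rt_peaks)) {
    peaks_by_group <- split(rt_peaks, rt_peaks$group)
    k <- 40L
    for (g in names(pairs)) {
      ctrl <- pairs[[g]]
      if (!is.null(peaks_by_group[[g]]) && !is.null(peaks_by_group[[ctrl]])) {
        k <- k + 1L
        tests[[paste0("rt_peak_", g, "_vs_", ctrl)]] <- tryCatch(
          compare_rt_peaks(peaks_by_group[[g]], peaks_by_group[[ctrl]],
                           tails = config$tails_other,
                           n_perm = config$n_perm,
                           seed = derive_seed(config$seed, k)),
          error = function(e) NULL
        )
      }
    }
  }

  tests <- tests[!vapply(tests, is.null, TRUE)]
  test_table <- dplyr::bind_rows(
    lapply(names(tests), function(id) test_row(id, tests[[id]]))
  )

  structure(
    list(
      participant_fits = fits,
      group_summary = group_summary,
      tests = test_table,
      rt_peaks = rt_peaks,
      filter_summary = filt$summary,
      truth = truth,
      provenance = list(
        package = "tojkit",
        version = as.character(utils::packageVersion("tojkit")),
        seed = config$seed,
        n_perm = config$n_perm,
        link = config$link,
        nagq = config$nagq,
        thresholds = list(
          fast_ms = config$fast_ms, outlier_sd = config$outlier_sd,
          pss_bound = config$pss_bound,
          corr_exclusion_sd = config$corr_exclusion_sd
        ),
        tails = list(planned = config$tails_planned,
                     other = config$tails_other)
      )
    ),
    class = "toj_report"
  )
}

#' @export
print.toj_report <- function(x, ...) {
  cat("TOJ analysis report\n")
  cat("  participants:", nrow(x$participant_fits),
      " groups:", paste(x$group_summary$group, collapse = ", "), "\n")
  cat(sprintf("  trial exclusion fraction: %.3f\n",
              x$filter_summary$exclusion_fraction))
  cat("  tests run:", nrow(x$tests), "\n")
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Persists the report as plain-text artefacts: CSV tables for participant
#' fits, group summaries, tests and RT peaks, plus a JSON provenance block.
#'
#' @param report A `toj_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "toj_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$participant_fits,
                   file.path(dir, "participant_fits.csv"))
  readr::write_csv(report$group_summary, file.path(dir, "group_summary.csv"))
  readr::write_csv(report$tests, file.path(dir, "tests.csv"))
  if (nrow(report$rt_peaks)) {
    readr::write_csv(report$rt_peaks, file.path(dir, "rt_peaks.csv"))
  }
  if (!is.null(report$truth)) {
    readr::write_csv(report$truth, file.path(dir, "true_parameters.csv"))
  }
  jsonlite::write_json(
    c(report$provenance, list(filter_summary = report$filter_summary)),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
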