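#' Experimental design of a spatial TOJ session
#'
#' Describes the factorial trial grid of one session: the set of signed
#' stimulus onset asynchronies (SOAs), the modality presented on each side,
#' and the number of repetitions per cell. The default reproduces the
#' canonical spatial TOJ design: 2 modalities x 2 sides x 8 SOAs
#' (+/-30, +/-90, +/-135, +/-400 ms) x 10 repetitions = 320 trials in
#' 10 blocks. Negative SOAs mean the left-side stimulus came first.
#'
#' @param soas Signed SOAs in ms; must be symmetric about zero and non-zero.
#' @param reps_per_cell Repetitions of each design cell (>= 1).
#' @param modalities Two modality labels; all four ordered (left, right)
#'   assignments are crossed, so the grid contains both unimodal pairs and
#'   the bimodal pair with either side assignment.
#' @param n_blocks Number of blocks the trial sequence is divided into.
#'
#' @return An object of class `toj_design`: a list with elements `soas`,
#'   `reps_per_cell`, `modality_pairs` (data frame of left/right labels) and
#'   `n_blocks`.
#' @examples
#' d <- toj_design()
#' nrow(d$modality_pairs) * length(d$soas) * d$reps_per_cell # 320
#' @export
toj_design <- function(soas = c(-400, -135, -90, -30, 30, 90, 135, 400),
                       reps_per_cell = 10,
                       modalities = c("visual", "auditory"),
                       n_blocks = 10) {
  soas <- sort(unique(as.double(soas)))
  if (any(soas == 0)) stop("SOAs must be non-zero (sign encodes which side led)")
  if (!setequal(soas, -soas)) stop("SOA set must be symmetric about 0")
  if (reps_per_cell < 1) stop("reps_per_cell must be >= 1")
  if (length(modalities) != 2L || anyDuplicated(modalities)) {
    stop("modalities must be two distinct labels")
  }
  pairs <- expand.grid(
    modality_left = modalities, modality_right = modalities,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      soas = soas, reps_per_cell = as.integer(reps_per_cell),
      modality_pairs = pairs, n_blocks = as.integer(n_blocks)
    ),
    class = "toj_design"
  )
}

#' @export
print.toj_design <- function(x, ...) {
  n <- nrow(x$modality_pairs) * length(x$soas) * x$reps_per_cell
  cat(
    "TOJ design:", nrow(x$modality_pairs), "modality pairs x",
    length(x$soas), "SOAs x", x$reps_per_cell, "reps =", n, "trials in",
    x$n_blocks, "blocks\n"
  )
  invisible(x)
}

#' Generative parameters of one synthetic observer
#'
#' A synthetic observer responds to bimodal trials through a
#' cumulative-Gaussian psychometric function of the visual-first SOA with a
#' symmetric lapse rate, and to unimodal trials through the analogous
#' right-first function centred at zero. Reaction times follow a Gaussian
#' bump peaking at the observer's PSS (uncertainty, and hence response time,
#' is maximal where the order is hardest to tell).
#'
#' @param pss Point of subjective simultaneity in ms; positive means the
#'   visual stimulus must lead to be perceived as simultaneous.
#' @param sigma SD (ms) of the cumulative-Gaussian psychometric on bimodal
#'   trials; must be > 0. Smaller sigma = better temporal resolution.
#' @param lapse Probability of a stimulus-independent guess, split evenly
#'   between the two responses (lambda/2 on each asymptote).
#' @param rt_baseline,rt_amplitude,rt_width,rt_noise_sd Reaction-time model:
#'   mean RT on a bimodal trial is
#'   `rt_baseline + rt_amplitude * exp(-(soa - pss)^2 / (2 * rt_width^2))`
#'   plus Gaussian noise with SD `rt_noise_sd`; unimodal RTs use the baseline
#'   only. All in ms; `rt_baseline + rt_amplitude` must be >= 100 so that
#'   not every trial falls below the fast-RT exclusion cutoff.
#' @param unimodal_sigma SD (ms) of the right-first psychometric on unimodal
#'   trials, a single value or a named vector per modality.
#'
#' @return An object of class `observer_params`.
#' @examples
#' p <- observer_params(pss = -30, sigma = 90)
#' p_first(0, p) # below 0.5: at physical simultaneity vision seems first
#' @export
observer_params <- function(pss = 0, sigma = 90, lapse = 0.02,
                            rt_baseline = 450, rt_amplitude = 150,
                            rt_width = 150, rt_noise_sd = 100,
                            unimodal_sigma = 90) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (lapse < 0 || lapse > 1) stop("lapse must be in [0, 1]")
  if (rt_width <= 0) stop("rt_width must be > 0")
  if (rt_noise_sd < 0) stop("rt_noise_sd must be >= 0")
  if (rt_baseline + rt_amplitude < 100) {
    stop("rt_baseline + rt_amplitude must be >= 100 ms")
  }
  if (any(unimodal_sigma <= 0)) stop("unimodal_sigma must be > 0")
  structure(
    list(
      pss = pss, sigma = sigma, lapse = lapse,
      rt_baseline = rt_baseline, rt_amplitude = rt_amplitude,
      rt_width = rt_width, rt_noise_sd = rt_noise_sd,
      unimodal_sigma = unimodal_sigma
    ),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "Synthetic TOJ observer: PSS %.1f ms, sigma %.1f ms, lapse %.3f\n",
    x$pss, x$sigma, x$lapse
  ))
  invisible(x)
}

#' Probability of a 'visual first' response
#'
#' The psychometric function of a synthetic observer on bimodal trials:
#' `P = lapse/2 + (1 - lapse) * pnorm((soa - pss) / sigma)`, where `soa` is
#' the visual-first SOA (positive = visual stimulus physically first).
#'
#' @param soa Signed SOA in ms, positive = visual first; vectorised.
#' @param params An [observer_params()] object.
#' @return Probability of a 'visual first' response, in
#'   `[lapse/2, 1 - lapse/2]`.
#' @examples
#' p_first(90, observer_params(pss = 0, sigma = 90, lapse = 0)) # pnorm(1)
#' @export
p_first <- function(soa, params) {
  stopifnot(inherits(params, "observer_params"))
  params$lapse / 2 + (1 - params$lapse) * pnorm((soa - params$pss) / params$sigma)
}

# Right-first response probability on unimodal trials: same functional form,
# PSS fixed at 0, modality-specific sigma.
p_right_first_unimodal <- function(soa_side, modality, params) {
  s <- params$unimodal_sigma
  sig <- if (!is.null(names(s)) && modality %in% names(s)) s[[modality]] else s[[1]]
  params$lapse / 2 + (1 - params$lapse) * pnorm(soa_side / sig)
}

#' Simulate one observer's TOJ session
#'
#' Builds the full trial grid of `design`, draws responses from the
#' observer's psychometric functions (Bernoulli per trial) and reaction
#' times from the Gaussian-bump RT model, and assigns trials to blocks in a
#' shuffled order. The same `params`, `design` and `seed` always reproduce
#' the identical table; the caller's RNG state is untouched.
#'
#' @param params An [observer_params()] object.
#' @param design A [toj_design()] object.
#' @param seed Integer seed for this participant's substream.
#' @param participant_id,group,experiment Identifier columns copied into the
#'   output. `experiment` defaults to the bimodal pairing implied by the
#'   design's modalities (e.g. "visual-auditory").
#' @return A tibble, one row per trial, with columns `participant_id`,
#'   `group`, `experiment`, `modality_left`, `modality_right`, `soa_side`
#'   (negative = left first), `response_side`, `rt` (ms; `NA` on
#'   experimenter-entered rows), `experimenter_entered`, `block`.
#' @examples
#' tr <- simulate_participant(observer_params(), toj_design(), seed = 1)
#' nrow(tr) # 320
#' @export
simulate_participant <- function(params, design, seed,
                                 participant_id = "P01", group = "other",
                                 experiment = NULL) {
  stopifnot(inherits(params, "observer_params"), inherits(design, "toj_design"))
  mods <- sort(unique(c(design$modality_pairs$modality_left,
                        design$modality_pairs$modality_right)))
  if (is.null(experiment)) {
    experiment <- if ("visual" %in% mods) {
      paste(c("visual", setdiff(mods, "visual")), collapse = "-")
    } else {
      paste(mods, collapse = "-")
    }
  }

  grid <- expand.grid(
    rep = seq_len(design$reps_per_cell),
    soa_side = design$soas,
    pair = seq_len(nrow(design$modality_pairs))
  )
  n <- nrow(grid)
  ml <- design$modality_pairs$modality_left[grid$pair]
  mr <- design$modality_pairs$modality_right[grid$pair]
  bimodal <- ml != mr

  withr::with_seed(seed, {
    # response model --------------------------------------------------------
    # bimodal: draw 'visual first' from the cumulative-Gaussian model on the
    # visual-first SOA, then map back to a side response
    visual_right <- mr == "visual"
    soa_visual <- ifelse(visual_right, grid$soa_side, -grid$soa_side)
    p_vf <- p_first(soa_visual, params)
    vf <- rbinom(n, 1L, p_vf)
    resp_bi <- ifelse(vf == 1L,
      ifelse(visual_right, "right", "left"),
      ifelse(visual_right, "left", "right")
    )
    # unimodal: right-first model centred at zero
    p_rf <- p_right_first_unimodal(grid$soa_side, ml, params)
    rf <- rbinom(n, 1L, p_rf)
    resp_uni <- ifelse(rf == 1L, "right", "left")
    response_side <- ifelse(bimodal, resp_bi, resp_uni)

    # reaction-time model ---------------------------------------------------
    mu_rt <- ifelse(
      bimodal,
      params$rt_baseline + params$rt_amplitude *
        exp(-(soa_visual - params$pss)^2 / (2 * params$rt_width^2)),
      params$rt_baseline
    )
    rt <- pmax(0, rnorm(n, mu_rt, params$rt_noise_sd))

    out <- tibble::tibble(
      participant_id = participant_id,
      group = group,
      experiment = experiment,
      modality_left = ml,
      modality_right = mr,
      soa_side = grid$soa_side,
      response_side = response_side,
      rt = rt,
      experimenter_entered = FALSE,
      block = 0L
    )
    # shuffled presentation order, split into blocks of equal size
    out <- out[sample.int(n), , drop = FALSE]
    out$block <- as.integer(ceiling(seq_len(n) / (n / design$n_blocks)))
    out
  })
}

#' Group- and study-level simulation specification
#'
#' @param label Group label (e.g. "CC", "MCC", "DC", "MDC").
#' @param n Number of participants (>= 2).
#' @param pss_mean,pss_sd Between-participant distribution of the true PSS (ms).
#' @param sigma_mean,sigma_sd Between-participant distribution of the
#'   psychometric SD (ms); draws are truncated below at 10 ms.
#' @param lapse Lapse rate shared by the group's observers.
#' @param unimodal_sigma Unimodal psychometric SD (ms) for the group.
#' @param rt_baseline,rt_amplitude,rt_width,rt_noise_sd RT model parameters
#'   shared by the group's observers (see [observer_params()]).
#' @return A `toj_group_spec` list.
#' @export
group_spec <- function(label, n, pss_mean = 0, pss_sd = 40,
                       sigma_mean = 90, sigma_sd = 30, lapse = 0.02,
                       unimodal_sigma = 90,
                       rt_baseline = 450, rt_amplitude = 150,
                       rt_width = 150, rt_noise_sd = 100) {
  if (n < 2) stop("each group needs at least 2 participants")
  if (pss_sd < 0 || sigma_sd < 0) stop("distribution SDs must be >= 0")
  structure(
    list(
      label = label, n = as.integer(n),
      pss_mean = pss_mean, pss_sd = pss_sd,
      sigma_mean = sigma_mean, sigma_sd = sigma_sd, lapse = lapse,
      unimodal_sigma = unimodal_sigma,
      rt_baseline = rt_baseline, rt_amplitude = rt_amplitude,
      rt_width = rt_width, rt_noise_sd = rt_noise_sd
    ),
    class = "toj_group_spec"
  )
}

#' @param groups List of [group_spec()] objects.
#' @param design A [toj_design()] shared by all participants.
#' @param fraction_experimenter_entered Probability that a participant's
#'   responses are entered by the experimenter (all of that participant's
#'   rows are flagged and their RTs set to missing, mirroring sessions where
#'   the participant signalled the response and the experimenter keyed it).
#' @param completion_rate Expected fraction of blocks a participant
#'   completes; each participant keeps `Binomial(n_blocks, completion_rate)`
#'   blocks (at least one), emulating sessions cut short.
#' @rdname group_spec
#' @return For `study_spec()`, a `toj_study_spec` list.
#' @export
study_spec <- function(groups, design = toj_design(),
                       fraction_experimenter_entered = 0,
                       completion_rate = 1) {
  if (inherits(groups, "toj_group_spec")) groups <- list(groups)
  stopifnot(
    all(vapply(groups, inherits, TRUE, "toj_group_spec")),
    inherits(design, "toj_design"),
    fraction_experimenter_entered >= 0, fraction_experimenter_entered <= 1,
    completion_rate > 0, completion_rate <= 1
  )
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("group labels must be unique")
  structure(
    list(
      groups = groups, design = design,
      fraction_experimenter_entered = fraction_experimenter_entered,
      completion_rate = completion_rate
    ),
    class = "toj_study_spec"
  )
}

#' Simulate a whole multi-group TOJ study
#'
#' Draws each participant's true parameters from their group's
#' between-participant distributions, simulates every session with
#' [simulate_participant()] using deterministic per-participant substreams of
#' the master seed, and applies study-level nuisance processes
#' (experimenter-entered sessions, incomplete sessions).
#'
#' @param spec A [study_spec()].
#' @param seed Master integer seed.
#' @return A list with `trials` (one tibble of all trials) and `truth`
#'   (one row per participant: group and the generative parameters), for
#'   parameter-recovery testing.
#' @examples
#' sp <- study_spec(list(
#'   group_spec("A", 3, pss_mean = -40),
#'   group_spec("B", 3, pss_mean = 40)
#' ))
#' sim <- simulate_study(sp, seed = 1)
#' table(sim$trials$group)
#' @export
simulate_study <- function(spec, seed) {
  stopifnot(inherits(spec, "toj_study_spec"))
  trials <- list()
  truth <- list()
  idx <- 0L
  for (g in spec$groups) {
    for (i in seq_len(g$n)) {
      idx <- idx + 1L
      pid <- sprintf("%s%02d", g$label, i)
      sub <- derive_seed(seed, idx)
      pars <- withr::with_seed(derive_seed(sub, 1L), {
        observer_params(
          pss = rnorm(1, g$pss_mean, g$pss_sd),
          sigma = max(10, rnorm(1, g$sigma_mean, g$sigma_sd)),
          lapse = g$lapse,
          unimodal_sigma = g$unimodal_sigma,
          rt_baseline = g$rt_baseline, rt_amplitude = g$rt_amplitude,
          rt_width = g$rt_width, rt_noise_sd = g$rt_noise_sd
        )
      })
      tr <- simulate_participant(pars, spec$design, seed = derive_seed(sub, 2L),
                                 participant_id = pid, group = g$label)
      tr <- withr::with_seed(derive_seed(sub, 3L), {
        if (spec$completion_rate < 1) {
          keep <- max(1L, rbinom(1L, spec$design$n_blocks, spec$completion_rate))
          tr <- tr[tr$block <= keep, , drop = FALSE]
        }
        if (runif(1) < spec$fraction_experimenter_entered) {
          tr$experimenter_entered <- TRUE
          tr$rt <- NA_real_
        }
        tr
      })
      trials[[idx]] <- tr
      truth[[idx]] <- tibble::tibble(
        participant_id = pid, group = g$label,
        pss = pars$pss, sigma = pars$sigma, lapse = pars$lapse,
        rt_baseline = pars$rt_baseline, rt_amplitude = pars$rt_amplitude,
        rt_width = pars$rt_width, rt_noise_sd = pars$rt_noise_sd
      )
    }
  }
  list(
    trials = dplyr::bind_rows(trials),
    truth = dplyr::bind_rows(truth)
  )
}
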