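# Shared fixtures: small designs and hand-built trial tables.

small_design <- function(reps = 3) {
  toj_design(reps_per_cell = reps, n_blocks = 1)
}

# A minimal valid trial table built by hand (no simulation), n rows.
manual_trials <- function(rt, experimenter_entered = FALSE,
                          participant_id = "P01",
                          soa_side = 90, response_side = "right") {
  n <- max(lengths(list(rt, soa_side, response_side, experimenter_entered)))
  tibble::tibble(
    participant_id = participant_id,
    group = "other",
    experiment = "visual-auditory",
    modality_left = "auditory",
    modality_right = "visual",
    soa_side = rep_len(soa_side, n),
    response_side = rep_len(response_side, n),
    rt = rep_len(rt, n),
    experimenter_entered = rep_len(experimenter_entered, n),
    block = 1L
  )
}

# Expand per-SOA binomial counts into a recoded bimodal trial table
# (visual stimulus on the right, so soa_side == soa_visual).
trials_from_counts <- function(soas, k, n) {
  dplyr::bind_rows(lapply(seq_along(soas), function(i) {
    vf <- c(rep(1L, k[i]), rep(0L, n[i] - k[i]))
    tibble::tibble(
      participant_id = "P01", group = "other",
      experiment = "visual-auditory", condition = "bimodal",
      soa_visual = soas[i], visual_first = vf,
      soa_side = soas[i],
      correct = as.integer((soas[i] > 0) == (vf == 1L)),
      right_first = vf, experimenter_entered = FALSE, rt = 500
    )
  }))
}

# Direct maximum-likelihood cumulative-Gaussian fit: the independent oracle
# for the probit-line PSS (binomial likelihood, no lapse).
ml_gaussian_pss <- function(soas, k, n) {
  nll <- function(par) {
    p <- pnorm((soas - par[1]) / exp(par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(k * log(p) + (n - k) * log(1 - p))
  }
  opt <- optim(c(0, log(90)), nll)
  c(pss = opt$par[1], sigma = exp(opt$par[2]))
}
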