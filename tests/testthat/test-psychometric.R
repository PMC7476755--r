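test_that("probit points clamp proportions and transform correctly", {
  # 5/10, 10/10, 0/10 at three SOAs
  tr <- trials_from_counts(c(-90, 30, 90), k = c(0, 5, 10), n = c(10, 10, 10))
  pts <- probit_points(tr)
  expect_equal(pts$soa, c(-90, 30, 90))
  expect_equal(pts$proportion, c(0, 0.5, 1))
  # proportion 0.5 -> probit 0; 10/10 clamped to 0.95 -> qnorm(0.95)
  expect_equal(pts$probit, c(qnorm(0.05), 0, qnorm(0.95)))
  expect_true(all(is.finite(pts$probit)))

  # near Phi(1): 8413/10000 -> probit ~ 1
  tr2 <- trials_from_counts(c(-90, 90), k = c(10000 - 8413, 8413),
                            n = c(10000, 10000))
  pts2 <- probit_points(tr2)
  expect_equal(pts2$probit[2], 1, tolerance = 1e-3)

  expect_error(probit_points(trials_from_counts(90, 5, 10)),
               "at least 2 distinct SOA")
})

test_that("the probit line recovers closed-form PSS and JND", {
  # probits exactly on z = soa / 90: slope 1/90, PSS 0, JND 0.6745 * 90
  soas <- c(-135, -90, -30, 30, 90, 135)
  pts <- structure(
    tibble::tibble(soa = soas, n_trials = 10L, k_first = 5L,
                   proportion = 0.5, probit = soas / 90),
    class = c("toj_probit_points", class(tibble::tibble())), coding = "visual_first"
  )
  fit <- fit_probit_line(pts)
  expect_equal(fit$slope, 1 / 90)
  expect_equal(fit$pss, 0)
  expect_equal(fit$jnd, qnorm(0.75) * 90)
  expect_false(fit$pss_bounded)

  # line z = (soa + 200) / 90 crosses zero at -200 -> clipped to -150
  pts$probit <- (soas + 200) / 90
  fit2 <- fit_probit_line(pts)
  expect_equal(fit2$pss_raw, -200)
  expect_equal(fit2$pss, -150)
  expect_true(fit2$pss_bounded)

  # non-positive slope: flagged, PSS and JND missing
  pts$probit <- -soas / 90
  expect_warning(fit3 <- fit_probit_line(pts), "non-positive slope")
  expect_false(fit3$identifiable)
  expect_true(is.na(fit3$pss) && is.na(fit3$jnd))
})

test_that("the asymptote rule drops the longest SOA when saturated", {
  soas <- c(-400, -135, -90, -30, 30, 90, 135, 400)
  pts <- structure(
    tibble::tibble(soa = soas, n_trials = 10L, k_first = 5L,
                   proportion = 0.5, probit = soas / 90),
    class = c("toj_probit_points", class(tibble::tibble())), coding = "visual_first"
  )
  flat <- tibble::tibble(abs_soa = c(30, 90, 135, 400),
                         prop_correct = c(0.6, 0.75, 0.9, 0.9))
  fit <- fit_probit_line(pts, flat)
  expect_true(fit$dropped_longest)
  expect_equal(max(abs(attr(fit, "soas_used"))), 135)
  expect_equal(fit$n_trials_used, 60)

  rising <- tibble::tibble(abs_soa = c(30, 90, 135, 400),
                           prop_correct = c(0.6, 0.75, 0.9, 0.95))
  fit2 <- fit_probit_line(pts, rising)
  expect_false(fit2$dropped_longest)
  expect_equal(fit2$n_trials_used, 80)

  # strict-equality variant: a drop below the second-longest does not trigger
  below <- tibble::tibble(abs_soa = c(30, 90, 135, 400),
                          prop_correct = c(0.6, 0.75, 0.9, 0.85))
  expect_true(fit_probit_line(pts, below, "lte")$dropped_longest)
  expect_false(fit_probit_line(pts, below, "eq")$dropped_longest)
  expect_false(fit_probit_line(pts, flat, "never")$dropped_longest)
})

test_that("PSS estimation is equivariant under mirroring the SOA axis", {
  tr <- recode_trials(
    simulate_participant(observer_params(pss = -45, sigma = 100),
                         toj_design(), seed = 21)
  )
  fit <- fit_psychometric(tr)
  mirrored <- tr
  mirrored$soa_visual <- -tr$soa_visual
  mirrored$visual_first <- 1L - tr$visual_first
  fit2 <- fit_psychometric(mirrored)
  expect_equal(fit2$pss_raw, -fit$pss_raw)
  expect_equal(fit2$slope, fit$slope)
})

test_that("probit-line PSS agrees with truth and the ML oracle at large n", {
  soas <- c(-400, -135, -90, -30, 30, 90, 135, 400)
  pss_true <- 10
  withr::with_seed(31, {
    k <- rbinom(8, 10000, pnorm((soas - pss_true) / 90))
  })
  tr <- trials_from_counts(soas, k, rep(10000, 8))
  fit <- fit_psychometric(tr)
  ml <- ml_gaussian_pss(soas, k, rep(10000, 8))
  expect_lt(abs(fit$pss - pss_true), 2)
  expect_lt(abs(fit$pss - ml["pss"]), 2)
})

test_that("participant summaries compute accuracy, p_visual_first and bias", {
  # perfect observer on the balanced design: accuracy 1, no bias
  pars <- observer_params(pss = 0, sigma = 1e-6, lapse = 0,
                          unimodal_sigma = 1e-6)
  co <- recode_trials(simulate_participant(pars, small_design(5), seed = 2))
  s <- summarize_participant(co)
  expect_equal(s$p_visual_first, 0.5)
  expect_equal(s$bias, 0)
  expect_true(all(s$accuracy$proportion_correct == 1))
  expect_setequal(s$accuracy$condition,
                  c("bimodal", "visual-visual", "auditory-auditory"))

  # negative PSS (vision perceived earlier) inflates 'visual first' reports
  co2 <- recode_trials(
    simulate_participant(observer_params(pss = -60, sigma = 90),
                         toj_design(), seed = 3)
  )
  s2 <- summarize_participant(co2)
  expect_gt(s2$p_visual_first, 0.5)
  expect_equal(s2$bias, abs(s2$p_visual_first - 0.5))
})

test_that("summarize_participants returns one row per participant", {
  sim <- simulate_study(
    study_spec(list(group_spec("A", 3), group_spec("B", 3)),
               design = small_design(5)),
    seed = 8
  )
  co <- recode_trials(filter_trials(sim$trials)$retained)
  fits <- summarize_participants(co)
  expect_equal(nrow(fits), 6)
  expect_true(all(fits$pss >= -150 & fits$pss <= 150, na.rm = TRUE))
  expect_true(all(c("pss", "jnd", "bias", "accuracy_bimodal") %in% names(fits)))
})
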