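test_that("one-sample permutation t matches exhaustive enumeration", {
  # all-positive values maximise t among the 16 sign patterns
  res <- perm_t_one_sample(c(1, 2, 3, 4), mu0 = 0, tails = "one")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 16)
  expect_equal(res$p_perm, 1 / 16)
  expect_equal(res$df, 3)
  expect_equal(res$statistic,
               mean(c(1, 2, 3, 4)) / (sd(c(1, 2, 3, 4)) / 2))

  # values symmetric about mu0: t = 0, two-tailed p = 1
  res2 <- perm_t_one_sample(c(-2, -1, 1, 2), mu0 = 0, tails = "two")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_perm, 1)

  # shift invariance
  v <- c(0.3, 1.2, -0.5, 2.2, 0.9)
  a <- perm_t_one_sample(v, 0, tails = "two")
  b <- perm_t_one_sample(v + 5, 5, tails = "two")
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_perm, b$p_perm)

  # degenerate: zero variance
  res3 <- perm_t_one_sample(c(3, 3, 3), 0)
  expect_true(is.na(res3$statistic))
  expect_equal(res3$p_perm, 1)
  expect_match(res3$note, "zero variance")
})

test_that("two-sample permutation t enumerates label assignments", {
  # identical multisets: t = 0, p = 1
  res <- perm_t_two_sample(c(1, 2, 3), c(3, 1, 2), tails = "two")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_perm, 1)

  # {1,2} vs {10,11}: 6 assignments, the two extreme ones tie on |t|
  res2 <- perm_t_two_sample(c(1, 2), c(10, 11), tails = "two")
  expect_true(res2$exhaustive)
  expect_equal(res2$n_perm, 6)
  expect_equal(res2$p_perm, 2 / 6)
  expect_equal(res2$df, 2)

  # swapping the groups negates t, p unchanged
  res3 <- perm_t_two_sample(c(10, 11), c(1, 2), tails = "two")
  expect_equal(res3$statistic, -res2$statistic)
  expect_equal(res3$p_perm, res2$p_perm)
})

test_that("Monte-Carlo and exhaustive permutation p agree within MC error", {
  withr::with_seed(13, {
    x <- rnorm(16, mean = 0.4) # 2^16 sign patterns: engine goes Monte-Carlo
  })
  res <- perm_t_one_sample(x, 0, tails = "two", n_perm = 4000, seed = 5)
  expect_false(res$exhaustive)

  # independent oracle: full enumeration of all 65536 sign patterns
  n <- length(x)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tstat <- function(v) mean(v) / (sd(v) / sqrt(n))
  t_all <- apply(signs * rep(x, each = nrow(signs)), 1, tstat)
  p_exact <- mean(abs(t_all) >= abs(tstat(x)) - 1e-12)
  expect_lt(abs(res$p_perm - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / 4000) + 1 / 4000)
})

test_that("one-way permutation ANOVA matches the t-test on two groups", {
  withr::with_seed(17, {
    a <- rnorm(8, 0)
    b <- rnorm(8, 1)
  })
  fa <- perm_anova_oneway(list(a, b), n_perm = 2000, seed = 3)
  tt <- perm_t_two_sample(a, b, tails = "two")
  expect_equal(fa$statistic, tt$statistic^2)
  expect_equal(fa$df, c(1, 14))

  # identical values across groups: degenerate, F = 0, p = 1
  fz <- perm_anova_oneway(list(rep(2, 4), rep(2, 4)))
  expect_equal(fz$statistic, 0)
  expect_equal(fz$p_perm, 1)
})

test_that("r_equivalent converts p and df to an effect-size correlation", {
  expect_equal(r_equivalent(0.009, 9),
               qt(0.991, 9) / sqrt(qt(0.991, 9)^2 + 9))
  # strictly decreasing in p at fixed df, bounded in [0, 1)
  ps <- seq(0.001, 0.499, length.out = 50)
  rs <- vapply(ps, r_equivalent, numeric(1), df = 9)
  expect_true(all(diff(rs) < 0))
  expect_true(all(rs > 0 & rs < 1))
  # p at or beyond 0.5: r clipped to zero
  expect_equal(suppressWarnings(r_equivalent(0.5, 9)), 0)
  expect_warning(r_equivalent(0.7, 9), "clipped")
  expect_error(r_equivalent(0, 9), "p must be")
  expect_error(r_equivalent(0.01, 0), "df")
})

test_that("the GLMM recovers an intercept-only chance-level fit", {
  withr::with_seed(23, {
    dat <- tibble::tibble(
      participant_id = rep(sprintf("P%02d", 1:8), each = 50),
      group = "A",
      visual_first = rep(c(0L, 1L), 200),
      correct = NA_integer_
    )
  })
  fit <- fit_binomial_glmm(dat, "visual_first", ~1, nagq = 9)
  expect_equal(fit$coefficients$estimate[1], 0, tolerance = 1e-6)
  expect_equal(fit$random_intercept_variance, 0, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$n_quadrature_nodes, 9)

  # log marginal likelihood is invariant to participant relabelling
  relab <- dat
  relab$participant_id <- factor(relab$participant_id,
                                 labels = sample(sprintf("Q%02d", 1:8)))
  fit2 <- fit_binomial_glmm(relab, "visual_first", ~1, nagq = 9)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("the marginal likelihood stabilises as quadrature nodes increase", {
  withr::with_seed(59, {
    u <- rnorm(10, 0, 0.8)
    dat <- dplyr::bind_rows(lapply(1:10, function(i) {
      tibble::tibble(participant_id = sprintf("P%02d", i), group = "A",
                     visual_first = rbinom(40, 1, plogis(-0.4 + u[i])),
                     correct = NA_integer_)
    }))
  })
  lls <- vapply(c(1, 5, 9, 15, 25), function(q) {
    fit_binomial_glmm(dat, "visual_first", ~1, nagq = q)$loglik
  }, numeric(1))
  # adaptive quadrature refines the Laplace approximation and settles:
  # successive increments shrink, and 15 nodes is already within 1e-6
  # of the 25-node value
  expect_lt(abs(lls[5] - lls[4]), 1e-6)
  expect_lt(abs(lls[4] - lls[3]), abs(lls[3] - lls[1]) + 1e-9)
})

test_that("likelihood-ratio tests compare nested GLMMs", {
  withr::with_seed(29, {
    u <- rnorm(12, 0, 0.4)
    grp <- rep(c("A", "B"), each = 6)
    eff <- ifelse(grp == "A", 0, 1.2)
    dat <- dplyr::bind_rows(lapply(1:12, function(i) {
      tibble::tibble(
        participant_id = sprintf("P%02d", i), group = grp[i],
        visual_first = rbinom(40, 1, plogis(u[i] + eff[i])),
        correct = NA_integer_
      )
    }))
  })
  full <- fit_binomial_glmm(dat, "visual_first", ~group, nagq = 9)
  red <- fit_binomial_glmm(dat, "visual_first", ~1, nagq = 9)
  lrt <- lrt_group_effect(full, red)
  expect_equal(lrt$df, 1)
  expect_gt(lrt$statistic, 0)
  expect_lt(lrt$p_perm, 0.05) # strong true effect
  expect_equal(lrt$p_perm, pchisq(lrt$statistic, 1, lower.tail = FALSE))

  # identical models: chi-square 0, p 1
  same <- lrt_group_effect(full, full)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_perm, 1)

  # Wald contrast on the group coefficient agrees in direction
  ct <- glmm_contrast(full, c(0, 1), tails = "two")
  expect_gt(ct$statistic, 0)
  expect_lt(ct$p_perm, 0.05)
})

test_that("r_equivalent attaches to GLMM group tests with participant df", {
  # chi-square p = 0.038 over 10 participants reconstructs with df = 9
  expect_equal(round(r_equivalent(0.038, 9), 2), 0.56, tolerance = 0.011)
})

test_that("bias-accuracy correlation applies the per-group leverage rule", {
  # points exactly on a decreasing line: r = -1, permutation p small
  s <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:8),
    group = rep(c("A", "B"), each = 4),
    accuracy = seq(0.5, 0.9, length.out = 8),
    bias = 0.5 - 0.5 * seq(0.5, 0.9, length.out = 8)
  )
  res <- bias_accuracy_correlation(s, n_perm = 2000, seed = 2)
  expect_equal(res$statistic, -1)
  expect_lt(res$p_perm, 0.01)
  expect_equal(res$df, 6)

  # {0.1, 0.1, 0.1, 0.9}: the 0.9 sits only 1.5 SDs from the group mean
  # ((0.9 - 0.3) / 0.4), so it stays in
  s2 <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:4), group = "A",
    bias = c(0.1, 0.1, 0.1, 0.9), accuracy = c(0.8, 0.7, 0.9, 0.6)
  )
  res2 <- bias_accuracy_correlation(s2, n_perm = 500, seed = 2)
  expect_equal(res2$df, 2) # all four retained
  expect_true(is.null(res2$note))

  # 9 tight values and one extreme: z = 2.85 > 2.5, excluded
  s3 <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:10), group = "A",
    bias = c(seq(0.05, 0.15, length.out = 9), 0.9),
    accuracy = seq(0.5, 0.95, length.out = 10)
  )
  res3 <- bias_accuracy_correlation(s3, n_perm = 500, seed = 2)
  expect_equal(res3$df, 7) # one participant dropped
  expect_match(res3$note, "P10")
})

test_that("null correlations reject at close to the nominal rate", {
  withr::with_seed(37, {
    rej <- replicate(400, {
      s <- tibble::tibble(
        participant_id = sprintf("P%02d", 1:12),
        group = rep(c("A", "B"), each = 6),
        bias = runif(12, 0, 0.5), accuracy = runif(12, 0.5, 1)
      )
      bias_accuracy_correlation(s, n_perm = 500,
                                seed = sample.int(1e6, 1))$p_perm <= 0.05
    })
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
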