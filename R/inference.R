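new_test_result <- function(statistic, df, p_perm, tails, n_perm, exhaustive,
                            r_equiv = NA_real_, seed = NA_integer_,
                            method = "", note = NULL) {
  structure(
    list(
      statistic = statistic, df = df, p_perm = p_perm, tails = tails,
      n_perm = n_perm, exhaustive = exhaustive, r_equiv = r_equiv,
      seed = seed, method = method, note = note
    ),
    class = "toj_test"
  )
}

#' @export
print.toj_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf(
    "%s: statistic = %.4g, df = %s, p = %.4g (%s-tailed, %d %s permutations)\n",
    x$method, x$statistic, dfs, x$p_perm, x$tails, x$n_perm,
    if (x$exhaustive) "exhaustive" else "Monte-Carlo"
  ))
  if (is.finite(x$r_equiv)) cat(sprintf("r_equivalent = %.2f\n", x$r_equiv))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

# Permutation p-value. Exhaustive enumerations include the identity
# permutation, so p = count/total (never 0); Monte-Carlo draws use the
# add-one convention (count + 1) / (n_perm + 1).
perm_p <- function(stat_obs, stat_null, tails, exhaustive) {
  cmp <- switch(tails,
    two = sum(abs(stat_null) >= abs(stat_obs) - 1e-12),
    one = if (stat_obs >= 0) {
      sum(stat_null >= stat_obs - 1e-12)
    } else {
      sum(stat_null <= stat_obs + 1e-12)
    }
  )
  if (exhaustive) cmp / length(stat_null) else (cmp + 1) / (length(stat_null) + 1)
}

# Directional (one-tailed, in the direction of the observed statistic)
# permutation p, used to attach r_equivalent to two-tailed tests.
perm_p_directional <- function(stat_obs, stat_null, exhaustive) {
  perm_p(stat_obs, stat_null, "one", exhaustive)
}

#' One-sample permutation t-test
#'
#' Computes the classical one-sample t statistic of `values - mu0` and
#' derives its permutation null by flipping the signs of the centred values
#' (valid under the null hypothesis of a distribution symmetric about
#' `mu0`). All `2^n` sign patterns are enumerated when `2^n <= 32768`
#' (n <= 15); otherwise `n_perm` random sign patterns are drawn.
#' One-tailed p-values are directional in the sign of the observed t.
#'
#' @param values Numeric vector of per-participant measures (n >= 3).
#' @param mu0 Null value.
#' @param tails `"two"` or `"one"`.
#' @param n_perm Monte-Carlo permutation count (ignored when exhaustive).
#' @param seed Seed for the Monte-Carlo draw.
#' @return A `toj_test` with `statistic` (t), `df = n - 1`, `p_perm`,
#'   `r_equiv` (from the directional one-tailed permutation p).
#' @examples
#' perm_t_one_sample(c(1, 2, 3, 4), tails = "one") # exhaustive, p = 1/16
#' @export
perm_t_one_sample <- function(values, mu0 = 0, tails = c("two", "one"),
                              n_perm = 10000, seed = 1) {
  tails <- match.arg(tails)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3) stop("need at least 3 finite values")
  x <- values - mu0
  if (sd(x) == 0) {
    return(new_test_result(NA_real_, n - 1, 1, tails, 0L, TRUE,
                           method = "one-sample permutation t",
                           note = "zero variance: statistic undefined"))
  }
  ssq <- sum(x^2)
  t_from_sum <- function(s) {
    m <- s / n
    se <- sqrt((ssq - n * m^2) / (n - 1) / n)
    m / se
  }
  t_obs <- t_from_sum(sum(x))
  exhaustive <- n <= 15
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    sums <- as.vector(signs %*% x)
  } else {
    sums <- withr::with_seed(seed, {
      signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
      as.vector(signs %*% x)
    })
  }
  t_null <- vapply(sums, t_from_sum, numeric(1))
  p <- perm_p(t_obs, t_null, tails, exhaustive)
  p_dir <- perm_p_directional(t_obs, t_null, exhaustive)
  new_test_result(
    t_obs, n - 1, p, tails, length(t_null), exhaustive,
    r_equiv = suppressWarnings(r_equivalent(p_dir, n - 1, clip = TRUE)),
    seed = seed,
    method = "one-sample permutation t"
  )
}

#' Two-sample (unpaired) permutation t-test
#'
#' Student's pooled-variance two-sample t, with the null built by permuting
#' group labels. All `choose(na + nb, na)` assignments are enumerated when
#' that count is at most 32768; otherwise `n_perm` random assignments are
#' drawn.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @inheritParams perm_t_one_sample
#' @return A `toj_test` with `df = na + nb - 2`.
#' @export
perm_t_two_sample <- function(a, b, tails = c("two", "one"),
                              n_perm = 10000, seed = 1) {
  tails <- match.arg(tails)
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop("need at least 2 finite values per group")
  pool <- c(a, b)
  ntot <- na + nb
  df <- ntot - 2
  if (sd(pool) == 0) {
    return(new_test_result(NA_real_, df, 1, tails, 0L, TRUE,
                           method = "two-sample permutation t",
                           note = "all values identical: degenerate"))
  }
  tot <- sum(pool)
  ssq <- sum(pool^2)
  t_from_sum_a <- function(sa) {
    ma <- sa / na
    mb <- (tot - sa) / nb
    sp2 <- (ssq - na * ma^2 - nb * mb^2) / df
    if (sp2 <= 0) return(0)
    (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  t_obs <- t_from_sum_a(sum(a))
  n_assign <- choose(ntot, na)
  exhaustive <- n_assign <= 32768
  if (exhaustive) {
    idx <- utils::combn(ntot, na)
    sums <- colSums(matrix(pool[idx], nrow = na))
  } else {
    sums <- withr::with_seed(seed, {
      vapply(seq_len(n_perm),
             function(i) sum(pool[sample.int(ntot, na)]), numeric(1))
    })
  }
  t_null <- vapply(sums, t_from_sum_a, numeric(1))
  p <- perm_p(t_obs, t_null, tails, exhaustive)
  p_dir <- perm_p_directional(t_obs, t_null, exhaustive)
  new_test_result(
    t_obs, df, p, tails, length(t_null), exhaustive,
    r_equiv = suppressWarnings(r_equivalent(p_dir, df, clip = TRUE)),
    seed = seed,
    method = "two-sample permutation t"
  )
}

#' One-way permutation ANOVA
#'
#' The classical one-way F statistic with a label-permutation null
#' (Monte-Carlo; the F test is inherently one-sided, large F = evidence).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups,
#'   each n >= 2).
#' @inheritParams perm_t_one_sample
#' @return A `toj_test` with `statistic` (F) and `df = c(k - 1, N - k)`.
#' @export
perm_anova_oneway <- function(groups, n_perm = 10000, seed = 1) {
  stopifnot(is.list(groups), length(groups) >= 2)
  groups <- lapply(groups, function(g) g[is.finite(g)])
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("each group needs at least 2 finite values")
  x <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  N <- length(x)
  if (sd(x) == 0) {
    return(new_test_result(0, c(k - 1, N - k), 1, "one", 0L, TRUE,
                           method = "one-way permutation ANOVA",
                           note = "all values identical: degenerate"))
  }
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  grand <- mean(x)
  sst <- sum((x - grand)^2)
  f_stat <- function(v) {
    ssb <- 0
    for (j in seq_len(k)) {
      m <- mean(v[starts[j]:ends[j]])
      ssb <- ssb + sizes[j] * (m - grand)^2
    }
    ssw <- sst - ssb
    if (ssw <= 0) return(Inf)
    (ssb / (k - 1)) / (ssw / (N - k))
  }
  f_obs <- f_stat(x)
  f_null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) f_stat(x[sample.int(N)]), numeric(1))
  })
  p <- (sum(f_null >= f_obs - 1e-12) + 1) / (n_perm + 1)
  new_test_result(
    f_obs, c(k - 1, N - k), p, "one", n_perm, FALSE, seed = seed,
    method = "one-way permutation ANOVA"
  )
}

#' r-equivalent effect size
#'
#' Converts a one-tailed p-value and the degrees of freedom of the
#' underlying comparison into an effect-size correlation: the t quantile
#' `t_eq = qt(1 - p, df)` that would have produced that p is mapped through
#' `r = t_eq / sqrt(t_eq^2 + df)`. For tests reported on other scales (e.g.
#' a chi-square likelihood-ratio statistic from a mixed model), `df` is the
#' participants-based degrees of freedom of the corresponding group
#' comparison (n - 1 within one group, N - 2 between two).
#'
#' @param p One-tailed p-value in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @param clip If `TRUE`, p >= 0.5 (a negative equivalent t) returns 0 with
#'   a warning rather than a negative r.
#' @return The effect size r in `[0, 1)`.
#' @examples
#' r_equivalent(0.009, 9) # ~0.69
#' r_equivalent(0.005, 18) # ~0.56
#' @export
r_equivalent <- function(p, df, clip = TRUE) {
  stopifnot(length(p) == 1, length(df) == 1)
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  t_eq <- qt(1 - p, df)
  if (t_eq < 0) {
    if (clip) {
      warning("p >= 0.5: equivalent t is negative, r clipped to 0")
      return(0)
    }
  }
  max(0, t_eq / sqrt(t_eq^2 + df))
}

#' Binomial random-intercept mixed model
#'
#' Fits `response ~ <fixed> + (1 | participant_id)` with a binomial family
#' by maximising the marginal likelihood with adaptive Gauss-Hermite
#' quadrature (via [lme4::glmer()]). Used for trial-level analyses of the
#' 'visual first' response probability (the criterion-like bias measure)
#' and of response accuracy.
#'
#' @param trials Recoded trials.
#' @param response `"visual_first"` or `"correct"`.
#' @param fixed Right-hand-side formula of fixed effects, e.g. `~ group` or
#'   `~ group * condition`; `~ 1` for an intercept-only model.
#' @param link `"logit"` (default) or `"log"`.
#' @param nagq Number of adaptive quadrature nodes (default 15).
#' @return An object of class `toj_glmm_fit`: list with `coefficients`
#'   (tibble: term, estimate, se, z), `random_intercept_variance`, `loglik`,
#'   `link`, `converged`, `n_quadrature_nodes`, `n_participants`,
#'   `n_parameters`, `separation_suspected`, and the underlying `model`.
#' @export
fit_binomial_glmm <- function(trials, response = c("visual_first", "correct"),
                              fixed = ~group, link = c("logit", "log"),
                              nagq = 15) {
  response <- match.arg(response)
  link <- match.arg(link)
  dat <- trials[!is.na(trials[[response]]), , drop = FALSE]
  if (length(unique(dat$participant_id)) < 2) {
    stop("need at least 2 participants")
  }
  rhs <- paste(deparse(fixed[[2]]), collapse = "")
  form <- as.formula(paste0(response, " ~ ", rhs, " + (1 | participant_id)"))
  warns <- character()
  fit <- withCallingHandlers(
    lme4::glmer(form, data = dat, family = binomial(link = link),
                nAGQ = nagq),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      # lme4 reports singular (boundary) fits as messages; keep them as
      # diagnostics rather than console noise
      warns <<- c(warns, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  # a boundary (singular) fit is converged -- the variance estimate is 0;
  # only optimizer failure or a genuine non-convergence warning counts
  diag_msgs <- c(warns, unlist(fit@optinfo$conv$lme4))
  conv <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", diag_msgs, ignore.case = TRUE))
  sep <- any(abs(fe) > 10) || any(se > 10)
  structure(
    list(
      coefficients = tibble::tibble(
        term = names(fe), estimate = unname(fe), se = unname(se),
        z = unname(fe / se)
      ),
      random_intercept_variance =
        unname(lme4::VarCorr(fit)$participant_id[1, 1]),
      loglik = as.numeric(logLik(fit)),
      link = link,
      converged = conv,
      n_quadrature_nodes = nagq,
      n_participants = length(unique(dat$participant_id)),
      n_parameters = attr(logLik(fit), "df"),
      separation_suspected = sep,
      warnings = warns,
      model = fit
    ),
    class = "toj_glmm_fit"
  )
}

#' @export
print.toj_glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Binomial random-intercept GLMM (%s link, %d quadrature nodes)\n",
    x$link, x$n_quadrature_nodes
  ))
  cat(sprintf(
    "  %d participants, random-intercept variance %.4f, logLik %.2f%s\n",
    x$n_participants, x$random_intercept_variance, x$loglik,
    if (x$converged) "" else " [NOT converged]"
  ))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  if (x$separation_suspected) cat("  warning: possible complete separation\n")
  invisible(x)
}

#' Likelihood-ratio test between nested binomial GLMMs
#'
#' `chi^2 = 2 * (logLik_full - logLik_reduced)` with degrees of freedom
#' equal to the difference in parameter count, referred to the chi-square
#' distribution. The attached r-equivalent uses a participants-based df
#' reconstruction: `n_participants - n_groups` of the comparison the fixed
#' effect encodes (n - 1 for one group against a constant, N - 2 for two
#' groups), supplied via `r_equiv_df`.
#'
#' @param full,reduced `toj_glmm_fit` objects, `reduced` nested in `full`.
#' @param r_equiv_df Degrees of freedom used for [r_equivalent()]; default
#'   `n_participants - (difference in parameters + 1)`.
#' @return A `toj_test` with `statistic` (chi-square), `df`, `p_perm`
#'   (here the analytic chi-square p), and `r_equiv`.
#' @export
lrt_group_effect <- function(full, reduced, r_equiv_df = NULL) {
  stopifnot(inherits(full, "toj_glmm_fit"), inherits(reduced, "toj_glmm_fit"))
  df <- full$n_parameters - reduced$n_parameters
  if (df < 0) stop("models are not nested (reduced has more parameters)")
  chi2 <- 2 * (full$loglik - reduced$loglik)
  if (chi2 < -1e-6 && df > 0) {
    stop("full model has lower likelihood than reduced: optimisation failure")
  }
  chi2 <- max(chi2, 0)
  p <- if (df == 0) 1 else pchisq(chi2, df, lower.tail = FALSE)
  if (is.null(r_equiv_df)) r_equiv_df <- full$n_participants - (df + 1)
  r <- if (p > 0 && p < 1 && r_equiv_df >= 1) {
    suppressWarnings(r_equivalent(p, r_equiv_df, clip = TRUE))
  } else {
    NA_real_
  }
  new_test_result(
    chi2, df, p, "one", 0L, FALSE, r_equiv = r,
    method = "likelihood-ratio chi-square (GLMM)"
  )
}

#' Wald contrast on GLMM fixed effects
#'
#' Tests `L %*% beta = 0` on the link scale with a normal-approximation
#' Wald z. Used for planned pairwise group contrasts and for testing a
#' single group's response probability against chance (0 on the logit
#' scale corresponds to probability 0.5).
#'
#' @param fit A `toj_glmm_fit`.
#' @param L Numeric contrast vector, one weight per fixed-effect
#'   coefficient (in the order of `fit$coefficients$term`).
#' @param tails `"two"` or `"one"` (directional in the observed sign).
#' @param r_equiv_df Participants-based df for the attached r-equivalent.
#' @return A `toj_test` with `statistic` (z) and analytic normal p.
#' @export
glmm_contrast <- function(fit, L, tails = c("two", "one"), r_equiv_df = NULL) {
  tails <- match.arg(tails)
  stopifnot(inherits(fit, "toj_glmm_fit"))
  beta <- fit$coefficients$estimate
  if (length(L) != length(beta)) stop("contrast length mismatch")
  V <- as.matrix(vcov(fit$model))
  est <- sum(L * beta)
  se <- sqrt(drop(t(L) %*% V %*% L))
  z <- est / se
  p <- if (tails == "two") 2 * pnorm(-abs(z)) else pnorm(-abs(z))
  p_dir <- pnorm(-abs(z))
  if (is.null(r_equiv_df)) r_equiv_df <- fit$n_participants - 1
  r <- if (p_dir > 0 && p_dir < 1 && r_equiv_df >= 1) {
    suppressWarnings(r_equivalent(p_dir, r_equiv_df, clip = TRUE))
  } else {
    NA_real_
  }
  new_test_result(
    z, r_equiv_df, p, tails, 0L, FALSE, r_equiv = r,
    method = "Wald contrast (GLMM, link scale)"
  )
}

#' Bias-resolution correlation across participants
#'
#' Pearson correlation, across participants from all groups, between the
#' size of the 'visual first' bias and the proportion of correct order
#' judgments, with a leverage guard: within each group, a participant whose
#' bias or accuracy lies more than `exclusion_sd` SDs from the group mean
#' of that measure is excluded before pooling. The p-value is obtained by
#' permuting one variable.
#'
#' @param summaries Tibble with columns `participant_id`, `group`, `bias`,
#'   `accuracy` (one row per participant).
#' @param exclusion_sd Per-group outlier cutoff in SDs (default 2.5).
#' @inheritParams perm_t_one_sample
#' @return A `toj_test` with `statistic` (Pearson r), `df = n - 2`, and the
#'   retained/excluded participant ids in `note` when exclusions occurred.
#' @export
bias_accuracy_correlation <- function(summaries, exclusion_sd = 2.5,
                                      tails = c("two", "one"),
                                      n_perm = 10000, seed = 1) {
  tails <- match.arg(tails)
  stopifnot(all(c("group", "bias", "accuracy") %in% names(summaries)))
  s <- summaries[complete.cases(summaries[, c("bias", "accuracy")]), ]
  zdist <- function(v) {
    if (length(v) < 2 || sd(v) == 0) return(rep(0, length(v)))
    abs(v - mean(v)) / sd(v)
  }
  s0 <- s
  keep <- rep(TRUE, nrow(s))
  for (g in unique(s$group)) {
    i <- s$group == g
    keep[i] <- zdist(s$bias[i]) <= exclusion_sd &
      zdist(s$accuracy[i]) <= exclusion_sd
  }
  s <- s[keep, , drop = FALSE]
  n <- nrow(s)
  if (n < 4) stop("fewer than 4 participants remain after exclusion")
  if (sd(s$bias) == 0 || sd(s$accuracy) == 0) {
    return(new_test_result(NA_real_, n - 2, 1, tails, 0L, TRUE,
                           method = "bias-accuracy Pearson correlation",
                           note = "zero variance in a measure"))
  }
  r_obs <- stats::cor(s$bias, s$accuracy)
  r_null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stats::cor(s$bias, s$accuracy[sample.int(n)]),
           numeric(1))
  })
  p <- perm_p(r_obs, r_null, tails, exhaustive = FALSE)
  note <- if (any(!keep)) {
    paste("excluded:", paste(s0$participant_id[!keep][
      seq_len(min(5, sum(!keep)))], collapse = ", "))
  }
  new_test_result(
    r_obs, n - 2, p, tails, n_perm, FALSE, seed = seed,
    method = "bias-accuracy Pearson correlation", note = note
  )
}
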