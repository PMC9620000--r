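test_that("centering subtracts the mean exactly", {
  expect_equal(center(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(center(rep(7, 5)), rep(0, 5))
  set.seed(1)
  expect_lt(abs(mean(center(rnorm(1000, 50, 10)))), 1e-12)
  expect_error(center(numeric(0)), "nothing")
})

test_that("odds ratios are exact exponentials with ordered CIs", {
  o <- odds_ratio(0.03, c(0.00, 0.05))
  expect_equal(round(o$or, 2), 1.03)
  expect_equal(round(o$or_ci, 2), c(1.00, 1.05))
  expect_equal(odds_ratio(0)$or, 1)
  expect_equal(round(odds_ratio(-0.15)$or, 2), 0.86)
  # log/exp consistency to machine precision
  b <- rnorm(20)
  expect_equal(log(odds_ratio(b)$or), b)

  f <- simulate_features(sim_config("small"), seed = 12)
  fit <- fit_recall_glmm(f)
  co <- fit$coefficients
  expect_equal(co$odds_ratio, exp(co$estimate))
  expect_true(all(co$ci_lo < co$ci_hi & co$or_lo < co$or_hi))
  expect_equal(co$or_lo, exp(co$ci_lo))
})

test_that("Type-II Wald statistics are squared z-scores with chi-square p-values", {
  f <- simulate_features(sim_config(n_participants = 15L, n_lists = 8L),
    seed = 9
  )
  fit <- fit_recall_glmm(f)
  w <- wald_type2(fit)
  co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_equal(w$chisq, (co$estimate / co$se)^2)
  expect_equal(w$p, pchisq(w$chisq, 1, lower.tail = FALSE))
  expect_true(all(w$df == 1))
  # beta/SE = 2 corresponds to chisq 4, p ~ 0.0455
  expect_equal(pchisq(4, 1, lower.tail = FALSE), 0.0455, tolerance = 1e-3)
})

test_that("Wald tests agree with an independent Type-II implementation", {
  skip_if_not_installed("car")
  f <- simulate_features(sim_config(n_participants = 15L, n_lists = 8L),
    seed = 14
  )
  fit <- fit_recall_glmm(f, fix_sigma = c(0, 0))
  d <- data.frame(
    y = fit$y, ppd = fit$X[, "ppd"], rs = fit$X[, "rs_score"],
    nr = fit$X[, "noise_reduction"], age = fit$X[, "age"],
    pta = fit$X[, "pta"]
  )
  g <- stats::glm(y ~ ppd + rs + nr + age + pta, data = d, family = binomial())
  a <- car::Anova(g, type = 2, test.statistic = "Wald")
  w <- wald_type2(fit)
  expect_equal(unname(a[["Chisq"]]), w$chisq, tolerance = 1e-4)
})

test_that("the likelihood ratio test compares full and null fits on 5 df", {
  f <- simulate_features(sim_config(n_participants = 20L, n_lists = 10L),
    seed = 10
  )
  fit <- fit_recall_glmm(f)
  nul <- null_model(fit)
  lrt <- likelihood_ratio_test(fit, nul)
  expect_identical(lrt$df, 5L)
  expect_gte(lrt$chisq, 0)
  expect_equal(lrt$p, pchisq(lrt$chisq, 5, lower.tail = FALSE))

  # identical models: chisq 0, p 1
  same <- likelihood_ratio_test(fit, fit)
  expect_equal(same$chisq, 0)
  expect_equal(same$p, 1)

  # with variances pinned to zero the statistic equals the glm deviance drop
  fit0 <- fit_recall_glmm(f, fix_sigma = c(0, 0))
  nul0 <- fit_recall_glmm(f, fixed = character(0), fix_sigma = c(0, 0))
  lrt0 <- likelihood_ratio_test(fit0, nul0)
  g_full <- stats::glm(fit0$y ~ fit0$X[, -1], family = binomial())
  g_null <- stats::glm(fit0$y ~ 1, family = binomial())
  expect_equal(lrt0$chisq, deviance(g_null) - deviance(g_full),
    tolerance = 1e-6
  )

  f2 <- f[-(1:7), ] # drop one list
  expect_error(
    likelihood_ratio_test(fit, fit_recall_glmm(f2)),
    "different rows"
  )
})

test_that("variance inflation factors follow the 1/(1-R2) definition", {
  set.seed(3)
  n <- 500
  # orthogonal predictors
  X <- qr.Q(qr(matrix(rnorm(n * 3), n)))
  v <- vif(X)
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-4)

  # correlation 0.8 gives 1 / (1 - 0.64) for both
  S <- chol(matrix(c(1, 0.8, 0.8, 1), 2))
  Y <- matrix(rnorm(2 * 20000), ncol = 2) %*% S
  v <- vif(Y)
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 0.05)

  # duplicated column is perfectly collinear
  Z <- cbind(a = rnorm(n), b = rnorm(n))
  expect_identical(unname(vif(cbind(Z, Z[, 1]))[3]), Inf)
  expect_error(vif(cbind(1, rep(2, n))), "constant")
})

test_that("Nakagawa R2 matches the logit-link closed form", {
  # var_f = 1, participant variance 1, trial 0
  r2 <- nakagawa_r2(1, 1, 0)
  expect_equal(unname(r2["marginal"]), 1 / (2 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(unname(r2["conditional"]), 2 / (2 + pi^2 / 3), tolerance = 1e-12)
  expect_equal(round(unname(r2), 4), c(0.1890, 0.3781), tolerance = 1e-4)

  expect_equal(unname(nakagawa_r2(0, 0, 0)), c(0, 0))

  # on a fit: marginal <= conditional, equality when variances are 0
  f <- simulate_features(sim_config("small"), seed = 13)
  fit <- fit_recall_glmm(f)
  r2f <- nakagawa_r2(fit)
  expect_lte(r2f[["marginal"]], r2f[["conditional"]])
  expect_true(all(r2f >= 0 & r2f <= 1))
  fit0 <- fit_recall_glmm(f, fix_sigma = c(0, 0))
  r20 <- nakagawa_r2(fit0)
  expect_equal(r20[["marginal"]], r20[["conditional"]])
})

test_that("the quadratic PPD model recovers curvature and its turning point", {
  cfg <- sim_config(n_participants = 40L, n_lists = 28L, amp_sd = 0.3)
  # inverted-U link: strong negative curvature
  f <- simulate_features(cfg, seed = 17, beta_ppd_sq = -3)
  qfit <- quadratic_variant(f)
  b2 <- qfit$beta[["ppd_sq"]]
  expect_lt(b2, 0)
  expect_equal(
    unname(qfit$turning_point["centered"]),
    -qfit$beta[["ppd"]] / (2 * b2)
  )

  # linear link: quadratic CI covers zero (no spurious curvature)
  f0 <- simulate_features(cfg, seed = 18)
  q0 <- quadratic_variant(f0)
  co <- q0$coefficients[q0$coefficients$term == "ppd_sq", ]
  expect_true(co$ci_lo <= 0 && 0 <= co$ci_hi)
})

test_that("the Pearson correlation matches the closed-form computation", {
  x <- c(0.2, 0.35, 0.5, 0.41, 0.28)
  y <- c(30, 45, 60, 40, 38)
  out <- pearson_r(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(out$r, r_hand)
  expect_equal(out$p, 2 * pt(-abs(t_hand), df = 3))

  expect_equal(pearson_r(x, x)$r, 1)
  # y orthogonal to centered x gives r = 0
  expect_equal(pearson_r(c(-1, 0, 1), c(1, -2, 1))$r, 0)
  expect_error(pearson_r(x, rep(1, 5)), "zero variance")
  expect_error(pearson_r(x[1:2], y[1:2]), "at least 3")
})

test_that("fit summaries expose the journal-style table and JSON export", {
  f <- simulate_features(sim_config("small"), seed = 19)
  fit <- fit_recall_glmm(f)
  lines <- format_fit_table(fit)
  expect_true(any(grepl("Odds ratio", lines)))
  expect_length(lines, nrow(fit$coefficients) + 2L)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(
    vapply(parsed$coefficients, function(x) x$estimate, numeric(1)),
    fit$coefficients$estimate,
    tolerance = 1e-12
  )
})
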