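#' Fit the subsequent-memory-recall logistic mixed model
#'
#' Fits word-level recall (recalled vs not) as a function of baseline-corrected
#' peak pupil dilation (PPD), Reading Span score, hearing-aid noise reduction
#' (on vs off, reference off), age and hearing threshold (PTA), with crossed
#' random intercepts for participant and for serial position. Continuous
#' predictors are centered by subtracting the mean. The model is fit by
#' maximum likelihood with a Laplace approximation of the integrated
#' likelihood (logit link); Wald 95% confidence intervals are
#' `beta +/- 1.96 SE`, and odds ratios are `exp(beta)` with exponentiated CI
#' bounds.
#'
#' @param features A trial-feature table as produced by [extract_features()]
#'   (or [simulate_features()]): columns `recalled`, `ppd`, `rs_score`,
#'   `noise_reduction`, `age`, `pta`, `participant_id`, `position`, and
#'   `list_id` when `trial_factor = "token"`.
#' @param fixed Character vector of fixed-effect terms to include, a subset
#'   of `c("ppd", "rs_score", "noise_reduction", "age", "pta")`. The
#'   intercept is always present; the empty vector gives the null model.
#' @param quadratic Add a squared centered-PPD term (exploratory model).
#' @param trial_factor `"position"` uses the 7 serial positions as the trial
#'   random factor (accounting for primacy/recency); `"token"` uses each
#'   list-by-position sentence token.
#' @param fix_sigma Length-2 numeric `(participant, trial)`: `NA` estimates
#'   the standard deviation, `0` pins it (both `0` reduces the model to plain
#'   logistic regression).
#' @param conf_level Confidence level for the Wald intervals.
#' @param control Optimizer control overrides (inner PIRLS tolerance
#'   `pirls_tol`, outer relative tolerance `outer_rel_tol`, separation guard
#'   `beta_bound`).
#' @return An object of class `recall_glmm` with a coefficient table
#'   (estimate, SE, CI, odds ratio and CI, Wald z and p), variance components
#'   `sigma` (standard deviations) for participant and trial, the
#'   log-likelihood, and convergence diagnostics.
#' @export
fit_recall_glmm <- function(features,
                            fixed = c(
                              "ppd", "rs_score", "noise_reduction",
                              "age", "pta"
                            ),
                            quadratic = FALSE,
                            trial_factor = c("position", "token"),
                            fix_sigma = c(NA_real_, NA_real_),
                            conf_level = 0.95,
                            control = list()) {
  trial_factor <- match.arg(trial_factor)
  all_terms <- c("ppd", "rs_score", "noise_reduction", "age", "pta")
  if (length(fixed)) {
    fixed <- unique(match.arg(fixed, all_terms, several.ok = TRUE))
  } else {
    fixed <- character(0)
  }
  stopifnot(all(c("recalled", "participant_id", "position") %in% names(features)))
  if (nrow(features) < 2L) stop("need at least two trials")
  if (length(unique(features$participant_id)) < 2L && is.na(fix_sigma[1])) {
    warning("fewer than 2 participants; participant variance is unidentified")
  }

  y <- as.numeric(features$recalled)
  n <- length(y)
  cols <- list("(Intercept)" = rep(1, n))
  if ("ppd" %in% fixed) cols$ppd <- center(features$ppd)
  if ("rs_score" %in% fixed) cols$rs_score <- center(features$rs_score)
  if ("noise_reduction" %in% fixed) {
    cols$noise_reduction <- as.numeric(features$noise_reduction == "on")
  }
  if ("age" %in% fixed) cols$age <- center(features$age)
  if ("pta" %in% fixed) cols$pta <- center(features$pta)
  if (quadratic) {
    if (!"ppd" %in% fixed) stop("quadratic term requires the ppd term")
    cols$ppd_sq <- cols$ppd^2
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  const <- apply(X[, -1, drop = FALSE], 2, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop(
      "constant predictor after centering: ",
      paste(names(which(const)), collapse = ", ")
    )
  }

  trial <- if (trial_factor == "position") {
    features$position
  } else {
    paste(features$list_id, features$position, sep = ":")
  }

  core <- glmm_laplace(y, X, features$participant_id, trial,
    fix_sigma = fix_sigma, control = control
  )

  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(diag(core$vcov))
  beta <- core$beta
  names(beta) <- colnames(X)
  zval <- beta / se
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    se = unname(se),
    ci_lo = unname(beta - zq * se),
    ci_hi = unname(beta + zq * se),
    odds_ratio = exp(unname(beta)),
    or_lo = exp(unname(beta - zq * se)),
    or_hi = exp(unname(beta + zq * se)),
    z = unname(zval),
    p = 2 * stats::pnorm(-abs(unname(zval)))
  )

  structure(list(
    coefficients = coefs,
    beta = beta,
    vcov = core$vcov,
    sigma = stats::setNames(core$sigma, c("participant", "trial")),
    loglik = core$loglik,
    deviance = -2 * core$loglik,
    converged = core$converged,
    boundary = core$boundary,
    grad_norm = core$grad_norm,
    n = n,
    n_participants = length(unique(features$participant_id)),
    n_trial_levels = length(unique(trial)),
    X = X,
    y = y,
    trial_factor = trial_factor,
    fixed = fixed,
    quadratic = quadratic,
    fix_sigma = fix_sigma,
    conf_level = conf_level,
    data = features
  ), class = "recall_glmm")
}

#' @export
print.recall_glmm <- function(x, digits = 3, ...) {
  cat("Binary logistic mixed model (Laplace), logit link\n")
  cat(sprintf(
    "  %d trials, %d participants, %d trial levels (%s)\n",
    x$n, x$n_participants, x$n_trial_levels, x$trial_factor
  ))
  cat(sprintf("  log-likelihood %.3f", x$loglik))
  if (!x$converged) cat("  [NOT CONVERGED]")
  cat("\n\nRandom intercept standard deviations:\n")
  print(round(x$sigma, digits))
  cat("\nFixed effects (Wald ", 100 * x$conf_level, "% CI):\n", sep = "")
  tab <- as.data.frame(x$coefficients)
  tab[-1] <- lapply(tab[-1], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.recall_glmm <- function(object, ...) {
  w <- wald_type2(object)
  r2 <- nakagawa_r2(object)
  out <- list(
    fit = object, wald = w, r2 = r2,
    vif = if (ncol(object$X) > 2) vif(object$X[, -1, drop = FALSE]) else NULL
  )
  class(out) <- "summary.recall_glmm"
  out
}

#' @export
print.summary.recall_glmm <- function(x, digits = 3, ...) {
  print(x$fit, digits = digits)
  cat("\nType-II Wald chi-square tests:\n")
  print(as.data.frame(lapply(x$wald, round, digits)), row.names = FALSE)
  cat(sprintf(
    "\nNakagawa R2: marginal %.3f, conditional %.3f\n",
    x$r2[["marginal"]], x$r2[["conditional"]]
  ))
  if (!is.null(x$vif)) {
    cat("\nVariance inflation factors:\n")
    print(round(x$vif, digits))
  }
  invisible(x)
}

#' Odds ratio from a log-odds coefficient
#'
#' Elementwise exponentiation of a coefficient and its confidence bounds;
#' `log(odds_ratio(beta)$or)` returns `beta` to machine precision.
#'
#' @param beta Log-odds coefficient(s).
#' @param ci Optional numeric vector or matrix of CI bounds.
#' @return A list with `or` and (when given) `or_ci`.
#' @export
odds_ratio <- function(beta, ci = NULL) {
  out <- list(or = exp(beta))
  if (!is.null(ci)) out$or_ci <- exp(ci)
  out
}

#' Type-II Wald chi-square tests
#'
#' For each fixed-effect term, the Wald chi-square statistic testing its
#' coefficients given all other terms. Without interactions every term here
#' is single-df, so the statistic is `(beta / SE)^2` with p from the
#' chi-square distribution on 1 df.
#'
#' @param fit A `recall_glmm` fit.
#' @return A tibble with `term`, `chisq`, `df`, `p` (intercept excluded).
#' @export
wald_type2 <- function(fit) {
  if (!fit$converged) stop("fit did not converge")
  terms <- setdiff(colnames(fit$X), "(Intercept)")
  V <- fit$vcov
  rownames(V) <- colnames(V) <- colnames(fit$X)
  rows <- lapply(terms, function(tm) {
    j <- which(colnames(fit$X) == tm)
    b <- fit$beta[j]
    Vj <- V[j, j, drop = FALSE]
    if (any(!is.finite(Vj)) || det(Vj) <= 0) stop("singular covariance")
    chisq <- drop(t(b) %*% solve(Vj, b))
    tibble::tibble(
      term = tm, chisq = chisq, df = length(j),
      p = stats::pchisq(chisq, df = length(j), lower.tail = FALSE)
    )
  })
  dplyr::bind_rows(rows)
}

#' Likelihood ratio test against a nested null model
#'
#' Compares a full fit with a null fit on the same rows (the null model keeps
#' the intercept and both random intercepts, dropping all five fixed
#' effects). The statistic is `2 (llik_full - llik_null)` on df equal to the
#' number of dropped fixed-effect columns.
#'
#' @param fit_full,fit_null `recall_glmm` fits of the same data.
#' @return A list with `chisq`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(fit_full, fit_null) {
  if (fit_full$n != fit_null$n ||
    !isTRUE(all.equal(fit_full$y, fit_null$y))) {
    stop("models were fit to different rows")
  }
  if (!all(colnames(fit_null$X) %in% colnames(fit_full$X))) {
    stop("models are not nested")
  }
  df <- ncol(fit_full$X) - ncol(fit_null$X)
  chisq <- max(0, 2 * (fit_full$loglik - fit_null$loglik))
  list(
    chisq = chisq, df = df,
    p = if (df > 0) {
      stats::pchisq(chisq, df = df, lower.tail = FALSE)
    } else {
      1
    }
  )
}

#' Fit the null model matching a full fit
#'
#' Intercept plus both random intercepts, on exactly the rows of the full
#' fit.
#'
#' @param fit A `recall_glmm` fit.
#' @return A `recall_glmm` null fit.
#' @export
null_model <- function(fit) {
  fit_recall_glmm(fit$data,
    fixed = character(0), quadratic = FALSE,
    trial_factor = fit$trial_factor, fix_sigma = fit$fix_sigma,
    conf_level = fit$conf_level
  )
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing predictor `j` on
#' all other predictors (with intercept). Perfectly collinear predictors get
#' `Inf`.
#'
#' @param design Numeric matrix or data frame of predictor columns (no
#'   intercept column).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2L) stop("need at least two predictors")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant predictor column")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

# distribution-specific residual variance of the logit link
logit_resid_var <- function() pi^2 / 3

#' Nakagawa marginal and conditional R-squared
#'
#' For a logit-link mixed model: with `var_f` the variance of the
#' fixed-effect linear predictor over the data, the marginal R2 is
#' `var_f / (var_f + s2_participant + s2_trial + pi^2/3)` and the conditional
#' R2 adds both random-intercept variances to the numerator. `pi^2/3` is the
#' logistic distribution-specific residual variance.
#'
#' @param fit A converged `recall_glmm` fit, or the fixed-predictor variance
#'   `var_f` (then `s2_participant` and `s2_trial` must be given).
#' @param s2_participant,s2_trial Random-intercept variances (used when
#'   `fit` is numeric).
#' @return Named numeric vector `c(marginal, conditional)`.
#' @export
nakagawa_r2 <- function(fit, s2_participant = NULL, s2_trial = NULL) {
  if (inherits(fit, "recall_glmm")) {
    var_f <- stats::var(drop(fit$X %*% fit$beta))
    s2p <- fit$sigma[["participant"]]^2
    s2t <- fit$sigma[["trial"]]^2
  } else {
    var_f <- fit
    s2p <- s2_participant
    s2t <- s2_trial
  }
  denom <- var_f + s2p + s2t + logit_resid_var()
  c(
    marginal = var_f / denom,
    conditional = (var_f + s2p + s2t) / denom
  )
}

#' Exploratory quadratic-PPD model
#'
#' Refits the recall model with a squared centered-PPD fixed effect. When the
#' quadratic coefficient is negative the turning point of the inverted-U,
#' `-b1 / (2 b2)`, is reported on the centered PPD scale (and on the raw
#' scale when the feature table is available).
#'
#' @inheritParams fit_recall_glmm
#' @param ... Passed to [fit_recall_glmm()].
#' @return A `recall_glmm` fit with an extra `turning_point` element.
#' @export
quadratic_variant <- function(features, ...) {
  fit <- fit_recall_glmm(features, quadratic = TRUE, ...)
  b1 <- fit$beta[["ppd"]]
  b2 <- fit$beta[["ppd_sq"]]
  if (is.finite(b2) && b2 < 0) {
    tp <- -b1 / (2 * b2)
    fit$turning_point <- c(
      centered = tp,
      raw = tp + mean(features$ppd)
    )
  } else {
    fit$turning_point <- NULL
  }
  fit
}

#' Pearson correlation between per-participant mean PPD and Reading Span
#'
#' Sample Pearson correlation with the two-sided t-test p-value (via
#' [stats::cor.test()]). Inputs with zero variance are rejected.
#'
#' @param x,y Numeric vectors of equal length, at least 3 values (typically
#'   `x` = per-participant mean PPD, `y` = RS score).
#' @return A list with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need equal-length vectors with at least 3 values")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Table-style text summary of a fit
#'
#' Formats the coefficient table the way journal tables print it: beta with
#' 95% CI, odds ratio with CI, and p per effect, followed by the variance
#' components.
#'
#' @param fit A `recall_glmm` fit.
#' @return A character vector of lines (also printed invisibly usable via
#'   `cat`).
#' @export
format_fit_table <- function(fit) {
  co <- fit$coefficients
  lines <- c(
    sprintf(
      "%-16s %-22s %-22s %s", "", "beta (95% CI)",
      "Odds ratio (95% CI)", "p"
    ),
    vapply(seq_len(nrow(co)), function(i) {
      sprintf(
        "%-16s %5.2f (%5.2f, %5.2f)   %5.2f (%5.2f, %5.2f)   %.3f",
        co$term[i], co$estimate[i], co$ci_lo[i], co$ci_hi[i],
        co$odds_ratio[i], co$or_lo[i], co$or_hi[i], co$p[i]
      )
    }, character(1)),
    sprintf(
      "sigma2: participant %.3f, trial %.3f; logLik %.2f",
      fit$sigma[["participant"]]^2, fit$sigma[["trial"]]^2, fit$loglik
    )
  )
  lines
}

#' Export a fit summary as JSON
#'
#' @param fit A `recall_glmm` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  s <- summary(fit)
  obj <- list(
    coefficients = fit$coefficients,
    sigma = as.list(fit$sigma),
    loglik = fit$loglik,
    converged = fit$converged,
    wald_type2 = s$wald,
    r2 = as.list(s$r2),
    vif = if (!is.null(s$vif)) as.list(s$vif) else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
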