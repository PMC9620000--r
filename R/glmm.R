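# Laplace-approximated binary logistic mixed model with two crossed random
# intercept factors. The inner loop is penalized iteratively reweighted least
# squares (PIRLS) for the mode of the random effects; the outer loop
# optimizes the Laplace deviance over the fixed effects and the log standard
# deviations of the two variance components. Random-effect cross-products go
# through a sparse indicator matrix built once per fit.

log1pexp <- function(x) {
  big <- x > 33
  if (any(big)) {
    out <- numeric(length(x))
    out[!big] <- log1p(exp(x[!big]))
    out[big] <- x[big]
    out
  } else {
    log1p(exp(x))
  }
}

inv_logit <- function(eta) 1 / (1 + exp(-eta))

#' Center a numeric vector
#'
#' Subtracts the mean, so that the output has mean (numerically) zero.
#' Continuous predictors of the recall model are centered this way.
#'
#' @param x Numeric vector with at least one finite value.
#' @return `x - mean(x)`.
#' @export
center <- function(x) {
  if (length(x) == 0L || !any(is.finite(x))) stop("nothing to center")
  x - mean(x)
}

# Sparse indicator of the active random-effect blocks: n x q with one 1 per
# row per block.
make_z <- function(gs, qs) {
  if (length(gs) == 0L) {
    return(NULL)
  }
  n <- length(gs[[1]])
  j <- gs[[1]]
  if (length(gs) > 1L) j <- c(j, qs[1] + gs[[2]])
  Matrix::sparseMatrix(
    i = rep.int(seq_len(n), length(gs)), j = j, x = 1,
    dims = c(n, sum(qs))
  )
}

# scale the rows of a dgCMatrix by w without densifying
row_scale <- function(Z, w) {
  Z@x <- Z@x * w[Z@i + 1L]
  Z
}

# q x q penalized information ZtWZ + Dinv (dense).
penalized_info <- function(Z, w, sigv) {
  H <- as.matrix(Matrix::crossprod(Z, row_scale(Z, w)))
  diag(H) <- diag(H) + 1 / sigv^2
  H
}

# PIRLS for the conditional mode of u given beta and sigma. Returns the mode
# together with the state (eta, mu, w) at the mode.
pirls_u <- function(y, xb, Z, sigv, u0 = NULL, tol = 1e-8, maxit = 100L) {
  q <- length(sigv)
  u <- if (is.null(u0) || length(u0) != q) numeric(q) else u0
  pll <- function(eta, u) {
    sum(y * eta - log1pexp(eta)) - 0.5 * sum(u^2 / sigv^2)
  }
  eta <- xb + as.vector(Z %*% u)
  cur <- pll(eta, u)
  for (it in seq_len(maxit)) {
    mu <- inv_logit(eta)
    w <- mu * (1 - mu)
    w[w < 1e-10] <- 1e-10
    H <- penalized_info(Z, w, sigv)
    g <- as.vector(Matrix::crossprod(Z, y - mu)) - u / sigv^2
    du <- solve(H, g)
    step <- 1
    repeat {
      newu <- u + step * du
      neweta <- xb + as.vector(Z %*% newu)
      new <- pll(neweta, newu)
      if (new >= cur - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    conv <- abs(new - cur) < tol
    u <- newu
    eta <- neweta
    cur <- new
    if (conv) break
  }
  mu <- inv_logit(eta)
  w <- mu * (1 - mu)
  w[w < 1e-10] <- 1e-10
  list(u = u, eta = eta, mu = mu, w = w, pll = cur)
}

# Laplace log-likelihood at (beta, sigma), u profiled out by PIRLS.
laplace_ll <- function(y, X, beta, Z, sigv, u0 = NULL, tol = 1e-8) {
  xb <- drop(X %*% beta)
  if (is.null(Z)) {
    return(list(ll = sum(y * xb - log1pexp(xb)), u = numeric(0)))
  }
  st <- pirls_u(y, xb, Z, sigv, u0 = u0, tol = tol)
  H <- penalized_info(Z, st$w, sigv)
  R <- chol(H)
  logdet <- 2 * sum(log(diag(R))) + 2 * sum(log(sigv))
  ll <- st$pll - 0.5 * logdet
  list(ll = ll, u = st$u)
}

# Exact gradient of the Laplace log-likelihood over (beta, log sigma),
# by implicit differentiation through the PIRLS mode: the mode condition
# kills first-order u-sensitivity of the penalized loglik, leaving the
# data term plus the derivative of the log-determinant, which for the
# logit link involves W' = mu (1 - mu) (1 - 2 mu).
laplace_ll_grad <- function(y, X, beta, Z, gs, qs, sig, u0 = NULL,
                            tol = 1e-10) {
  sigv <- rep(sig, times = qs)
  xb <- drop(X %*% beta)
  st <- pirls_u(y, xb, Z, sigv, u0 = u0, tol = tol)
  u <- st$u
  w <- st$w
  mu <- st$mu
  wp <- w * (1 - 2 * mu)
  H <- penalized_info(Z, w, sigv)
  R <- chol(H)
  logdet <- 2 * sum(log(diag(R))) + 2 * sum(log(sigv))
  ll <- st$pll - 0.5 * logdet
  S <- chol2inv(R)
  dS <- diag(S)
  # per-row quadratic form z_i' S z_i (Z has one 1 per active block per row)
  if (length(qs) == 1L) {
    cvec <- dS[gs[[1]]]
  } else {
    j2 <- qs[1] + gs[[2]]
    cvec <- dS[gs[[1]]] + dS[j2] + 2 * S[cbind(gs[[1]], j2)]
  }
  cw <- cvec * wp
  # beta block
  Tm <- as.matrix(Matrix::crossprod(Z, X * w)) # q x p
  V <- X - as.matrix(Z %*% (S %*% Tm)) # n x p
  g_beta <- drop(crossprod(X, y - mu)) - 0.5 * drop(crossprod(V, cw))
  # log-sigma block
  off <- 0L
  g_ls <- numeric(length(qs))
  for (b in seq_along(qs)) {
    idx <- off + seq_len(qs[b])
    s2 <- sig[b]^2
    du <- (2 / s2) * drop(S[, idx, drop = FALSE] %*% u[idx])
    zdu <- as.vector(Z %*% du)
    g_ls[b] <- sum(u[idx]^2) / s2 -
      0.5 * (-(2 / s2) * sum(dS[idx]) + sum(cw * zdu)) - qs[b]
    off <- off + qs[b]
  }
  list(ll = ll, grad = c(g_beta, g_ls), u = u)
}

# Joint Newton on (beta, u) -- profiles beta cheaply during the initial
# theta-only search, and is the whole fit when both variances are pinned
# to zero.
pirls_joint <- function(y, X, Z, sigv, beta0, u0 = NULL, tol = 1e-8,
                        maxit = 100L, beta_bound = 15) {
  p <- ncol(X)
  q <- length(sigv)
  beta <- beta0
  u <- if (is.null(u0) || length(u0) != q) numeric(q) else u0
  pll <- function(eta, u) {
    pen <- if (q) 0.5 * sum(u^2 / sigv^2) else 0
    sum(y * eta - log1pexp(eta)) - pen
  }
  eta <- drop(X %*% beta) + (if (q) as.vector(Z %*% u) else 0)
  cur <- pll(eta, u)
  for (it in seq_len(maxit)) {
    mu <- inv_logit(eta)
    w <- mu * (1 - mu)
    w[w < 1e-10] <- 1e-10
    r <- y - mu
    XtWX <- crossprod(X, X * w)
    grad_b <- drop(crossprod(X, r))
    if (q) {
      Hu <- penalized_info(Z, w, sigv)
      XtWZ <- as.matrix(Matrix::crossprod(Z, X * w)) # q x p
      M <- rbind(cbind(XtWX, t(XtWZ)), cbind(XtWZ, Hu))
      g <- c(grad_b, as.vector(Matrix::crossprod(Z, r)) - u / sigv^2)
    } else {
      M <- XtWX
      g <- grad_b
    }
    d <- solve(M, g)
    step <- 1
    repeat {
      nb <- beta + step * d[seq_len(p)]
      nu <- if (q) u + step * d[p + seq_len(q)] else u
      neweta <- drop(X %*% nb) + (if (q) as.vector(Z %*% nu) else 0)
      new <- pll(neweta, nu)
      if (new >= cur - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    conv <- abs(new - cur) < tol
    beta <- nb
    if (q) u <- nu
    eta <- neweta
    cur <- new
    if (max(abs(beta)) > beta_bound) {
      stop("complete separation detected: |beta| exceeded ", beta_bound,
        " on the logit scale",
        call. = FALSE
      )
    }
    if (conv) break
  }
  list(beta = beta, u = u, pll = cur)
}

# Wald covariance of beta: Schur complement of the random-effects block of
# the joint observed information at the fitted values.
beta_vcov <- function(y, X, beta, Z, sigv, u) {
  eta <- drop(X %*% beta) + (if (length(sigv)) as.vector(Z %*% u) else 0)
  mu <- inv_logit(eta)
  w <- mu * (1 - mu)
  w[w < 1e-10] <- 1e-10
  XtWX <- crossprod(X, X * w)
  if (length(sigv) == 0L) {
    return(solve(XtWX))
  }
  Hu <- penalized_info(Z, w, sigv)
  XtWZ <- as.matrix(Matrix::crossprod(Z, X * w)) # q x p
  solve(XtWX - crossprod(XtWZ, solve(Hu, XtWZ)))
}

# Core fitter. fix_sigma entries: NA = estimate, 0 = pin the block's
# variance to zero (both 0 reduces to plain logistic regression).
glmm_laplace <- function(y, X, participant, trial,
                         fix_sigma = c(NA_real_, NA_real_),
                         control = list()) {
  ctrl <- utils::modifyList(list(
    pirls_tol = 1e-10, outer_rel_tol = 1e-6, beta_bound = 15,
    lsig_lower = log(1e-3), lsig_upper = log(10), outer_iter = 500L
  ), control)
  y <- as.numeric(y)
  if (any(!y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(y)) < 2L) {
    stop("complete separation: all outcomes identical", call. = FALSE)
  }
  p <- ncol(X)
  f1 <- as.integer(factor(participant))
  f2 <- as.integer(factor(trial))
  all_qs <- c(max(f1), max(f2))

  active <- is.na(fix_sigma)
  if (any(!active & fix_sigma != 0)) {
    stop("fix_sigma entries must be NA (estimate) or 0 (pin to zero)")
  }
  gs <- list(f1, f2)[active]
  qs <- all_qs[active]
  Z <- make_z(gs, qs)
  expand_sig <- function(sig) rep(sig, times = qs)

  # starting beta from plain logistic regression (Newton, separation-guarded)
  init <- pirls_joint(y, X,
    Z = NULL, sigv = numeric(0), beta0 = numeric(p),
    tol = ctrl$pirls_tol, beta_bound = ctrl$beta_bound
  )
  beta0 <- init$beta

  if (sum(active) == 0L) {
    ll <- sum(y * drop(X %*% init$beta) -
      log1pexp(drop(X %*% init$beta)))
    V <- beta_vcov(y, X, init$beta, NULL, numeric(0), numeric(0))
    return(list(
      beta = init$beta, vcov = V, sigma = c(0, 0),
      u = list(participant = numeric(0), trial = numeric(0)),
      loglik = ll, converged = TRUE, boundary = c(FALSE, FALSE),
      grad_norm = NA_real_, n_evals = 1L,
      groups = list(participant = f1, trial = f2)
    ))
  }

  env <- new.env()
  env$u <- numeric(sum(qs))
  env$beta <- beta0
  env$evals <- 0L

  # Stage A: theta-only search with beta profiled by joint PIRLS.
  devA <- function(lsig) {
    sigv <- expand_sig(exp(lsig))
    fit <- tryCatch(
      pirls_joint(y, X, Z, sigv,
        beta0 = env$beta, u0 = env$u,
        tol = ctrl$pirls_tol, beta_bound = ctrl$beta_bound
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(1e10)
    }
    env$u <- fit$u
    env$beta <- fit$beta
    -2 * laplace_ll(y, X, fit$beta, Z, sigv,
      u0 = fit$u,
      tol = ctrl$pirls_tol
    )$ll
  }
  if (sum(active) == 1L) {
    oA <- stats::optimize(devA,
      lower = ctrl$lsig_lower,
      upper = ctrl$lsig_upper, tol = 1e-3
    )
    lsigA <- oA$minimum
    devA(lsigA) # refresh env$beta / env$u at the chosen point
  } else {
    oA <- stats::optim(rep(log(0.5), 2L), devA,
      method = "Nelder-Mead",
      control = list(maxit = 20L, reltol = 1e-2)
    )
    lsigA <- oA$par
  }
  betaA <- env$beta

  # Stage B: joint outer optimization over (beta, log sigma), driven by the
  # exact Laplace-deviance gradient (one PIRLS solve serves both the
  # objective and the gradient at a given point).
  inner_tol <- ctrl$pirls_tol
  evalB <- function(par) {
    if (!is.null(env$last_par) && identical(par, env$last_par)) {
      return(env$last)
    }
    env$evals <- env$evals + 1L
    out <- tryCatch(
      laplace_ll_grad(y, X, par[seq_len(p)], Z, gs, qs,
        exp(par[p + seq_along(qs)]),
        u0 = env$u, tol = inner_tol
      ),
      error = function(e) NULL
    )
    if (is.null(out)) {
      out <- list(ll = -1e10, grad = rep(0, length(par)), u = env$u)
    }
    env$u <- out$u
    env$last_par <- par
    env$last <- out
    out
  }
  lower <- c(rep(-ctrl$beta_bound, p), rep(ctrl$lsig_lower, length(qs)))
  upper <- c(rep(ctrl$beta_bound, p), rep(ctrl$lsig_upper, length(qs)))
  # projected deviance gradient: at an active bound (a variance pinned at
  # its floor, say) the component pushing into the bound is legitimately
  # nonzero and does not count against convergence
  proj_grad <- function(par, grad_ll) {
    g <- -2 * grad_ll
    g[(par <= lower + 1e-8 & g > 0) | (par >= upper - 1e-8 & g < 0)] <- 0
    g
  }

  start <- c(betaA, lsigA)
  dev_prev <- Inf
  settled <- FALSE
  for (attempt in 1:3) {
    oB <- stats::nlminb(start,
      objective = function(par) -2 * evalB(par)$ll,
      gradient = function(par) -2 * evalB(par)$grad,
      lower = lower, upper = upper,
      control = list(
        iter.max = ctrl$outer_iter, eval.max = 4L * ctrl$outer_iter,
        rel.tol = ctrl$outer_rel_tol * 1e-2
      )
    )
    par <- oB$par
    env$last_par <- NULL
    fin <- evalB(par)
    grad_norm <- max(abs(proj_grad(par, fin$grad)))
    dev_now <- -2 * fin$ll
    if (grad_norm < 0.05) break
    # a sizeable gradient can coexist with a converged fit when the
    # objective is extremely curved (small variances); accept once a
    # restart no longer improves the deviance measurably
    if (dev_prev - dev_now < max(1e-6 * abs(dev_now), 1e-4)) {
      settled <- TRUE
      break
    }
    dev_prev <- dev_now
    start <- par
    inner_tol <- max(inner_tol * 1e-2, 1e-14)
    env$last_par <- NULL
  }
  beta <- par[seq_len(p)]
  if (max(abs(beta)) >= ctrl$beta_bound - 1e-6) {
    stop("complete separation detected: |beta| exceeded ", ctrl$beta_bound,
      " on the logit scale",
      call. = FALSE
    )
  }
  sig_act <- exp(par[p + seq_along(qs)])
  u <- fin$u

  # a fit that will not settle in the interior usually wants a variance on
  # the zero boundary, which the log-SD scale can only approach
  # asymptotically; try pinning each unsettled block and keep the better fit
  if (grad_norm >= 0.05 && !settled) {
    for (b in which(active)) {
      fs <- fix_sigma
      fs[b] <- 0
      alt <- tryCatch(
        glmm_laplace(y, X, participant, trial,
          fix_sigma = fs,
          control = control
        ),
        error = function(e) NULL
      )
      if (!is.null(alt) && alt$loglik >= fin$ll - 5e-5) {
        alt$boundary[b] <- TRUE
        return(alt)
      }
    }
  }

  V <- beta_vcov(y, X, beta, Z, expand_sig(sig_act), u)

  sigma <- numeric(2)
  sigma[active] <- sig_act
  boundary <- logical(2)
  boundary[active] <- par[p + seq_along(qs)] <= ctrl$lsig_lower + 1e-3
  sigma[active][boundary[active]] <- 0

  u_split <- list(participant = numeric(all_qs[1]), trial = numeric(all_qs[2]))
  if (active[1]) u_split$participant <- u[seq_len(qs[1])]
  if (active[2]) {
    off <- if (active[1]) qs[1] else 0L
    u_split$trial <- u[off + seq_len(all_qs[2])]
  }

  list(
    beta = beta, vcov = V, sigma = sigma, u = u_split,
    loglik = fin$ll,
    converged = oB$convergence == 0 || grad_norm < 0.05 || settled,
    boundary = boundary, grad_norm = grad_norm, n_evals = env$evals,
    groups = list(participant = f1, trial = f2)
  )
}
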