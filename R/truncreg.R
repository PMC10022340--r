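# Maximum-likelihood normal linear regression left-truncated at a known
# point.  This is the second-stage model of the double bootstrap: the DEA
# distance delta >= 1 (the reciprocal of the efficiency score) is regressed
# on country covariates, and the normal error is truncated so that the
# fitted response respects delta >= 1.

# log-likelihood and analytic score for theta = c(beta, log sigma)
.tr_loglik <- function(theta, y, Z, point) {
  p <- ncol(Z)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1L])
  mu <- drop(Z %*% beta)
  a <- (y - mu) / sigma
  c0 <- (mu - point) / sigma
  sum(dnorm(a, log = TRUE)) - length(y) * log(sigma) -
    sum(pnorm(c0, log.p = TRUE))
}

.tr_score <- function(theta, y, Z, point) {
  p <- ncol(Z)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1L])
  mu <- drop(Z %*% beta)
  a <- (y - mu) / sigma
  c0 <- (mu - point) / sigma
  # inverse Mills ratio phi(c)/Phi(c), computed on the log scale for stability
  imr <- exp(dnorm(c0, log = TRUE) - pnorm(c0, log.p = TRUE))
  gbeta <- drop(crossprod(Z, (a - imr) / sigma))
  glogsig <- sum(a^2 - 1 + c0 * imr) # d/d log sigma
  c(gbeta, glogsig)
}

#' Fit a left-truncated normal regression by maximum likelihood
#'
#' Maximises \deqn{\sum_i \log\phi\{(\delta_i - z_i\beta)/\sigma\} -
#' \log\sigma - \log\Phi\{(z_i\beta - c)/\sigma\}} over \eqn{(\beta,
#' \log\sigma)} with a quasi-Newton optimiser and analytic gradient, starting
#' from the ordinary least-squares fit.  The truncation point \eqn{c}
#' defaults to 1, the lower bound of the DEA distance scale.
#'
#' Observations exactly at the truncation point are excluded by default: the
#' second-stage estimator conditions on strictly inefficient units, and units
#' sitting on the empirical frontier carry no information about the truncated
#' error.  Set `include_boundary = TRUE` to keep them (they are then nudged
#' to the boundary itself, where the density is still finite).
#'
#' @param delta numeric response vector, all `>= truncation_point`.
#' @param Z design matrix including the intercept column.
#' @param truncation_point left truncation bound (default 1).
#' @param include_boundary keep observations with `delta == truncation_point`?
#' @param control list: `maxit` (default 500), `reltol` (default 1e-12),
#'   `grad_tol` (default 1e-5) for the convergence flag.
#' @return An object of class `truncreg_fit`: `beta` (named, intercept
#'   first), `sigma`, `loglik`, `gradient_norm`, `converged`, `n_used`,
#'   `truncation_point`, `vcov_names`.
#' @export
fit_truncated_regression <- function(delta, Z, truncation_point = 1,
                                     include_boundary = FALSE,
                                     control = list()) {
  ctl <- modifyList(list(maxit = 500L, reltol = 1e-12, grad_tol = 1e-5),
                    control)
  Z <- as.matrix(Z)
  delta <- as.numeric(delta)
  if (length(delta) != nrow(Z)) stop("delta and Z must have matching rows")
  if (any(delta < truncation_point - 1e-9)) {
    stop("all responses must lie at or above the truncation point")
  }
  keep <- if (include_boundary) rep(TRUE, length(delta)) else
    delta > truncation_point + 1e-9
  y <- delta[keep]
  Zk <- Z[keep, , drop = FALSE]
  n <- length(y)
  p <- ncol(Zk)
  if (n <= p + 1L) stop("too few observations above the truncation point (",
                        n, ") for ", p, " coefficients")
  if (qr(Zk)$rank < p) stop("design matrix is rank deficient")
  cn <- colnames(Zk)
  if (is.null(cn)) cn <- c("(Intercept)", paste0("z", seq_len(p - 1L)))[seq_len(p)]

  ols <- lm.fit(Zk, y)
  beta0 <- ols$coefficients
  sig0 <- sqrt(max(sum(ols$residuals^2) / max(n - p, 1), 1e-6))
  theta0 <- c(beta0, log(sig0))
  ll0 <- .tr_loglik(theta0, y, Zk, truncation_point)

  opt <- optim(theta0, fn = .tr_loglik, gr = .tr_score,
               y = y, Z = Zk, point = truncation_point,
               method = "BFGS",
               control = list(fnscale = -1, maxit = ctl$maxit,
                              reltol = ctl$reltol))
  theta <- opt$par
  if (opt$value < ll0) { # never return worse than the initializer
    theta <- theta0
    opt$value <- ll0
  }
  # Newton polish on the analytic score (finite-difference Jacobian) to push
  # the gradient norm to machine level; kept only while the likelihood and
  # the score norm improve
  for (it in seq_len(25L)) {
    g <- .tr_score(theta, y, Zk, truncation_point)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-10) break
    k <- length(theta)
    H <- matrix(0, k, k)
    h <- 1e-6 * pmax(abs(theta), 1)
    for (j in seq_len(k)) {
      e <- rep(0, k); e[j] <- h[j]
      H[, j] <- (.tr_score(theta + e, y, Zk, truncation_point) -
                 .tr_score(theta - e, y, Zk, truncation_point)) / (2 * h[j])
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    cand <- theta - step
    # backtrack if the full step worsens the likelihood
    for (half in 0:10) {
      llc <- .tr_loglik(cand, y, Zk, truncation_point)
      if (is.finite(llc) && llc >= opt$value - 1e-12) break
      cand <- theta - step / 2^(half + 1)
    }
    gc2 <- .tr_score(cand, y, Zk, truncation_point)
    if (!is.finite(llc) || sqrt(sum(gc2^2)) >= gn) break
    theta <- cand
    opt$value <- max(opt$value, llc)
  }
  g <- .tr_score(theta, y, Zk, truncation_point)
  gnorm <- sqrt(sum(g^2))
  beta <- setNames(theta[seq_len(p)], cn)
  structure(list(beta = beta,
                 sigma = unname(exp(theta[p + 1L])),
                 loglik = opt$value,
                 loglik_start = ll0,
                 gradient_norm = gnorm,
                 converged = opt$convergence == 0L && gnorm <= ctl$grad_tol,
                 n_used = n,
                 truncation_point = truncation_point),
            class = "truncreg_fit")
}

#' @export
print.truncreg_fit <- function(x, ...) {
  cat(sprintf("Left-truncated normal regression (truncation at %g), n = %d\n",
              x$truncation_point, x$n_used))
  print(round(x$beta, 4))
  cat(sprintf("sigma = %.4f, logLik = %.3f, converged: %s\n",
              x$sigma, x$loglik, x$converged))
  invisible(x)
}

#' Draw from a left-truncated normal distribution
#'
#' Inverse-CDF sampling of \eqn{N(\mu, \sigma^2)} conditioned on the value
#' being at least `lower`.  When the untruncated mass above `lower` is
#' numerically exhausted the sampler falls back to a translated-exponential
#' rejection proposal for the extreme tail.
#'
#' @param n number of draws.
#' @param mean,sd mean(s) and standard deviation of the parent normal
#'   (recycled to length `n`).
#' @param lower left truncation bound(s).
#' @return Numeric vector of `n` draws, each `>= lower`.
#' @export
rtruncnorm_left <- function(n, mean = 0, sd = 1, lower = 0) {
  if (any(sd <= 0)) stop("sd must be positive")
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  lower <- rep_len(lower, n)
  alpha <- (lower - mean) / sd
  out <- numeric(n)
  plo <- pnorm(alpha)
  easy <- plo < 1 - 1e-15 & alpha < 6
  if (any(easy)) {
    u <- runif(sum(easy), plo[easy], 1)
    out[easy] <- mean[easy] + sd[easy] * qnorm(u)
  }
  if (any(!easy)) {
    # extreme tail: exponential proposal with the optimal rate (Robert 1995)
    idx <- which(!easy)
    for (i in idx) {
      a <- alpha[i]
      rate <- (a + sqrt(a^2 + 4)) / 2
      repeat {
        e <- a + stats::rexp(1, rate)
        if (runif(1) <= exp(-(e - rate)^2 / 2)) { out[i] <- mean[i] + sd[i] * e; break }
      }
    }
  }
  pmax(out, lower)
}
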