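# Two-stage double bootstrap for DEA distance scores (the standard
# "Algorithm 2" structure): loop 1 bias-corrects the distances using
# covariate-conditional truncated-normal pseudo-data; loop 2 bootstraps the
# truncated regression of the bias-corrected distances on the covariates to
# obtain coefficient confidence intervals.

#' Configuration for the double bootstrap
#'
#' @param L1 loop-1 (bias-correction) replications; the study default is
#'   1,000.
#' @param L2 loop-2 (coefficient CI) replications; the study default is
#'   3,000.
#' @param alpha complement of the CI level (default 0.05 for 95% CIs).
#' @param seed master integer seed; every replication derives its own
#'   substream seed from it, so results are reproducible bit-for-bit.
#' @param include_boundary passed to [fit_truncated_regression()]; keep
#'   frontier units (distance exactly 1) in the truncated fits?
#' @return A list of class `sw_config`.
#' @export
sw_config <- function(L1 = 1000L, L2 = 3000L, alpha = 0.05, seed = 1L,
                      include_boundary = FALSE) {
  stopifnot(L1 >= 1, L2 >= 1, alpha > 0, alpha < 1)
  structure(list(L1 = as.integer(L1), L2 = as.integer(L2), alpha = alpha,
                 seed = as.integer(seed),
                 include_boundary = isTRUE(include_boundary)),
            class = "sw_config")
}

#' Pseudo-output construction for the bias-correction loop
#'
#' Shrinks each unit's outputs by the ratio of its estimated distance to a
#' bootstrap draw: row i of the result is \eqn{(\hat\delta_i/\delta^*_i)
#' y_i}.  Inputs are left unchanged by the output-oriented bootstrap.
#'
#' @param Y output matrix (rows = DMUs).
#' @param delta_hat estimated distances, `>= 1`.
#' @param delta_star bootstrap distance draws, `>= 1`.
#' @return Matrix of pseudo-outputs, same shape as `Y`.
#' @export
pseudo_outputs <- function(Y, delta_hat, delta_star) {
  Y <- as.matrix(Y)
  if (length(delta_hat) != nrow(Y) || length(delta_star) != nrow(Y)) {
    stop("delta vectors must match the rows of Y")
  }
  if (any(delta_star < 1 - 1e-12)) stop("delta_star must be >= 1")
  Y * (delta_hat / delta_star)
}

#' Bootstrap bias correction of a distance score
#'
#' `bias_hat = mean(bootstrap_deltas) - delta_hat`;
#' `delta_bc = delta_hat - bias_hat`, clamped to at least 1 (clamping is
#' counted by the caller).  Because the empirical frontier lies inside the
#' true frontier, raw distances are biased downward (efficiencies biased
#' upward), so the correction typically increases the distance.
#'
#' @param delta_hat estimated distance of one DMU.
#' @param bootstrap_deltas its loop-1 bootstrap distances.
#' @return List with `bias_hat`, `delta_bc` (clamped), `clamped` flag.
#' @export
bias_correct <- function(delta_hat, bootstrap_deltas) {
  if (!length(bootstrap_deltas)) stop("bootstrap_deltas must be nonempty")
  bias_hat <- mean(bootstrap_deltas) - delta_hat
  raw <- delta_hat - bias_hat
  list(bias_hat = bias_hat, delta_bc = max(raw, 1), clamped = raw < 1)
}

#' Run the Simar-Wilson double bootstrap
#'
#' Stage 1: score all DMUs (output-oriented VRS DEA), fit the truncated
#' regression of the distances on `Z`, and repeat `L1` times: draw
#' truncated-normal errors around each unit's fitted inefficiency, build
#' pseudo-outputs, rescore every unit against the pseudo reference set.
#' The bootstrap distances give each unit's bias estimate, bias-corrected
#' distance and percentile CI (percentile interval of the bootstrap
#' distribution shifted by the bias estimate, then mirrored to the
#' efficiency scale).
#'
#' Stage 2: refit the truncated regression on the bias-corrected distances,
#' then repeat `L2` times: simulate truncated responses from the fitted
#' model and refit, giving bootstrap SEs and percentile CIs for every
#' coefficient and for sigma.
#'
#' @param X input matrix (one column here: spending per PLHIV).
#' @param Y output matrix (ART and PMTCT coverage).
#' @param Z covariate matrix *without* intercept (added internally), or with
#'   an explicit `(Intercept)` first column.
#' @param config an [sw_config()].
#' @param dmu_ids optional DMU labels.
#' @return An object of class `sw_result`; see Details.  Key pieces:
#'   `scores` data.frame (`delta_hat`, `bias_hat`, `delta_bc`, `eff_bc`,
#'   `ci_low`/`ci_high` on the distance scale, `eff_ci_low`/`eff_ci_high`),
#'   `beta_hat`, `sigma_hat`, `beta_se`, `beta_ci`, `sigma_ci`, `boot_beta`
#'   matrix, `stage1_fit`, `stage2_fit`, `clamped` count, `config`.
#' @export
run_double_bootstrap <- function(X, Y, Z, config = sw_config(),
                                 dmu_ids = NULL) {
  stopifnot(inherits(config, "sw_config"))
  X <- as.matrix(X); Y <- as.matrix(Y); Z <- as.matrix(Z)
  n <- nrow(X)
  if (nrow(Y) != n || nrow(Z) != n) stop("X, Y, Z must have matching rows")
  if (is.null(dmu_ids)) dmu_ids <- as.character(seq_len(n))
  has_int <- ncol(Z) > 0 && all(abs(Z[, 1] - 1) < 1e-12)
  Zi <- if (has_int) Z else cbind(`(Intercept)` = 1, Z)

  set.seed(config$seed)
  seeds1 <- sample.int(.Machine$integer.max - 1L, config$L1)
  seeds2 <- sample.int(.Machine$integer.max - 1L, config$L2)

  # stage 1: initial scores and first-pass truncated fit
  prob <- dea_problem(X, Y, rts = "vrs", dmu_ids = dmu_ids)
  delta_hat <- dea_score_all(prob)$delta
  fit1 <- fit_truncated_regression(delta_hat, Zi,
                                   include_boundary = config$include_boundary)
  mu1 <- drop(Zi %*% fit1$beta)

  # loop 1: covariate-conditional pseudo-data, rescore on pseudo frontier
  boot_delta <- matrix(NA_real_, n, config$L1)
  for (b in seq_len(config$L1)) {
    set.seed(seeds1[b])
    eps <- rtruncnorm_left(n, mean = 0, sd = fit1$sigma, lower = 1 - mu1)
    delta_star <- mu1 + eps
    Ystar <- pseudo_outputs(Y, delta_hat, delta_star)
    boot_delta[, b] <- dea_score_ref(X, Y, X, Ystar, rts = "vrs")
  }

  bias_hat <- rowMeans(boot_delta) - delta_hat
  raw_bc <- delta_hat - bias_hat
  clamped <- sum(raw_bc < 1)
  delta_bc <- pmax(raw_bc, 1)
  # percentile interval of the bootstrap distance distribution, recentred on
  # the bias-corrected score: the bootstrap quantiles sit around
  # mean(delta*) = delta_hat + bias, so subtracting the bias twice moves the
  # interval's centre from delta_hat to delta_bc = delta_hat - bias
  qs <- t(apply(boot_delta, 1, quantile,
                probs = c(config$alpha / 2, 1 - config$alpha / 2),
                names = FALSE))
  ci_low <- pmax(qs[, 1] - 2 * bias_hat, 1)
  ci_high <- pmax(qs[, 2] - 2 * bias_hat, ci_low)

  scores <- data.frame(dmu_id = dmu_ids,
                       delta_hat = delta_hat,
                       bias_hat = bias_hat,
                       delta_bc = delta_bc,
                       eff_init = 1 / delta_hat,
                       eff_bc = 1 / delta_bc,
                       ci_low = ci_low,
                       ci_high = ci_high,
                       eff_ci_low = 1 / ci_high,
                       eff_ci_high = 1 / ci_low,
                       stringsAsFactors = FALSE)

  # stage 2: truncated fit on bias-corrected distances, then parametric
  # bootstrap of the fit
  fit2 <- fit_truncated_regression(delta_bc, Zi,
                                   include_boundary = config$include_boundary)
  mu2 <- drop(Zi %*% fit2$beta)
  p <- length(fit2$beta)
  boot_beta <- matrix(NA_real_, config$L2, p,
                      dimnames = list(NULL, names(fit2$beta)))
  boot_sigma <- rep(NA_real_, config$L2)
  nonconv <- 0L
  for (b in seq_len(config$L2)) {
    set.seed(seeds2[b])
    eps <- rtruncnorm_left(n, mean = 0, sd = fit2$sigma, lower = 1 - mu2)
    dstar <- mu2 + eps
    fb <- tryCatch(fit_truncated_regression(dstar, Zi, include_boundary = TRUE),
                   error = function(e) NULL)
    if (is.null(fb)) { nonconv <- nonconv + 1L; next }
    if (!fb$converged) nonconv <- nonconv + 1L
    boot_beta[b, ] <- fb$beta
    boot_sigma[b] <- fb$sigma
  }
  if (nonconv > 0.01 * config$L2) {
    warning(nonconv, " of ", config$L2,
            " loop-2 refits did not converge cleanly")
  }
  ok <- !is.na(boot_sigma)
  pr <- c(config$alpha / 2, 1 - config$alpha / 2)
  beta_ci <- t(apply(boot_beta[ok, , drop = FALSE], 2, quantile, probs = pr,
                     names = FALSE))
  colnames(beta_ci) <- c("lower", "upper")
  beta_se <- apply(boot_beta[ok, , drop = FALSE], 2, sd)
  pval <- 2 * pnorm(-abs(fit2$beta) / beta_se)

  structure(list(scores = scores,
                 beta_hat = fit2$beta,
                 sigma_hat = fit2$sigma,
                 beta_se = beta_se,
                 beta_pvalue = pval,
                 beta_ci = beta_ci,
                 sigma_ci = quantile(boot_sigma[ok], probs = pr, names = FALSE),
                 boot_beta = boot_beta,
                 boot_sigma = boot_sigma,
                 stage1_fit = fit1,
                 stage2_fit = fit2,
                 clamped = clamped,
                 n_nonconverged = nonconv,
                 config = config),
            class = "sw_result")
}

#' @export
print.sw_result <- function(x, ...) {
  cat(sprintf("Simar-Wilson double bootstrap: %d DMUs, L1 = %d, L2 = %d\n",
              nrow(x$scores), x$config$L1, x$config$L2))
  cat(sprintf("Mean efficiency: initial %.3f -> bias-corrected %.3f (mean bias %.4f on the efficiency scale)\n",
              mean(x$scores$eff_init), mean(x$scores$eff_bc),
              mean(x$scores$eff_bc - x$scores$eff_init)))
  tab <- data.frame(coef = round(x$beta_hat, 4),
                    se = round(x$beta_se, 4),
                    p = round(x$beta_pvalue, 4),
                    ci_low = round(x$beta_ci[, 1], 4),
                    ci_high = round(x$beta_ci[, 2], 4))
  print(tab)
  cat(sprintf("sigma = %.4f [%.4f, %.4f]\n", x$sigma_hat,
              x$sigma_ci[1], x$sigma_ci[2]))
  invisible(x)
}
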