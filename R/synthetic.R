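# Synthetic country-year panels with a known production frontier and known
# covariate-driven inefficiency, so every pipeline stage can be tested
# against ground truth.
#
# Frontier family: g_m(x) = a_m * x^(b_m) with 0 < b_m < 1 — monotone and
# concave in the input (VRS-compatible), calibrated so frontier outputs peak
# just under 100 at the top of the spending range.  True distances follow
# the second-stage model delta = z beta + eps with eps truncated-normal so
# delta >= 1, and observed outputs are y_m = g_m(x) / delta, kept in (0,100].

.default_beta_true <- function() {
  c(intercept = 1.5,
    rule_of_law = -0.20, anc_coverage = -0.15, gni_pc = 0.15,
    che_pct_gdp = -0.10, che_pc = 0.10, pop_density = 0.05,
    hdi = -0.25, hiv_prev = -0.30, oop_share = 0.10, dahs_share = 0.05,
    nurses_10k = 0, health_posts_100k = 0, gov_share = 0, ext_che_pct = 0)
}

# random correlation matrix via a Gaussian-copula style construction,
# rejected until every pairwise |rho| stays below the cap
.random_corr <- function(p, cap = 0.7, max_tries = 200L) {
  for (k in seq_len(max_tries)) {
    W <- matrix(rnorm(p * (p + 2)), p + 2, p)
    S <- crossprod(W)
    R <- stats::cov2cor(S)
    if (max(abs(R[upper.tri(R)])) < cap) return(R)
  }
  diag(p)
}

#' Generate a synthetic country-year panel with known truth
#'
#' The default scenario mirrors the study dimensions: 78 countries over
#' 2010-2018 with about 83% of country-years retained (~581 observations),
#' one input (spending per PLHIV, log-normal within \[45, 3502\] USD), two
#' percentage outputs, 14 covariates (10 base + 4 auxiliary, pairwise
#' `|rho| < 0.7`), 15% covariate cells deleted completely at random, and
#' inefficiency driven by the covariates through
#' `delta = beta0 + z beta + eps`, `eps ~ N(0, sigma^2)` truncated so
#' `delta >= 1`.
#'
#' @param n_countries number of countries (>= 5).
#' @param years calendar years of the panel.
#' @param beta_true named inefficiency coefficients, intercept first; one
#'   entry per covariate after the intercept.  Covariates named here are the
#'   ones generated.
#' @param sigma_true truncated-normal inefficiency scale (>= 0).
#' @param missing_rate fraction of covariate cells deleted MCAR, in [0, 0.5).
#' @param retention fraction of country-years kept (emulates the unbalanced
#'   availability of input/output data; 1 keeps the full grid).
#' @param year_effect linear drift of true inefficiency per year (negative
#'   values make programmes more efficient over time).
#' @param frontier_b concavity exponents of the two outputs.
#' @param seed integer RNG seed; the generator is deterministic given it.
#' @return List with `panel` (an `hiv_panel`) and `truth` (a
#'   `synthetic_truth`: `beta_true`, `sigma_true`, `delta_true`, frontier
#'   parameters, covariate correlation matrix, seed).
#' @export
generate_panel <- function(n_countries = 78L, years = 2010:2018,
                           beta_true = .default_beta_true(),
                           sigma_true = 0.3, missing_rate = 0.15,
                           retention = 0.83, year_effect = 0,
                           frontier_b = c(0.12, 0.07), seed = 1L) {
  stopifnot(n_countries >= 5, missing_rate >= 0, missing_rate < 0.5,
            sigma_true >= 0, retention > 0, retention <= 1)
  if (is.null(names(beta_true))) {
    names(beta_true) <- c("intercept",
                          paste0("z", seq_len(length(beta_true) - 1L)))
  }
  covs <- names(beta_true)[-1]
  p <- length(covs)
  set.seed(seed)

  grid <- expand.grid(country = seq_len(n_countries), year = years)
  keep <- if (retention < 1) runif(nrow(grid)) < retention else rep(TRUE, nrow(grid))
  # make sure every country keeps at least one year
  for (cidx in seq_len(n_countries)) {
    rows <- which(grid$country == cidx)
    if (!any(keep[rows])) keep[rows[sample.int(length(rows), 1)]] <- TRUE
  }
  grid <- grid[keep, ]
  n <- nrow(grid)

  # input: spending per PLHIV, log-normal within the observed USD range
  x <- rlnorm(n, meanlog = log(300), sdlog = 0.9)
  while (any(bad <- x < 45 | x > 3502)) {
    x[bad] <- rlnorm(sum(bad), meanlog = log(300), sdlog = 0.9)
  }

  # covariates: Gaussian copula with a random correlation matrix (|rho|<0.7)
  R <- if (p > 1) .random_corr(p) else diag(1)
  Zs <- matrix(rnorm(n * p), n, p) %*% chol(R)
  colnames(Zs) <- covs

  mid <- mean(years)
  mu <- beta_true[1] + drop(Zs %*% beta_true[-1]) +
    year_effect * (grid$year - mid)
  eps <- if (sigma_true > 0) {
    rtruncnorm_left(n, mean = 0, sd = sigma_true, lower = 1 - mu)
  } else {
    pmax(1 - mu, 0)
  }
  delta_true <- pmax(mu + eps, 1)

  a <- c(99, 98) / max(x)^frontier_b # frontier peaks just under 100
  g <- cbind(a[1] * x^frontier_b[1], a[2] * x^frontier_b[2])
  Y <- g / delta_true
  if (any(Y <= 0) || any(Y > 100)) {
    stop("generated outputs left (0,100]; offending parameters: sigma_true=",
         sigma_true, ", beta intercept=", beta_true[1])
  }

  Zmiss <- Zs
  if (missing_rate > 0) {
    del <- matrix(runif(n * p) < missing_rate, n, p)
    Zmiss[del] <- NA_real_
  }

  iso3 <- sprintf("C%02d", grid$country)
  plhiv <- round(runif(n, 5e3, 2e6))
  df <- data.frame(country_code = iso3, year = grid$year,
                   spend_total = x * plhiv, plhiv = plhiv,
                   pct_art = Y[, 1], pct_pmtct = Y[, 2],
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(Zmiss))
  df$who_region <- sprintf("WHO-%d", (grid$country %% 6) + 1)
  df$unaids_region <- sprintf("UNAIDS-%d", (grid$country %% 7) + 1)
  gni <- exp(rnorm(n_countries, log(3800), 1))[grid$country]
  df$income_group <- as.character(classify_income(gni))

  panel <- hiv_panel(df, covariates = covs)
  truth <- structure(list(beta_true = beta_true, sigma_true = sigma_true,
                          delta_true = delta_true,
                          efficiency_true = 1 / delta_true,
                          frontier = list(a = a, b = frontier_b),
                          covariate_corr = R,
                          Z_true = Zs,
                          missing_rate = missing_rate,
                          year_effect = year_effect,
                          dmu_id = paste(iso3, grid$year, sep = ":"),
                          seed = seed),
                     class = "synthetic_truth")
  list(panel = panel, truth = truth)
}

#' Recovery metrics: how well did the pipeline find the planted truth?
#'
#' @param truth a `synthetic_truth` from [generate_panel()].
#' @param result an `sw_result` from [run_double_bootstrap()] computed on the
#'   same panel (same DMUs, same order).
#' @return List with `pearson`/`spearman` correlations between the
#'   bias-corrected efficiencies and the true efficiencies `1/delta_true`,
#'   a per-coefficient table (`estimate`, `truth`, `bias`, `covered` by the
#'   bootstrap CI), and RMSE of the coefficients.
#' @export
recovery_metrics <- function(truth, result) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(result, "sw_result"))
  if (nrow(result$scores) != length(truth$delta_true)) {
    stop("panel size mismatch between truth (", length(truth$delta_true),
         ") and result (", nrow(result$scores), ")")
  }
  ids <- as.character(result$scores$dmu_id)
  default_ids <- identical(ids, as.character(seq_along(ids)))
  if (!is.null(truth$dmu_id) && !default_ids && !identical(ids, truth$dmu_id)) {
    stop("DMU ids of truth and result do not match")
  }
  eff_true <- 1 / truth$delta_true
  eff_bc <- result$scores$eff_bc
  bt <- truth$beta_true
  bh <- result$beta_hat
  k <- min(length(bt), length(bh))
  tab <- data.frame(coefficient = names(bh)[seq_len(k)],
                    estimate = unname(bh[seq_len(k)]),
                    truth = unname(bt[seq_len(k)]),
                    stringsAsFactors = FALSE)
  tab$bias <- tab$estimate - tab$truth
  tab$ci_low <- result$beta_ci[seq_len(k), 1]
  tab$ci_high <- result$beta_ci[seq_len(k), 2]
  tab$covered <- tab$truth >= tab$ci_low & tab$truth <= tab$ci_high
  list(pearson = cor(eff_bc, eff_true),
       spearman = cor(eff_bc, eff_true, method = "spearman"),
       coefficients = tab,
       beta_rmse = sqrt(mean(tab$bias^2)))
}
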