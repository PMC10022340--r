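# Two-step missing-covariate imputation.
#
# Step 1 (temporal): within each country and covariate series, interior gaps
# are filled with the within-country mean of the observed values, and years
# outside the observed span are filled by carrying the earliest value back /
# the latest value forward.
#
# Step 2 (MVN): remaining gaps (countries with no observation at all for a
# covariate) are imputed from a multivariate-normal model fitted to the
# standardized pooled covariates by EM; M completed datasets are drawn from
# the conditional distribution of missing given observed, and each missing
# cell is set to the mean of its M draws.  Inputs and outputs are never
# imputed.

#' Temporal fill of one within-country covariate series
#'
#' @param values numeric vector with gaps (`NA`), indexed by consecutive
#'   study years.
#' @param years optional year labels, same length (only used for names).
#' @return List with `values` (completed where possible) and `provenance`
#'   (`"observed"`, `"temporal_fill"`, `"edge_carry"`, or `"missing"` when
#'   the whole series is unobserved and is left for the MVN step).
#' @export
fill_within_country <- function(values, years = seq_along(values)) {
  stopifnot(length(values) == length(years))
  prov <- ifelse(is.na(values), "missing", "observed")
  obs <- which(!is.na(values))
  if (length(obs) == 0L) {
    return(list(values = values, provenance = prov))
  }
  out <- values
  m <- mean(values[obs])
  interior <- setdiff(seq(min(obs), max(obs)), obs)
  if (length(interior)) {
    out[interior] <- m
    prov[interior] <- "temporal_fill"
  }
  before <- seq_len(min(obs) - 1L)
  if (length(before)) {
    out[before] <- values[min(obs)]
    prov[before] <- "edge_carry"
  }
  after <- if (max(obs) < length(values)) seq(max(obs) + 1L, length(values)) else integer(0)
  if (length(after)) {
    out[after] <- values[max(obs)]
    prov[after] <- "edge_carry"
  }
  names(out) <- names(prov) <- years
  list(values = out, provenance = prov)
}

# EM for the mean and covariance of a multivariate normal with missing data,
# on already-standardized columns.  Ridge keeps the covariance invertible.
.mvn_em <- function(Z, ridge = 1e-6, max_iter = 200L, tol = 1e-6) {
  n <- nrow(Z); p <- ncol(Z)
  mu <- vapply(seq_len(p), function(j) mean(Z[, j], na.rm = TRUE), numeric(1))
  mu[is.nan(mu)] <- 0
  S <- suppressWarnings(stats::cov(Z, use = "pairwise.complete.obs"))
  S[!is.finite(S)] <- 0
  diag(S)[diag(S) < ridge] <- 1
  S <- S + ridge * diag(p)
  pattern <- apply(is.na(Z), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(n), pattern)
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    sumx <- numeric(p)
    sumxx <- matrix(0, p, p)
    for (g in groups) {
      misv <- is.na(Z[g[1], ])
      if (!any(misv)) {
        Xg <- Z[g, , drop = FALSE]
        sumx <- sumx + colSums(Xg)
        sumxx <- sumxx + crossprod(Xg)
        next
      }
      o <- which(!misv); mi <- which(misv)
      Xg <- Z[g, , drop = FALSE]
      if (length(o) == 0L) {
        cm <- matrix(mu, nrow = length(g), ncol = p, byrow = TRUE)
        cv <- S
      } else {
        Soo_inv <- solve(S[o, o, drop = FALSE] + ridge * diag(length(o)))
        B <- S[mi, o, drop = FALSE] %*% Soo_inv
        cm <- Xg
        cm[, mi] <- matrix(mu[mi], length(g), length(mi), byrow = TRUE) +
          t(B %*% t(sweep(Xg[, o, drop = FALSE], 2, mu[o])))
        cv <- matrix(0, p, p)
        cv[mi, mi] <- S[mi, mi, drop = FALSE] - B %*% t(S[mi, o, drop = FALSE])
      }
      sumx <- sumx + colSums(cm)
      sumxx <- sumxx + crossprod(cm) + length(g) * cv
    }
    mu_new <- sumx / n
    S_new <- sumxx / n - tcrossprod(mu_new)
    S_new <- (S_new + t(S_new)) / 2 + ridge * diag(p)
    delta <- max(abs(mu_new - mu), abs(S_new - S))
    mu <- mu_new; S <- S_new
    if (delta < tol) break
  }
  if (delta >= tol) {
    warning("MVN EM did not reach tolerance ", tol, " after ", max_iter,
            " iterations (last delta = ", signif(delta, 3), ")")
  }
  list(mu = mu, sigma = S, iterations = iter, delta = delta,
       converged = delta < tol)
}

#' Multivariate-normal multiple imputation of remaining covariate gaps
#'
#' Fits an MVN model to the standardized covariates by EM, draws `M`
#' completed datasets from the conditional distributions of missing given
#' observed, and replaces each missing cell with the mean of its `M` draws.
#' Deterministic given `seed`.  Covariates with no observed value anywhere
#' carry no information; they are flagged and filled at the pooled centre
#' (zero on the standardized scale).
#'
#' @param panel an `hiv_panel`, normally after [fill_within_country()] has
#'   been applied (see [impute_panel()]).
#' @param M number of imputations to average (default 50).
#' @param seed integer RNG seed.
#' @return An `imputation_result`: `panel` (completed), `provenance` matrix
#'   (rows = observations, columns = covariates, values in observed /
#'   temporal_fill / edge_carry / mvn_imputed / pooled_mean), `M`, `seed`,
#'   `em` diagnostics.
#' @export
impute_mvn <- function(panel, M = 50L, seed = 1L) {
  covs <- panel_covariates(panel)
  df <- as.data.frame(panel)
  Z <- as.matrix(df[, covs, drop = FALSE])
  prov <- attr(panel, "imputation_provenance")
  if (is.null(prov)) {
    prov <- matrix(ifelse(is.na(Z), "missing", "observed"),
                   nrow(Z), ncol(Z), dimnames = list(NULL, covs))
  }
  if (!anyNA(Z)) {
    out <- panel
    attr(out, "imputation_provenance") <- prov
    return(structure(list(panel = out, provenance = prov, M = M, seed = seed,
                          em = NULL), class = "imputation_result"))
  }

  centers <- vapply(seq_along(covs), function(j) mean(Z[, j], na.rm = TRUE), numeric(1))
  scales <- vapply(seq_along(covs), function(j) sd(Z[, j], na.rm = TRUE), numeric(1))
  dead <- !is.finite(centers) # no observed value anywhere
  centers[dead] <- 0
  scales[!is.finite(scales) | scales < 1e-12] <- 1
  Zs <- sweep(sweep(Z, 2, centers), 2, scales, "/")

  em <- .mvn_em(Zs)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  acc <- matrix(0, nrow(Zs), ncol(Zs))
  for (m_i in seq_len(M)) {
    draw <- Zs
    for (i in which(apply(is.na(Zs), 1, any))) {
      misv <- which(is.na(Zs[i, ]))
      o <- which(!is.na(Zs[i, ]))
      if (length(o)) {
        Soo_inv <- solve(em$sigma[o, o, drop = FALSE] + 1e-8 * diag(length(o)))
        B <- em$sigma[misv, o, drop = FALSE] %*% Soo_inv
        cmean <- em$mu[misv] + drop(B %*% (Zs[i, o] - em$mu[o]))
        cvar <- em$sigma[misv, misv, drop = FALSE] - B %*% t(em$sigma[misv, o, drop = FALSE])
      } else {
        cmean <- em$mu[misv]
        cvar <- em$sigma[misv, misv, drop = FALSE]
      }
      cvar <- (cvar + t(cvar)) / 2
      L <- tryCatch(chol(cvar + 1e-10 * diag(length(misv))),
                    error = function(e) diag(sqrt(pmax(diag(cvar), 0)), length(misv)))
      draw[i, misv] <- cmean + drop(crossprod(L, rnorm(length(misv))))
    }
    acc <- acc + draw
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  Zimp <- acc / M
  filled <- is.na(Z)
  Zs[filled] <- Zimp[filled]
  Zout <- sweep(sweep(Zs, 2, scales, "*"), 2, centers, "+")
  Zout[!filled] <- Z[!filled] # observed cells untouched, exactly

  prov[filled] <- "mvn_imputed"
  if (any(dead)) prov[, dead] <- ifelse(filled[, dead], "pooled_mean", prov[, dead])
  df[, covs] <- Zout
  out <- hiv_panel(df, covariates = covs)
  attr(out, "imputation_provenance") <- prov
  structure(list(panel = out, provenance = prov, M = M, seed = seed, em = em),
            class = "imputation_result")
}

#' Run the full two-step imputation on a panel
#'
#' Applies [fill_within_country()] to every (country, covariate) series,
#' then [impute_mvn()] to whatever remains missing.
#'
#' @inheritParams impute_mvn
#' @return An `imputation_result` (see [impute_mvn()]).
#' @export
impute_panel <- function(panel, M = 50L, seed = 1L) {
  covs <- panel_covariates(panel)
  df <- as.data.frame(panel)
  ord <- order(df$country_code, df$year)
  prov <- matrix("observed", nrow(df), length(covs),
                 dimnames = list(NULL, covs))
  for (cc in unique(df$country_code)) {
    rows <- ord[df$country_code[ord] == cc]
    for (cv in covs) {
      filled <- fill_within_country(df[rows, cv], df$year[rows])
      df[rows, cv] <- filled$values
      prov[rows, cv] <- filled$provenance
    }
  }
  step1 <- hiv_panel(df, covariates = covs)
  attr(step1, "imputation_provenance") <- prov
  impute_mvn(step1, M = M, seed = seed)
}

#' @export
print.imputation_result <- function(x, ...) {
  tab <- table(x$provenance)
  cat("Imputation result (M =", x$M, ", seed =", x$seed, ")\n")
  print(tab)
  invisible(x)
}
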