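test_that("within-country temporal fill applies mean fill and edge carries", {
  # interior gap <- within-country mean; trailing year <- carry forward
  r <- fill_within_country(c(4, NA, 6, NA), years = 2010:2013)
  expect_equal(unname(r$values), c(4, 5, 6, 6))
  expect_equal(unname(r$provenance),
               c("observed", "temporal_fill", "observed", "edge_carry"))

  # fully observed series is untouched
  r2 <- fill_within_country(c(1, 2, 3))
  expect_equal(unname(r2$values), c(1, 2, 3))
  expect_true(all(r2$provenance == "observed"))

  # single observation carried across the whole span
  r3 <- fill_within_country(c(NA, NA, NA, NA, 9, NA, NA, NA, NA), 2010:2018)
  expect_equal(unname(r3$values), rep(9, 9))
  expect_equal(sum(r3$provenance == "edge_carry"), 8)

  # all-missing series passes through for the MVN step
  r4 <- fill_within_country(c(NA_real_, NA_real_))
  expect_true(all(is.na(r4$values)))
  expect_true(all(r4$provenance == "missing"))
})

test_that("MVN imputation is a no-op on complete data and deterministic", {
  df <- tiny_panel_df()
  df$cov_a[2] <- 0.7 # complete
  p <- hiv_panel(df)
  r <- impute_mvn(p, M = 10, seed = 5)
  expect_equal(as.data.frame(r$panel), as.data.frame(p), ignore_attr = TRUE)
  expect_true(all(r$provenance == "observed"))

  g <- generate_panel(n_countries = 20, years = 2012:2016, missing_rate = 0.2,
                      retention = 1, seed = 77)
  a <- impute_panel(g$panel, M = 10, seed = 9)
  b <- impute_panel(g$panel, M = 10, seed = 9)
  expect_identical(as.data.frame(a$panel), as.data.frame(b$panel))

  # observed cells never altered, provenance partitions all cells
  covs <- panel_covariates(g$panel)
  Z0 <- as.matrix(as.data.frame(g$panel)[, covs])
  Z1 <- as.matrix(as.data.frame(a$panel)[, covs])
  obs <- !is.na(Z0)
  expect_identical(Z1[obs], Z0[obs])
  expect_false(anyNA(Z1))
  expect_true(all(a$provenance %in% c("observed", "temporal_fill",
                                      "edge_carry", "mvn_imputed",
                                      "pooled_mean")))
  expect_equal(dim(a$provenance), dim(Z0))
})

test_that("MVN imputation beats pooled-mean fill under MCAR bivariate truth", {
  set.seed(42)
  n <- 500
  rho <- 0.8
  Z <- matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
  miss <- matrix(runif(n * 2) < 0.2, n, 2)
  miss[rowSums(miss) == 2, 2] <- FALSE # keep one column observed per row
  Zm <- Z; Zm[miss] <- NA
  df <- data.frame(country_code = sprintf("C%03d", 1:n), year = 2015L,
                   spend_total = 1e5, plhiv = 100, pct_art = 50, pct_pmtct = 50,
                   v1 = Zm[, 1], v2 = Zm[, 2])
  p <- hiv_panel(df, covariates = c("v1", "v2"))
  r <- impute_mvn(p, M = 50, seed = 3)
  Zi <- as.matrix(as.data.frame(r$panel)[, c("v1", "v2")])
  rmse_mvn <- sqrt(mean((Zi[miss] - Z[miss])^2))
  mean_fill <- Zm
  for (j in 1:2) mean_fill[is.na(Zm[, j]), j] <- mean(Zm[, j], na.rm = TRUE)
  rmse_mean <- sqrt(mean((mean_fill[miss] - Z[miss])^2))
  expect_lte(rmse_mvn, rmse_mean)
})

test_that("averaging more imputations stabilises the imputed cells", {
  # |bias| of imputed-cell means shrinks from M=5 to M=50 on average
  bias <- sapply(1:20, function(rep) {
    set.seed(rep + 500)
    n <- 150
    Z <- matrix(rnorm(n * 2), n, 2) %*% chol(matrix(c(1, .8, .8, 1), 2))
    miss <- matrix(runif(n * 2) < 0.2, n, 2)
    miss[rowSums(miss) == 2, 2] <- FALSE
    Zm <- Z; Zm[miss] <- NA
    df <- data.frame(country_code = sprintf("C%03d", 1:n), year = 2015L,
                     spend_total = 1e5, plhiv = 100, pct_art = 50,
                     pct_pmtct = 50, v1 = Zm[, 1], v2 = Zm[, 2])
    p <- hiv_panel(df, covariates = c("v1", "v2"))
    vals <- sapply(c(5, 50), function(M) {
      r <- impute_mvn(p, M = M, seed = rep)
      Zi <- as.matrix(as.data.frame(r$panel)[, c("v1", "v2")])
      # deviation from the conditional-mean target the averaging approaches
      em <- r$em
      tgt <- numeric(sum(miss))
      kk <- 1
      for (i in which(apply(miss, 1, any))) {
        mi <- which(miss[i, ]); o <- which(!miss[i, ])
        sds <- apply(Zm, 2, sd, na.rm = TRUE); mus <- colMeans(Zm, na.rm = TRUE)
        zs <- (Zm[i, o] - mus[o]) / sds[o]
        cm <- em$mu[mi] + em$sigma[mi, o] / em$sigma[o, o] * (zs - em$mu[o])
        tgt[kk] <- cm * sds[mi] + mus[mi]; kk <- kk + 1
      }
      mean(abs(Zi[miss] - tgt))
    })
    vals
  })
  expect_lt(mean(bias[2, ]), mean(bias[1, ]))
})
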