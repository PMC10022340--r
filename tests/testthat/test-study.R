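test_that("descriptive statistics follow the interpolated-percentile rule", {
  n <- 100
  df <- data.frame(country_code = sprintf("C%03d", 1:n), year = 2015L,
                   spend_total = (1:n) * 1000, plhiv = rep(1000, n),
                   pct_art = rep(50, n), pct_pmtct = runif(n, 10, 90),
                   z1 = rnorm(n))
  p <- hiv_panel(df, covariates = "z1")
  tab <- descriptive_stats(p)
  # spend_per_plhiv is 1..100: linear-interpolation percentiles
  r <- tab[tab$variable == "spend_per_plhiv", ]
  expect_equal(r$mean, 50.5)
  expect_equal(r$p25, 25.75)
  expect_equal(r$p75, 75.25)
  expect_equal(c(r$min, r$max), c(1, 100))
  # constant column degenerates cleanly
  cst <- tab[tab$variable == "pct_art", ]
  expect_equal(c(cst$mean, cst$sd, cst$p25, cst$p75), c(50, 0, 50, 50))
  # empty variable: omitted with a warning
  df$z1 <- NA_real_
  p2 <- hiv_panel(df, covariates = "z1")
  expect_warning(tab2 <- descriptive_stats(p2), "no observations")
  expect_false("z1" %in% tab2$variable)
})

test_that("outlier trimming drops exactly the tails it is asked to", {
  n <- 20
  df <- data.frame(country_code = sprintf("C%02d", 1:n), year = 2015L,
                   spend_total = seq(100, 2000, length.out = n) * 1000,
                   plhiv = rep(1000, n),
                   pct_art = rep(50, n), pct_pmtct = rep(60, n))
  p <- hiv_panel(df, covariates = character(0))
  # 20 distinct values, both tails at 5%: exactly min and max rows go
  t1 <- trim_outliers(p, "both", variables = "spend_per_plhiv")
  expect_equal(nrow(t1), 18)
  expect_equal(range(t1$spend_per_plhiv),
               range(p$spend_per_plhiv[-c(1, n)]))
  log <- attr(t1, "drop_log")
  expect_setequal(log$country_code, c("C01", "C20"))

  t0 <- trim_outliers(p, "none")
  expect_equal(as.data.frame(t0), as.data.frame(p), ignore_attr = TRUE)
  t2 <- trim_outliers(p, "lower5", variables = "spend_per_plhiv")
  expect_equal(nrow(t2), 19)

  # never drops more than 2*fraction + 2/n of rows per trimmed variable
  for (s in 1:10) {
    set.seed(s)
    m <- 80
    df2 <- df[rep(1, m), ]
    df2$country_code <- sprintf("C%03d", 1:m)
    df2$spend_total <- runif(m, 1e5, 1e7)
    p2 <- hiv_panel(df2, covariates = character(0))
    t3 <- trim_outliers(p2, "both", variables = "spend_per_plhiv")
    expect_lte((m - nrow(t3)) / m, 2 * 0.05 + 2 / m)
  }

  # refusal when the remainder would be tiny
  small <- hiv_panel(df[1:11, ], covariates = character(0))
  expect_error(trim_outliers(small, "both", variables = "spend_per_plhiv"),
               "fewer than 10")
})

test_that("group summaries report means, medians, IQR and normal CIs", {
  sc <- data.frame(eff_bc = c(0.5, 0.7), grp = "g1")
  g <- group_summary(sc, by = "grp", per_year = FALSE)
  expect_equal(c(g$mean, g$median, g$n), c(0.6, 0.6, 2))
  se <- sd(c(0.5, 0.7)) / sqrt(2)
  expect_equal(g$ci_low, 0.6 - 1.96 * se)

  sc2 <- data.frame(eff_bc = runif(12, 0.3, 0.9),
                    grp = rep(c("a", "b"), each = 6),
                    year = rep(c(2010L, 2011L), 6))
  g2 <- group_summary(sc2, by = "grp")
  expect_equal(nrow(g2), 4) # 2 groups x 2 years

  # singleton group: CI suppressed and flagged
  sc3 <- data.frame(eff_bc = c(0.4, 0.5, 0.6), grp = c("a", "a", "b"))
  g3 <- group_summary(sc3, by = "grp", per_year = FALSE)
  expect_true(g3$ci_suppressed[g3$group == "b"])
  expect_true(is.na(g3$ci_low[g3$group == "b"]))
  expect_error(group_summary(data.frame(eff_bc = 1, grp = NA), "grp"),
               "label")
})

test_that("a covariate that raises inefficiency separates the group means", {
  hits <- sapply(1:20, function(s) {
    g <- generate_panel(n_countries = 100, years = 2015, retention = 1,
                        missing_rate = 0,
                        beta_true = c(intercept = 1.3, z1 = 0.5, z2 = 0),
                        sigma_true = 0.2, seed = 700 + s)
    d <- as.data.frame(g$panel)
    p <- dea_problem(matrix(d$spend_per_plhiv),
                     as.matrix(d[, c("pct_art", "pct_pmtct")]))
    sc <- data.frame(eff_bc = dea_score_all(p)$efficiency,
                     grp = ifelse(g$truth$Z_true[, "z1"] > 0, "B", "A"))
    gs <- group_summary(sc, by = "grp", per_year = FALSE)
    gs$mean[gs$group == "A"] > gs$mean[gs$group == "B"]
  })
  expect_gte(sum(hits), 18)
})

test_that("model comparison flags only real differences", {
  r <- recovery_run(31, L1 = 50, L2 = 30)
  base <- r$res
  noisy <- base
  set.seed(1)
  noisy$scores$eff_bc <- pmin(base$scores$eff_bc + rnorm(nrow(base$scores), 0, 1e-6), 1)
  cmp <- compare_models(list(base = base, same = base, noisy = noisy))
  expect_equal(cmp$p_value[cmp$model == "same"], 1)
  expect_equal(cmp$diff_vs_base[cmp$model == "same"], 0)
  expect_lt(abs(cmp$diff_vs_base[cmp$model == "noisy"]), 1e-4)
  expect_gt(cmp$p_value[cmp$model == "noisy"], 0.99)
})

test_that("the orchestrated study is complete, deterministic, and extensible", {
  g <- generate_panel(n_countries = 25, years = 2013:2015, seed = 44,
                      retention = 1, missing_rate = 0.1)
  cfg <- study_config(covariate_model = "base",
                      sw = sw_config(L1 = 30, L2 = 30, seed = 2),
                      impute_m = 5)
  out1 <- tempfile(); out2 <- tempfile()
  rep1 <- run_study(cfg, g$panel, outdir = out1)
  rep2 <- run_study(cfg, g$panel, outdir = out2)

  expect_true(all(c("descriptives", "scores", "annual", "groups",
                    "regression") %in% names(rep1)))
  expect_true(all(file.exists(file.path(out1,
    c("descriptives.csv", "scores_bc.csv", "annual.csv", "groups.csv",
      "regression.csv", "manifest.json")))))
  # reruns reproduce every table bit-identically
  for (f in c("descriptives.csv", "scores_bc.csv", "annual.csv",
              "groups.csv", "regression.csv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_true(all(rep1$scores$eff_bc > 0 & rep1$scores$eff_bc <= 1))
  expect_true(all(rep1$annual$ci_low <= rep1$annual$mean &
                    rep1$annual$mean <= rep1$annual$ci_high))

  # covariate model A adds its two staffing covariates to the regression
  cfgA <- study_config(covariate_model = "A",
                       sw = sw_config(L1 = 30, L2 = 30, seed = 2),
                       impute_m = 5)
  repA <- run_study(cfgA, g$panel)
  expect_equal(nrow(repA$regression), nrow(rep1$regression) + 2)
  expect_true(all(c("nurses_10k", "health_posts_100k") %in% repA$regression$term))
})

test_that("time-improving truth yields a rising annual efficiency profile", {
  g <- generate_panel(year_effect = -0.15, seed = 55)
  cfg <- study_config(sw = sw_config(L1 = 40, L2 = 20, seed = 6), impute_m = 5)
  rep <- run_study(cfg, g$panel)
  ann <- rep$annual[order(rep$annual$year), ]
  expect_gte(sum(diff(ann$mean) > 0), 7) # rising in all but at most one step
})
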