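# Shared fixtures: tiny panels and random DEA instances built in code.

# three-DMU textbook instance: C is enveloped by the A-B midpoint
toy_dea <- function() {
  dea_problem(matrix(c(1, 1, 1), 3),
              rbind(c(2, 1), c(1, 2), c(1, 1)),
              dmu_ids = c("A", "B", "C"))
}

# random well-posed instance: strictly positive input, positive outputs
rand_dea <- function(n, seed) {
  set.seed(seed)
  dea_problem(matrix(runif(n, 1, 10)),
              cbind(runif(n, 1, 10), runif(n, 1, 10)))
}

# minimal valid panel data.frame with two covariates
tiny_panel_df <- function() {
  data.frame(country_code = c("KEN", "KEN", "UGA"),
             year = c(2011L, 2012L, 2011L),
             spend_total = c(2e6, 2.2e6, 1e6),
             plhiv = c(1e4, 1.1e4, 5e3),
             pct_art = c(40, 45, 30),
             pct_pmtct = c(60, 62, 50),
             cov_a = c(0.5, NA, -0.2),
             cov_b = c(1.2, 1.3, 0.8),
             who_region = "AFRO",
             unaids_region = "ESA",
             income_group = "low",
             stringsAsFactors = FALSE)
}

# the parameter-recovery design: 120 DMUs, two covariates, known truth
recovery_design <- function(seed) {
  generate_panel(n_countries = 120, years = 2015,
                 beta_true = c(intercept = 1.5, z1 = 0.6, z2 = -0.6),
                 sigma_true = 0.3, missing_rate = 0, retention = 1,
                 seed = seed)
}

recovery_run <- function(seed, L1 = 200, L2 = 500) {
  g <- recovery_design(seed)
  d <- as.data.frame(g$panel)
  res <- run_double_bootstrap(matrix(d$spend_per_plhiv),
                              as.matrix(d[, c("pct_art", "pct_pmtct")]),
                              g$truth$Z_true,
                              sw_config(L1 = L1, L2 = L2, seed = seed + 1000))
  list(truth = g$truth, res = res)
}
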