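# Country-year panel container and pre-analysis diagnostics.
#
# A panel is a plain data.frame with class "hiv_panel": one row per
# country-year, columns
#   country_code, year, spend_total, plhiv, pct_art, pct_pmtct,
#   <covariates...>, who_region, unaids_region, income_group
# plus the derived DEA input spend_per_plhiv.  The covariate registry is
# kept in attr(panel, "covariates"); empty cells in the covariate columns
# are missing values, never silent zeros.

.panel_core_cols <- c("country_code", "year", "spend_total", "plhiv",
                      "pct_art", "pct_pmtct")
.panel_label_cols <- c("who_region", "unaids_region", "income_group")

#' Covariate registries for the base and sensitivity models
#'
#' The base model uses ten country-level covariates (rule of law, antenatal
#' care coverage, GNI per capita, current health expenditure as % of GDP and
#' per capita, population density, HDI, HIV prevalence, out-of-pocket and
#' development-assistance shares of HIV spending).  Sensitivity model A adds
#' nurse density and health-post density; model B adds the government share
#' of HIV spending and external expenditure as % of current health
#' expenditure; model "AB" adds all four.
#'
#' @param model one of `"base"`, `"A"`, `"B"`, `"AB"`.
#' @return Character vector of covariate column names.
#' @export
covariate_model <- function(model = c("base", "A", "B", "AB")) {
  model <- match.arg(model)
  base <- c("rule_of_law", "anc_coverage", "gni_pc", "che_pct_gdp", "che_pc",
            "pop_density", "hdi", "hiv_prev", "oop_share", "dahs_share")
  a <- c("nurses_10k", "health_posts_100k")
  b <- c("gov_share", "ext_che_pct")
  switch(model, base = base, A = c(base, a), B = c(base, b),
         AB = c(base, a, b))
}

#' Construct and validate a country-year panel
#'
#' @param df data.frame with the core columns (`country_code`, `year`,
#'   `spend_total`, `plhiv`, `pct_art`, `pct_pmtct`), any covariate columns,
#'   and optional group label columns.
#' @param covariates character vector naming the covariate columns; defaults
#'   to every column not recognised as core or label.
#' @param year_range allowed calendar years (default 1990:2030).
#' @return A validated `hiv_panel` (data.frame subclass) with the derived
#'   column `spend_per_plhiv` and the covariate registry attached.
#' @export
hiv_panel <- function(df, covariates = NULL, year_range = 1990:2030) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  miss <- setdiff(.panel_core_cols, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(covariates)) {
    covariates <- setdiff(names(df),
                          c(.panel_core_cols, .panel_label_cols,
                            "spend_per_plhiv"))
  }
  absent <- setdiff(covariates, names(df))
  if (length(absent)) stop("covariate column(s) not in data: ",
                           paste(absent, collapse = ", "))
  for (lc in .panel_label_cols) if (!lc %in% names(df)) df[[lc]] <- NA_character_

  problems <- character(0)
  bad_rows <- function(cond, what) {
    w <- which(cond)
    if (length(w)) problems <<- c(problems, paste0(what, " in row(s): ",
                                                   paste(w, collapse = ", ")))
  }
  bad_rows(!df$year %in% year_range, "year outside configured range")
  bad_rows(!is.na(df$pct_art) & (df$pct_art < 0 | df$pct_art > 100),
           "pct_art outside [0,100]")
  bad_rows(!is.na(df$pct_pmtct) & (df$pct_pmtct < 0 | df$pct_pmtct > 100),
           "pct_pmtct outside [0,100]")
  bad_rows(!is.na(df$spend_total) & df$spend_total < 0, "negative spend_total")
  bad_rows(!is.na(df$plhiv) & df$plhiv <= 0, "non-positive plhiv")
  if (length(problems)) stop("panel validation failed:\n  ",
                             paste(problems, collapse = "\n  "))

  key <- paste(df$country_code, df$year, sep = ":")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate (country_code, year) pair(s): ", paste(dup, collapse = ", "))
  }
  df$spend_per_plhiv <- derive_input(df$spend_total, df$plhiv)
  attr(df, "covariates") <- covariates
  class(df) <- c("hiv_panel", "data.frame")
  df
}

#' Covariate registry of a panel
#' @param panel an `hiv_panel`.
#' @return Character vector of covariate column names.
#' @export
panel_covariates <- function(panel) attr(panel, "covariates")

#' Load a country-year panel from CSV
#'
#' Long-format CSV is the canonical interchange: one row per country-year,
#' empty cells meaning missing.  Column names can be remapped through
#' `schema` (a named character vector `c(canonical = "file_column")`).
#'
#' @param path CSV file path.
#' @param schema optional column-name mapping.
#' @param covariates covariate registry passed to [hiv_panel()].
#' @param ... further arguments to [hiv_panel()].
#' @return A validated `hiv_panel`.
#' @export
load_panel <- function(path, schema = NULL, covariates = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df)) stop("schema maps ", canon, " to absent column ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  hiv_panel(df, covariates = covariates, ...)
}

#' Write a panel to CSV
#'
#' Inverse of [load_panel()]: values round-trip bit-exactly for integer
#' fields and to full double precision (15 significant digits) for reals.
#'
#' @param panel an `hiv_panel`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$spend_per_plhiv <- NULL # derived, recomputed on load
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive the DEA input: spending per person living with HIV
#'
#' @param spend_total total annual HIV spending, constant USD.
#' @param plhiv number of people living with HIV (must be positive).
#' @return `spend_total / plhiv`.
#' @export
derive_input <- function(spend_total, plhiv) {
  if (any(!is.na(plhiv) & plhiv <= 0)) stop("plhiv must be positive")
  spend_total / plhiv
}

#' Classify a country by World Bank income group (2020 thresholds)
#'
#' GNI per capita at or below $1,045 is low income; above that and at or
#' below $4,095 lower-middle; above that and at or below $12,695
#' upper-middle; above $12,695 high income.
#'
#' @param gni_per_capita nonnegative GNI per capita, current USD.
#' @return Factor with levels `low`, `lower-middle`, `upper-middle`, `high`.
#' @export
classify_income <- function(gni_per_capita) {
  if (any(!is.na(gni_per_capita) & gni_per_capita < 0)) {
    stop("gni_per_capita must be nonnegative")
  }
  cut(gni_per_capita, breaks = c(-Inf, 1045, 4095, 12695, Inf),
      labels = c("low", "lower-middle", "upper-middle", "high"))
}

#' Pre-analysis diagnostics: correlation screen, isotonicity, VIF
#'
#' Computes (i) the pairwise Pearson correlation matrix of the covariates
#' with flags where `|rho| >= corr_threshold`, (ii) the input-output Pearson
#' correlations (the isotonicity check: DEA variables must be positively
#' related), both pooled over country-years and per year, and (iii) the
#' variance inflation factor of each covariate, `1/(1 - R^2)` from an OLS
#' regression of that covariate on the others.  A covariate that is constant
#' across the panel has undefined VIF, reported as `Inf` and flagged.
#'
#' @param panel an `hiv_panel`.
#' @param corr_threshold flag threshold for `|rho|` (default 0.7).
#' @return An object of class `hiv_diagnostics`: `corr`, `flagged_pairs`,
#'   `isotonicity` (pooled), `isotonicity_by_year`, `vif`, `mean_vif`.
#' @export
panel_diagnostics <- function(panel, corr_threshold = 0.7) {
  covs <- panel_covariates(panel)
  Zfull <- as.matrix(as.data.frame(panel)[, covs, drop = FALSE])
  cc <- complete.cases(Zfull)
  if (sum(cc) < 3) stop("need at least 3 complete observations")
  Z <- Zfull[cc, , drop = FALSE]

  constant <- apply(Z, 2, function(v) var(v) < 1e-24)
  rho <- suppressWarnings(cor(Z))
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- 1

  flagged <- which(abs(rho) >= corr_threshold & upper.tri(rho), arr.ind = TRUE)
  flagged_pairs <- if (nrow(flagged)) {
    data.frame(var1 = covs[flagged[, 1]], var2 = covs[flagged[, 2]],
               rho = rho[flagged], stringsAsFactors = FALSE)
  } else {
    data.frame(var1 = character(0), var2 = character(0), rho = numeric(0))
  }

  vif <- vapply(seq_along(covs), function(j) {
    if (constant[j]) return(Inf)
    others <- Z[, -j, drop = FALSE]
    others <- others[, !constant[-j], drop = FALSE]
    if (ncol(others) == 0L) return(1)
    fit <- lm.fit(cbind(1, others), Z[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((Z[, j] - mean(Z[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else max(1 / (1 - r2), 1)
  }, numeric(1))
  names(vif) <- covs

  iso <- function(d) {
    ok <- !is.na(d$spend_per_plhiv)
    c(pct_art = suppressWarnings(cor(d$spend_per_plhiv[ok & !is.na(d$pct_art)],
                                     d$pct_art[ok & !is.na(d$pct_art)])),
      pct_pmtct = suppressWarnings(cor(d$spend_per_plhiv[ok & !is.na(d$pct_pmtct)],
                                       d$pct_pmtct[ok & !is.na(d$pct_pmtct)])))
  }
  df <- as.data.frame(panel)
  iso_year <- do.call(rbind, lapply(split(df, df$year), iso))

  structure(list(corr = rho,
                 flagged_pairs = flagged_pairs,
                 corr_threshold = corr_threshold,
                 isotonicity = iso(df),
                 isotonicity_by_year = iso_year,
                 vif = vif,
                 mean_vif = mean(vif[is.finite(vif)]),
                 n_complete = sum(cc)),
            class = "hiv_diagnostics")
}

#' @export
print.hiv_diagnostics <- function(x, ...) {
  cat("Panel diagnostics on", x$n_complete, "complete observations\n")
  cat(sprintf("Isotonicity (pooled): ART rho = %.3f, PMTCT rho = %.3f\n",
              x$isotonicity[["pct_art"]], x$isotonicity[["pct_pmtct"]]))
  cat(sprintf("Mean VIF = %.2f\n", x$mean_vif))
  if (nrow(x$flagged_pairs)) {
    cat("Flagged pairs (|rho| >=", x$corr_threshold, "):\n")
    print(x$flagged_pairs)
  } else cat("No covariate pair at or above |rho| =", x$corr_threshold, "\n")
  invisible(x)
}
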