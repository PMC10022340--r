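# End-to-end orchestration: descriptives, pooled double-bootstrap run,
# grouped summaries, the regression table, and the sensitivity analyses
# (alternative covariate models and 5% outlier trimming).

#' Descriptive statistics table
#'
#' Mean, SD, 25th/75th percentiles (linear interpolation between order
#' statistics), min and max per analysis variable over all country-year
#' observations.  Variables with no observations are omitted with a warning.
#'
#' @param panel an `hiv_panel`.
#' @param variables columns to summarise; defaults to the DEA input, both
#'   outputs and every covariate.
#' @return data.frame with one row per variable.
#' @export
descriptive_stats <- function(panel, variables = NULL) {
  df <- as.data.frame(panel)
  if (is.null(variables)) {
    variables <- c("spend_per_plhiv", "pct_art", "pct_pmtct",
                   panel_covariates(panel))
  }
  rows <- lapply(variables, function(v) {
    x <- df[[v]]
    x <- x[!is.na(x)]
    if (!length(x)) {
      warning("variable ", v, " has no observations; omitted")
      return(NULL)
    }
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    data.frame(variable = v, mean = mean(x), sd = sd(x),
               p25 = q[1], p75 = q[2], min = min(x), max = max(x),
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Trim outlying observations on the input and/or outputs
#'
#' Drops country-years whose value falls strictly below the lower or
#' strictly above the upper pooled percentile of any trimmed variable
#' (percentiles by linear interpolation between order statistics).
#'
#' @param panel an `hiv_panel`.
#' @param spec `"none"`, `"lower5"`, `"upper5"` or `"both"`.
#' @param variables variables the trim applies to (default: the DEA input
#'   and both outputs, jointly).
#' @param fraction tail fraction per side (default 0.05, must be <= 0.25).
#' @return Trimmed `hiv_panel` with a `drop_log` attribute (data.frame of
#'   dropped `country_code`, `year`, offending variable).
#' @export
trim_outliers <- function(panel, spec = c("none", "lower5", "upper5", "both"),
                          variables = c("spend_per_plhiv", "pct_art", "pct_pmtct"),
                          fraction = 0.05) {
  spec <- match.arg(spec)
  stopifnot(fraction >= 0, fraction <= 0.25, nrow(panel) > 0)
  if (spec == "none") {
    attr(panel, "drop_log") <- data.frame(country_code = character(0),
                                          year = integer(0),
                                          variable = character(0))
    return(panel)
  }
  df <- as.data.frame(panel)
  drop <- rep(FALSE, nrow(df))
  why <- rep(NA_character_, nrow(df))
  for (v in variables) {
    x <- df[[v]]
    lo <- quantile(x, fraction, type = 7, names = FALSE, na.rm = TRUE)
    hi <- quantile(x, 1 - fraction, type = 7, names = FALSE, na.rm = TRUE)
    hit <- (!is.na(x)) & ((spec %in% c("lower5", "both") & x < lo) |
                          (spec %in% c("upper5", "both") & x > hi))
    why[hit & !drop] <- v
    drop <- drop | hit
  }
  if (nrow(df) - sum(drop) < 10) {
    stop("trimming would leave fewer than 10 observations; refusing")
  }
  out <- hiv_panel(df[!drop, , drop = FALSE],
                   covariates = panel_covariates(panel))
  attr(out, "drop_log") <- data.frame(country_code = df$country_code[drop],
                                      year = df$year[drop],
                                      variable = why[drop],
                                      stringsAsFactors = FALSE)
  out
}

#' Grouped efficiency summaries
#'
#' Per group (and optionally per year): mean, median, interquartile range,
#' n, and the normal-approximation 95% CI for the mean
#' (mean +- 1.96 SD/sqrt(n)).  Groups of size one get their CI suppressed
#' and flagged.
#'
#' @param scores data.frame with an efficiency column and label columns
#'   (e.g. the `scores` element of an `sw_result` merged with the panel).
#' @param by name of the grouping column.
#' @param value name of the efficiency column (default `"eff_bc"`).
#' @param per_year also split by a `year` column if present?
#' @return data.frame of group summaries.
#' @export
group_summary <- function(scores, by, value = "eff_bc", per_year = TRUE) {
  stopifnot(by %in% names(scores), value %in% names(scores))
  if (anyNA(scores[[by]])) stop("every score must carry a group label")
  keys <- if (per_year && "year" %in% names(scores)) {
    interaction(scores[[by]], scores$year, drop = TRUE, sep = "\r")
  } else {
    factor(scores[[by]])
  }
  rows <- lapply(split(seq_len(nrow(scores)), keys), function(idx) {
    x <- scores[[value]][idx]
    n <- length(x)
    parts <- strsplit(as.character(keys[idx[1]]), "\r", fixed = TRUE)[[1]]
    se <- if (n > 1) sd(x) / sqrt(n) else NA_real_
    data.frame(group = parts[1],
               year = if (length(parts) > 1) as.integer(parts[2]) else NA_integer_,
               n = n, mean = mean(x), median = median(x),
               q25 = quantile(x, 0.25, type = 7, names = FALSE),
               q75 = quantile(x, 0.75, type = 7, names = FALSE),
               ci_low = if (n > 1) mean(x) - 1.96 * se else NA_real_,
               ci_high = if (n > 1) mean(x) + 1.96 * se else NA_real_,
               ci_suppressed = n == 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$year), , drop = FALSE]
}

#' Compare mean bias-corrected efficiency across model variants
#'
#' Welch two-sample t-test of each variant against the base variant, on the
#' DMUs the two runs share.
#'
#' @param results named list of `sw_result` objects; must contain `base`.
#' @param base name of the reference variant (default `"base"`).
#' @return data.frame with mean efficiency per variant, difference from
#'   base, and Welch p-value (p = 1 for an identical variant).
#' @export
compare_models <- function(results, base = "base") {
  stopifnot(base %in% names(results))
  ref <- results[[base]]$scores
  rows <- lapply(names(results), function(nm) {
    sc <- results[[nm]]$scores
    common <- intersect(sc$dmu_id, ref$dmu_id)
    if (length(common) < length(ref$dmu_id) && nm != base) {
      warning("variant ", nm, " compared on the ", length(common),
              "-DMU intersection with base")
    }
    a <- sc$eff_bc[match(common, sc$dmu_id)]
    b <- ref$eff_bc[match(common, ref$dmu_id)]
    d <- a - b
    pv <- if (nm == base || all(abs(d) < 1e-15)) 1 else
      tryCatch(t.test(a, b)$p.value, error = function(e) 1)
    data.frame(model = nm, n = length(common), mean_eff = mean(a),
               diff_vs_base = mean(a) - mean(b), p_value = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Study configuration
#'
#' @param covariate_model `"base"`, `"A"`, `"B"` or `"AB"` (see
#'   [covariate_model()]), or a character vector of covariate names.
#' @param trim trimming spec for [trim_outliers()].
#' @param sw an [sw_config()].
#' @param groupings label columns used for [group_summary()].
#' @param impute_m,impute_seed imputation settings.
#' @return List of class `study_config`.
#' @export
study_config <- function(covariate_model = "base", trim = "none",
                         sw = sw_config(), groupings = c("who_region",
                                                         "unaids_region",
                                                         "income_group"),
                         impute_m = 50L, impute_seed = 1L) {
  covs <- if (length(covariate_model) == 1L &&
              covariate_model %in% c("base", "A", "B", "AB")) {
    covariate_model(covariate_model)
  } else {
    as.character(covariate_model)
  }
  structure(list(covariates = covs, trim = trim, sw = sw,
                 groupings = groupings, impute_m = impute_m,
                 impute_seed = impute_seed),
            class = "study_config")
}

#' Run the full study on a panel
#'
#' load -> impute -> (trim) -> DEA -> double bootstrap -> tables.  All
#' randomness derives from the seeds recorded in the returned manifest, so
#' a rerun with the same configuration reproduces every table exactly.
#'
#' @param config a [study_config()].
#' @param panel an `hiv_panel`, or a CSV path for [load_panel()].
#' @param outdir optional directory; when given, writes `descriptives.csv`,
#'   `scores_bc.csv`, `annual.csv`, `groups.csv`, `regression.csv` and
#'   `manifest.json` there.
#' @return A `study_report`: `descriptives`, `scores` (with labels),
#'   `annual` (mean efficiency and 95% CI per year), `groups`,
#'   `regression` (coefficient, bootstrap SE, p-value, CI), `sw` (the full
#'   `sw_result`), `manifest`.
#' @export
run_study <- function(config, panel, outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.character(panel)) panel <- load_panel(panel)
  stopifnot(inherits(panel, "hiv_panel"))
  missing_covs <- setdiff(config$covariates, names(panel))
  if (length(missing_covs)) {
    stop("panel lacks covariate(s) required by the model: ",
         paste(missing_covs, collapse = ", "))
  }
  df <- as.data.frame(panel)[, c(.panel_core_cols, config$covariates,
                                 .panel_label_cols)]
  panel <- hiv_panel(df, covariates = config$covariates)

  # exclusion flow: records lacking input or either output never enter DEA
  have_io <- !is.na(panel$spend_per_plhiv) & panel$spend_per_plhiv > 0 &
    !is.na(panel$pct_art) & !is.na(panel$pct_pmtct) &
    (panel$pct_art > 0 | panel$pct_pmtct > 0)
  n_excluded <- sum(!have_io)
  panel <- hiv_panel(as.data.frame(panel)[have_io, , drop = FALSE],
                     covariates = config$covariates)

  imp <- impute_panel(panel, M = config$impute_m, seed = config$impute_seed)
  work <- imp$panel
  work <- trim_outliers(work, spec = config$trim)
  drop_log <- attr(work, "drop_log")

  d <- as.data.frame(work)
  ids <- paste(d$country_code, d$year, sep = ":")
  X <- matrix(d$spend_per_plhiv, ncol = 1)
  Y <- as.matrix(d[, c("pct_art", "pct_pmtct")])
  Z <- as.matrix(d[, config$covariates, drop = FALSE])
  sw <- run_double_bootstrap(X, Y, Z, config = config$sw, dmu_ids = ids)

  scores <- cbind(d[, c("country_code", "year", .panel_label_cols)],
                  sw$scores[, setdiff(names(sw$scores), "dmu_id")])
  scores$dmu_id <- sw$scores$dmu_id

  annual <- group_summary(transform(scores, all = "all"), by = "all",
                          value = "eff_bc", per_year = TRUE)
  annual <- annual[, c("year", "n", "mean", "ci_low", "ci_high", "median",
                       "q25", "q75")]
  groups <- do.call(rbind, lapply(config$groupings, function(g) {
    gs <- group_summary(scores, by = g, value = "eff_bc", per_year = TRUE)
    cbind(grouping = g, gs)
  }))

  regression <- data.frame(term = names(sw$beta_hat),
                           coefficient = unname(sw$beta_hat),
                           se = unname(sw$beta_se),
                           p_value = unname(sw$beta_pvalue),
                           ci_low = sw$beta_ci[, 1],
                           ci_high = sw$beta_ci[, 2],
                           stringsAsFactors = FALSE)
  regression <- rbind(regression,
                      data.frame(term = "sigma", coefficient = sw$sigma_hat,
                                 se = NA_real_, p_value = NA_real_,
                                 ci_low = sw$sigma_ci[1],
                                 ci_high = sw$sigma_ci[2]))

  manifest <- list(covariates = config$covariates, trim = config$trim,
                   L1 = config$sw$L1, L2 = config$sw$L2,
                   alpha = config$sw$alpha, sw_seed = config$sw$seed,
                   impute_m = config$impute_m,
                   impute_seed = config$impute_seed,
                   n_observations = nrow(d), n_excluded_io = n_excluded,
                   n_trimmed = nrow(drop_log),
                   package_version = as.character(utils::packageVersion("hiveff")))

  report <- structure(list(descriptives = descriptive_stats(work),
                           scores = scores, annual = annual, groups = groups,
                           regression = regression, sw = sw,
                           imputation = imp, drop_log = drop_log,
                           manifest = manifest),
                      class = "study_report")
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(report$descriptives, file.path(outdir, "descriptives.csv"), row.names = FALSE)
    write.csv(report$scores, file.path(outdir, "scores_bc.csv"), row.names = FALSE)
    write.csv(report$annual, file.path(outdir, "annual.csv"), row.names = FALSE)
    write.csv(report$groups, file.path(outdir, "groups.csv"), row.names = FALSE)
    write.csv(report$regression, file.path(outdir, "regression.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", x$manifest$n_observations, "country-year observations\n")
  cat(sprintf("Mean bias-corrected efficiency %.3f (initial %.3f)\n",
              mean(x$scores$eff_bc), mean(x$scores$eff_init)))
  cat("Annual means:\n")
  print(x$annual[, c("year", "n", "mean", "ci_low", "ci_high")], row.names = FALSE)
  invisible(x)
}
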