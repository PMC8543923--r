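# Batch survey of networks: per-network records, prevalence of evidence of
# inconsistency, structural correlations, regression and subgroup summaries.

#' Analyse one network for the survey
#'
#' Runs the full per-network pipeline: structural metrics, consistency-model
#' fits (between-study standard deviation, I-squared) and the global DBT
#' test under the requested heterogeneity estimators. Statistical
#' degeneracies never raise; the affected fields are recorded as `NA` and
#' the reason appended to `note`.
#'
#' @param ds An [nma_dataset()].
#' @param estimators Subset of `c("reml", "dl")`.
#' @return A one-row data frame (a survey record) with the structural
#'   metrics, per-estimator DBT p-values (`p_dbt_reml`, `p_dbt_dl`),
#'   between-study standard deviations under both models
#'   (`tau_cons_*`, `tau_dbt_*`), `I2`, the network metadata and `note`.
#' @export
analyze_network <- function(ds, estimators = c("reml", "dl")) {
  stopifnot(inherits(ds, "nma_dataset"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  met <- as.data.frame(structure_metrics(ds))
  rec <- met
  notes <- character(0)
  cs <- build_contrast_set(ds)
  dm <- build_design_matrices(cs)
  q <- tryCatch(cochran_q(cs, dm$X), error = function(e) NULL)
  rec$I2 <- if (is.null(q)) NA_real_ else q$I2
  for (est in c("reml", "dl")) {
    rec[[paste0("p_dbt_", est)]] <- NA_real_
    rec[[paste0("tau_cons_", est)]] <- NA_real_
    rec[[paste0("tau_dbt_", est)]] <- NA_real_
  }
  for (est in estimators) {
    t <- tryCatch(dbt_test(cs, estimator = est), error = function(e) {
      notes <<- c(notes, paste0("dbt-", est, ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(t) && t$applicable) {
      rec[[paste0("p_dbt_", est)]] <- t$p_value
      rec[[paste0("tau_dbt_", est)]] <- sqrt(t$tau2_within)
    } else if (!is.null(t)) {
      notes <- c(notes, paste0("dbt-", est, ": not assessable (df = 0)"))
    }
    tc <- tryCatch({
      if (est == "dl") estimate_tau2_dl(cs, dm$X)
      else estimate_tau2_reml(cs, dm$X)
    }, error = function(e) {
      notes <<- c(notes, paste0("tau-", est, ": ", conditionMessage(e)))
      NA_real_
    })
    rec[[paste0("tau_cons_", est)]] <- sqrt(tc)
  }
  rec$year <- if (is.null(ds$year)) NA_integer_ else ds$year
  rec$outcome_type <- ds$outcome_type %||% NA_character_
  rec$comparison_type <- ds$comparison_type %||% NA_character_
  rec$complex_interventions <- ds$complex_interventions %||% NA
  rec$note <- paste(notes, collapse = "; ")
  rec
}

#' Survey a collection of networks
#'
#' Applies [analyze_network()] to every long-format CSV in a directory (or
#' an explicit vector of files / list of datasets). Networks failing the
#' eligibility screen — connected, at least four treatment nodes, at least
#' one closed loop, no single-arm studies — are skipped with a logged
#' reason, mirroring the eligibility screening of an empirical survey.
#'
#' @param x Directory path, character vector of CSV paths, or list of
#'   [nma_dataset()] objects.
#' @param estimators Subset of `c("reml", "dl")`.
#' @param verbose Print progress messages.
#' @return A list of class `nma_survey`: `records` (data frame, one row per
#'   analysed network) and `skipped` (data frame `network_id`, `reason`).
#' @export
survey_networks <- function(x, estimators = c("reml", "dl"),
                            verbose = FALSE) {
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    x <- sort(list.files(x, pattern = "\\.csv$", full.names = TRUE))
  }
  datasets <- if (is.character(x)) lapply(x, read_nma_csv) else x
  records <- list()
  skipped <- list()
  for (ds in datasets) {
    val <- validate_network(ds)
    if (!val$eligible) {
      reason <- paste(c(
        if (!val$connected) "disconnected",
        if (!val$eligible_nodes) "fewer than 4 treatment nodes",
        if (!val$eligible_loop) "no closed loop",
        if (length(val$single_arm_studies) > 0L) "single-arm studies"
      ), collapse = "; ")
      skipped[[length(skipped) + 1L]] <- data.frame(
        network_id = ds$network_id, reason = reason, stringsAsFactors = FALSE)
      if (verbose) message("skipping '", ds$network_id, "': ", reason)
      next
    }
    if (verbose) message("analysing '", ds$network_id, "'")
    records[[length(records) + 1L]] <- analyze_network(ds, estimators)
  }
  structure(list(
    records = if (length(records) > 0L) {
      do.call(rbind, c(records, list(make.row.names = FALSE)))
    } else NULL,
    skipped = if (length(skipped) > 0L) {
      do.call(rbind, c(skipped, list(make.row.names = FALSE)))
    } else data.frame(network_id = character(), reason = character())
  ), class = "nma_survey")
}

#' @export
print.nma_survey <- function(x, ...) {
  cat(sprintf("Survey: %d networks analysed, %d skipped\n",
              if (is.null(x$records)) 0L else nrow(x$records),
              nrow(x$skipped)))
  invisible(x)
}

#' Prevalence of evidence of inconsistency
#'
#' Cross-tabulates, per heterogeneity estimator and significance threshold,
#' how many surveyed networks show a DBT p-value below the threshold.
#' Networks with a missing p-value (not assessable or failed) are excluded
#' from that cell's denominator; their count is reported in `n_missing`.
#'
#' @param records Survey record data frame (or an `nma_survey`).
#' @param thresholds Significance levels; default `c(0.05, 0.10)`.
#' @param estimators Subset of `c("reml", "dl")`.
#' @return Data frame with `estimator`, `threshold`, `n_inconsistent`,
#'   `n_total`, `percent`, `n_missing`.
#' @export
prevalence <- function(records, thresholds = c(0.05, 0.10),
                       estimators = c("reml", "dl")) {
  records <- survey_records(records)
  rows <- list()
  for (est in estimators) {
    p <- records[[paste0("p_dbt_", est)]]
    ok <- !is.na(p)
    for (thr in thresholds) {
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, threshold = thr,
        n_inconsistent = sum(p[ok] < thr), n_total = sum(ok),
        percent = 100 * mean(p[ok] < thr), n_missing = sum(!ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

survey_records <- function(records) {
  if (inherits(records, "nma_survey")) records <- records$records
  if (is.null(records) || nrow(records) == 0L) {
    stop("no survey records", call. = FALSE)
  }
  records
}

# The characteristics correlated with the DBT p-value, and whether the
# multi-arm zero -> one substitution applies before the log.
correlation_characteristics <- function() {
  list(
    n_studies = "n_studies", n_treatments = "n_treatments",
    n_edges = "n_edges", n_designs = "n_designs", n_loops = "n_loops",
    n_multiarm = "n_multiarm",
    ratio_studies_treatments = "ratio_studies_treatments",
    ratio_loops_treatments = "ratio_loops_treatments",
    ratio_loops_studies = "ratio_loops_studies",
    ratio_designs_studies = "ratio_designs_studies",
    ratio_edges_studies = "ratio_edges_studies",
    ratio_multiarm_studies = "ratio_multiarm_studies"
  )
}

#' Correlation of the DBT p-value with structural characteristics
#'
#' Pearson correlation of the (raw) DBT p-value against each structural
#' characteristic on a logarithmic scale: counts (studies, treatments,
#' direct comparisons, designs, loops, multi-arm studies) and the six ratio
#' metrics. Networks with zero multi-arm studies are treated as having a
#' single multi-arm study before taking logs, so they are not dropped.
#'
#' @param records Survey records (or an `nma_survey`).
#' @param estimator Which p-value column to use; `"reml"` (default) or
#'   `"dl"`.
#' @return Data frame with `characteristic`, `r` (Pearson), `p_value`, `n`.
#'   Constant characteristics yield `NA` correlations.
#' @export
characteristic_correlations <- function(records, estimator = c("reml", "dl")) {
  estimator <- match.arg(estimator)
  records <- survey_records(records)
  p <- records[[paste0("p_dbt_", estimator)]]
  rows <- list()
  for (chname in names(correlation_characteristics())) {
    x <- records[[chname]]
    if (chname %in% c("n_multiarm", "ratio_multiarm_studies")) {
      zero <- !is.na(x) & x == 0
      if (chname == "n_multiarm") x[zero] <- 1
      else x[zero] <- 1 / records$n_studies[zero]
    }
    ok <- !is.na(p) & !is.na(x) & x > 0
    lx <- log(x[ok])
    if (sum(ok) < 3L || stats::sd(lx) == 0 || stats::sd(p[ok]) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = chname, r = NA_real_, p_value = NA_real_,
        n = sum(ok), stringsAsFactors = FALSE)
      next
    }
    ct <- stats::cor.test(p[ok], lx, method = "pearson")
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = chname, r = unname(ct$estimate),
      p_value = ct$p.value, n = sum(ok), stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Multivariable regression of the DBT p-value on network size measures
#'
#' Gaussian-identity `glm` (ordinary least squares) of the raw DBT p-value
#' on the numbers of studies, treatments, direct comparisons and loops
#' jointly.
#'
#' @param records Survey records (>= 10 complete rows).
#' @param estimator `"reml"` or `"dl"`.
#' @return Data frame of coefficients (`term`, `estimate`, `se`,
#'   `statistic`, `p_value`), with the fitted `glm` in attribute `"fit"`.
#' @export
multivariable_regression <- function(records, estimator = c("reml", "dl")) {
  estimator <- match.arg(estimator)
  records <- survey_records(records)
  d <- records[, c("n_studies", "n_treatments", "n_edges", "n_loops")]
  d$p <- records[[paste0("p_dbt_", estimator)]]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10L) {
    stop("multivariable regression needs at least 10 complete records",
         call. = FALSE)
  }
  fit <- stats::glm(p ~ n_studies + n_treatments + n_edges + n_loops,
                    family = stats::gaussian(), data = d)
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                    statistic = sm[, 3L], p_value = sm[, 4L],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Distribution of DBT p-values across subgroups
#'
#' Per-group quartiles of the DBT p-value (with the fourth-root transform
#' reported alongside for plotting parity; no statistic depends on it) and a
#' Kruskal-Wallis rank test of group differences.
#'
#' @param records Survey records.
#' @param by Name of a categorical column (e.g. `"outcome_type"`,
#'   `"comparison_type"`, `"complex_interventions"`,
#'   `"has_single_study_edge"`).
#' @param estimator `"reml"` or `"dl"`.
#' @return List with `summary` (per-group quartiles and counts) and
#'   `test_p_value` (Kruskal-Wallis).
#' @export
subgroup_distributions <- function(records, by, estimator = c("reml", "dl")) {
  estimator <- match.arg(estimator)
  records <- survey_records(records)
  if (!by %in% names(records)) stop("unknown grouping column: ", by,
                                    call. = FALSE)
  p <- records[[paste0("p_dbt_", estimator)]]
  g <- as.factor(records[[by]])
  ok <- !is.na(p) & !is.na(g)
  p <- p[ok]
  g <- droplevels(g[ok])
  counts <- table(g)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need at least two groups with at least two records each",
         call. = FALSE)
  }
  qs <- t(vapply(levels(g), function(lv) {
    stats::quantile(p[g == lv], c(0.25, 0.5, 0.75))
  }, numeric(3)))
  summary <- data.frame(group = levels(g), n = as.integer(counts),
                        q25 = qs[, 1L], median = qs[, 2L], q75 = qs[, 3L],
                        median_fourth_root = qs[, 2L]^0.25,
                        row.names = NULL, stringsAsFactors = FALSE)
  kw <- stats::kruskal.test(p, g)
  list(summary = summary, test_p_value = kw$p.value)
}

#' Chi-squared trend test of inconsistency prevalence over publication years
#'
#' Tabulates inconsistent (DBT p below `alpha`) versus consistent networks
#' by publication year and tests for a linear trend in proportions.
#'
#' @param records Survey records with a `year` column.
#' @param alpha Significance threshold defining "inconsistent".
#' @param estimator `"reml"` or `"dl"`.
#' @return List with the per-year `table` (year, n_inconsistent, n_total)
#'   and `test_p_value` (from [stats::prop.trend.test()]).
#' @export
year_trend <- function(records, alpha = 0.05, estimator = c("reml", "dl")) {
  estimator <- match.arg(estimator)
  records <- survey_records(records)
  p <- records[[paste0("p_dbt_", estimator)]]
  ok <- !is.na(p) & !is.na(records$year)
  if (sum(ok) < 4L) stop("too few records with year information",
                         call. = FALSE)
  years <- sort(unique(records$year[ok]))
  tab <- data.frame(
    year = years,
    n_inconsistent = vapply(years, function(y) {
      sum(p[ok][records$year[ok] == y] < alpha)
    }, integer(1)),
    n_total = vapply(years, function(y) sum(records$year[ok] == y),
                     integer(1))
  )
  tt <- stats::prop.trend.test(tab$n_inconsistent, tab$n_total)
  list(table = tab, test_p_value = tt$p.value)
}

#' Write survey outputs to CSV and JSON
#'
#' Writes the per-network record table as CSV and a JSON summary holding the
#' prevalence table, structural correlations and the multivariable
#' regression coefficients.
#'
#' @param survey An `nma_survey` (or record data frame).
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @param estimator Estimator for the correlation/regression summaries.
#' @return Invisibly, the summary list.
#' @export
write_survey <- function(survey, csv_path = NULL, json_path = NULL,
                         estimator = "reml") {
  records <- survey_records(survey)
  if (!is.null(csv_path)) {
    utils::write.csv(records, csv_path, row.names = FALSE)
  }
  summary <- list(
    n_networks = nrow(records),
    prevalence = prevalence(records),
    correlations = tryCatch(characteristic_correlations(records, estimator),
                            error = function(e) NULL),
    regression = tryCatch(multivariable_regression(records, estimator),
                          error = function(e) NULL),
    skipped = if (inherits(survey, "nma_survey")) survey$skipped else NULL
  )
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                                na = "null", dataframe = "rows"),
               json_path)
  }
  invisible(summary)
}
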