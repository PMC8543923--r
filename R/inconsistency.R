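# Global inconsistency assessment: the design-by-treatment interaction Wald
# chi-squared test and the within-/between-design decomposition of Q.

#' Global Wald chi-squared test of the design-by-treatment interaction
#'
#' Tests all inconsistency parameters of a network jointly. The procedure:
#' 1. estimate the within-design between-study variance by fitting the DBT
#'    model (design matrix `X_dbt`) with the chosen estimator;
#' 2. GLS-fit the DBT model at that variance, giving design-level effects
#'    `theta` with covariance `V`;
#' 3. form `C`, an orthonormal basis of the left null space of the
#'    consistency embedding `A` (so `C %*% A = 0`); the inconsistency
#'    parameters are `omega = C %*% theta`, identically zero under
#'    consistency;
#' 4. `Q_inc = omega' (C V C')^+ omega`, compared to a chi-squared
#'    distribution with `df = rank(X_dbt) - rank(X)` degrees of freedom.
#'
#' The within-design variance is treated as known (plug-in). As an internal
#' cross-check the statistic is also computed as the drop in generalized
#' residual sum of squares between the consistency and DBT fits at the same
#' variance; the two routes agree to numerical precision and the difference
#' is stored in `check_rss_diff`.
#'
#' @param ds An [nma_dataset()] or [build_contrast_set()] result; must be
#'   connected.
#' @param estimator `"reml"` (default) or `"dl"` for the within-design
#'   variance.
#' @param tau2 Optional fixed within-design variance (skips estimation).
#' @param reference Reference treatment for the consistency comparison.
#' @return An object of class `dbt_test`: `Q_inc`, `df`, `p_value`,
#'   `tau2_within`, `estimator`, `omega` (estimated inconsistency contrasts),
#'   `omega_vcov`, `applicable` (FALSE when `df = 0`, in which case the test
#'   is reported as not applicable, never as p = 1), and `check_rss_diff`.
#' @export
#' @examples
#' cfg <- sim_config_triangle(studies_per_design = 3,
#'                            inconsistency = list("B:C" = c(C = 1)))
#' dbt_test(simulate_network(cfg, seed = 42), estimator = "dl")
dbt_test <- function(ds, estimator = c("reml", "dl"), tau2 = NULL,
                     reference = NULL) {
  estimator <- match.arg(estimator)
  cs <- if (inherits(ds, "contrast_set")) ds else build_contrast_set(ds)
  dm <- build_design_matrices(cs, reference)
  df <- dm$df_inconsistency
  if (df < 1L) {
    out <- list(Q_inc = NA_real_, df = 0L, p_value = NA_real_,
                tau2_within = NA_real_, estimator = estimator,
                omega = numeric(0), omega_vcov = matrix(0, 0, 0),
                applicable = FALSE, check_rss_diff = NA_real_,
                network_id = cs$network_id)
    class(out) <- "dbt_test"
    return(out)
  }
  if (is.null(tau2)) {
    dbt_df <- length(cs$y) - ncol(dm$X_dbt)
    tau2 <- if (dbt_df < 1L) {
      0
    } else if (estimator == "dl") {
      estimate_tau2_dl(cs, dm$X_dbt)
    } else {
      estimate_tau2_reml(cs, dm$X_dbt)
    }
  }
  fit_dbt <- gls_fit(cs, dm$X_dbt, tau2)
  C <- left_null_basis(dm$A)
  omega <- drop(C %*% fit_dbt$estimates)
  V_omega <- C %*% fit_dbt$vcov %*% t(C)
  V_omega <- (V_omega + t(V_omega)) / 2
  Q_inc <- drop(t(omega) %*% mp_pinv(V_omega) %*% omega)
  fit_cons <- gls_fit(cs, dm$X, tau2)
  check <- fit_cons$rss - fit_dbt$rss
  out <- list(Q_inc = Q_inc, df = df,
              p_value = stats::pchisq(Q_inc, df, lower.tail = FALSE),
              tau2_within = tau2, estimator = estimator, omega = omega,
              omega_vcov = V_omega, applicable = TRUE,
              check_rss_diff = check - Q_inc, network_id = cs$network_id)
  class(out) <- "dbt_test"
  out
}

#' @export
print.dbt_test <- function(x, digits = 4, ...) {
  cat(sprintf("Design-by-treatment interaction test for '%s'\n", x$network_id))
  if (!x$applicable) {
    cat("  not assessable: single effective design (0 inconsistency df)\n")
    return(invisible(x))
  }
  cat(sprintf("  Q_inc = %.*f on %d df, p = %.4g (%s, tau^2_within = %.*f)\n",
              digits, x$Q_inc, x$df, x$p_value, toupper(x$estimator),
              digits, x$tau2_within))
  invisible(x)
}

#' Serialize a DBT test (with companion fits) to a JSON report
#'
#' @param ds An [nma_dataset()].
#' @param estimator `"reml"` or `"dl"`.
#' @param path Optional file to write to.
#' @return The JSON string, invisibly if `path` is given.
#' @export
dbt_report_json <- function(ds, estimator = c("reml", "dl"), path = NULL) {
  estimator <- match.arg(estimator)
  test <- dbt_test(ds, estimator)
  fit_cons <- nma_fit(ds, "consistency", estimator)
  fit_dbt <- nma_fit(ds, "dbt", estimator)
  rep <- list(
    network_id = ds$network_id,
    Q_inc = test$Q_inc, df = test$df, p_value = test$p_value,
    tau_within = sqrt(fit_dbt$tau2), tau_consistency = sqrt(fit_cons$tau2),
    I2 = fit_cons$I2, estimator = estimator,
    classification = as.character(classify_inconsistency(test$p_value))
  )
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Decompose Cochran's Q into within- and between-design parts
#'
#' At `tau2 = 0`: `Q_total` is the generalized Q of the consistency fit;
#' `Q_within` sums the design-specific homogeneity statistics (each design's
#' studies against their own pooled design-level effects, which is exactly
#' the DBT-model residual); `Q_between = Q_total - Q_within >= 0` measures
#' design disagreement.
#'
#' @param ds An [nma_dataset()] or contrast set.
#' @param reference Reference treatment.
#' @return A list with `Q_total`, `Q_within`, `Q_between`, `per_design`
#'   (named vector of design-specific Q), and the degrees of freedom of each
#'   part.
#' @export
q_decomposition <- function(ds, reference = NULL) {
  cs <- if (inherits(ds, "contrast_set")) ds else build_contrast_set(ds)
  dm <- build_design_matrices(cs, reference)
  q_total <- cochran_q(cs, dm$X)
  # independent per-design pooled fits; their residual Q sums to the
  # DBT-model Q because X_dbt is block-diagonal by design
  designs <- sort(unique(cs$rows$design))
  per_design <- numeric(length(designs))
  names(per_design) <- designs
  for (d in designs) {
    keep <- cs$rows$design == d
    sub <- subset_contrast_set(cs, unique(cs$rows$study[keep]))
    dmd <- build_design_matrices(sub)
    per_design[d] <- cochran_q(sub, dmd$X_dbt)$Q
  }
  q_within <- sum(per_design)
  list(Q_total = q_total$Q, Q_within = q_within,
       Q_between = q_total$Q - q_within, per_design = per_design,
       df_total = q_total$df,
       df_within = length(cs$y) - ncol(dm$X_dbt),
       df_between = dm$df_inconsistency)
}

# Restrict a contrast set to a subset of studies (used by the per-design Q).
subset_contrast_set <- function(cs, studies) {
  keep_rows <- cs$rows$study %in% studies
  rows <- cs$rows[keep_rows, , drop = FALSE]
  blocks <- cs$blocks[studies]
  offset <- 0L
  for (s in studies) {
    m <- length(blocks[[s]]$idx)
    blocks[[s]]$idx <- offset + seq_len(m)
    offset <- offset + m
  }
  structure(list(rows = rows, y = rows$y, blocks = blocks,
                 treatments = sort(unique(c(rows$baseline, rows$comparator))),
                 network_id = cs$network_id),
            class = "contrast_set")
}

#' Classify a DBT p-value at the 0.05 and 0.10 thresholds
#'
#' Three-way classification of the global inconsistency p-value, with a
#' separate level for tests that are not applicable (zero inconsistency
#' degrees of freedom).
#'
#' @param p_value Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param thresholds Two increasing cut-offs; default `c(0.05, 0.10)`.
#' @return Factor with levels `"inconsistent@5%"`, `"inconsistent@5-10%"`,
#'   `"consistent@10%"`, `"not-applicable"`.
#' @export
classify_inconsistency <- function(p_value, thresholds = c(0.05, 0.10)) {
  stopifnot(length(thresholds) == 2L, thresholds[1L] < thresholds[2L])
  lv <- c(sprintf("inconsistent@%g%%", 100 * thresholds[1L]),
          sprintf("inconsistent@%g-%g%%", 100 * thresholds[1L],
                  100 * thresholds[2L]),
          sprintf("consistent@%g%%", 100 * thresholds[2L]),
          "not-applicable")
  out <- ifelse(is.na(p_value), lv[4L],
         ifelse(p_value < thresholds[1L], lv[1L],
         ifelse(p_value < thresholds[2L], lv[2L], lv[3L])))
  factor(out, levels = lv)
}
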