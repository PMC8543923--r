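# Generalized-least-squares engine: weighted fits under Sigma = S + tau^2 P,
# Cochran's Q, I^2, and the DL / REML estimators of the common between-study
# variance.

# Blockwise GLS core. Returns the cross-products, generalized residual sum of
# squares and log|Sigma| needed by every estimator. M is the full design
# matrix (rows aligned with cs$y).
gls_core <- function(cs, M, tau2) {
  p <- ncol(M)
  # fast path: all studies two-arm, so every block is scalar
  if (all(vapply(cs$blocks, function(b) length(b$idx) == 1L, logical(1)))) {
    s <- vapply(cs$blocks, function(b) b$S[1L, 1L], numeric(1))
    ord <- vapply(cs$blocks, function(b) b$idx[1L], integer(1))
    sig <- numeric(length(s))
    sig[ord] <- s + tau2
    w <- 1 / sig
    WM <- M * w
    return(list(XtWX = crossprod(M, WM), XtWy = drop(crossprod(WM, cs$y)),
                yWy = sum(cs$y^2 * w), logdet_sigma = sum(log(sig))))
  }
  XtWX <- matrix(0, p, p)
  XtWy <- numeric(p)
  yWy <- 0
  logdet <- 0
  for (b in cs$blocks) {
    idx <- b$idx
    Sig <- b$S + tau2 * b$P
    R <- tryCatch(chol(Sig), error = function(e) {
      stop("within-study covariance block is not positive definite (study '",
           cs$rows$study[idx[1L]], "')", call. = FALSE)
    })
    logdet <- logdet + 2 * sum(log(diag(R)))
    yi <- cs$y[idx]
    Mi <- M[idx, , drop = FALSE]
    Wyi <- backsolve(R, forwardsolve(t(R), yi))
    WMi <- backsolve(R, forwardsolve(t(R), Mi))
    XtWX <- XtWX + crossprod(Mi, WMi)
    XtWy <- XtWy + crossprod(Mi, Wyi)[, 1L]
    yWy <- yWy + sum(yi * Wyi)
  }
  list(XtWX = XtWX, XtWy = XtWy, yWy = yWy, logdet_sigma = logdet)
}

#' Generalized-least-squares fit at a fixed between-study variance
#'
#' Fits `y = M %*% est + error` by GLS with blockwise weights
#' `W = (S + tau2 * P)^{-1}`: estimates `(M'WM)^+ M'W y`, covariance
#' `(M'WM)^+` (Moore-Penrose where rank-deficient), and the generalized
#' residual sum of squares.
#'
#' @param cs A [build_contrast_set()] result.
#' @param M Design matrix with one row per contrast (e.g. `X` or `X_dbt` from
#'   [build_design_matrices()]).
#' @param tau2 Non-negative between-study variance to plug in.
#' @return A list of class `gls_fit` with `estimates`, `vcov`, `rss`, `rank`,
#'   `tau2`, `n` (number of contrasts) and `logdet_sigma`.
#' @export
gls_fit <- function(cs, M, tau2 = 0) {
  stopifnot(inherits(cs, "contrast_set"), is.finite(tau2), tau2 >= 0)
  M <- as.matrix(M)
  core <- gls_core(cs, M, tau2)
  r <- mat_rank(core$XtWX)
  if (r == ncol(M)) {
    Vinv <- core$XtWX
    V <- chol2inv(chol(Vinv))
  } else {
    V <- mp_pinv(core$XtWX)
  }
  est <- drop(V %*% core$XtWy)
  names(est) <- colnames(M)
  rss <- core$yWy - sum(est * core$XtWy)
  dimnames(V) <- list(colnames(M), colnames(M))
  structure(list(estimates = est, vcov = V, rss = max(rss, 0), rank = r,
                 tau2 = tau2, n = length(cs$y),
                 logdet_sigma = core$logdet_sigma),
            class = "gls_fit")
}

#' Cochran's Q and the I-squared statistic
#'
#' The generalized Q of the fixed-effect (tau^2 = 0) GLS fit of `M`, its
#' residual degrees of freedom `n - rank(M)`, and
#' `I2 = max(0, 1 - df/Q) * 100` (reported as `NA` when `df = 0`).
#'
#' @inheritParams gls_fit
#' @return A list with `Q`, `df` and `I2` (percent).
#' @export
cochran_q <- function(cs, M) {
  fit <- gls_fit(cs, M, tau2 = 0)
  df <- fit$n - fit$rank
  I2 <- if (df == 0L) NA_real_ else if (fit$rss > 0) {
    max(0, 1 - df / fit$rss) * 100
  } else 0
  list(Q = fit$rss, df = df, I2 = I2)
}

#' Method-of-moments (DerSimonian-Laird) between-study variance
#'
#' Matrix generalization of the DerSimonian-Laird estimator:
#' `tau2 = max(0, (Q - df) / tr[(W0 - W0 M (M'W0M)^+ M'W0) P])` with
#' `W0 = S^{-1}` blockwise. For a pairwise meta-analysis this reduces to the
#' classical `(Q - (k-1)) / (sum(w) - sum(w^2)/sum(w))`.
#'
#' @inheritParams gls_fit
#' @return The non-negative variance estimate (scalar).
#' @export
estimate_tau2_dl <- function(cs, M) {
  stopifnot(inherits(cs, "contrast_set"))
  M <- as.matrix(M)
  q <- cochran_q(cs, M)
  if (q$df < 1L) {
    stop("heterogeneity not estimable: zero residual degrees of freedom",
         call. = FALSE)
  }
  p <- ncol(M)
  if (all(vapply(cs$blocks, function(b) length(b$idx) == 1L, logical(1)))) {
    s <- numeric(length(cs$y))
    for (b in cs$blocks) s[b$idx] <- b$S[1L, 1L]
    WM <- M / s
    XtWX <- crossprod(M, WM)
    G <- mp_pinv(XtWX)
    denom <- sum(1 / s) - sum(G * crossprod(WM))
    if (denom <= 0) return(0)
    return(max(0, (q$Q - q$df) / denom))
  }
  XtWX <- matrix(0, p, p)
  trWP <- 0
  MWPWM <- matrix(0, p, p)
  for (b in cs$blocks) {
    idx <- b$idx
    R <- chol(b$S)
    Mi <- M[idx, , drop = FALSE]
    WMi <- backsolve(R, forwardsolve(t(R), Mi))
    Wi <- chol2inv(R)
    XtWX <- XtWX + crossprod(Mi, WMi)
    trWP <- trWP + sum(Wi * b$P)           # tr(Wi Pi), both symmetric
    MWPWM <- MWPWM + crossprod(WMi, b$P %*% WMi)
  }
  G <- mp_pinv(XtWX)
  denom <- trWP - sum(G * MWPWM)           # tr(G MWPWM), both symmetric
  if (denom <= 0) return(0)
  max(0, (q$Q - q$df) / denom)
}

# Restricted log-likelihood (up to a constant) at tau2 for design matrix M.
reml_loglik <- function(cs, M, tau2) {
  core <- gls_core(cs, M, tau2)
  ed <- eigen(core$XtWX, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(ed, .Machine$double.eps)
  logdet_info <- sum(log(ed[ed > tol]))
  est <- mp_pinv(core$XtWX) %*% core$XtWy
  rss <- core$yWy - sum(est * core$XtWy)
  -0.5 * (core$logdet_sigma + logdet_info + rss)
}

# Derivative of the restricted log-likelihood with respect to tau2:
# -0.5 * [tr(W P) - tr((M'WM)^+ M'WPWM) - (We)' P (We)], W = Sigma^{-1},
# e the GLS residual. Every term is invariant to the basis of the design
# matrix, so the root (the REML estimate) does not depend on the reference
# parameterization.
reml_score <- function(cs, M, tau2) {
  p <- ncol(M)
  scalar <- all(vapply(cs$blocks, function(b) length(b$idx) == 1L,
                       logical(1)))
  if (scalar) {
    s <- numeric(length(cs$y))
    for (b in cs$blocks) s[b$idx] <- b$S[1L, 1L]
    w <- 1 / (s + tau2)
    WM <- M * w
    XtWX <- crossprod(M, WM)
    G <- mp_pinv(XtWX)
    est <- drop(G %*% crossprod(WM, cs$y))
    we <- w * (cs$y - drop(M %*% est))
    return(-0.5 * (sum(w) - sum(G * crossprod(WM)) - sum(we^2)))
  }
  XtWX <- matrix(0, p, p)
  XtWy <- numeric(p)
  trWP <- 0
  MWPWM <- matrix(0, p, p)
  WMs <- vector("list", length(cs$blocks))
  Wys <- vector("list", length(cs$blocks))
  for (j in seq_along(cs$blocks)) {
    b <- cs$blocks[[j]]
    Sig <- b$S + tau2 * b$P
    R <- chol(Sig)
    Wi <- chol2inv(R)
    Mi <- M[b$idx, , drop = FALSE]
    WMi <- Wi %*% Mi
    XtWX <- XtWX + crossprod(Mi, WMi)
    XtWy <- XtWy + drop(crossprod(WMi, cs$y[b$idx]))
    trWP <- trWP + sum(Wi * b$P)
    MWPWM <- MWPWM + crossprod(WMi, b$P %*% WMi)
    WMs[[j]] <- WMi
    Wys[[j]] <- drop(Wi %*% cs$y[b$idx])
  }
  G <- mp_pinv(XtWX)
  est <- drop(G %*% XtWy)
  quad <- 0
  for (j in seq_along(cs$blocks)) {
    b <- cs$blocks[[j]]
    we <- Wys[[j]] - drop(WMs[[j]] %*% est)
    quad <- quad + drop(crossprod(we, b$P %*% we))
  }
  -0.5 * (trWP - sum(G * MWPWM) - quad)
}

#' Restricted maximum likelihood between-study variance
#'
#' Maximizes the restricted log-likelihood
#' `-0.5 * (log|Sigma(tau2)| + log|M' Sigma^{-1} M|_+ + RSS(tau2))`
#' over `tau2` in `[0, tau2_max]` by derivative-free bounded scalar search
#' (tolerance 1e-8 on `tau2`), with the boundary value `tau2 = 0` checked
#' explicitly. `|.|_+` is the pseudo-determinant on the estimable subspace.
#'
#' @inheritParams gls_fit
#' @param tau2_max Upper search bound; defaults to ten times the
#'   DerSimonian-Laird estimate plus one.
#' @return The non-negative variance estimate (scalar).
#' @export
estimate_tau2_reml <- function(cs, M, tau2_max = NULL) {
  stopifnot(inherits(cs, "contrast_set"))
  M <- as.matrix(M)
  n_df <- length(cs$y) - mat_rank(M)
  if (n_df < 1L) {
    stop("heterogeneity not estimable: zero residual degrees of freedom",
         call. = FALSE)
  }
  if (is.null(tau2_max)) {
    tau2_max <- 10 * estimate_tau2_dl(cs, M) + 1
  }
  # profile is maximized where the (basis-invariant) score crosses zero;
  # a non-positive score at the origin puts the maximum on the boundary
  if (reml_score(cs, M, 0) <= 0) return(0)
  hi <- tau2_max
  tries <- 0L
  while (reml_score(cs, M, hi) > 0 && tries < 40L) {
    hi <- hi * 2
    tries <- tries + 1L
  }
  if (reml_score(cs, M, hi) > 0) {
    stop("REML profile still increasing at tau^2 = ", hi,
         "; optimizer failed", call. = FALSE)
  }
  root <- stats::uniroot(function(t2) reml_score(cs, M, t2),
                         interval = c(0, hi), tol = 1e-10)$root
  # guard against a pathological (non-unimodal) profile
  if (reml_loglik(cs, M, 0) > reml_loglik(cs, M, root)) return(0)
  root
}

#' Fit a network meta-analysis model
#'
#' High-level fit of either the consistency model (basic parameters versus a
#' reference treatment) or the design-by-treatment interaction model
#' (design-specific relative effects) to a network of dichotomous trials,
#' with the common between-study variance estimated by REML (default) or
#' DerSimonian-Laird, and Cochran's Q / I-squared of the corresponding
#' fixed-effect fit.
#'
#' Under the DBT model the estimated variance captures within-design
#' heterogeneity only; under the consistency model it absorbs between-design
#' disagreement (inconsistency) as well.
#'
#' @param ds An [nma_dataset()] (connected).
#' @param model `"consistency"` or `"dbt"`.
#' @param estimator `"reml"` (default) or `"dl"`.
#' @param reference Reference treatment (consistency model); default
#'   lexicographically smallest.
#' @param tau2 Optional fixed between-study variance; when supplied the
#'   estimator is skipped and the value is plugged in.
#' @return An object of class `nma_fit`: the `gls_fit` fields plus `model`,
#'   `tau2_estimator`, `Q`, `Q_df`, `I2`, the design-matrix bundle and the
#'   contrast set.
#' @export
#' @examples
#' ds <- simulate_network(sim_config_triangle(studies_per_design = 3), seed = 7)
#' fit <- nma_fit(ds, model = "consistency", estimator = "dl")
#' fit
nma_fit <- function(ds, model = c("consistency", "dbt"),
                    estimator = c("reml", "dl"), reference = NULL,
                    tau2 = NULL) {
  model <- match.arg(model)
  estimator <- match.arg(estimator)
  cs <- if (inherits(ds, "contrast_set")) ds else build_contrast_set(ds)
  dm <- build_design_matrices(cs, reference)
  M <- if (model == "consistency") dm$X else dm$X_dbt
  q <- cochran_q(cs, M)
  tau2_fixed <- !is.null(tau2)
  if (!tau2_fixed) {
    tau2 <- if (q$df < 1L) {
      0
    } else if (estimator == "dl") {
      estimate_tau2_dl(cs, M)
    } else {
      estimate_tau2_reml(cs, M)
    }
  }
  fit <- gls_fit(cs, M, tau2)
  fit$model <- model
  fit$tau2_estimator <- if (tau2_fixed) "fixed" else estimator
  fit$Q <- q$Q
  fit$Q_df <- q$df
  fit$I2 <- q$I2
  fit$design <- dm
  fit$contrasts <- cs
  class(fit) <- c("nma_fit", "gls_fit")
  fit
}

#' @export
print.nma_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Network meta-analysis fit: %s model (%s)\n",
              x$model, toupper(x$tau2_estimator)))
  cat(sprintf("  contrasts: %d | parameters: %d (rank %d)\n",
              x$n, length(x$estimates), x$rank))
  cat(sprintf("  tau^2 = %.*f (tau = %.*f) | Q = %.*f on %d df | I^2 = %s\n",
              digits, x$tau2, digits, sqrt(x$tau2), digits, x$Q, x$Q_df,
              if (is.na(x$I2)) "NA" else sprintf("%.1f%%", x$I2)))
  est <- cbind(estimate = x$estimates, se = sqrt(diag(x$vcov)))
  print(round(est, digits))
  invisible(x)
}

#' All pairwise treatment effects from a consistency fit
#'
#' Expands the basic parameters of a consistency-model [nma_fit()] into the
#' full table of pairwise log odds ratios `d(t1, t2) = beta_t2 - beta_t1`
#' with standard errors, which is invariant to the reference treatment.
#'
#' @param fit A consistency-model `nma_fit`.
#' @return Data frame with `t1`, `t2`, `estimate`, `se`.
#' @export
pairwise_estimates <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  if (fit$model != "consistency") {
    stop("pairwise estimates require a consistency-model fit", call. = FALSE)
  }
  trts <- fit$contrasts$treatments
  basics <- fit$design$basics
  coef_of <- function(t) basic_row(t, basics)
  pairs <- utils::combn(trts, 2L)
  out <- data.frame(t1 = pairs[1L, ], t2 = pairs[2L, ],
                    estimate = NA_real_, se = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    ell <- coef_of(out$t2[i]) - coef_of(out$t1[i])
    out$estimate[i] <- sum(ell * fit$estimates)
    out$se[i] <- sqrt(drop(t(ell) %*% fit$vcov %*% ell))
  }
  out
}
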