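# Synthetic networks of randomised trials with known truth: basic effects,
# common heterogeneity tau, and optional design-level inconsistency shifts.

#' Simulation configuration for a synthetic trial network
#'
#' Describes the data-generating process for networks of randomised trials
#' with a dichotomous outcome: the network geometry (designs and studies per
#' design), arm sizes, baseline risk, true relative effects, a common
#' between-study standard deviation `tau` with compound-symmetry correlation
#' 0.5 across a study's contrasts, and optional design-level inconsistency
#' shifts `omega`.
#'
#' @param treatments Character vector of treatment labels (>= 2).
#' @param designs List of treatment sets (character vectors); together they
#'   must connect all treatments.
#' @param studies_per_design Integer count, recycled over designs.
#' @param n_per_arm Patients per arm, recycled over designs.
#' @param baseline_risk Either a single probability (fixed baseline risk) or
#'   a list `list(mean_logit=, sd_logit=)` for a logit-normal draw per study.
#'   Default: logit-normal with mean `qlogis(0.2)` and sd 0.5, so baseline
#'   risks vary across studies as they do in practice.
#' @param true_effects Named vector of true log odds ratios versus the
#'   reference treatment (the lexicographically smallest label, effect 0);
#'   missing treatments default to 0.
#' @param tau Common between-study standard deviation (>= 0).
#' @param inconsistency Named list mapping a design label (treatments sorted
#'   and joined by `":"`, e.g. `"B:C"`) to a named vector of log-odds-ratio
#'   shifts for that design's non-baseline treatments. Default: none (a
#'   consistent network).
#' @param seed Default root seed for [simulate_network()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(treatments, designs, studies_per_design = 2L,
                       n_per_arm = 100L,
                       baseline_risk = list(mean_logit = stats::qlogis(0.2),
                                            sd_logit = 0.5),
                       true_effects = NULL, tau = 0,
                       inconsistency = list(), seed = 1L) {
  treatments <- sort(unique(as.character(treatments)))
  if (length(treatments) < 2L) stop("need at least two treatments", call. = FALSE)
  designs <- lapply(designs, function(d) sort(unique(as.character(d))))
  if (any(vapply(designs, length, integer(1)) < 2L)) {
    stop("every design needs at least two treatments", call. = FALSE)
  }
  if (!all(unlist(designs) %in% treatments)) {
    stop("designs mention treatments not in the treatment list", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    do.call(rbind, lapply(designs, function(d) {
      idx <- utils::combn(length(d), 2L)
      data.frame(from = d[idx[1L, ]], to = d[idx[2L, ]])
    })), directed = FALSE, vertices = data.frame(name = treatments))
  if (igraph::components(g)$no != 1L) {
    stop("designs do not connect all treatments", call. = FALSE)
  }
  studies_per_design <- rep_len(as.integer(studies_per_design), length(designs))
  n_per_arm <- rep_len(as.integer(n_per_arm), length(designs))
  if (any(studies_per_design < 1L) || any(n_per_arm < 2L)) {
    stop("studies_per_design must be >= 1 and n_per_arm >= 2", call. = FALSE)
  }
  eff <- stats::setNames(numeric(length(treatments)), treatments)
  if (!is.null(true_effects)) {
    if (is.null(names(true_effects))) {
      stop("true_effects must be a named vector", call. = FALSE)
    }
    eff[names(true_effects)] <- true_effects
  }
  eff[treatments[1L]] <- 0
  if (length(inconsistency) > 0L) {
    labels <- vapply(designs, design_label, "")
    bad <- setdiff(names(inconsistency), labels)
    if (length(bad) > 0L) {
      stop("inconsistency shifts reference unknown design(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (is.numeric(baseline_risk) && length(baseline_risk) == 1L) {
    stopifnot(baseline_risk > 0, baseline_risk < 1)
    baseline_risk <- list(mean_logit = stats::qlogis(baseline_risk),
                          sd_logit = 0)
  }
  # margin check: extreme linear predictors should keep risks inside (0,1)
  # comfortably, otherwise event counts pile up at the boundary
  shift_max <- if (length(inconsistency) > 0L) {
    max(abs(unlist(inconsistency)))
  } else 0
  extreme <- baseline_risk$mean_logit + 3 * baseline_risk$sd_logit + 3 * tau +
    max(abs(eff)) + shift_max
  if (expit(extreme) > 0.999 ||
      expit(baseline_risk$mean_logit - 3 * baseline_risk$sd_logit - 3 * tau -
              max(abs(eff)) - shift_max) < 0.001) {
    warning("configured effects push event risks very close to 0 or 1; ",
            "zero cells will be common", call. = FALSE)
  }
  structure(list(treatments = treatments, designs = designs,
                 studies_per_design = studies_per_design,
                 n_per_arm = n_per_arm, baseline_risk = baseline_risk,
                 true_effects = eff, tau = tau,
                 inconsistency = inconsistency, seed = as.integer(seed)),
            class = "sim_config")
}

#' Convenience triangle configuration
#'
#' A three-treatment network with the three two-arm designs A:B, A:C, B:C —
#' the smallest geometry with a closed loop, used throughout the Monte-Carlo
#' harnesses.
#'
#' @param studies_per_design,n_per_arm,tau,inconsistency,baseline_risk,seed
#'   Passed to [sim_config()].
#' @param true_effects Default log odds ratios `B = 0.3`, `C = 0.5` vs A.
#' @return A `sim_config`.
#' @export
sim_config_triangle <- function(studies_per_design = 2L, n_per_arm = 100L,
                                tau = 0, inconsistency = list(),
                                true_effects = c(B = 0.3, C = 0.5),
                                baseline_risk = list(mean_logit = stats::qlogis(0.2),
                                                     sd_logit = 0.5),
                                seed = 1L) {
  sim_config(c("A", "B", "C"),
             list(c("A", "B"), c("A", "C"), c("B", "C")),
             studies_per_design = studies_per_design, n_per_arm = n_per_arm,
             baseline_risk = baseline_risk, true_effects = true_effects,
             tau = tau, inconsistency = inconsistency, seed = seed)
}

#' Read a simulation configuration from a YAML file
#'
#' Fields mirror the arguments of [sim_config()]; `designs` is a list of
#' treatment-label lists and `inconsistency` a mapping from design label to
#' a treatment->shift mapping.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  inc <- lapply(cfg$inconsistency, unlist)
  sim_config(treatments = unlist(cfg$treatments),
             designs = lapply(cfg$designs, unlist),
             studies_per_design = cfg$studies_per_design %||% 2L,
             n_per_arm = cfg$n_per_arm %||% 100L,
             baseline_risk = cfg$baseline_risk %||%
               list(mean_logit = stats::qlogis(0.2), sd_logit = 0.5),
             true_effects = unlist(cfg$true_effects),
             tau = cfg$tau %||% 0,
             inconsistency = if (length(inc) > 0L) inc else list(),
             seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one network of randomised trials
#'
#' For each study: the baseline logit is drawn from the configured
#' logit-normal (or fixed) baseline risk; study-level random effects for the
#' study's contrasts are multivariate normal with variance `tau^2` and
#' compound-symmetry correlation 0.5; each non-baseline arm's event count is
#' binomial with probability
#' `plogis(baseline_logit + d_k - d_b + omega_{d,k} + delta_k)`, where `d`
#' are the true effects, `omega` the design's inconsistency shift and
#' `delta` the random effect. The design's baseline arm (lexicographically
#' smallest treatment) gets probability `plogis(baseline_logit)`.
#'
#' @param cfg A [sim_config()].
#' @param seed Root seed; defaults to `cfg$seed`. Output is a deterministic
#'   function of `(cfg, seed)`.
#' @return An [nma_dataset()].
#' @export
simulate_network <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(seed, 0L))
  arms <- list()
  study_no <- 0L
  for (j in seq_along(cfg$designs)) {
    d_trts <- cfg$designs[[j]]
    d_lab <- design_label(d_trts)
    m <- length(d_trts) - 1L
    omega <- stats::setNames(numeric(m), d_trts[-1L])
    if (d_lab %in% names(cfg$inconsistency)) {
      sh <- cfg$inconsistency[[d_lab]]
      if (is.null(names(sh))) {
        stop("inconsistency shift for design ", d_lab, " must be named",
             call. = FALSE)
      }
      omega[names(sh)] <- sh
    }
    for (rep in seq_len(cfg$studies_per_design[j])) {
      study_no <- study_no + 1L
      bl <- stats::rnorm(1, cfg$baseline_risk$mean_logit,
                         cfg$baseline_risk$sd_logit)
      # compound-symmetry random effects: common + idiosyncratic halves
      u <- stats::rnorm(1)
      z <- stats::rnorm(m)
      delta <- cfg$tau * (u + z) / sqrt(2)
      d_base <- cfg$true_effects[d_trts[1L]]
      lp <- c(0, cfg$true_effects[d_trts[-1L]] - d_base + omega + delta) + bl
      n <- cfg$n_per_arm[j]
      arms[[study_no]] <- data.frame(
        study = sprintf("s%03d", study_no), treatment = d_trts,
        events = stats::rbinom(length(d_trts), n, expit(lp)), n = n,
        stringsAsFactors = FALSE
      )
    }
  }
  nma_dataset(do.call(rbind, arms),
              network_id = sprintf("sim-seed%d", seed))
}

# Shared replicate loop: simulate, run the DBT test, collect results.
# Failed replicates are tolerated up to `fail_cap` (fraction), then error.
run_replicates <- function(cfg, reps, estimators, seed, fail_cap = 0.01,
                           collect = c("p", "full")) {
  collect <- match.arg(collect)
  results <- vector("list", reps)
  failures <- 0L
  for (i in seq_len(reps)) {
    res <- tryCatch({
      ds <- simulate_network(cfg, seed = substream_seed(seed, i))
      cs <- build_contrast_set(ds)
      one <- list()
      for (est in estimators) {
        t <- dbt_test(cs, estimator = est)
        one[[paste0("p_", est)]] <- t$p_value
        one[[paste0("tau2_dbt_", est)]] <- t$tau2_within
        one[[paste0("Q_inc_", est)]] <- t$Q_inc
        if (collect == "full") {
          dm <- build_design_matrices(cs)
          one[[paste0("tau2_cons_", est)]] <- if (est == "dl") {
            estimate_tau2_dl(cs, dm$X)
          } else {
            estimate_tau2_reml(cs, dm$X)
          }
        }
      }
      one
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else results[[i]] <- res
  }
  if (failures > max(1, fail_cap * reps)) {
    stop(failures, " of ", reps, " replicates failed to fit", call. = FALSE)
  }
  list(records = do.call(rbind, lapply(results[!vapply(results, is.null,
                                                       logical(1))],
                                       as.data.frame)),
       failures = failures)
}

#' Monte-Carlo type-I error of the DBT test
#'
#' Simulates consistent networks (all inconsistency shifts zero are required)
#' from `cfg` and reports the fraction of replicates whose global Wald test
#' rejects at each significance level, with its binomial Monte-Carlo
#' standard error `sqrt(alpha (1 - alpha) / reps)`.
#'
#' @param cfg A consistent [sim_config()] (`inconsistency` empty).
#' @param reps Number of replicates (>= 100).
#' @param alphas Significance levels.
#' @param estimators Subset of `c("reml", "dl")`.
#' @param seed Root seed; per-replicate substreams make the result
#'   independent of replicate order.
#' @return An object of class `sim_result` with the rejection-rate table,
#'   mean `Q_inc` and failure count.
#' @export
type_one_error <- function(cfg, reps = 1000L, alphas = c(0.05, 0.10),
                           estimators = "reml", seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 100L)
  if (length(cfg$inconsistency) > 0L) {
    stop("type-I error requires a consistent configuration (omega = 0)",
         call. = FALSE)
  }
  sim_result(run_replicates(cfg, reps, estimators, seed), reps, alphas,
             estimators, what = "type-I error")
}

#' Monte-Carlo power of the DBT test over a grid of inconsistency shifts
#'
#' For each value of `omega`, plants that shift on one design's contrasts
#' (default: the last design, on its first non-baseline treatment) and
#' reports the rejection rate. At `omega = 0` this reproduces the type-I
#' error.
#'
#' @param cfg Base [sim_config()] (its own `inconsistency` is replaced).
#' @param omega_grid Numeric vector of design-shift magnitudes (log OR).
#' @param design Design label to receive the shift; default the last design.
#' @param reps,alphas,estimators,seed As in [type_one_error()].
#' @return A list of `sim_result` objects, one per `omega` value, with the
#'   grid in `names`.
#' @export
power_curve <- function(cfg, omega_grid, design = NULL, reps = 500L,
                        alphas = 0.05, estimators = "reml",
                        seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 100L)
  labels <- vapply(cfg$designs, design_label, "")
  if (is.null(design)) design <- labels[length(labels)]
  if (!design %in% labels) stop("unknown design: ", design, call. = FALSE)
  d_trts <- cfg$designs[[match(design, labels)]]
  out <- list()
  for (w in omega_grid) {
    cfg_w <- cfg
    cfg_w$inconsistency <- if (w == 0) list() else {
      stats::setNames(list(stats::setNames(w, d_trts[2L])), design)
    }
    out[[sprintf("%g", w)]] <- sim_result(
      run_replicates(cfg_w, reps, estimators, seed), reps, alphas,
      estimators, what = sprintf("power at omega = %g", w))
  }
  out
}

#' Monte-Carlo power as a function of evidence density
#'
#' Holds the design shift fixed and varies the number of studies per design,
#' exhibiting how power to detect inconsistency grows with the amount of
#' direct evidence per comparison.
#'
#' @param cfg Base [sim_config()].
#' @param studies_grid Integer vector of studies-per-design values.
#' @param omega Design-shift magnitude (log OR) planted on `design`.
#' @param design Design label to receive the shift; default the last design.
#' @param reps,alphas,estimators,seed As in [type_one_error()].
#' @return A list of `sim_result` objects named by studies-per-design.
#' @export
power_by_studies <- function(cfg, studies_grid, omega, design = NULL,
                             reps = 200L, alphas = 0.05,
                             estimators = "reml", seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 100L)
  out <- list()
  for (k in studies_grid) {
    cfg_k <- cfg
    cfg_k$studies_per_design <- rep_len(as.integer(k), length(cfg$designs))
    out[[sprintf("%d", k)]] <- power_curve(
      cfg_k, omega_grid = omega, design = design, reps = reps,
      alphas = alphas, estimators = estimators,
      seed = seed)[[sprintf("%g", omega)]]
  }
  out
}

#' Monte-Carlo recovery of the between-study standard deviation
#'
#' Simulates networks at each true `tau`, estimates the between-study
#' variance under both the consistency and the DBT model with the requested
#' estimators, and reports mean bias and root-mean-square error of `tau-hat`
#' (on the standard-deviation scale), plus the mean estimates themselves.
#' Under planted inconsistency the consistency-model `tau-hat` absorbs the
#' design disagreement and exceeds the DBT-model (within-design) one.
#'
#' @param cfg Base [sim_config()]; its `tau` is replaced by each grid value.
#' @param tau_grid True between-study standard deviations.
#' @param reps Replicates per grid point (>= 100).
#' @param estimators Subset of `c("reml", "dl")`.
#' @param seed Root seed.
#' @return Data frame with one row per (tau, estimator, model) and columns
#'   `mean_tau_hat`, `bias`, `rmse`, `reps_used`.
#' @export
tau_recovery <- function(cfg, tau_grid, reps = 200L,
                         estimators = c("reml", "dl"), seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"), reps >= 100L)
  rows <- list()
  for (tau in tau_grid) {
    cfg_t <- cfg
    cfg_t$tau <- tau
    rr <- run_replicates(cfg_t, reps, estimators, seed, collect = "full")
    for (est in estimators) {
      for (model in c("cons", "dbt")) {
        th <- sqrt(rr$records[[paste0("tau2_", model, "_", est)]])
        rows[[length(rows) + 1L]] <- data.frame(
          tau_true = tau, estimator = est,
          model = if (model == "cons") "consistency" else "dbt",
          mean_tau_hat = mean(th), bias = mean(th - tau),
          rmse = sqrt(mean((th - tau)^2)), reps_used = length(th),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Assemble the rejection-rate table from a run_replicates() result.
sim_result <- function(rr, reps, alphas, estimators, what = "simulation") {
  rows <- list()
  for (est in estimators) {
    p <- rr$records[[paste0("p_", est)]]
    p <- p[!is.na(p)]
    for (a in alphas) {
      rows[[length(rows) + 1L]] <- data.frame(
        estimator = est, alpha = a, rejection_rate = mean(p < a),
        mc_se = sqrt(a * (1 - a) / length(p)), reps_used = length(p),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(what = what, replicates = reps, failures = rr$failures,
                 rejection = do.call(rbind,
                                     c(rows, list(make.row.names = FALSE))),
                 mean_Q_inc = vapply(estimators, function(est) {
                   mean(rr$records[[paste0("Q_inc_", est)]], na.rm = TRUE)
                 }, numeric(1)),
                 records = rr$records),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo %s: %d replicates (%d failed)\n", x$what,
              x$replicates, x$failures))
  print(x$rejection, row.names = FALSE)
  invisible(x)
}
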