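# A fabricated record table with the columns the survey statistics consume.
fake_records <- function(n, p = runif(n), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  studies <- sample(5:60, n, replace = TRUE)
  trts <- sample(4:12, n, replace = TRUE)
  edges <- pmin(trts * (trts - 1) / 2, trts - 1 + sample(1:8, n, TRUE))
  data.frame(
    network_id = sprintf("net%03d", seq_len(n)),
    n_studies = studies, n_treatments = trts, n_edges = edges,
    n_designs = edges + sample(0:2, n, TRUE),
    n_loops = edges - trts + 1L,
    n_multiarm = sample(0:4, n, TRUE),
    ratio_studies_treatments = studies / trts,
    ratio_loops_treatments = (edges - trts + 1) / trts,
    ratio_loops_studies = (edges - trts + 1) / studies,
    ratio_designs_studies = (edges + 1) / studies,
    ratio_edges_studies = edges / studies,
    ratio_multiarm_studies = sample(0:4, n, TRUE) / studies,
    p_dbt_reml = p, p_dbt_dl = p,
    year = sample(2005:2018, n, TRUE),
    outcome_type = sample(c("objective", "subjective"), n, TRUE),
    stringsAsFactors = FALSE)
}

test_that("analyze_network fills a record for consistent and inconsistent fixtures", {
  cfg <- sim_config(c("A", "B", "C", "D"),
                    list(c("A", "B"), c("A", "C"), c("B", "C"),
                         c("A", "B", "D")),
                    studies_per_design = c(6, 6, 6, 4), n_per_arm = 2000,
                    tau = 0, inconsistency = list("B:C" = c(C = 1.2)))
  rec <- analyze_network(simulate_network(cfg, seed = 3))
  expect_lt(rec$p_dbt_reml, 0.05)
  expect_lt(rec$p_dbt_dl, 0.05)
  expect_gte(rec$n_multiarm, 1L)
  expect_true(rec$tau_cons_reml >= rec$tau_dbt_reml - 1e-8)

  rec0 <- analyze_network(consistent_fixture())
  expect_equal(rec0$p_dbt_dl, 1, tolerance = 1e-6)
  expect_equal(rec0$tau_cons_dl, 0, tolerance = 1e-6)
})

test_that("survey pipeline skips ineligible networks with a logged reason", {
  dir <- withr::local_tempdir()
  write_nma_csv(simulate_network(random_network_config(1, tau = 0.1)),
                file.path(dir, "net1.csv"))
  write_nma_csv(triangle_fixture(), file.path(dir, "small.csv"))  # 3 nodes
  line <- nma_dataset(data.frame(study = rep(c("s1", "s2", "s3"), each = 2),
                                 treatment = c("A", "B", "B", "C", "C", "D"),
                                 events = 5, n = 50))  # no loop
  write_nma_csv(line, file.path(dir, "line.csv"))
  sv <- survey_networks(dir)
  expect_equal(nrow(sv$records), 1L)
  expect_equal(sort(sv$skipped$network_id), c("line", "small"))
  expect_match(sv$skipped$reason[sv$skipped$network_id == "small"],
               "fewer than 4")
  expect_match(sv$skipped$reason[sv$skipped$network_id == "line"], "loop")
})

test_that("prevalence counts are exact and order-invariant", {
  rec <- fake_records(3, p = c(0.03, 0.07, 0.50), seed = 1)
  tab <- prevalence(rec)
  get <- function(est, thr) tab[tab$estimator == est & tab$threshold == thr, ]
  expect_equal(get("reml", 0.05)$n_inconsistent, 1L)
  expect_equal(get("reml", 0.10)$n_inconsistent, 2L)
  expect_equal(get("reml", 0.10)$percent, 200 / 3)
  expect_equal(prevalence(rec[3:1, ]), tab)

  rec$p_dbt_reml <- c(0.5, 0.6, NA)
  tab <- prevalence(rec)
  expect_equal(get("reml", 0.05)$n_total, 2L)
  expect_equal(get("reml", 0.05)$n_missing, 1L)
  expect_equal(get("reml", 0.05)$percent, 0)
})

test_that("correlations recover perfect dependence and vanish under permutation", {
  rec <- fake_records(60, seed = 2)
  rec$p_dbt_reml <- (log(rec$n_studies) - min(log(rec$n_studies))) /
    diff(range(log(rec$n_studies)))
  out <- characteristic_correlations(rec)
  expect_equal(out$r[out$characteristic == "n_studies"], 1, tolerance = 1e-8)

  rec <- fake_records(1000, seed = 3)  # p independent of structure
  out <- characteristic_correlations(rec)
  expect_true(all(abs(out$r) < 0.1, na.rm = TRUE))
  # zero multi-arm networks are retained via the one-study substitution
  expect_equal(out$n[out$characteristic == "n_multiarm"], 1000L)
})

test_that("regression recovers a planted linear signal and flat nulls", {
  rec <- fake_records(300, seed = 4)
  rec$p_dbt_reml <- 0.5 + 0.004 * rec$n_studies +
    rnorm(300, sd = 1e-4)
  out <- multivariable_regression(rec)
  est <- out$estimate[out$term == "n_studies"]
  expect_lt(abs(est - 0.004) / 0.004, 0.01)

  rec <- fake_records(500, seed = 5)  # independent p: no term significant often
  out <- multivariable_regression(rec)
  expect_lt(mean(out$p_value[-1] < 0.05), 0.5)

  rec$p_dbt_reml <- 0.42  # constant outcome: all slopes vanish
  out <- multivariable_regression(rec)
  expect_lt(max(abs(out$estimate[-1])), 1e-10)

  expect_error(multivariable_regression(fake_records(5)), "at least 10")
})

test_that("subgroup summaries separate disjoint groups and reject degenerate ones", {
  rec <- fake_records(40, seed = 6)
  rec$outcome_type <- rep(c("objective", "subjective"), each = 20)
  rec$p_dbt_reml <- c(runif(20, 0, 0.2), runif(20, 0.7, 1))
  out <- subgroup_distributions(rec, "outcome_type")
  expect_lt(out$test_p_value, 1e-3)
  expect_equal(out$summary$n, c(20L, 20L))
  expect_equal(out$summary$median_fourth_root, out$summary$median^0.25)

  rec$outcome_type <- "objective"
  expect_error(subgroup_distributions(rec, "outcome_type"), "two groups")
})

test_that("year trend test runs on tabulated inconsistency counts", {
  rec <- fake_records(80, seed = 7)
  out <- year_trend(rec, alpha = 0.05)
  expect_equal(sum(out$table$n_total), 80L)
  expect_true(out$test_p_value >= 0 && out$test_p_value <= 1)
})

test_that("survey outputs round-trip to CSV and JSON", {
  dir <- withr::local_tempdir()
  cfgs <- lapply(1:3, function(s) random_network_config(s, tau = 0.1))
  for (i in 1:3) {
    write_nma_csv(simulate_network(cfgs[[i]], seed = i),
                  file.path(dir, sprintf("net%d.csv", i)))
  }
  sv <- survey_networks(dir, estimators = "dl")
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_survey(sv, csv_path = csv, json_path = js, estimator = "dl")
  expect_equal(nrow(utils::read.csv(csv)), 3L)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$n_networks, 3L)
  expect_true(is.data.frame(parsed$prevalence))
})
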