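test_that("GLS at fixed tau^2 reproduces the hand-computed inverse-variance average", {
  cs <- manual_contrast_set(list(c("A", "B"), c("A", "B")),
                            y = c(0.5, 1.0), v = c(0.1, 0.1))
  dm <- build_design_matrices(cs)
  f0 <- gls_fit(cs, dm$X, tau2 = 0)
  expect_equal(unname(f0$estimates), 0.75, tolerance = 1e-12)
  expect_equal(unname(f0$vcov[1, 1]), 0.05, tolerance = 1e-12)
  f1 <- gls_fit(cs, dm$X, tau2 = 0.1)
  expect_equal(unname(f1$estimates), 0.75, tolerance = 1e-12)  # equal weights
  expect_equal(unname(f1$vcov[1, 1]), 0.1, tolerance = 1e-12)
})

test_that("Q, I2 and residuals behave on homogeneous and heterogeneous data", {
  cs <- manual_contrast_set(rep(list(c("A", "B")), 4),
                            y = rep(0.4, 4), v = rep(0.2, 4))
  dm <- build_design_matrices(cs)
  q <- cochran_q(cs, dm$X)
  expect_equal(q$Q, 0, tolerance = 1e-12)
  expect_equal(q$df, 3L)
  expect_equal(q$I2, 0)

  # saturated model: df = 0 makes I2 undefined
  cs1 <- manual_contrast_set(list(c("A", "B")), y = 0.3, v = 0.1)
  dm1 <- build_design_matrices(cs1)
  expect_true(is.na(cochran_q(cs1, dm1$X)$I2))
})

test_that("matrix DL reduces to the classical estimator on a pairwise meta-analysis", {
  y <- c(0.2, 0.5, 0.9, -0.1, 0.6)
  v <- c(0.05, 0.12, 0.20, 0.08, 0.15)
  cs <- manual_contrast_set(rep(list(c("A", "B")), 5), y = y, v = v)
  dm <- build_design_matrices(cs)
  w <- 1 / v
  mu <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu)^2)
  classical <- max(0, (Q - 4) / (sum(w) - sum(w^2) / sum(w)))
  expect_equal(estimate_tau2_dl(cs, dm$X), classical, tolerance = 1e-10)
  expect_equal(cochran_q(cs, dm$X)$Q, Q, tolerance = 1e-10)
})

test_that("DL and REML match independent pairwise oracles", {
  skip_if_not_installed("metafor")
  set.seed(17)
  for (rep in 1:5) {
    k <- sample(4:10, 1)
    y <- rnorm(k, 0.4, 0.4)
    v <- runif(k, 0.02, 0.3)
    cs <- manual_contrast_set(rep(list(c("A", "B")), k), y = y, v = v)
    dm <- build_design_matrices(cs)

    oracle_dl <- metafor::rma(y, v, method = "DL")
    expect_equal(estimate_tau2_dl(cs, dm$X), oracle_dl$tau2,
                 tolerance = 1e-10)

    # scalar textbook REML profile, maximized directly
    ll <- function(t2) {
      w <- 1 / (v + t2)
      mu <- sum(w * y) / sum(w)
      -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
    }
    t2_oracle <- stats::optimize(ll, c(0, 10), maximum = TRUE,
                                 tol = 1e-12)$maximum
    if (ll(0) >= ll(t2_oracle)) t2_oracle <- 0
    t2 <- estimate_tau2_reml(cs, dm$X)
    expect_equal(t2, t2_oracle, tolerance = 1e-6)
    # metafor agrees to its Fisher-scoring termination precision
    oracle_reml <- metafor::rma(y, v, method = "REML")
    expect_lt(abs(t2 - oracle_reml$tau2), 1e-4)
    w <- 1 / (v + t2)
    expect_equal(unname(gls_fit(cs, dm$X, t2)$estimates),
                 sum(w * y) / sum(w), tolerance = 1e-10)
  }
})

test_that("REML returns zero heterogeneity for identical effects", {
  cs <- manual_contrast_set(rep(list(c("A", "B")), 5),
                            y = rep(0.7, 5), v = runif(5, 0.05, 0.2))
  dm <- build_design_matrices(cs)
  expect_equal(estimate_tau2_reml(cs, dm$X), 0)
  expect_equal(estimate_tau2_dl(cs, dm$X), 0)
})

test_that("heterogeneity is not estimable without residual degrees of freedom", {
  cs <- manual_contrast_set(list(c("A", "B")), y = 0.3, v = 0.1)
  dm <- build_design_matrices(cs)
  expect_error(estimate_tau2_dl(cs, dm$X), "not estimable")
  expect_error(estimate_tau2_reml(cs, dm$X), "not estimable")
})

test_that("consistency residuals dominate DBT residuals at any shared tau^2", {
  for (seed in 1:6) {
    cs <- build_contrast_set(random_network(seed, tau = 0.2,
                                            inconsistent = seed %% 2 == 0))
    dm <- build_design_matrices(cs)
    for (t2 in c(0, 0.05, 0.3)) {
      expect_gte(gls_fit(cs, dm$X, t2)$rss,
                 gls_fit(cs, dm$X_dbt, t2)$rss - 1e-10)
    }
  }
})

test_that("reference choice permutes parameters but not pairwise estimates or tau^2", {
  ds <- random_network(21, tau = 0.15)
  for (est in c("dl", "reml")) {
    fits <- lapply(c("A", "B"), function(ref) {
      nma_fit(ds, "consistency", est, reference = ref)
    })
    expect_equal(fits[[1]]$tau2, fits[[2]]$tau2, tolerance = 1e-8)
    expect_equal(fits[[1]]$Q, fits[[2]]$Q, tolerance = 1e-8)
    pw <- lapply(fits, pairwise_estimates)
    expect_equal(pw[[1]]$estimate, pw[[2]]$estimate, tolerance = 1e-8)
    expect_equal(pw[[1]]$se, pw[[2]]$se, tolerance = 1e-8)
  }
})

test_that("design matrices satisfy the consistency embedding identity", {
  for (seed in c(3, 9)) {
    cs <- build_contrast_set(random_network(seed))
    dm <- build_design_matrices(cs)
    expect_lt(max(abs(dm$X_dbt %*% dm$A - dm$X)), 1e-12)
    expect_true(all(dm$X %in% c(-1, 0, 1)))
    expect_equal(qr(dm$X)$rank, length(cs$treatments) - 1L)
    expect_equal(qr(dm$X_dbt)$rank, ncol(dm$X_dbt))
  }
  cs <- build_contrast_set(triangle_fixture())
  expect_error(build_design_matrices(cs, reference = "Z"), "not in the network")
  dm <- build_design_matrices(cs, reference = "A")
  expect_equal(dim(dm$X), c(6L, 2L))
  expect_equal(dim(dm$X_dbt), c(6L, 3L))
})
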