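test_that("CSV round-trip preserves a canonical dataset", {
  ds <- triangle_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_nma_csv(ds, path)
  back <- read_nma_csv(path, network_id = "triangle")
  expect_identical(back$arms[, c("study", "treatment", "events", "n")],
                   ds$arms[, c("study", "treatment", "events", "n")])
  expect_equal(length(unique(back$arms$study)), 6L)
  expect_equal(sort(unique(back$arms$treatment)), c("A", "B", "C"))
})

test_that("CSV reader accepts case-insensitive headers and keeps metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Study,Treatment,Events,N,year,extra",
               "s1,A,10,100,2012,x", "s1,B,20,100,2012,y"), path)
  ds <- read_nma_csv(path)
  expect_equal(ds$year, 2012L)
  expect_true("extra" %in% names(ds$arms))
  expect_equal(ds$arms$events, c(10L, 20L))
})

test_that("malformed arm tables are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("study,arm,events,n", "s1,A,10,100"), path)
  expect_error(read_nma_csv(path), "treatment")

  base <- data.frame(study = c("s1", "s1"), treatment = c("A", "B"),
                     events = c(10, 20), n = c(100, 100))
  bad <- base; bad$events[2] <- 120
  expect_error(nma_dataset(bad), "events > n.*2")
  bad <- base; bad$n[1] <- 0
  expect_error(nma_dataset(bad), "positive")
  bad <- base; bad$events[1] <- 2.5
  expect_error(nma_dataset(bad), "integers")
  bad <- rbind(base, base[1, ])
  expect_error(nma_dataset(bad), "duplicate")
})

test_that("validation reports connectivity, degeneracies and eligibility", {
  expect_false(validate_network(triangle_fixture())$eligible)  # 3 < 4 nodes

  disjoint <- nma_dataset(data.frame(
    study = c("s1", "s1", "s2", "s2"),
    treatment = c("A", "B", "C", "D"),
    events = c(1, 2, 3, 4), n = 10))
  val <- validate_network(disjoint)
  expect_equal(val$n_components, 2L)
  expect_false(val$connected)

  square <- nma_dataset(data.frame(
    study = rep(c("s1", "s2", "s3", "s4"), each = 2),
    treatment = c("A", "B", "B", "C", "C", "D", "A", "D"),
    events = 5, n = 50))
  val <- validate_network(square)
  expect_true(val$connected)
  expect_true(val$eligible_nodes)
  expect_equal(val$n_loops, 1L)
  expect_true(val$eligible)

  zero <- nma_dataset(data.frame(study = c("s1", "s1"),
                                 treatment = c("A", "B"),
                                 events = c(0, 0), n = 20))
  expect_equal(validate_network(zero)$all_zero_studies, "s1")
})

test_that("structure metrics match direct enumeration on known geometries", {
  m <- structure_metrics(triangle_fixture())
  expect_equal(m$n_studies, 6L)
  expect_equal(m$n_treatments, 3L)
  expect_equal(m$n_edges, 3L)
  expect_equal(m$n_designs, 3L)
  expect_equal(m$n_multiarm, 0L)
  expect_equal(m$n_loops, 1L)
  expect_equal(m$df_inconsistency, 3L * (2L - 1L) - (3L - 1L))
  expect_false(m$has_single_study_edge)
  expect_equal(m$ratio_studies_treatments, 2)

  # a single three-arm design: one loop but no room for inconsistency
  abc <- nma_dataset(data.frame(study = rep(c("s1", "s2"), each = 3),
                                treatment = rep(c("A", "B", "C"), 2),
                                events = c(10, 20, 30, 12, 18, 28), n = 100))
  m <- structure_metrics(abc)
  expect_equal(m$n_edges, 3L)
  expect_equal(m$n_designs, 1L)
  expect_equal(m$n_loops, 1L)
  expect_equal(m$df_inconsistency, 0L)
  expect_equal(m$n_multiarm, 2L)

  # designs {ABC, AB}: (2 + 1) - 2 = 1 inconsistency parameter
  mixed <- nma_dataset(data.frame(
    study = c("s1", "s1", "s1", "s2", "s2"),
    treatment = c("A", "B", "C", "A", "B"),
    events = c(10, 20, 30, 12, 18), n = 100))
  expect_equal(structure_metrics(mixed)$df_inconsistency, 1L)
  expect_true(structure_metrics(mixed)$has_single_study_edge)

  expect_error(structure_metrics(nma_dataset(data.frame(
    study = c("s1", "s1", "s2", "s2"), treatment = c("A", "B", "C", "D"),
    events = 1, n = 10))), "disconnected")
})

test_that("loop count equals the cycle-space dimension of the simple graph", {
  for (seed in 1:8) {
    ds <- random_network(seed, tau = 0)
    m <- structure_metrics(ds)
    g <- igraph::graph_from_data_frame(
      unique(do.call(rbind, lapply(split(ds$arms$treatment, ds$arms$study),
                                   function(t) {
                                     t <- sort(unique(t))
                                     idx <- utils::combn(length(t), 2)
                                     data.frame(a = t[idx[1, ]], b = t[idx[2, ]])
                                   }))), directed = FALSE)
    expect_equal(m$n_loops,
                 igraph::ecount(g) - igraph::vcount(g) +
                   igraph::components(g)$no)
  }
})

test_that("design-formula inconsistency df equals the model rank surplus", {
  for (seed in 1:10) {
    ds <- random_network(seed, tau = 0.1)
    cs <- build_contrast_set(ds)
    dm <- build_design_matrices(cs)
    rank_gap <- qr(dm$X_dbt)$rank - qr(dm$X)$rank
    expect_equal(structure_metrics(ds)$df_inconsistency, rank_gap)
    expect_equal(dm$df_inconsistency, rank_gap)
  }
})
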