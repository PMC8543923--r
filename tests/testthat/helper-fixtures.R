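# Fixtures and independent oracles shared across the suite.
# Everything is generated in code; no stored data files.

# Deterministic 6-study triangle: two studies per two-arm design (A:B, A:C,
# B:C), 100 patients per arm, fixed event counts.
triangle_fixture <- function() {
  arms <- rbind(
    data.frame(study = "ab1", treatment = c("A", "B"), events = c(10, 20), n = 100),
    data.frame(study = "ab2", treatment = c("A", "B"), events = c(12, 22), n = 100),
    data.frame(study = "ac1", treatment = c("A", "C"), events = c(11, 30), n = 100),
    data.frame(study = "ac2", treatment = c("A", "C"), events = c(9, 28), n = 100),
    data.frame(study = "bc1", treatment = c("B", "C"), events = c(21, 31), n = 100),
    data.frame(study = "bc2", treatment = c("B", "C"), events = c(19, 29), n = 100)
  )
  nma_dataset(arms, network_id = "triangle")
}

# A network whose observed arm logits are exactly consistent: every arm of a
# given treatment has identical counts in every study, so all log odds
# ratios derive from a single set of treatment-level logits.
consistent_fixture <- function() {
  counts <- c(A = 20, B = 30, C = 40, D = 25)
  mk <- function(study, trts) {
    data.frame(study = study, treatment = trts, events = unname(counts[trts]),
               n = 100)
  }
  nma_dataset(rbind(
    mk("s1", c("A", "B")), mk("s2", c("A", "C")), mk("s3", c("B", "C")),
    mk("s4", c("A", "B", "C")), mk("s5", c("C", "D")), mk("s6", c("B", "D"))
  ), network_id = "consistent")
}

# Random eligible network geometry drawn from a small menu, fitted out by
# the package's own generator (geometry is the random part under test).
random_network_config <- function(seed, tau = 0.2, inconsistent = FALSE) {
  set.seed(seed)
  geometry <- sample(3L, 1L)
  if (geometry == 1L) {
    designs <- list(c("A", "B"), c("A", "C"), c("B", "C"), c("A", "B", "C"),
                    c("A", "D"))
    trts <- c("A", "B", "C", "D")
  } else if (geometry == 2L) {
    designs <- list(c("A", "B"), c("B", "C"), c("C", "D"), c("A", "D"),
                    c("A", "C"))
    trts <- c("A", "B", "C", "D")
  } else {
    designs <- list(c("A", "B", "C"), c("A", "D"), c("B", "D"), c("C", "D"))
    trts <- c("A", "B", "C", "D")
  }
  eff <- stats::setNames(round(stats::runif(length(trts) - 1L, -0.5, 0.5), 2),
                         trts[-1L])
  inc <- if (inconsistent) {
    d <- designs[[sample(length(designs), 1L)]]
    stats::setNames(list(stats::setNames(0.8, d[2L])),
                    paste(d, collapse = ":"))
  } else {
    list()
  }
  sim_config(trts, designs, studies_per_design = sample(2:4, length(designs),
                                                        replace = TRUE),
             n_per_arm = 400L, true_effects = eff, tau = tau,
             inconsistency = inc, seed = seed)
}

random_network <- function(seed, tau = 0.2, inconsistent = FALSE) {
  simulate_network(random_network_config(seed, tau, inconsistent), seed = seed)
}

# Independent Bucher loop oracle for a triangle of two-arm designs at
# tau^2 = 0: inverse-variance pooled direct log odds ratios per comparison
# computed from scratch from the raw arm counts, then
# w = d_AB + d_BC - d_AC and Q = w^2 / (v_AB + v_AC + v_BC).
bucher_oracle <- function(ds) {
  arms <- ds$arms
  pooled <- list()
  for (s in unique(arms$study)) {
    a <- arms[arms$study == s, ]
    a <- a[order(a$treatment), ]
    stopifnot(nrow(a) == 2L)
    e <- a$events; n <- a$n
    if (any(e == 0 | e == n)) { e <- e + 0.5; n <- n + 1 }
    y <- log(e[2] / (n[2] - e[2])) - log(e[1] / (n[1] - e[1]))
    v <- sum(1 / e + 1 / (n - e))
    key <- paste(a$treatment, collapse = ":")
    pooled[[key]] <- rbind(pooled[[key]], c(y = y, v = v))
  }
  dir <- lapply(pooled, function(m) {
    w <- 1 / m[, "v"]
    c(est = sum(w * m[, "y"]) / sum(w), var = 1 / sum(w))
  })
  w_incons <- dir[["A:B"]]["est"] + dir[["B:C"]]["est"] - dir[["A:C"]]["est"]
  v_sum <- dir[["A:B"]]["var"] + dir[["B:C"]]["var"] + dir[["A:C"]]["var"]
  list(Q = unname(w_incons^2 / v_sum), w = unname(w_incons))
}

# Minimal hand-built contrast set (scalar blocks) for algebraic tests where
# exact y and S values matter more than realistic counts.
manual_contrast_set <- function(designs, y, v) {
  stopifnot(length(designs) == length(y), length(y) == length(v))
  rows <- data.frame(
    study = sprintf("m%02d", seq_along(y)),
    design = vapply(designs, function(d) paste(sort(d), collapse = ":"), ""),
    baseline = vapply(designs, function(d) sort(d)[1L], ""),
    comparator = vapply(designs, function(d) sort(d)[2L], ""),
    y = y, stringsAsFactors = FALSE
  )
  blocks <- lapply(seq_along(y), function(i) {
    list(S = matrix(v[i], 1, 1), P = matrix(1, 1, 1), idx = i)
  })
  names(blocks) <- rows$study
  structure(list(rows = rows, y = rows$y, blocks = blocks,
                 treatments = sort(unique(c(rows$baseline, rows$comparator))),
                 network_id = "manual"),
            class = "contrast_set")
}
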