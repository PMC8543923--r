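#' Construct a network of trials from arm-level data
#'
#' Bundles arm-level dichotomous trial data (one row per study arm) with
#' optional network-level metadata into an `nma_dataset` object, the raw unit
#' of every analysis in this package.
#'
#' @param arms A data frame with columns `study`, `treatment`, `events`, `n`
#'   (one row per arm). Extra columns are preserved.
#' @param network_id Character label for the network.
#' @param year Optional publication year (integer).
#' @param outcome_type Optional; one of `"objective"`, `"semi-objective"`,
#'   `"subjective"`.
#' @param comparison_type Optional; one of `"pharm-vs-pharm"`,
#'   `"pharm-vs-placebo"`, `"nonpharm-vs-any"`.
#' @param complex_interventions Optional logical flag.
#'
#' @return An object of class `nma_dataset`: a list with elements `network_id`,
#'   `arms` (the validated arm table) and the metadata fields.
#'
#' @details Basic integrity is enforced at construction: counts must be
#'   non-negative integers with `events <= n` and `n > 0`, and each
#'   `(study, treatment)` pair may appear at most once. Structural checks
#'   (connectivity, eligibility for inconsistency assessment) are report-only
#'   and live in [validate_network()].
#'
#' @seealso [read_nma_csv()], [validate_network()], [structure_metrics()]
#' @export
#' @examples
#' arms <- data.frame(
#'   study = c("s1", "s1", "s2", "s2"),
#'   treatment = c("A", "B", "A", "B"),
#'   events = c(10, 20, 12, 18), n = c(100, 100, 100, 100)
#' )
#' nma_dataset(arms, network_id = "example")
nma_dataset <- function(arms, network_id = "network", year = NULL,
                        outcome_type = NULL, comparison_type = NULL,
                        complex_interventions = NULL) {
  arms <- as.data.frame(arms)
  required <- c("study", "treatment", "events", "n")
  missing_cols <- setdiff(required, names(arms))
  if (length(missing_cols) > 0L) {
    stop("arm table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  arms$study <- as.character(arms$study)
  arms$treatment <- trimws(as.character(arms$treatment))
  check_count <- function(x, name, positive = FALSE) {
    bad <- !is.finite(x) | x != round(x) | x < if (positive) 1 else 0
    if (any(bad)) {
      stop(sprintf("column '%s' must contain %s integers (rows: %s)", name,
                   if (positive) "positive" else "non-negative",
                   paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    as.integer(round(x))
  }
  arms$events <- check_count(as.numeric(arms$events), "events")
  arms$n <- check_count(as.numeric(arms$n), "n", positive = TRUE)
  bad <- arms$events > arms$n
  if (any(bad)) {
    stop("events > n in row(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(arms[, c("study", "treatment")])
  if (any(dup)) {
    stop("duplicate (study, treatment) arm(s) in row(s): ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  if (!is.null(outcome_type)) {
    outcome_type <- match.arg(outcome_type,
                              c("objective", "semi-objective", "subjective"))
  }
  if (!is.null(comparison_type)) {
    comparison_type <- match.arg(comparison_type,
                                 c("pharm-vs-pharm", "pharm-vs-placebo",
                                   "nonpharm-vs-any"))
  }
  structure(
    list(network_id = as.character(network_id), arms = arms,
         year = if (is.null(year)) NULL else as.integer(year),
         outcome_type = outcome_type, comparison_type = comparison_type,
         complex_interventions = complex_interventions),
    class = "nma_dataset"
  )
}

#' @export
print.nma_dataset <- function(x, ...) {
  cat(sprintf("Network '%s': %d studies, %d treatments, %d arms\n",
              x$network_id, length(unique(x$arms$study)),
              length(unique(x$arms$treatment)), nrow(x$arms)))
  invisible(x)
}

#' Read a network from a long-format arm-level CSV file
#'
#' Reads one network of trials from a comma-separated file with one row per
#' study arm and (case-insensitive) header columns `study`, `treatment`,
#' `events`, `n`. Optional columns `year`, `outcome_type`, `comparison_type`
#' and `complex` populate network metadata; any other columns are preserved in
#' the arm table.
#'
#' @param path Path to the CSV file.
#' @param network_id Label for the network; defaults to the file name without
#'   extension.
#' @return An [nma_dataset()] with arms in file order.
#' @export
read_nma_csv <- function(path, network_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  lc <- tolower(names(raw))
  required <- c("study", "treatment", "events", "n")
  for (col in required) {
    if (!col %in% lc) {
      stop(sprintf("CSV '%s' is missing required column '%s'", path, col),
           call. = FALSE)
    }
  }
  names(raw) <- ifelse(lc %in% c(required, "year", "outcome_type",
                                 "comparison_type", "complex"),
                       lc, names(raw))
  if (is.null(network_id)) {
    network_id <- sub("\\.[^.]*$", "", basename(path))
  }
  meta1 <- function(col) {
    if (!col %in% names(raw)) return(NULL)
    v <- unique(raw[[col]][!is.na(raw[[col]])])
    if (length(v) == 0L) NULL else v[1L]
  }
  nma_dataset(raw, network_id = network_id, year = meta1("year"),
              outcome_type = meta1("outcome_type"),
              comparison_type = meta1("comparison_type"),
              complex_interventions = {
                v <- meta1("complex")
                if (is.null(v)) NULL else as.logical(v)
              })
}

#' Write a network to the long-format arm-level CSV dialect
#'
#' @param ds An [nma_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nma_csv <- function(ds, path) {
  stopifnot(inherits(ds, "nma_dataset"))
  out <- ds$arms
  if (!is.null(ds$year)) out$year <- ds$year
  if (!is.null(ds$outcome_type)) out$outcome_type <- ds$outcome_type
  if (!is.null(ds$comparison_type)) out$comparison_type <- ds$comparison_type
  if (!is.null(ds$complex_interventions)) out$complex <- ds$complex_interventions
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Unique undirected treatment pairs compared head-to-head within studies.
# Returns a data.frame with columns t1 < t2 and the number of distinct
# studies informing each edge.
direct_edges <- function(ds) {
  per_study <- split(ds$arms$treatment, ds$arms$study)
  pieces <- lapply(names(per_study), function(s) {
    trts <- sort(unique(per_study[[s]]))
    if (length(trts) < 2L) return(NULL)
    idx <- utils::combn(length(trts), 2L)
    data.frame(t1 = trts[idx[1L, ]], t2 = trts[idx[2L, ]], study = s,
               stringsAsFactors = FALSE)
  })
  all_pairs <- do.call(rbind, pieces)
  if (is.null(all_pairs)) {
    return(data.frame(t1 = character(), t2 = character(),
                      n_studies = integer()))
  }
  key <- paste(all_pairs$t1, all_pairs$t2, sep = "\r")
  counts <- tapply(all_pairs$study, key, function(s) length(unique(s)))
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  data.frame(t1 = vapply(parts, `[[`, "", 1L),
             t2 = vapply(parts, `[[`, "", 2L),
             n_studies = as.integer(counts), stringsAsFactors = FALSE)
}

# igraph object on the simple graph of direct comparisons.
network_graph <- function(ds) {
  edges <- direct_edges(ds)
  igraph::graph_from_data_frame(
    edges[, c("t1", "t2")], directed = FALSE,
    vertices = data.frame(name = sort(unique(ds$arms$treatment)))
  )
}

#' Validate a network and report its structure and eligibility
#'
#' Report-only checks: connectivity of the treatment graph, single-arm
#' studies, studies with zero events (or all events) in every arm, and the
#' eligibility conditions for global inconsistency assessment (at least four
#' treatment nodes, at least one closed loop, connected). Nothing is mutated
#' and nothing raises; downstream fitting functions enforce what they need.
#'
#' @param ds An [nma_dataset()].
#' @return An object of class `network_validation`: a list with the component
#'   treatment sets, counts, flagged studies and eligibility booleans.
#' @export
validate_network <- function(ds) {
  stopifnot(inherits(ds, "nma_dataset"))
  g <- network_graph(ds)
  comp <- igraph::components(g)
  comp_sets <- split(igraph::V(g)$name, comp$membership)
  arms_per_study <- table(ds$arms$study)
  single_arm <- names(arms_per_study)[arms_per_study < 2L]
  by_study <- split(ds$arms, ds$arms$study)
  all_zero <- names(by_study)[vapply(by_study, function(a) all(a$events == 0L),
                                     logical(1))]
  all_events <- names(by_study)[vapply(by_study,
                                       function(a) all(a$events == a$n),
                                       logical(1))]
  n_trt <- igraph::vcount(g)
  n_edges <- igraph::ecount(g)
  n_loops <- n_edges - n_trt + comp$no
  out <- list(
    network_id = ds$network_id,
    n_treatments = n_trt,
    n_components = comp$no,
    components = unname(comp_sets),
    connected = comp$no == 1L,
    single_arm_studies = single_arm,
    all_zero_studies = all_zero,
    all_events_studies = all_events,
    n_loops = n_loops,
    eligible_nodes = n_trt >= 4L,
    eligible_loop = n_loops >= 1L
  )
  out$eligible <- out$connected && out$eligible_nodes && out$eligible_loop &&
    length(single_arm) == 0L
  class(out) <- "network_validation"
  out
}

#' @export
print.network_validation <- function(x, ...) {
  cat(sprintf("Validation of network '%s'\n", x$network_id))
  cat(sprintf("  treatments: %d in %d component(s)%s\n", x$n_treatments,
              x$n_components, if (x$connected) "" else "  [DISCONNECTED]"))
  cat(sprintf("  independent loops: %d\n", x$n_loops))
  if (length(x$single_arm_studies) > 0L) {
    cat("  single-arm studies:", paste(x$single_arm_studies, collapse = ", "), "\n")
  }
  if (length(x$all_zero_studies) > 0L) {
    cat("  all-zero studies:", paste(x$all_zero_studies, collapse = ", "), "\n")
  }
  cat(sprintf("  eligible for inconsistency assessment: %s\n",
              if (x$eligible) "yes" else "no"))
  invisible(x)
}

#' Structural metrics of a treatment network
#'
#' Computes the descriptive characteristics used to profile a network:
#' numbers of studies, treatments, direct comparisons (edges of the simple
#' comparison graph), unique designs (distinct treatment sets), multi-arm
#' studies, independent loops (cycle-space dimension: edges − nodes +
#' components), whether any direct comparison is informed by a single study,
#' the inconsistency degrees of freedom, and the six ratio metrics
#' (studies/treatments, loops/treatments, loops/studies, designs/studies,
#' edges/studies, multi-arm/studies).
#'
#' @param ds An [nma_dataset()]; must be connected.
#' @return An object of class `structure_metrics` (a named list).
#' @details For a connected network the inconsistency degrees of freedom equal
#'   `sum(t_d - 1) - (T - 1)` over designs `d` with `t_d` treatments, which is
#'   exactly the rank surplus of the design-by-treatment interaction model
#'   over the consistency model.
#' @export
structure_metrics <- function(ds) {
  stopifnot(inherits(ds, "nma_dataset"))
  val <- validate_network(ds)
  if (!val$connected) {
    stop("network '", ds$network_id, "' is disconnected (",
         val$n_components, " components); analyse the largest connected ",
         "component separately or fix the data", call. = FALSE)
  }
  edges <- direct_edges(ds)
  by_study <- split(ds$arms$treatment, ds$arms$study)
  designs <- vapply(by_study, design_label, "")
  design_sizes <- vapply(unique(designs),
                         function(d) length(strsplit(d, ":", fixed = TRUE)[[1L]]),
                         integer(1))
  n_studies <- length(by_study)
  n_trt <- val$n_treatments
  out <- list(
    network_id = ds$network_id,
    n_studies = n_studies,
    n_treatments = n_trt,
    n_edges = nrow(edges),
    n_designs = length(design_sizes),
    n_multiarm = sum(vapply(by_study, function(t) length(unique(t)),
                            integer(1)) >= 3L),
    n_loops = val$n_loops,
    has_single_study_edge = any(edges$n_studies == 1L),
    df_inconsistency = as.integer(sum(design_sizes - 1L) - (n_trt - 1L)),
    ratio_studies_treatments = n_studies / n_trt,
    ratio_loops_treatments = val$n_loops / n_trt,
    ratio_loops_studies = val$n_loops / n_studies,
    ratio_designs_studies = length(design_sizes) / n_studies,
    ratio_edges_studies = nrow(edges) / n_studies,
    ratio_multiarm_studies = sum(vapply(by_study,
                                        function(t) length(unique(t)),
                                        integer(1)) >= 3L) / n_studies
  )
  class(out) <- "structure_metrics"
  out
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf("Structure of network '%s'\n", x$network_id))
  cat(sprintf("  studies %d | treatments %d | direct comparisons %d | designs %d\n",
              x$n_studies, x$n_treatments, x$n_edges, x$n_designs))
  cat(sprintf("  multi-arm studies %d | independent loops %d | df(inconsistency) %d\n",
              x$n_multiarm, x$n_loops, x$df_inconsistency))
  cat(sprintf("  single-study comparison present: %s\n",
              if (x$has_single_study_edge) "yes" else "no"))
  invisible(x)
}

#' @export
as.data.frame.structure_metrics <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}
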