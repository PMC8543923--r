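# Arm-level data -> study-level baseline-contrast log odds ratios with exact
# within-study covariance.

#' Log odds-ratio contrasts for a single study
#'
#' Converts one study's dichotomous arms into `arms - 1` log odds ratios
#' against a common baseline arm, with their exact large-sample covariance.
#' For comparator k versus baseline b:
#' `y_k = log((e_k/(n_k-e_k)) / (e_b/(n_b-e_b)))`,
#' `Var(y_k) = 1/e_k + 1/(n_k-e_k) + 1/e_b + 1/(n_b-e_b)`, and
#' `Cov(y_k, y_j) = 1/e_b + 1/(n_b-e_b)` (the shared baseline arm).
#'
#' If any cell (events or non-events) of any arm is zero, 0.5 is added to
#' every cell of every arm of the study (so `events + 0.5` out of `n + 1`)
#' before computing; studies with zero events in all arms are retained.
#'
#' @param arms Data frame of one study's arms (`treatment`, `events`, `n`).
#' @param baseline_rule Which arm anchors the contrasts: `"first"` (default,
#'   lexicographically smallest treatment label) or `"last"`. Model results
#'   are invariant to this choice.
#' @return A list with the contrast vector `y` (named by comparator), the
#'   covariance block `S`, `baseline`, `comparators`, and `corrected`
#'   (whether the continuity correction was applied).
#' @export
study_contrasts <- function(arms, baseline_rule = c("first", "last")) {
  baseline_rule <- match.arg(baseline_rule)
  arms <- as.data.frame(arms)
  if (nrow(arms) < 2L) {
    stop("study has fewer than two arms; contrasts undefined", call. = FALSE)
  }
  ord <- order(arms$treatment)
  arms <- arms[ord, , drop = FALSE]
  if (baseline_rule == "last") {
    arms <- arms[c(nrow(arms), seq_len(nrow(arms) - 1L)), , drop = FALSE]
  }
  e <- as.numeric(arms$events)
  n <- as.numeric(arms$n)
  corrected <- any(e == 0 | e == n)
  if (corrected) {
    e <- e + 0.5
    n <- n + 1
  }
  lodds <- log(e / (n - e))
  v_arm <- 1 / e + 1 / (n - e)
  if (any(!is.finite(lodds))) {
    stop("non-finite log odds after continuity correction (internal error)",
         call. = FALSE)
  }
  m <- length(e) - 1L
  y <- lodds[-1L] - lodds[1L]
  S <- matrix(v_arm[1L], m, m)
  diag(S) <- v_arm[1L] + v_arm[-1L]
  comparators <- arms$treatment[-1L]
  names(y) <- comparators
  dimnames(S) <- list(comparators, comparators)
  list(y = y, S = S, baseline = arms$treatment[1L], comparators = comparators,
       corrected = corrected)
}

# Compound-symmetry heterogeneity structure block: 1 on the diagonal, 0.5 off.
# Under tau^2 * P every pairwise contrast within a multi-arm study has
# between-study variance tau^2.
cs_block <- function(m) {
  P <- matrix(0.5, m, m)
  diag(P) <- 1
  P
}

#' Build the contrast set for a whole network
#'
#' Stacks the per-study baseline contrasts of [study_contrasts()] in stable
#' study order, recording for each row its study, design, baseline and
#' comparator treatment, alongside the block-diagonal within-study covariance
#' `S` and the block-diagonal compound-symmetry heterogeneity structure `P`
#' (correlation 0.5) used as the multiplier of the common between-study
#' variance.
#'
#' @param ds An [nma_dataset()] (validated, connected).
#' @param baseline_rule Passed to [study_contrasts()].
#' @return An object of class `contrast_set`: a list with
#'   * `rows`: data frame (`study`, `design`, `baseline`, `comparator`, `y`);
#'   * `y`: the stacked contrast vector;
#'   * `blocks`: per-study list with elements `S`, `P`, `idx` (row indices);
#'   * `treatments`: sorted treatment labels;
#'   * `network_id`.
#' @export
build_contrast_set <- function(ds, baseline_rule = c("first", "last")) {
  stopifnot(inherits(ds, "nma_dataset"))
  baseline_rule <- match.arg(baseline_rule)
  by_study <- split(ds$arms, ds$arms$study)
  by_study <- by_study[unique(ds$arms$study)]  # stable file order
  rows <- list()
  blocks <- vector("list", length(by_study))
  names(blocks) <- names(by_study)
  offset <- 0L
  for (s in names(by_study)) {
    sc <- tryCatch(study_contrasts(by_study[[s]], baseline_rule),
                   error = function(e) {
                     stop("study '", s, "': ", conditionMessage(e),
                          call. = FALSE)
                   })
    m <- length(sc$y)
    rows[[s]] <- data.frame(
      study = s, design = design_label(by_study[[s]]$treatment),
      baseline = sc$baseline, comparator = sc$comparators, y = unname(sc$y),
      stringsAsFactors = FALSE
    )
    blocks[[s]] <- list(S = sc$S, P = cs_block(m),
                        idx = offset + seq_len(m))
    offset <- offset + m
  }
  rows <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(
    list(rows = rows, y = rows$y, blocks = blocks,
         treatments = sort(unique(ds$arms$treatment)),
         network_id = ds$network_id),
    class = "contrast_set"
  )
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("Contrast set for '%s': %d contrasts from %d studies, %d treatments\n",
              x$network_id, length(x$y), length(x$blocks),
              length(x$treatments)))
  invisible(x)
}
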