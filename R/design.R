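# Design matrices for the consistency and design-by-treatment interaction
# (DBT) models.

# beta-coefficient row for treatment t relative to `reference`, over columns
# `basics` (all treatments except the reference, sorted).
basic_row <- function(t, basics) {
  r <- numeric(length(basics))
  names(r) <- basics
  if (t %in% basics) r[t] <- 1
  r
}

#' Design matrices for the consistency and DBT models
#'
#' Builds, for a contrast set:
#' * `X` — the consistency design matrix (one column per non-reference
#'   treatment; each contrast row is the difference of treatment indicators,
#'   so entries lie in -1/0/1);
#' * `X_dbt` — the design-by-treatment interaction design matrix, with one
#'   set of `t_d - 1` effect parameters per design (each design's own
#'   baseline is its lexicographically smallest treatment);
#' * `A` — the consistency embedding with `X_dbt %*% A == X`, i.e. the map
#'   `theta = A %*% beta` that the design-level parameters satisfy under
#'   consistency.
#'
#' For a connected network `rank(X) = T - 1`, `X_dbt` has full column rank
#' `sum(t_d - 1)`, and their difference is the inconsistency degrees of
#' freedom.
#'
#' @param cs A [build_contrast_set()] result.
#' @param reference Reference treatment for the basic parameters; defaults to
#'   the lexicographically smallest label. Results of all fits are invariant
#'   to this choice.
#' @return A list with `X`, `X_dbt`, `A`, `reference`, `basics` (column
#'   labels of `X`), `dbt_params` (column labels of `X_dbt`, `"design:trt"`),
#'   and `df_inconsistency`.
#' @export
build_design_matrices <- function(cs, reference = NULL) {
  stopifnot(inherits(cs, "contrast_set"))
  trts <- cs$treatments
  if (is.null(reference)) reference <- trts[1L]
  if (!reference %in% trts) {
    stop("reference treatment '", reference, "' is not in the network",
         call. = FALSE)
  }
  basics <- setdiff(trts, reference)
  rows <- cs$rows
  nr <- nrow(rows)

  X <- matrix(0, nr, length(basics), dimnames = list(NULL, basics))
  for (i in seq_len(nr)) {
    X[i, ] <- basic_row(rows$comparator[i], basics) -
      basic_row(rows$baseline[i], basics)
  }

  designs <- sort(unique(rows$design))
  dbt_cols <- list()
  for (d in designs) {
    d_trts <- strsplit(d, ":", fixed = TRUE)[[1L]]
    dbt_cols[[d]] <- paste(d, d_trts[-1L], sep = "|")  # design baseline = d_trts[1]
  }
  param_names <- unlist(dbt_cols, use.names = FALSE)
  X_dbt <- matrix(0, nr, length(param_names),
                  dimnames = list(NULL, param_names))
  for (i in seq_len(nr)) {
    d <- rows$design[i]
    for (t in c(rows$comparator[i], rows$baseline[i])) {
      nm <- paste(d, t, sep = "|")
      if (nm %in% param_names) {
        X_dbt[i, nm] <- X_dbt[i, nm] + if (t == rows$comparator[i]) 1 else -1
      }
    }
  }

  A <- matrix(0, length(param_names), length(basics),
              dimnames = list(param_names, basics))
  for (d in designs) {
    d_trts <- strsplit(d, ":", fixed = TRUE)[[1L]]
    d_base <- d_trts[1L]
    for (t in d_trts[-1L]) {
      A[paste(d, t, sep = "|"), ] <- basic_row(t, basics) -
        basic_row(d_base, basics)
    }
  }

  list(X = X, X_dbt = X_dbt, A = A, reference = reference, basics = basics,
       dbt_params = param_names,
       df_inconsistency = as.integer(length(param_names) - length(basics)))
}
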