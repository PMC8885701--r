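#' Construct and validate a cohort
#'
#' A cohort is a tibble holding one row per individual: an identifier, a
#' discrete subpopulation label, a binary outcome and numeric feature
#' columns. The declared group vocabulary (either supplied or the sorted
#' unique labels) fixes the ordering used everywhere downstream — DRO group
#' weights, additive adjustments and evaluation reports all index
#' subpopulations in vocabulary order.
#'
#' @param data A data frame.
#' @param id_col,group_col,outcome_col Names of the identifier, subpopulation
#'   and outcome columns. Defaults `"id"`, `"group"`, `"outcome"`.
#' @param feature_cols Character vector of feature column names, or `NULL`
#'   to use every remaining column.
#' @param group_levels Optional character vector declaring the group
#'   vocabulary (and its order). Defaults to the sorted unique labels.
#' @param require_nonempty_groups If `TRUE` (default), every vocabulary entry
#'   must have at least one member — appropriate for full training cohorts;
#'   set `FALSE` for sub-cohorts (e.g. a single fold).
#' @return A `cohort` tibble with canonical columns `id`, `group`, `outcome`
#'   followed by the feature columns; attributes `feature_cols` and
#'   `group_levels` record the schema.
#' @examples
#' df <- data.frame(id = 1:4, group = c("a", "a", "b", "b"),
#'                  outcome = c(1, 0, 0, 0), x1 = rnorm(4), x2 = rnorm(4))
#' as_cohort(df)
#' @export
as_cohort <- function(data, id_col = "id", group_col = "group",
                      outcome_col = "outcome", feature_cols = NULL,
                      group_levels = NULL, require_nonempty_groups = TRUE) {
  stopifnot(is.data.frame(data))
  for (col in c(id_col, group_col, outcome_col)) {
    if (!col %in% names(data)) {
      abort(paste0("schema error: column '", col, "' not found"),
            class = "groupdro_schema_error")
    }
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(data), c(id_col, group_col, outcome_col))
  }
  missing_feat <- setdiff(feature_cols, names(data))
  if (length(missing_feat) > 0) {
    abort(paste0("schema error: feature column(s) not found: ",
                 paste(missing_feat, collapse = ", ")),
          class = "groupdro_schema_error")
  }
  if (length(feature_cols) < 1) {
    abort("schema error: no feature columns", class = "groupdro_schema_error")
  }
  if (nrow(data) < 1) abort("cohort must contain at least one row")

  ids <- as.character(data[[id_col]])
  if (anyDuplicated(ids)) abort("validation error: duplicate ids")
  groups <- as.character(data[[group_col]])
  outcome <- data[[outcome_col]]
  if (!all(outcome %in% c(0, 1))) {
    abort("validation error: outcome values must be 0 or 1",
          class = "groupdro_validation_error")
  }
  feats <- lapply(data[feature_cols], function(x) as.numeric(x))
  if (any(vapply(feats, anyNA, logical(1)))) {
    abort("validation error: NaN/NA in feature columns (impute upstream)",
          class = "groupdro_validation_error")
  }
  if (is.null(group_levels)) {
    group_levels <- sort(unique(groups))
  } else {
    group_levels <- as.character(group_levels)
    group_codes(groups, group_levels)  # errors on stray labels
    if (require_nonempty_groups) {
      empty <- setdiff(group_levels, unique(groups))
      if (length(empty) > 0) {
        abort(paste0("validation error: empty group(s) in full cohort: ",
                     paste(empty, collapse = ", ")),
              class = "groupdro_validation_error")
      }
    }
  }
  out <- tibble::tibble(id = ids, group = groups,
                        outcome = as.integer(outcome))
  out <- dplyr::bind_cols(out, tibble::as_tibble(feats))
  new_cohort(out, feature_cols, group_levels)
}

new_cohort <- function(tbl, feature_cols, group_levels) {
  structure(tibble::as_tibble(as.data.frame(tbl)),
            feature_cols = feature_cols,
            group_levels = group_levels,
            class = c("cohort", "tbl_df", "tbl", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> N =", nrow(x), " K =", length(group_levels(x)),
      " m =", length(feature_cols(x)), "\n")
  NextMethod()
}

restore_cohort <- function(out, template) {
  needed <- c("id", "group", "outcome", feature_cols(template))
  if (is.data.frame(out) && all(needed %in% names(out))) {
    new_cohort(out, feature_cols(template), group_levels(template))
  } else if (is.data.frame(out)) {
    # column subsets that break the schema degrade to a plain tibble
    tibble::as_tibble(as.data.frame(out))
  } else {
    out
  }
}

#' @export
`[.cohort` <- function(x, ...) {
  restore_cohort(NextMethod(), x)
}

#' @importFrom dplyr dplyr_reconstruct
#' @export
dplyr_reconstruct.cohort <- function(data, template) {
  restore_cohort(data, template)
}

#' Schema accessors for a cohort
#'
#' @param cohort A [as_cohort()] tibble.
#' @return `feature_cols()` the feature column names; `group_levels()` the
#'   declared group vocabulary in its canonical order; `feature_matrix()` the
#'   N x m numeric feature matrix.
#' @export
feature_cols <- function(cohort) attr(cohort, "feature_cols")

#' @rdname feature_cols
#' @export
group_levels <- function(cohort) attr(cohort, "group_levels")

#' @rdname feature_cols
#' @export
feature_matrix <- function(cohort) {
  as.matrix(as.data.frame(cohort)[, feature_cols(cohort), drop = FALSE])
}

# subset rows of a cohort, keeping schema; vocabulary is retained so that
# sub-cohorts (folds, groups) stay index-compatible with the full cohort
cohort_slice <- function(cohort, idx) {
  tbl <- tibble::as_tibble(as.data.frame(cohort)[idx, , drop = FALSE])
  new_cohort(tbl, feature_cols(cohort), group_levels(cohort))
}

#' Read a cohort from a delimited file
#'
#' Expects a CSV with a header row; the schema maps column roles. Feature
#' columns are coerced to numeric; the group vocabulary is taken from the
#' schema when given, otherwise inferred as the sorted unique labels.
#'
#' @param path Path to a CSV file.
#' @param schema Named list with entries `id_col`, `group_col`, `outcome_col`,
#'   `feature_cols` (character vector or `"rest"`), and optional
#'   `group_vocabulary`. Missing entries fall back to the defaults of
#'   [as_cohort()].
#' @inheritParams as_cohort
#' @return A validated `cohort` tibble.
#' @export
read_cohort <- function(path, schema = list(),
                        require_nonempty_groups = TRUE) {
  stopifnot(file.exists(path))
  # base strtod parsing is correctly rounded, so text round trips bit-exactly
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  fc <- schema$feature_cols
  if (!is.null(fc) && identical(fc, "rest")) fc <- NULL
  as_cohort(raw,
            id_col = schema$id_col %||% "id",
            group_col = schema$group_col %||% "group",
            outcome_col = schema$outcome_col %||% "outcome",
            feature_cols = fc,
            group_levels = schema$group_vocabulary,
            require_nonempty_groups = require_nonempty_groups)
}

#' Write a cohort to CSV
#'
#' Doubles are written with full round-trip precision so that
#' `read_cohort(write_cohort(x))` reproduces `x` bit-exactly.
#'
#' @param cohort A cohort.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  tbl <- tibble::as_tibble(as.data.frame(cohort))
  # %.17g guarantees exact double round trip through text
  for (col in feature_cols(cohort)) {
    tbl[[col]] <- sprintf("%.17g", tbl[[col]])
  }
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Per-subpopulation summary statistics
#'
#' Sizes \eqn{n_k}, relative sizes \eqn{p_k = n_k / N} and outcome incidences
#' per declared group, in vocabulary order. These feed the size-based DRO
#' adjustments (reciprocal `C / p_k`, proportional `C * sqrt(n_k / N)`) and
#' the precomputed marginal-entropy baseline.
#'
#' @param cohort A cohort.
#' @return A tibble with columns `group`, `n`, `fraction`, `incidence`
#'   (incidence is `NA` for an empty group).
#' @export
group_summary <- function(cohort) {
  lv <- group_levels(cohort)
  codes <- group_codes(cohort$group, lv)
  n <- tabulate(codes, nbins = length(lv))
  pos <- vapply(seq_along(lv),
                function(k) sum(cohort$outcome[codes == k]), numeric(1))
  tibble::tibble(
    group = lv,
    n = n,
    fraction = n / nrow(cohort),
    incidence = ifelse(n > 0, pos / pmax(n, 1), NA_real_)
  )
}
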