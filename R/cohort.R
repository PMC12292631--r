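#' Construct a cohort table
#'
#' The universal currency of the pipeline: a numeric feature matrix whose
#' columns follow the schema order, a binary label vector (1 = case /
#' minority, 0 = control) and a per-row provenance flag distinguishing real
#' from generated rows.
#'
#' @param schema A `feature_schema`.
#' @param values Numeric matrix, one column per schema feature (categoricals
#'   integer-coded).
#' @param labels Binary vector (`0`/`1`), one per row.
#' @param provenance Character vector of `"real"`/`"synthetic"`, recycled if
#'   length 1. Defaults to `"real"`.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(schema, values, labels, provenance = "real") {
  stopifnot(inherits(schema, "feature_schema"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != nrow(schema$features)) {
    stop("value matrix has ", ncol(values), " columns but schema declares ",
         nrow(schema$features), " features", call. = FALSE)
  }
  colnames(values) <- schema$features$name
  labels <- as.integer(labels)
  if (length(labels) != nrow(values)) {
    stop("labels length does not match row count", call. = FALSE)
  }
  if (length(labels) && !all(labels %in% c(0L, 1L))) {
    bad <- which(!labels %in% c(0L, 1L))[1]
    stop("non-binary label at row ", bad, call. = FALSE)
  }
  if (length(provenance) == 1) provenance <- rep(provenance, nrow(values))
  if (!all(provenance %in% c("real", "synthetic"))) {
    stop("provenance must be 'real' or 'synthetic'", call. = FALSE)
  }
  structure(list(schema = schema, values = values, labels = labels,
                 provenance = provenance),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cr <- class_ratio(x)
  cat("<cohort_table> ", nrow(x$values), " rows x ", ncol(x$values),
      " features; ", cr$n_pos, " pos / ", cr$n_neg, " neg",
      if (!cr$undefined) sprintf(" (1:%.1f)", cr$neg_per_pos) else "",
      "; ", sum(x$provenance == "synthetic"), " synthetic\n", sep = "")
  invisible(x)
}

#' Number of rows in a cohort table
#' @param table A `cohort_table`.
#' @return Integer row count.
#' @export
n_rows <- function(table) nrow(table$values)

#' Subset rows of a cohort table
#' @param table A `cohort_table`.
#' @param idx Integer or logical row index.
#' @return A `cohort_table` with the selected rows, order preserved.
#' @export
cohort_subset <- function(table, idx) {
  cohort_table(table$schema, table$values[idx, , drop = FALSE],
               table$labels[idx], table$provenance[idx])
}

#' Row-bind two cohort tables sharing a schema
#' @param a,b `cohort_table` objects with identical schemas.
#' @return Combined `cohort_table` (rows of `a` first).
#' @export
cohort_rbind <- function(a, b) {
  if (!identical(a$schema$features$name, b$schema$features$name)) {
    stop("schemas do not match", call. = FALSE)
  }
  cohort_table(a$schema, rbind(a$values, b$values),
               c(a$labels, b$labels), c(a$provenance, b$provenance))
}

#' Read a cohort from delimited text
#'
#' Expects a comma-delimited UTF-8 file with a header row containing every
#' schema feature and the label column; an optional `provenance` column
#' (values `real`/`synthetic`) is honoured. Extra columns are ignored.
#' Missing values are rejected unless `impute_median = TRUE`, in which case
#' each feature's median fills its gaps.
#'
#' @param path Path to a CSV file.
#' @param schema A `feature_schema`.
#' @param impute_median Impute missing feature values with per-column
#'   medians instead of failing. Default `FALSE`.
#' @return A `cohort_table` with rows in file order.
#' @export
read_cohort <- function(path, schema, impute_median = FALSE) {
  stopifnot(inherits(schema, "feature_schema"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(schema$features$name, schema$label_name)
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("column(s) missing from ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lab <- df[[schema$label_name]]
  bad <- which(!(lab %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary label value '", lab[bad[1]], "' at row ", bad[1],
         call. = FALSE)
  }
  vals <- as.matrix(df[, schema$features$name, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    if (!impute_median) {
      nab <- which(rowSums(is.na(vals)) > 0)[1]
      stop("missing feature value at row ", nab,
           " (set impute_median = TRUE to impute)", call. = FALSE)
    }
    for (j in seq_len(ncol(vals))) {
      nj <- is.na(vals[, j])
      if (any(nj)) vals[nj, j] <- stats::median(vals[!nj, j])
    }
  }
  prov <- if ("provenance" %in% names(df)) as.character(df$provenance) else "real"
  cohort_table(schema, vals, as.integer(lab), prov)
}

#' Write a cohort to delimited text
#'
#' Emits a CSV whose columns are the schema features in order, then the
#' label. A `provenance` column is appended only when at least one row is
#' synthetic, so purely real cohorts round-trip through files produced by
#' other tools. [read_cohort()] inverts this writer.
#'
#' @param table A `cohort_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  df <- as.data.frame(table$values)
  df[[table$schema$label_name]] <- table$labels
  if (any(table$provenance == "synthetic")) df$provenance <- table$provenance
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits each class separately so the class ratio is preserved as closely
#' as integer rounding allows; the per-class test count is the ceiling of
#' `test_fraction` times the class size (this is the rounding that maps a
#' 1,142/73,499 cohort at 0.2 onto a 229/14,700 test set). Deterministic for
#' a fixed seed.
#'
#' @param table A `cohort_table` with both classes present.
#' @param test_fraction Proportion in (0, 1) assigned to the test set.
#' @param seed Integer seed.
#' @return A list with `cohort_table` elements `train` and `test`.
#' @export
split_cohort <- function(table, test_fraction, seed) {
  stopifnot(inherits(table, "cohort_table"),
            test_fraction > 0, test_fraction < 1)
  for (cls in c(0L, 1L)) {
    if (sum(table$labels == cls) < 2) {
      stop("class ", cls, " has fewer than 2 rows; cannot stratify",
           call. = FALSE)
    }
  }
  test_idx <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(cls) {
      rows <- which(table$labels == cls)
      n_test <- min(length(rows) - 1L, ceiling(test_fraction * length(rows)))
      sample(rows, n_test)
    }))
  })
  test_idx <- sort(test_idx)
  list(train = cohort_subset(table, setdiff(seq_len(n_rows(table)), test_idx)),
       test = cohort_subset(table, test_idx))
}

#' Class counts and imbalance ratio
#'
#' @param table A non-empty `cohort_table`.
#' @return A list with `n_pos`, `n_neg`, `neg_per_pos` (negatives per
#'   positive, `NA` when there are no positives) and the flag `undefined`.
#' @export
class_ratio <- function(table) {
  stopifnot(inherits(table, "cohort_table"), n_rows(table) >= 1)
  n_pos <- sum(table$labels == 1L)
  n_neg <- sum(table$labels == 0L)
  list(n_pos = n_pos, n_neg = n_neg,
       neg_per_pos = if (n_pos > 0) n_neg / n_pos else NA_real_,
       undefined = n_pos == 0)
}
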