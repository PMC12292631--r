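#' Declare a feature schema for a screening cohort
#'
#' A schema fixes the ordered feature set of a cohort: each feature has a
#' name, a category (`demographic`, `blood`, `urine`) and a storage dtype
#' (`continuous`, `count`, `categorical`). The binary outcome column is named
#' separately and is never part of the feature list.
#'
#' @param features A data.frame with columns `name`, `category`, `dtype`.
#' @param label_name Name of the binary label column.
#' @return An object of class `feature_schema`.
#' @seealso [kd_schema()] for the bundled 22-feature panel.
#' @export
feature_schema <- function(features, label_name = "label") {
  stopifnot(is.data.frame(features),
            all(c("name", "category", "dtype") %in% names(features)))
  features$name <- as.character(features$name)
  features$category <- as.character(features$category)
  features$dtype <- as.character(features$dtype)
  if (anyDuplicated(features$name)) {
    stop("feature names must be unique", call. = FALSE)
  }
  bad <- setdiff(features$category, c("demographic", "blood", "urine"))
  if (length(bad)) stop("unknown feature category: ", bad[1], call. = FALSE)
  bad <- setdiff(features$dtype, c("continuous", "count", "categorical"))
  if (length(bad)) stop("unknown feature dtype: ", bad[1], call. = FALSE)
  if (label_name %in% features$name) {
    stop("label column '", label_name, "' must not appear among features",
         call. = FALSE)
  }
  structure(list(features = features[, c("name", "category", "dtype")],
                 label_name = label_name),
            class = "feature_schema")
}

#' The bundled Kawasaki-disease screening panel
#'
#' 22 routine clinical features in three groups: 3 demographic (sex, age,
#' month of visit), 17 blood-test parameters (counts, differentials, liver
#' enzymes, C-reactive protein) and 2 urinalysis indicators (urinary white
#' blood cells and pyuria). Sex, month of visit and pyuria are
#' integer-coded categoricals; cell counts are `count`-typed; the rest are
#' continuous laboratory values.
#'
#' @return A `feature_schema` with 22 features and label column `"KD"`.
#' @export
kd_schema <- function() {
  feats <- rbind(
    data.frame(name = c("Sex", "Age", "MonthOfVisit"),
               category = "demographic",
               dtype = c("categorical", "continuous", "categorical")),
    data.frame(name = c("WBC", "RBC", "Hemoglobin", "Hematocrit", "Platelet",
                        "CRP", "AST", "ALT", "Band", "Segment", "Lymphocyte",
                        "Monocyte", "Eosinophil", "Basophil", "MCV", "MCH",
                        "MCHC"),
               category = "blood",
               dtype = c("count", "continuous", "continuous", "continuous",
                         "count", "continuous", "continuous", "continuous",
                         "count", "continuous", "continuous", "continuous",
                         "continuous", "continuous", "continuous",
                         "continuous", "continuous")),
    data.frame(name = c("UWBC", "Pyuria"),
               category = "urine",
               dtype = c("count", "categorical"))
  )
  feature_schema(feats, label_name = "KD")
}

#' @export
print.feature_schema <- function(x, ...) {
  tab <- table(factor(x$features$category,
                      levels = c("demographic", "blood", "urine")))
  cat("<feature_schema> ", nrow(x$features), " features (",
      paste(names(tab), tab, sep = ": ", collapse = ", "),
      "), label '", x$label_name, "'\n", sep = "")
  invisible(x)
}

#' Write or read a schema sidecar as JSON
#'
#' @param schema A `feature_schema`.
#' @param path File path for the JSON sidecar.
#' @return `write_schema` returns `path` invisibly; `read_schema` returns a
#'   `feature_schema`.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(list(features = schema$features,
                            label_name = schema$label_name),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feature_schema(as.data.frame(x$features), label_name = x$label_name)
}
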