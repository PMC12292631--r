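# Synthetic minority augmentation: size the synthetic batch so that the
# class ratio reaches a target (default 1:24), generate it from a backend
# fitted on the minority rows only, and merge it back into the cohort.

#' Size a synthetic minority batch for a target class ratio
#'
#' The required batch size is
#' `n_aug = max(0, round_rule(n_major / r_target) - n_minor)`, so
#' `n_minor + n_aug` positives against `n_major` negatives lands on the
#' target ratio up to the rounding rule. With the default ceiling rule and
#' (52,454 negatives, 913 positives, target 24) the plan asks for 1,273
#' synthetic rows, i.e. 2,186 final positives.
#'
#' @param n_major Number of majority-class (negative) rows.
#' @param n_minor Number of minority-class (positive) rows.
#' @param r_target Target negatives-per-positive ratio (default 24).
#' @param rounding `"ceil"` (default), `"nearest"` or `"floor"`.
#' @return An object of class `augmentation_plan` with fields `n_major`,
#'   `n_minor`, `r_target`, `rounding`, `n_aug` and `n_final_minor`.
#' @export
augmentation_count <- function(n_major, n_minor, r_target = 24,
                               rounding = c("ceil", "nearest", "floor")) {
  rounding <- match.arg(rounding)
  stopifnot(n_major >= 0, n_minor >= 0, r_target > 0)
  rounder <- switch(rounding, ceil = ceiling, nearest = round, floor = floor)
  target_minor <- as.integer(rounder(n_major / r_target))
  n_aug <- max(0L, target_minor - as.integer(n_minor))
  structure(list(n_major = as.integer(n_major), n_minor = as.integer(n_minor),
                 r_target = r_target, rounding = rounding, n_aug = n_aug,
                 n_final_minor = as.integer(n_minor) + n_aug),
            class = "augmentation_plan")
}

#' @export
print.augmentation_plan <- function(x, ...) {
  cat("<augmentation_plan> ", x$n_minor, " + ", x$n_aug, " synthetic = ",
      x$n_final_minor, " positives vs ", x$n_major,
      " negatives (target 1:", x$r_target, ", ", x$rounding, ")\n", sep = "")
  invisible(x)
}

#' Generator backend configuration
#'
#' Two self-contained reference backends are implemented: `"kde"` (product
#' Gaussian kernel with per-feature Scott-rule bandwidths; categorical
#' features resampled independently from their empirical distribution) and
#' `"gaussian_copula"` (rank-based Gaussian copula over empirical
#' marginals). `"ctgan"` and `"ganblr"` are recognised adapter names whose
#' implementations are external; requesting them without an installed
#' adapter raises an explicit capability error rather than silently falling
#' back.
#'
#' @param backend One of `"kde"`, `"gaussian_copula"`, `"ctgan"`, `"ganblr"`.
#' @param bandwidth_factor Multiplier on the Scott-rule bandwidths of the
#'   KDE backend (default 1).
#' @param seed Integer seed used by [sample_synthetic()] unless overridden.
#' @return An object of class `generator_backend_config`.
#' @export
backend_config <- function(backend = c("kde", "gaussian_copula", "ctgan", "ganblr"),
                           bandwidth_factor = 1, seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(bandwidth_factor > 0)
  structure(list(backend = backend, bandwidth_factor = bandwidth_factor,
                 seed = as.integer(seed)),
            class = "generator_backend_config")
}

#' Fit a synthetic-minority generator
#'
#' Fits the configured backend on the minority rows of a cohort (all labels
#' must be 1). The KDE backend records the fitting matrix and per-feature
#' univariate Scott-rule bandwidths `sigma_j * n^(-1/5)` (product kernel on
#' the numeric features); sampling draws a training row uniformly and perturbs its
#' numeric features with Gaussian noise of those bandwidths. The Gaussian
#' copula backend records rank-based normal scores, their correlation, and
#' the empirical marginals it inverts through.
#'
#' @param minority A non-empty `cohort_table` whose labels are all 1.
#' @param config A `generator_backend_config`.
#' @return A generator handle of class `synth_generator`.
#' @export
fit_backend <- function(minority, config = backend_config()) {
  stopifnot(inherits(minority, "cohort_table"),
            inherits(config, "generator_backend_config"))
  if (n_rows(minority) == 0) stop("minority table is empty", call. = FALSE)
  if (!all(minority$labels == 1L)) {
    stop("fit_backend expects minority rows only (all labels 1)", call. = FALSE)
  }
  if (config$backend %in% c("ctgan", "ganblr")) {
    stop("backend '", config$backend, "' requires an external adapter that ",
         "is not installed; use 'kde' or 'gaussian_copula'", call. = FALSE)
  }
  X <- minority$values
  dtypes <- minority$schema$features$dtype
  numeric_cols <- which(dtypes != "categorical")
  cat_cols <- which(dtypes == "categorical")
  fingerprint <- rlang::hash(list(X, minority$labels))
  fit <- if (config$backend == "kde") {
    n <- nrow(X)
    bw <- rep(0, ncol(X))
    if (length(numeric_cols) > 0) {
      sds <- apply(X[, numeric_cols, drop = FALSE], 2, stats::sd)
      sds[!is.finite(sds) | sds == 0] <- 0
      # univariate Scott rule applied feature-wise (product kernel)
      bw[numeric_cols] <- sds * n^(-1 / 5) * config$bandwidth_factor
    }
    cat_tabs <- lapply(cat_cols, function(j) table(X[, j]) / n)
    list(X = X, bandwidth = bw, cat_tabs = cat_tabs)
  } else {
    n <- nrow(X)
    Z <- matrix(0, n, ncol(X))
    for (j in seq_len(ncol(X))) {
      r <- rank(X[, j], ties.method = "average")
      Z[, j] <- stats::qnorm(r / (n + 1))
    }
    R <- stats::cor(Z)
    R[!is.finite(R)] <- 0; diag(R) <- 1
    # jitter to positive definiteness if needed
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-8) {
      R <- R + diag(1e-6 - min(ev, 0), ncol(R))
      R <- stats::cov2cor(R)
    }
    list(X = X, chol = chol(R))
  }
  structure(list(backend = config$backend, config = config, fit = fit,
                 schema = minority$schema, numeric_cols = numeric_cols,
                 cat_cols = cat_cols, source_fingerprint = fingerprint),
            class = "synth_generator")
}

#' Draw a synthetic minority batch
#'
#' Samples exactly `n` rows from a fitted generator. Count-typed features
#' are rounded to the nearest non-negative integer; categorical features
#' are snapped to the category set observed in the fitting data. All rows
#' carry provenance `"synthetic"` and label 1.
#'
#' @param generator A `synth_generator` from [fit_backend()].
#' @param n Number of rows to draw (`>= 0`).
#' @param seed Integer seed; defaults to the backend config seed.
#' @return A list of class `synthetic_batch` with fields `rows` (matrix),
#'   `backend` and `source_fingerprint`; convert with
#'   [synthetic_batch_to_cohort()].
#' @export
sample_synthetic <- function(generator, n, seed = NULL) {
  stopifnot(inherits(generator, "synth_generator"))
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  seed <- seed %||% generator$config$seed
  p <- ncol(generator$fit$X)
  dtypes <- generator$schema$features$dtype
  rows <- with_seed(seed, {
    if (n == 0) {
      matrix(0, 0, p)
    } else if (generator$backend == "kde") {
      X <- generator$fit$X
      pick <- sample.int(nrow(X), n, replace = TRUE)
      out <- X[pick, , drop = FALSE]
      for (j in generator$numeric_cols) {
        out[, j] <- out[, j] + stats::rnorm(n, sd = generator$fit$bandwidth[j])
      }
      for (idx in seq_along(generator$cat_cols)) {
        j <- generator$cat_cols[idx]
        tab <- generator$fit$cat_tabs[[idx]]
        out[, j] <- as.numeric(sample(names(tab), n, replace = TRUE,
                                      prob = as.numeric(tab)))
      }
      out
    } else {
      X <- generator$fit$X
      Z <- matrix(stats::rnorm(n * p), n, p) %*% generator$fit$chol
      U <- stats::pnorm(Z)
      out <- matrix(0, n, p)
      for (j in seq_len(p)) {
        out[, j] <- stats::quantile(X[, j], probs = U[, j], type = 8,
                                    names = FALSE)
      }
      out
    }
  })
  if (n > 0) {
    for (j in which(dtypes == "count")) rows[, j] <- pmax(0, round(rows[, j]))
    for (j in which(dtypes == "categorical")) {
      obs <- sort(unique(generator$fit$X[, j]))
      rows[, j] <- vapply(rows[, j], function(v) obs[which.min(abs(obs - v))],
                          numeric(1))
    }
  }
  colnames(rows) <- generator$schema$features$name
  structure(list(rows = rows, backend = generator$backend,
                 source_fingerprint = generator$source_fingerprint),
            class = "synthetic_batch")
}

#' Convert a synthetic batch into a cohort table
#'
#' @param batch A `synthetic_batch`.
#' @param schema The `feature_schema` it was generated under.
#' @return A `cohort_table` of all-positive, all-synthetic rows.
#' @export
synthetic_batch_to_cohort <- function(batch, schema) {
  cohort_table(schema, batch$rows, rep(1L, nrow(batch$rows)),
               provenance = "synthetic")
}

#' Balance a cohort to a target class ratio via augmentation
#'
#' Sizes the synthetic batch with [augmentation_count()], fits the backend
#' on the real minority rows, samples the batch and appends it. Negatives
#' are never generated, deleted or modified; real rows pass through
#' untouched. If the cohort already meets the target ratio the input is
#' returned unchanged.
#'
#' @param table A `cohort_table` with both classes present.
#' @param r_target Target negatives-per-positive ratio (default 24).
#' @param backend A `generator_backend_config`.
#' @param rounding Rounding rule for the plan (default `"ceil"`).
#' @param seed Optional sampling seed (defaults to the backend seed).
#' @return A list with `table` (the balanced `cohort_table`) and `plan`
#'   (the `augmentation_plan`).
#' @export
balance_cohort <- function(table, r_target = 24, backend = backend_config(),
                           rounding = "ceil", seed = NULL) {
  stopifnot(inherits(table, "cohort_table"))
  cr <- class_ratio(table)
  if (cr$n_pos == 0 || cr$n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  plan <- augmentation_count(cr$n_neg, cr$n_pos, r_target, rounding)
  if (plan$n_aug == 0) return(list(table = table, plan = plan))
  minority <- cohort_subset(table, table$labels == 1L &
                              table$provenance == "real")
  gen <- fit_backend(minority, backend)
  batch <- sample_synthetic(gen, plan$n_aug, seed = seed)
  out <- cohort_rbind(table, synthetic_batch_to_cohort(batch, table$schema))
  list(table = out, plan = plan)
}
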