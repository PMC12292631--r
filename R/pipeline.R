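# Orchestration of the full screening pipeline: ingest/simulate -> cluster
# -> filter -> augment -> audit -> train -> evaluate, with deterministic
# per-stage seeds derived from one top-level seed and an artifact manifest.

#' Pipeline configuration
#'
#' @param train Training input: a `cohort_table`, a `cohort_sim_config`, or
#'   a CSV path (read with `schema`).
#' @param test Internal evaluation input (same forms); optional.
#' @param external External-institution evaluation input; optional.
#' @param schema Schema used when inputs are CSV paths (default
#'   [kd_schema()]).
#' @param clustering A `clustering_config` for the undersampling stage.
#' @param policy A `filter_policy`.
#' @param undersampler `"cbu"` (default) or `"random"` (the RUS baseline).
#' @param rus_ratio Negatives-per-positive ratio for the RUS baseline
#'   (default 59, the typical post-filter ratio of the CBU stage).
#' @param r_target Target ratio for augmentation (default 24).
#' @param backend A `generator_backend_config`.
#' @param stacking A `stacking_config`.
#' @param recall_targets Recall targets for the evaluation sweep.
#' @param fidelity_bins Binning for the fidelity audit.
#' @param seed Top-level integer seed; every stochastic stage derives its
#'   own seed from it via [derive_seed()].
#' @param output_dir Optional directory for stage artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(train, test = NULL, external = NULL,
                            schema = kd_schema(),
                            clustering = clustering_config(),
                            policy = filter_policy(),
                            undersampler = c("cbu", "random"),
                            rus_ratio = 59,
                            r_target = 24,
                            backend = backend_config(),
                            stacking = stacking_config(),
                            recall_targets = c(0.80, 0.85, 0.90, 0.95),
                            fidelity_bins = 64,
                            seed = 1L,
                            output_dir = NULL) {
  undersampler <- match.arg(undersampler)
  structure(list(train = train, test = test, external = external,
                 schema = schema, clustering = clustering, policy = policy,
                 undersampler = undersampler, rus_ratio = rus_ratio,
                 r_target = r_target, backend = backend, stacking = stacking,
                 recall_targets = recall_targets,
                 fidelity_bins = fidelity_bins,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

resolve_cohort <- function(x, schema) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "cohort_table")) return(x)
  if (inherits(x, "cohort_sim_config")) return(simulate_cohort(x))
  if (is.character(x)) return(read_cohort(x, schema))
  stop("cannot interpret cohort input of class ", class(x)[1], call. = FALSE)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full screening pipeline
#'
#' Executes the stages in order — ingest, clustering-based (or random)
#' undersampling, minority augmentation to the target ratio, fidelity
#' audit, stacking-ensemble training, fixed-recall evaluation — and
#' returns a manifest of stage seeds, row counts, input hashes and
#' results. When `output_dir` is set, per-stage artifacts (filtered and
#' balanced cohorts as CSV, fidelity report and manifest as JSON, metrics
#' tables as CSV) are written as each stage completes, so artifacts from
#' stages preceding a failure persist. Rerunning an identical config
#' reproduces identical artifacts.
#'
#' @param config A `pipeline_config`.
#' @return A list of class `pipeline_result`: `manifest`, `filtered`,
#'   `balanced`, `cluster_summary` (CBU only), `fidelity`, `model`,
#'   `metrics_test`, `metrics_external`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  seeds <- list(cluster = derive_seed(config$seed, "cluster"),
                undersample = derive_seed(config$seed, "undersample"),
                augment = derive_seed(config$seed, "augment"),
                stacking = derive_seed(config$seed, "stacking"))

  train <- run_stage("ingest", resolve_cohort(config$train, config$schema))
  test <- run_stage("ingest", resolve_cohort(config$test, config$schema))
  external <- run_stage("ingest", resolve_cohort(config$external, config$schema))

  cluster_summary <- NULL
  if (config$undersampler == "cbu") {
    cl_cfg <- config$clustering
    cl_cfg$seed <- seeds$cluster
    assignment <- run_stage("cluster", assign_clusters(train, cl_cfg))
    cluster_summary <- summarize_clusters(assignment, train$labels)
    filtered <- run_stage("filter",
                          filter_clusters(train, assignment, config$policy))
  } else {
    filtered <- run_stage("undersample",
                          random_undersample(train, config$rus_ratio,
                                             seeds$undersample))
  }
  emit("filtered.csv", function(p) write_cohort(filtered, p))

  be <- config$backend
  bal <- run_stage("augment",
                   balance_cohort(filtered, config$r_target, be,
                                  seed = seeds$augment))
  balanced <- bal$table
  emit("balanced.csv", function(p) write_cohort(balanced, p))

  fid <- run_stage("fidelity",
                   fidelity_report(filtered, balanced, backend = be$backend,
                                   bins = config$fidelity_bins))
  emit("fidelity.json", function(p) {
    jsonlite::write_json(list(backend = fid$backend, mmd = fid$mmd,
                              pcd = fid$pcd, per_feature = fid$per_feature),
                         p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  })

  st_cfg <- config$stacking
  st_cfg$seed <- seeds$stacking
  model <- run_stage("train", train_stacking(balanced, st_cfg))

  metrics_test <- NULL
  if (!is.null(test)) {
    metrics_test <- run_stage("evaluate",
                              recall_sweep(model, test, config$recall_targets))
    emit("metrics_test.csv", function(p) {
      utils::write.csv(metrics_test, p, row.names = FALSE)
    })
  }
  metrics_external <- NULL
  if (!is.null(external)) {
    metrics_external <- run_stage("evaluate",
                                  recall_sweep(model, external,
                                               config$recall_targets))
    emit("metrics_external.csv", function(p) {
      utils::write.csv(metrics_external, p, row.names = FALSE)
    })
  }

  manifest <- list(
    seed = config$seed, stage_seeds = seeds,
    undersampler = config$undersampler, backend = config$backend$backend,
    r_target = config$r_target,
    input_hash = rlang::hash(list(train$values, train$labels)),
    rows = list(train = n_rows(train),
                filtered = n_rows(filtered),
                balanced = n_rows(balanced),
                synthetic = sum(balanced$provenance == "synthetic"),
                test = if (is.null(test)) 0L else n_rows(test),
                external = if (is.null(external)) 0L else n_rows(external)),
    artifacts = c("filtered.csv", "balanced.csv", "fidelity.json",
                  if (!is.null(test)) "metrics_test.csv",
                  if (!is.null(external)) "metrics_external.csv"))
  emit("manifest.json", function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
  })

  structure(list(manifest = manifest, filtered = filtered,
                 balanced = balanced, cluster_summary = cluster_summary,
                 fidelity = fid, model = model, plan = bal$plan,
                 metrics_test = metrics_test,
                 metrics_external = metrics_external),
            class = "pipeline_result")
}

#' Ablate one pipeline axis
#'
#' Runs the pipeline once per axis value with everything else fixed,
#' repeated over `n_seeds` derived seeds (stochastic pipelines compared on
#' single runs are noise-dominated), and returns a long-format comparison
#' table of the evaluation metrics at `target_recall`.
#'
#' @param config A `pipeline_config` (its `test` input is required).
#' @param axis One of `"undersampler"`, `"metric"`, `"backend"`, `"ratio"`.
#' @param values Axis values (e.g. `c(59, 24, 10, 4, 1)` for `"ratio"`).
#' @param n_seeds Number of replicate seeds (default 5).
#' @param target_recall Operating point for the comparison (default 0.9).
#' @return A data.frame with columns `axis`, `value`, `seed`, `recall`,
#'   `precision`, `specificity`, `f1`, `f2`.
#' @export
run_ablation <- function(config, axis = c("undersampler", "metric", "backend", "ratio"),
                         values, n_seeds = 5, target_recall = 0.9) {
  axis <- match.arg(axis)
  stopifnot(inherits(config, "pipeline_config"), length(values) >= 1)
  config$output_dir <- NULL
  config$recall_targets <- target_recall
  rows <- list()
  for (v in values) {
    cfg <- config
    if (axis == "undersampler") {
      cfg$undersampler <- match.arg(as.character(v), c("cbu", "random"))
    } else if (axis == "metric") {
      cfg$clustering$metric <- match.arg(as.character(v),
                                         c("euclidean", "manhattan", "cosine"))
    } else if (axis == "backend") {
      cfg$backend$backend <- match.arg(as.character(v),
                                       c("kde", "gaussian_copula", "ctgan", "ganblr"))
    } else {
      cfg$r_target <- as.numeric(v)
    }
    for (s in seq_len(n_seeds)) {
      cfg$seed <- derive_seed(config$seed, paste0("ablate-", v, "-", s))
      res <- run_pipeline(cfg)
      m <- res$metrics_test[1, ]
      rows[[length(rows) + 1]] <- data.frame(
        axis = axis, value = as.character(v), seed = cfg$seed,
        recall = m$recall, precision = m$precision,
        specificity = m$specificity, f1 = m$f1, f2 = m$f2)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
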