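#' Pipeline configuration
#'
#' Validated settings for [run_pipeline()].  Every random draw in the
#' pipeline flows from the single `seed`, so the same configuration yields
#' an identical report.
#'
#' @param cohort a [cohort_spec()] describing the synthetic cohort, or
#'   `NULL` when `input_dir` points at a cohort written by [write_cohort()].
#' @param input_dir optional directory with a `manifest.json` cohort.
#' @param n_train number of normal samples used for training; remaining
#'   normals and all abnormals form the test set.
#' @param ranks GND-PCA per-mode ranks.
#' @param grid_dims FFD control intervals for shape normalization.
#' @param normalize logical: apply 3D shape normalization before modeling?
#' @param rigid logical: include the global rigid stage (disable for
#'   cohorts already position-normalized upstream).
#' @param registration a [registration_config()].
#' @param max_iter,tol GND-PCA iteration controls.
#' @param seed integer seed overriding `cohort$seed` (optional).
#' @param out_dir optional output directory for model, classifier, report
#'   and log files.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), input_dir = NULL,
                            n_train = 15L, ranks = c(24L, 24L, 16L),
                            grid_dims = c(6L, 6L, 3L), normalize = TRUE,
                            rigid = FALSE,
                            registration = registration_config(),
                            max_iter = 50L, tol = 1e-6, seed = NULL,
                            out_dir = NULL) {
  if (is.null(cohort) && is.null(input_dir)) {
    stop("either 'cohort' or 'input_dir' must be given")
  }
  if (!is.null(cohort) && !inherits(cohort, "cohort_spec")) {
    stop("'cohort' must be a cohort_spec")
  }
  if (!is.null(seed) && !is.null(cohort)) cohort$seed <- as.integer(seed)
  ranks <- as.integer(ranks); grid_dims <- as.integer(grid_dims)
  if (length(ranks) != 3L || any(ranks < 1L)) stop("'ranks' must be 3 positive integers")
  if (length(grid_dims) != 3L || any(grid_dims < 1L)) stop("'grid_dims' must be 3 positive integers")
  if (n_train < 1L) stop("'n_train' must be >= 1")
  structure(list(cohort = cohort, input_dir = input_dir,
                 n_train = as.integer(n_train), ranks = ranks,
                 grid_dims = grid_dims, normalize = isTRUE(normalize),
                 rigid = isTRUE(rigid), registration = registration,
                 max_iter = as.integer(max_iter), tol = tol,
                 out_dir = out_dir),
            class = "pipeline_config")
}

read_cohort_dir <- function(input_dir) {
  mf_path <- file.path(input_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", input_dir)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  vols <- lapply(file.path(input_dir, mf$samples$file), function(p) {
    if (!file.exists(p)) stop("cohort volume missing: ", p)
    read_volume(p)
  })
  tmpl <- read_volume(file.path(input_dir, mf$template))
  list(volumes = vols, labels = mf$samples$label, template = tmpl)
}

#' Run the full texture-modeling pipeline
#'
#' Executes the whole scheme on a synthetic (or on-disk) cohort: generate
#' or load the volumes; shape-normalize every volume to the template
#' reference; fit the GND-PCA texture model on the training normals;
#' project all samples to core-tensor features; build the LDT classifier
#' from the training features; classify the test set.  Per-stage timings
#' and the per-sweep fitting cost are collected in a log; when `out_dir`
#' is set, the model archive, classifier JSON, per-sample JSON report and
#' log are written there.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"pipeline_report"`: `report` (data.frame with one
#'   test row: sample, true label, predicted label, ed, ldt, ed_minus_ldt),
#'   `model`, `classifier`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log[[name]] <<- c(log[[name]], list(seconds = tic() - t0))
    out
  }

  coh <- stage("simulate", {
    if (!is.null(config$input_dir)) read_cohort_dir(config$input_dir)
    else generate_cohort(config$cohort)
  })
  normal_idx <- which(coh$labels == "normal")
  if (length(normal_idx) < config$n_train) {
    stop(sprintf("pipeline needs %d normal training samples but cohort has %d",
                 config$n_train, length(normal_idx)))
  }
  train_idx <- normal_idx[seq_len(config$n_train)]
  test_idx <- setdiff(seq_along(coh$volumes), train_idx)

  tensors <- stage("normalize", {
    if (config$normalize) {
      lapply(coh$volumes, function(v) {
        shape_normalize(v, coh$template, config$grid_dims,
                        config$registration, rigid = config$rigid)$warped$data
      })
    } else {
      lapply(coh$volumes, function(v) v$data)
    }
  })

  model <- stage("fit", {
    gndpca(tensors[train_idx], ranks = config$ranks,
           max_iter = config$max_iter, tol = config$tol)
  })
  log$fit_history <- model$fit_history

  clf <- stage("classifier", ldt_classifier(model$scores))

  report <- stage("classify", {
    if (length(test_idx) > 0L) {
      cores <- lapply(tensors[test_idx], function(t) project(model, t))
      pred <- predict(clf, cores)
      cbind(data.frame(sample = test_idx, true_label = coh$labels[test_idx],
                       stringsAsFactors = FALSE), pred)
    } else {
      data.frame(sample = integer(0), true_label = character(0),
                 label = character(0), ed = numeric(0), ldt = numeric(0),
                 ed_minus_ldt = numeric(0))
    }
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_model(model, file.path(config$out_dir, "model.rds"))
    write_classifier(clf, file.path(config$out_dir, "classifier.json"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(log, file.path(config$out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(report = report, model = model, classifier = clf,
                 log = log),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Texture-modeling pipeline report\n")
  print(x$model)
  print(x$classifier)
  if (nrow(x$report) > 0) {
    correct <- sum(x$report$label == x$report$true_label)
    cat(sprintf("  test samples: %d, correctly classified: %d (%.0f%%)\n",
                nrow(x$report), correct, 100 * correct / nrow(x$report)))
    print(x$report, row.names = FALSE)
  } else {
    cat("  (empty test set)\n")
  }
  invisible(x)
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognized top-level keys mirror the arguments of [pipeline_config()]
#' and [cohort_spec()] (under `cohort:`); unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  allowed <- c("cohort", "input_dir", "n_train", "ranks", "grid_dims",
               "normalize", "rigid", "max_iter", "tol", "seed", "out_dir")
  bad <- setdiff(names(y), allowed)
  if (length(bad) > 0) {
    stop("unknown pipeline config keys: ", paste(bad, collapse = ", "))
  }
  if (!is.null(y$cohort)) {
    y$cohort <- do.call(cohort_spec, y$cohort)
  }
  do.call(pipeline_config, y)
}
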