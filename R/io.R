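# Readers/writers and the end-to-end pipeline. All file writes are atomic
# (temp file in the target directory, then rename).

write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path)
  invisible(path)
}

#' Read an observation table from CSV
#'
#' Expects a header with columns `v_1 ... v_k`, `delta`, `outcome`
#' (+1/-1/0) and optional quantitative columns; `#` starts a comment line.
#' Exclusion-labeled rows are kept (they are dropped, with a message, at
#' training time).
#'
#' @param path File path.
#' @return An `observation_table`.
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("empty observation table: ", path)
  vcols <- grep("^v_[0-9]+$", names(raw), value = TRUE)
  if (length(vcols) == 0)
    stop("missing required context columns v_1..v_k in ", path)
  vcols <- paste0("v_", seq_along(vcols))
  if (!all(vcols %in% names(raw)))
    stop("context columns must be consecutively numbered v_1..v_k")
  for (cn in c(vcols, "delta", "outcome")) {
    if (!cn %in% names(raw)) stop("missing required column '", cn, "'")
    if (!is.numeric(raw[[cn]]))
      stop("non-numeric values in column '", cn, "'")
    if (any(is.na(raw[[cn]])))
      stop(sprintf("missing value in column '%s' (row %s)", cn,
                   paste(which(is.na(raw[[cn]])), collapse = ", ")))
  }
  bad <- which(!raw$outcome %in% c(-1, 0, 1))
  if (length(bad))
    stop(sprintf("invalid outcome value%s in row %s: labels must be +1, -1 or 0",
                 if (length(bad) > 1) "s" else "",
                 paste(bad, collapse = ", ")))
  n_excl <- sum(raw$outcome == 0)
  if (n_excl > 0)
    message(sprintf("%d exclusion-labeled row(s) present; they are dropped at training time",
                    n_excl))
  quant <- setdiff(names(raw), c(vcols, "delta", "outcome"))
  observation_table(as.matrix(raw[, vcols, drop = FALSE]), raw$delta,
                    raw$outcome,
                    quantitative = if (length(quant))
                      raw[, quant, drop = FALSE] else NULL)
}

#' Write an observation table to CSV
#'
#' @param table An `observation_table`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_observation_table <- function(table, path) {
  df <- as.data.frame(table)
  for (cn in names(df)) # full precision so read(write(x)) is lossless
    if (is.double(df[[cn]])) df[[cn]] <- sprintf("%.17g", df[[cn]])
  write_atomic(path, function(tmp)
    write.csv(df, tmp, row.names = FALSE, quote = FALSE))
}

MODEL_FORMAT_VERSION <- 1L

#' Save / load a calibrated benefit model
#'
#' The model is serialized as JSON (format version 1): kernel
#' specification, support vectors and weights, bias, `S_delta`,
#' standardization, directionality and rescaling, and diagnostics.
#' `load_benefit_model()` reproduces `B(v)` evaluations exactly.
#'
#' @param calibrated A `calibrated_benefit`.
#' @param path File path (`.json`).
#' @return `save_benefit_model`: the path, invisibly;
#'   `load_benefit_model`: a `calibrated_benefit`.
#' @export
save_benefit_model <- function(calibrated, path) {
  stopifnot(inherits(calibrated, "calibrated_benefit"))
  clf <- calibrated$classifier
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    kernel = unclass(clf$kernel),
    V_sv = clf$V_sv, d_sv = clf$d_sv, weights = clf$weights,
    bias = clf$bias, S_delta = clf$S_delta,
    standardization = list(columns = clf$standardization$columns,
                           mean = as.numeric(clf$standardization$mean),
                           sd = as.numeric(clf$standardization$sd)),
    direction = calibrated$direction,
    rescale = calibrated$rescale,
    train_match_fraction = calibrated$train_match_fraction,
    diagnostics = calibrated$diagnostics)
  write_atomic(path, function(tmp)
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA))
}

#' @rdname save_benefit_model
#' @export
load_benefit_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("corrupt model file ", path, ": ",
                         conditionMessage(e)))
  need <- c("format_version", "kernel", "V_sv", "d_sv", "weights", "bias",
            "S_delta", "standardization", "direction", "rescale")
  miss <- setdiff(need, names(doc))
  if (length(miss))
    stop("model file is missing field(s): ", paste(miss, collapse = ", "))
  if (!identical(as.integer(doc$format_version), MODEL_FORMAT_VERSION))
    stop(sprintf("model format version %s not supported (expected %d)",
                 doc$format_version, MODEL_FORMAT_VERSION))
  kern <- kernel_spec(doc$kernel$family, doc$kernel$k_delta, doc$kernel$C,
                      doc$kernel$scale, doc$kernel$offset)
  std <- structure(list(columns = doc$standardization$columns,
                        mean = setNames(doc$standardization$mean,
                                        doc$standardization$columns),
                        sd = setNames(doc$standardization$sd,
                                      doc$standardization$columns)),
                   class = "standardization")
  clf <- structure(list(
    V_sv = matrix(unlist(doc$V_sv), ncol = length(std$columns) - 1L),
    d_sv = doc$d_sv, weights = doc$weights, bias = doc$bias, kernel = kern,
    S_delta = doc$S_delta, standardization = std,
    n = length(doc$d_sv), converged = TRUE,
    gram_min_eig = NA_real_), class = "svm_classifier")
  structure(list(classifier = clf, direction = as.integer(doc$direction),
                 rescale = list(mean = doc$rescale$mean,
                                sd = doc$rescale$sd),
                 train_match_fraction = doc$train_match_fraction,
                 diagnostics = doc$diagnostics),
            class = "calibrated_benefit")
}

#' Write a trajectory to CSV
#'
#' Columns `time`, `X_1 ... X_n`.
#'
#' @param trajectory A recorded `trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(trajectory, path) {
  if (is.null(trajectory$times))
    stop("trajectory was not recorded; simulate with record = TRUE")
  df <- data.frame(time = trajectory$times, trajectory$states)
  names(df) <- c("time", paste0("X_", seq_len(ncol(trajectory$states))))
  write_atomic(path, function(tmp) write.csv(df, tmp, row.names = FALSE))
}

#' Run the full pipeline on a synthetic scenario
#'
#' Generates the scenario, writes the train/test tables, ranks the kernel
#' grid on the training table, saves the best calibrated model, predicts
#' the test set with `B(v)/delta`, assesses the quantitative trend against
#' total density, and writes a machine-readable metrics report.
#'
#' @param config A list (or `scenario_config`) with at least `scenario` and
#'   `seed`; optional `out_dir` (default: a temporary directory), `folds`,
#'   `n_boot`, `kernel_grid`.
#' @return A `pipeline_report` list: `metrics` (test accuracy %, CV
#'   accuracy %, trend correlation, R-squared vs truth when available),
#'   `paths`, `best` (the calibrated model), `dataset`.
#' @export
run_pipeline <- function(config) {
  if (inherits(config, "scenario_config")) config <- list(scenario = config)
  scfg <- if (inherits(config$scenario, "scenario_config")) config$scenario
    else scenario_config(config$scenario, seed = config$seed)
  out_dir <- config$out_dir %||% tempfile("bdrule_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  folds <- config$folds # NULL selects the CV default
  n_boot <- config$n_boot %||% 100
  grid <- config$kernel_grid %||% default_kernel_grid()

  ds <- generate_scenario(scfg)
  paths <- list(train = file.path(out_dir, "train.csv"),
                test = file.path(out_dir, "test.csv"),
                model = file.path(out_dir, "model.json"),
                predictions = file.path(out_dir, "predictions.csv"),
                metrics = file.path(out_dir, "metrics.json"))
  write_observation_table(ds$train, paths$train)
  write_observation_table(ds$test, paths$test)

  rk <- rank_candidates(ds$train, grid, folds = folds, n_boot = n_boot,
                        seed = scfg$seed + 101L)
  best <- rk$best
  save_benefit_model(best, paths$model)

  pred <- predict(best, table_v(ds$test), ds$test$delta)
  test_accuracy <- 100 * mean(pred$label == ds$test$outcome)
  pred_out <- cbind(as.data.frame(ds$test), pred[, c("B", "ratio", "label",
                                                     "margin")])
  names(pred_out)[names(pred_out) == "label"] <- "predicted_outcome"
  write_atomic(paths$predictions, function(tmp)
    write.csv(pred_out, tmp, row.names = FALSE))

  trend <- tryCatch(quantitative_trend(pred, ds$test$total_density),
                    error = function(e) NULL)
  r2 <- if (!is.null(ds$test$b_truth)) {
    tr <- ds$test$b_truth
    1 - sum((pred$B - tr)^2) / sum((tr - mean(tr))^2)
  } else NA_real_
  metrics <- list(
    scenario = scfg$scenario, seed = scfg$seed,
    n_train = nrow(ds$train), n_test = nrow(ds$test),
    dropped_train = ds$meta$dropped_train,
    dropped_test = ds$meta$dropped_test,
    best_kernel = unclass(best$classifier$kernel),
    cv_accuracy = best$diagnostics$cv_accuracy,
    test_accuracy = test_accuracy,
    trend_correlation = if (is.null(trend)) NA_real_ else trend$correlation,
    r_squared_vs_truth = r2,
    package_version = as.character(utils::packageVersion("bdrule")))
  write_atomic(paths$metrics, function(tmp)
    jsonlite::write_json(metrics, tmp, auto_unbox = TRUE, digits = NA,
                         na = "null"))
  structure(list(metrics = metrics, paths = paths, best = best,
                 dataset = ds, ranking = rk), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<pipeline> %s (seed %d): test accuracy %.2f%%, CV %.1f%%, trend rho %.3f%s\n",
              m$scenario, m$seed, m$test_accuracy, m$cv_accuracy,
              m$trend_correlation,
              if (is.finite(m$r_squared_vs_truth))
                sprintf(", R^2 vs truth %.3f", m$r_squared_vs_truth) else ""))
  invisible(x)
}
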