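# Learning / validation / classification modes of the SVM classifier stage,
# plus reference-marker relabeling and model serialization.

#' Train an SVM classification model (learning mode)
#'
#' Pipeline: wrapper feature-subset selection ([select_feature_subset()]),
#' scaler refit on the entire training set, C/gamma grid optimization on
#' the selected features, final fit. Multi-class handling is pairwise
#' one-vs-one inside [svm_fit()].
#'
#' @param table A `feature_table` of training events.
#' @param labels Class labels, one per event row (>= 2 classes).
#' @param config A [selection_config()].
#' @param select Run the wrapper selection (default `TRUE`; `FALSE` keeps
#'   all features).
#' @return An `hfo_svm_model`: scaler, feature subset, tuned `C`/`gamma`,
#'   the fitted machines, class labels and training metadata.
#' @export
train_model <- function(table, labels, config = selection_config(),
                        select = TRUE) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("train_model(): need >= 2 classes")
  sel <- NULL
  if (select) {
    sel <- select_feature_subset(table, labels, config)
    subset <- sel$subset
    if (!length(subset)) {
      stop("train_model(): empty final feature subset; lower min_occurrence ",
           "or review the training data")
    }
  } else {
    subset <- colnames(table$values)
  }
  scaler <- fit_scaler(table)                  # refit over the entire set
  xs <- apply_scaler(scaler, table)$values[, subset, drop = FALSE]
  opt <- grid_optimize(xs, labels, config$C_grid, config$gamma_grid,
                       folds = config$cv_folds, seed = config$seed)
  fit <- svm_fit(xs, labels, C = opt$C, gamma = opt$gamma)
  structure(list(scaler = scaler, feature_subset = subset,
                 C = opt$C, gamma = opt$gamma, fit = fit,
                 class_labels = fit$classes,
                 metadata = list(seed = config$seed,
                                 cv_accuracy = opt$cv_accuracy,
                                 histogram = if (!is.null(sel)) sel$histogram,
                                 n_train = nrow(table$values))),
            class = "hfo_svm_model")
}

#' @export
print.hfo_svm_model <- function(x, ...) {
  cat("<hfo_svm_model> classes:", paste(x$class_labels, collapse = "/"),
      "| features:", paste(x$feature_subset, collapse = ", "),
      sprintf("| C = %g, gamma = %g | cv-acc = %.3f\n",
              x$C, x$gamma, x$metadata$cv_accuracy))
  invisible(x)
}

model_features_check <- function(model, table) {
  miss <- setdiff(model$feature_subset, colnames(table$values))
  if (length(miss)) {
    stop("model requires missing feature(s): ", paste(miss, collapse = ", "))
  }
}

predict_model <- function(model, table) {
  model_features_check(model, table)
  xs <- apply_scaler(model$scaler,
                     table$values[, model$feature_subset, drop = FALSE])
  svm_predict(model$fit, xs)
}

#' Validate a model against labeled events (validation mode)
#'
#' @param model An `hfo_svm_model`.
#' @param table A `feature_table` of events to classify.
#' @param labels The reference labels.
#' @return A `validation_report`: per-class counters (`P_T`, `P_F`,
#'   `N_F`), derived metrics from [compute_metrics()], overall accuracy
#'   and the predictions.
#' @export
validate_model <- function(model, table, labels) {
  labels <- as.character(labels)
  pred <- predict_model(model, table)
  counters <- counters_from_labels(labels, pred)
  structure(list(counters = counters, metrics = compute_metrics(counters),
                 accuracy = mean(pred == labels), predictions = pred),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> accuracy:", sprintf("%.4f", x$accuracy), "\n")
  print(x$metrics)
  invisible(x)
}

#' Classify events with a trained model (classification mode)
#'
#' @param model An `hfo_svm_model`.
#' @param table A `feature_table` whose event keys get relabeled.
#' @return The event list with predicted labels.
#' @export
classify_events <- function(model, table) {
  pred <- predict_model(model, table)
  ev <- table$events
  ev$label <- pred
  as_event_list(ev)
}

#' Relabel detected events from reference markers
#'
#' Detected events that match a reference marker (same channel and epoch,
#' temporal overlap of the shorter event >= `min_overlap_pct`) take the
#' reference label; unmatched events keep (or get) the generic label
#' `EOI`.
#'
#' @param detected,reference `hfo_events` lists.
#' @param min_overlap_pct Minimum overlap percentage (0, 100].
#' @return The relabeled detected events.
#' @export
relabel_by_reference <- function(detected, reference, min_overlap_pct = 50) {
  if (!nrow(detected)) return(detected)
  mr <- match_events(reference, detected, min_overlap_pct)
  detected$label <- rep("EOI", nrow(detected))
  if (nrow(mr$pairs)) {
    detected$label[mr$pairs$test_row] <- reference$label[mr$pairs$reference_row]
  }
  as_event_list(detected)
}

#' Save / load a trained model
#'
#' The model file is a versioned JSON container holding the scaler, the
#' selected feature subset, `C`/`gamma`, and each binary machine's support
#' data; numbers are stored at full precision so predictions round-trip
#' exactly.
#'
#' @param model An `hfo_svm_model`.
#' @param path File path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   model.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "hfokit-svm-model", version = 1L,
    scaler = list(x_min = as.list(model$scaler$x_min),
                  x_max = as.list(model$scaler$x_max),
                  m = model$scaler$m, M = model$scaler$M,
                  features = model$scaler$features),
    feature_subset = model$feature_subset,
    C = model$C, gamma = model$gamma,
    classes = model$fit$classes,
    machines = lapply(model$fit$machines, function(m) {
      list(pos = m$pos, neg = m$neg, x = m$x, y = m$y,
           alpha = m$alpha, b = m$b)
    }),
    metadata = model$metadata)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(p$format, "hfokit-svm-model")) {
    stop("load_model(): not an hfokit model file")
  }
  scaler <- structure(list(x_min = unlist(p$scaler$x_min),
                           x_max = unlist(p$scaler$x_max),
                           m = p$scaler$m, M = p$scaler$M,
                           features = unlist(p$scaler$features)),
                      class = "hfo_scaler")
  machines <- lapply(p$machines, function(m) {
    x <- do.call(rbind, lapply(m$x, unlist))
    colnames(x) <- unlist(p$feature_subset)
    list(pos = m$pos, neg = m$neg, x = x, y = unlist(m$y),
         alpha = unlist(m$alpha), b = m$b)
  })
  fit <- structure(list(machines = machines, classes = unlist(p$classes),
                        C = p$C, gamma = p$gamma,
                        n_features = length(p$feature_subset),
                        feature_names = unlist(p$feature_subset)),
                   class = "hfo_svm")
  structure(list(scaler = scaler, feature_subset = unlist(p$feature_subset),
                 C = p$C, gamma = p$gamma, fit = fit,
                 class_labels = fit$classes, metadata = p$metadata),
            class = "hfo_svm_model")
}
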