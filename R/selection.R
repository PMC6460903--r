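# Feature scaling, ANOVA ranking, greedy-forward wrapper selection with a
# resampled outer loop, and C/gamma grid optimization.

#' Fit / apply a per-feature linear scaler
#'
#' Maps each feature from its observed `[x_min, x_max]` onto `[m, M]` via
#' `x' = m + (x - x_min) (M - m) / (x_max - x_min)`. Out-of-range values
#' extrapolate linearly (no clipping); a constant feature maps everything
#' to `m`.
#'
#' @param table A `feature_table` (or bare numeric matrix).
#' @param m,M Target range, default unity-based `[0, 1]`.
#' @return An `hfo_scaler`.
#' @export
fit_scaler <- function(table, m = 0, M = 1) {
  x <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  if (!nrow(x)) stop("fit_scaler(): empty table")
  structure(list(x_min = apply(x, 2L, min), x_max = apply(x, 2L, max),
                 m = m, M = M, features = colnames(x)),
            class = "hfo_scaler")
}

#' @rdname fit_scaler
#' @param scaler An `hfo_scaler`.
#' @export
apply_scaler <- function(scaler, table) {
  is_ft <- inherits(table, "feature_table")
  x <- if (is_ft) table$values else as.matrix(table)
  feats <- colnames(x)
  miss <- setdiff(feats, scaler$features)
  if (length(miss)) stop("apply_scaler(): unknown feature(s): ",
                         paste(miss, collapse = ", "))
  for (f in feats) {
    rng <- scaler$x_max[[f]] - scaler$x_min[[f]]
    x[, f] <- if (rng == 0) scaler$m
              else scaler$m + (x[, f] - scaler$x_min[[f]]) *
                     (scaler$M - scaler$m) / rng
  }
  if (is_ft) feature_table(x, table$events, table$id) else x
}

#' Rank features by one-way ANOVA F statistic
#'
#' Computed per feature across the class groups on the supplied rows only
#' (callers pass the training subset). Constant features get `F = 0` and
#' sort last (stable order).
#'
#' @param x Samples x features matrix (or `feature_table`).
#' @param labels Class labels.
#' @return A list with `order` (feature indices, descending discriminative
#'   power) and `f_stat` (per-feature F values in input order).
#' @export
anova_rank <- function(x, labels) {
  if (inherits(x, "feature_table")) x <- x$values
  x <- as.matrix(x)
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2L) stop("anova_rank(): need >= 2 classes")
  if (any(tab < 2L)) {
    stop("anova_rank(): class(es) with < 2 samples: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  k <- length(tab)
  N <- nrow(x)
  f_stat <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    grand <- mean(v)
    ssb <- 0; ssw <- 0
    for (g in names(tab)) {
      vg <- v[labels == g]
      ssb <- ssb + length(vg) * (mean(vg) - grand)^2
      ssw <- ssw + sum((vg - mean(vg))^2)
    }
    if (ssb == 0) return(0)                 # constant (or class-constant) -> last
    if (ssw == 0) return(Inf)
    (ssb / (k - 1)) / (ssw / (N - k))
  }, numeric(1))
  list(order = order(-f_stat), f_stat = f_stat)
}

majority_accuracy <- function(train_labels, val_labels) {
  tab <- table(train_labels)
  maj <- names(tab)[which.max(tab)]
  mean(val_labels == maj)
}

#' Greedy forward ("hill climbing") feature selection
#'
#' Starting from the empty set (baseline = majority-class accuracy on the
#' validation subset), each round trains one SVM per remaining ranked
#' feature appended to the current subset and scores validation accuracy.
#' The best-improving feature is added permanently; the loop stops when no
#' candidate improves the score. After each round, candidates whose trial
#' accuracy fell below `mean - sd` of that round's trial accuracies are
#' removed from further consideration.
#'
#' @param ranked_features Feature names, descending discriminative power.
#' @param train_x,train_labels Training subset (already scaled).
#' @param val_x,val_labels Disjoint validation subset (already scaled).
#' @param C,gamma SVM parameters for the trial models; `gamma = NULL`
#'   uses `1 / n_features_in_trial`.
#' @return A list with `subset` (selected names, in addition order),
#'   `accuracy` (final score) and `steps` (per-round best accuracies).
#' @export
greedy_forward_select <- function(ranked_features, train_x, train_labels,
                                  val_x, val_labels, C = 1, gamma = NULL) {
  stopifnot(length(ranked_features) >= 1L)
  subset <- character()
  best <- majority_accuracy(train_labels, val_labels)
  remaining <- ranked_features
  steps <- numeric()
  repeat {
    if (!length(remaining)) break
    acc <- vapply(remaining, function(f) {
      cols <- c(subset, f)
      fit <- svm_fit(train_x[, cols, drop = FALSE], train_labels, C, gamma)
      svm_accuracy(fit, val_x[, cols, drop = FALSE], val_labels)
    }, numeric(1))
    cand_best <- which.max(acc)
    improved <- acc[[cand_best]] > best
    drop <- acc < mean(acc) - stats::sd(acc)
    if (length(remaining) == 1L) drop[] <- FALSE
    drop[is.na(drop)] <- FALSE
    if (improved) {
      best <- acc[[cand_best]]
      steps <- c(steps, best)
      picked <- remaining[[cand_best]]
      subset <- c(subset, picked)
      remaining <- remaining[!drop & remaining != picked]
    } else {
      break
    }
  }
  list(subset = subset, accuracy = best, steps = steps)
}

#' Selection configuration
#'
#' @param ratio Validation holdout ratio r, `0 < r <= 0.5`; the outer loop
#'   runs `floor(1 / r)` times.
#' @param seed Integer seed; per-iteration streams are derived from it.
#' @param min_occurrence Minimum number of local subsets a feature must
#'   appear in to enter the final subset (default 2).
#' @param C_grid,gamma_grid Grids for the final parameter optimization
#'   (defaults: `2^seq(-5, 15, 2)` and `2^seq(-15, 3, 2)`).
#' @param cv_folds Cross-validation folds for the grid search (default 3).
#' @param C,gamma SVM parameters used inside the wrapper selection.
#' @return A `selection_config` list.
#' @export
selection_config <- function(ratio = 0.1, seed = 1L, min_occurrence = 2L,
                             C_grid = 2^seq(-5, 15, 2),
                             gamma_grid = 2^seq(-15, 3, 2),
                             cv_folds = 3L, C = 1, gamma = NULL) {
  stopifnot(ratio > 0, ratio <= 0.5)
  n_outer <- as.integer(floor(1 / ratio))
  stopifnot(n_outer >= 2L)
  structure(list(ratio = ratio, seed = as.integer(seed),
                 min_occurrence = as.integer(min_occurrence),
                 C_grid = C_grid, gamma_grid = gamma_grid,
                 cv_folds = as.integer(cv_folds), C = C, gamma = gamma,
                 n_outer = n_outer),
            class = "selection_config")
}

#' Outer-loop arithmetic of the wrapper selection
#'
#' @param rows Total number of samples.
#' @param ratio Validation holdout ratio r.
#' @return List with `n_runs = floor(1/r)`, `n_validation = floor(rows*r)`
#'   and `n_training = rows - n_validation`.
#' @export
selection_plan <- function(rows, ratio) {
  n_val <- as.integer(floor(rows * ratio))
  list(n_runs = as.integer(floor(1 / ratio)),
       n_validation = n_val,
       n_training = as.integer(rows) - n_val)
}

#' Resampled wrapper feature-subset selection
#'
#' Runs `floor(1/ratio)` outer iterations. Each iteration shuffles the
#' rows, holds out `floor(rows * ratio)` samples for validation, fits the
#' scaler on the training subset only, ranks the training features by
#' ANOVA, and runs [greedy_forward_select()]. The locally optimal subsets
#' are aggregated into an occurrence histogram; the final subset keeps
#' features appearing at least `min_occurrence` times.
#'
#' @param table A `feature_table` (unscaled).
#' @param labels Class labels, one per event row.
#' @param config A [selection_config()].
#' @return A list with `subset`, `histogram` (named occurrence counts),
#'   `runs` (per-iteration subsets and accuracies) and `plan`.
#' @export
select_feature_subset <- function(table, labels, config = selection_config()) {
  x <- table$values
  labels <- as.character(labels)
  n <- nrow(x)
  if (n < 10L * length(unique(labels))) {
    stop("select_feature_subset(): need >= 10 rows per class")
  }
  plan <- selection_plan(n, config$ratio)
  if (plan$n_validation < 1L) stop("select_feature_subset(): empty validation subset")
  runs <- vector("list", plan$n_runs)
  hist <- integer(0)
  for (i in seq_len(plan$n_runs)) {
    perm <- with_seed(config$seed + 1013L * i, sample.int(n))
    val_idx <- perm[seq_len(plan$n_validation)]
    train_idx <- perm[-seq_len(plan$n_validation)]
    sc <- fit_scaler(x[train_idx, , drop = FALSE])
    xs <- apply_scaler(sc, x)
    rk <- anova_rank(xs[train_idx, , drop = FALSE], labels[train_idx])
    ranked <- colnames(x)[rk$order]
    sel <- greedy_forward_select(ranked,
                                 xs[train_idx, , drop = FALSE], labels[train_idx],
                                 xs[val_idx, , drop = FALSE], labels[val_idx],
                                 C = config$C, gamma = config$gamma)
    runs[[i]] <- sel
    for (f in sel$subset) hist[f] <- (if (is.na(hist[f])) 0L else hist[f]) + 1L
  }
  subset <- names(hist)[hist >= config$min_occurrence]
  # keep the original column order in the final subset
  subset <- colnames(x)[colnames(x) %in% subset]
  list(subset = subset, histogram = hist, runs = runs, plan = plan)
}

stratified_folds <- function(labels, folds, seed = 1L) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < folds)) {
    stop("grid_optimize(): class(es) with fewer samples than folds (",
         paste(names(tab)[tab < folds], collapse = ", "),
         "); use fewer folds")
  }
  assign <- integer(length(labels))
  with_seed(seed, {
    for (g in names(tab)) {
      idx <- which(labels == g)
      idx <- idx[sample.int(length(idx))]
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Exhaustive C/gamma grid optimization
#'
#' Evaluates every `(C, gamma)` pair with stratified k-fold
#' cross-validation and returns the accuracy-maximizing pair; ties break
#' toward the smallest `C`, then the smallest `gamma`.
#'
#' @param x Samples x features matrix (scaled).
#' @param labels Class labels.
#' @param C_grid,gamma_grid Non-empty parameter grids.
#' @param folds Folds, >= 2.
#' @param seed Seed for the fold assignment.
#' @return List with `C`, `gamma`, `cv_accuracy`, and the full `grid` of
#'   accuracies.
#' @export
grid_optimize <- function(x, labels, C_grid, gamma_grid, folds = 3L, seed = 1L) {
  stopifnot(length(C_grid) >= 1L, length(gamma_grid) >= 1L, folds >= 2L)
  x <- if (inherits(x, "feature_table")) x$values else as.matrix(x)
  labels <- as.character(labels)
  fold_of <- stratified_folds(labels, folds, seed)
  C_grid <- sort(C_grid)
  gamma_grid <- sort(gamma_grid)
  grid <- matrix(NA_real_, length(C_grid), length(gamma_grid),
                 dimnames = list(format(C_grid), format(gamma_grid)))
  best <- list(C = C_grid[[1L]], gamma = gamma_grid[[1L]], cv_accuracy = -1)
  for (ci in seq_along(C_grid)) {
    for (gi in seq_along(gamma_grid)) {
      correct <- 0L
      for (k in seq_len(folds)) {
        tr <- fold_of != k
        fit <- svm_fit(x[tr, , drop = FALSE], labels[tr],
                       C = C_grid[[ci]], gamma = gamma_grid[[gi]])
        pred <- svm_predict(fit, x[!tr, , drop = FALSE])
        correct <- correct + sum(pred == labels[!tr])
      }
      acc <- correct / length(labels)
      grid[ci, gi] <- acc
      if (acc > best$cv_accuracy) {
        best <- list(C = C_grid[[ci]], gamma = gamma_grid[[gi]],
                     cv_accuracy = acc)
      }
    }
  }
  best$grid <- grid
  best
}
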