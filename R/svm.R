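# RBF-kernel C-SVC on top of the internal SMO solver, with one-vs-one
# pairwise decomposition (n(n-1)/2 binary machines, majority vote).

#' Train a multi-class RBF support vector machine
#'
#' @param x Numeric samples x features matrix.
#' @param labels Character/factor class labels, length `nrow(x)`.
#' @param C Misclassification penalty, > 0.
#' @param gamma RBF width; `NULL` uses `1 / ncol(x)`.
#' @return An `hfo_svm` fit (binary machines plus metadata).
#' @export
svm_fit <- function(x, labels, C = 1, gamma = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), C > 0)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  classes <- sort(unique(labels), method = "radix")
  if (length(classes) < 2L) stop("svm_fit(): need at least 2 classes")
  pairs <- utils::combn(classes, 2L, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    xs <- x[sel, , drop = FALSE]
    yy <- ifelse(labels[sel] == pr[[1L]], 1, -1)
    fit <- svm_smo_train(xs, yy, C, gamma)
    list(pos = pr[[1L]], neg = pr[[2L]], x = xs, y = yy,
         alpha = fit$alpha, b = fit$b)
  })
  structure(list(machines = machines, classes = classes, C = C,
                 gamma = gamma, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "hfo_svm")
}

#' Predict class labels with a fitted SVM
#'
#' One-vs-one majority vote; ties go to the earliest class in sorted order.
#'
#' @param fit An `hfo_svm`.
#' @param x New samples x features matrix (same columns as training).
#' @return Character vector of predicted labels.
#' @export
svm_predict <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != fit$n_features) {
    stop("svm_predict(): expected ", fit$n_features, " features, got ", ncol(x))
  }
  votes <- matrix(0L, nrow(x), length(fit$classes),
                  dimnames = list(NULL, fit$classes))
  for (m in fit$machines) {
    f <- svm_smo_decision(m$x, m$y, m$alpha, m$b, fit$gamma, x)
    pos <- f >= 0
    votes[, m$pos] <- votes[, m$pos] + pos
    votes[, m$neg] <- votes[, m$neg] + !pos
  }
  fit$classes[apply(votes, 1L, which.max)]
}

svm_accuracy <- function(fit, x, labels) {
  mean(svm_predict(fit, x) == as.character(labels))
}
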