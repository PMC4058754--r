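# S3 model object: metric-MDS embedding + polynomial-kernel SVM fitted to a
# cohort's graph-distance matrix.

#' Fit the embed-and-classify model to a distance matrix
#'
#' Embeds the cohort with metric-stress MDS and fits a polynomial-kernel
#' SVM on the embedded coordinates. The returned object supports
#' `print()`, `summary()`, `predict()`, `fitted()` and `plot()`.
#'
#' `predict()` with no new data returns the in-sample fitted labels. To
#' score held-out subjects, embed train and test jointly (transductively)
#' and pass the test rows' coordinates as `newdata`, or use
#' [classify_train_test()] which wraps exactly that protocol.
#'
#' @param D Symmetric graph-distance matrix over the cohort.
#' @param labels Subject labels in `{control, case}`.
#' @param ecfg An [embedding_config()].
#' @param ccfg A [classifier_config()].
#' @return An `ag_model`.
#' @export
ag_fit <- function(D, labels, ecfg = embedding_config(),
                   ccfg = classifier_config()) {
  y <- as_class_factor(labels)
  D <- as.matrix(D)
  if (nrow(D) != length(y)) stop("D and labels disagree", call. = FALSE)
  if (length(unique(y)) < 2L) stop("need both classes to fit", call. = FALSE)
  emb <- mds_embed(D, ecfg)
  fit <- fit_svm(emb$coords, y, ccfg)
  structure(list(embedding = emb, svm = fit, labels = y,
                 ecfg = ecfg, ccfg = ccfg),
            class = "ag_model")
}

#' @export
predict.ag_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$embedding$coords
  stats::predict(object$svm, as.matrix(newdata))
}

#' @export
fitted.ag_model <- function(object, ...) predict(object)

#' @export
print.ag_model <- function(x, ...) {
  cat(sprintf("<ag_model> %d subjects (%d control / %d case), %d-D embedding, stress %.3g\n",
              length(x$labels), sum(x$labels == "control"),
              sum(x$labels == "case"), ncol(x$embedding$coords),
              x$embedding$stress))
  cat(sprintf("polynomial SVM: degree %d, cost %g\n",
              x$ccfg$degree, x$ccfg$cost))
  invisible(x)
}

#' @export
summary.ag_model <- function(object, ...) {
  m <- detection_metrics(fitted(object), object$labels)
  out <- list(model = object, training_metrics = m)
  class(out) <- "summary.ag_model"
  out
}

#' @export
print.summary.ag_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("in-sample: detection %.2f%%, specificity %.2f%%, sensitivity %.2f%%\n",
              x$training_metrics[["detection_rate"]],
              x$training_metrics[["specificity"]],
              x$training_metrics[["sensitivity"]]))
  invisible(x)
}

#' @export
plot.ag_model <- function(x, ...) {
  X <- x$embedding$coords
  if (ncol(X) < 2L) X <- cbind(X, 0)
  ok <- fitted(x) == x$labels
  plot(X[, 1], X[, 2], col = ifelse(x$labels == "case", 2L, 4L),
       pch = ifelse(ok, 19L, 1L),
       xlab = "dimension 1", ylab = "dimension 2",
       main = "embedded subjects", ...)
  graphics::legend("topright",
                   legend = c("control", "case", "misclassified"),
                   col = c(4L, 2L, 1L), pch = c(19L, 19L, 1L), bty = "n")
  invisible(x)
}
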