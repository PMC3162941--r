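# Feed-forward surrogate classifier: learns the fuzzy engine's five-way
# situation mapping from labelled (MBP, SpO2) samples. The network stands
# in for the engine only as a classification study; the engine remains the
# reference labeller.

scale_inputs <- function(dataset) {
  # min-max scaling by the variable domains (MBP 0-200 mmHg, SpO2 0-100 %)
  cbind(MBP = dataset$MBP / 200, SpO2 = dataset$SpO2 / 100)
}

#' Train the surrogate classifier
#'
#' Fits a single-hidden-layer feed-forward network (sigmoidal hidden
#' units, softmax output) on fuzzy-labelled samples to predict the five
#' clinical situations from the raw (MBP, SpO2) pair, min-max scaled to
#' `[0, 1]` by the variable domains. Training is deterministic given the
#' seed.
#'
#' @param dataset Data.frame from [generate_labelled_dataset()] (needs
#'   `MBP`, `SpO2`, `label`); at least two classes must be present.
#' @param hidden Hidden-layer size (>= 1); 15 reproduces the reference
#'   topology.
#' @param seed Integer seed for weight initialization.
#' @param maxit Maximum training iterations.
#' @return Object of class `surrogate_classifier` wrapping the fitted
#'   network, the class levels and training metadata.
#' @export
train_surrogate <- function(dataset, hidden = 15, seed = 1,
                            maxit = 500) {
  stopifnot(is.data.frame(dataset),
            all(c("MBP", "SpO2", "label") %in% names(dataset)),
            hidden >= 1)
  levels_all <- situation_labels()
  present <- intersect(levels_all, unique(dataset$label))
  if (length(present) < 2L)
    stop("dataset must contain at least two classes", call. = FALSE)
  y <- factor(dataset$label, levels = present)
  x <- scale_inputs(dataset)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fit <- nnet::nnet(x, nnet::class.ind(y), size = hidden, softmax = TRUE,
                    maxit = maxit, decay = 1e-4, trace = FALSE,
                    MaxNWts = 10000)
  structure(list(fit = fit, levels = present,
                 metadata = list(hidden = as.integer(hidden),
                                 seed = as.integer(seed),
                                 n_train = nrow(dataset),
                                 maxit = maxit)),
            class = "surrogate_classifier")
}

#' @export
print.surrogate_classifier <- function(x, ...) {
  cat("<surrogate_classifier> ", x$metadata$hidden,
      " hidden units, trained on ", x$metadata$n_train, " samples (",
      length(x$levels), " classes)\n", sep = "")
  invisible(x)
}

#' Predict situations with the surrogate
#'
#' @param object A `surrogate_classifier`.
#' @param newdata Data.frame with `MBP` and `SpO2` columns.
#' @param ... Unused.
#' @return Character vector of predicted situation labels.
#' @export
predict.surrogate_classifier <- function(object, newdata, ...) {
  p <- predict(object$fit, scale_inputs(newdata))
  object$levels[max.col(p, ties.method = "first")]
}

#' Evaluate the surrogate against fuzzy labels
#'
#' Scores the classifier on a held-out split: overall agreement with the
#' fuzzy labels, per-class precision and recall, and the full confusion
#' matrix (rows = true fuzzy label, columns = predicted).
#'
#' @param classifier A `surrogate_classifier`.
#' @param test Held-out data.frame with `MBP`, `SpO2`, `label`; must be
#'   non-empty and disjoint from the training split.
#' @return Object of class `classifier_report`: `confusion` (5x5 matrix),
#'   `agreement`, `precision`, `recall`, `metadata`.
#' @export
evaluate_surrogate <- function(classifier, test) {
  stopifnot(inherits(classifier, "surrogate_classifier"),
            is.data.frame(test))
  if (nrow(test) == 0L) stop("empty test split", call. = FALSE)
  labs <- situation_labels()
  pred <- predict(classifier, test)
  truth <- factor(test$label, levels = labs)
  pred <- factor(pred, levels = labs)
  confusion <- table(truth = truth, predicted = pred)
  agreement <- mean(as.character(truth) == as.character(pred))
  tp <- diag(confusion)
  precision <- ifelse(colSums(confusion) > 0, tp / colSums(confusion),
                      NA_real_)
  recall <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion),
                   NA_real_)
  structure(list(confusion = unclass(confusion), agreement = agreement,
                 precision = precision, recall = recall,
                 metadata = c(classifier$metadata,
                              list(n_test = nrow(test)))),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> agreement %.3f on %d held-out samples\n",
              x$agreement, x$metadata$n_test))
  print(x$confusion)
  invisible(x)
}

#' Write a classifier report to disk
#'
#' Confusion matrix as CSV plus the full report (agreement, per-class
#' precision/recall, training metadata) as JSON.
#'
#' @param report A `classifier_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "classifier_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm_path <- file.path(dir, "confusion_matrix.csv")
  utils::write.csv(as.data.frame.matrix(report$confusion), cm_path)
  js_path <- file.path(dir, "classifier_report.json")
  jsonlite::write_json(
    list(agreement = report$agreement,
         precision = as.list(report$precision),
         recall = as.list(report$recall),
         confusion = report$confusion,
         metadata = report$metadata),
    js_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(cm_path, js_path))
}
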