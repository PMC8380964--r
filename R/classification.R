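# Single-region patient-vs-control classification with a Gaussian-kernel
# soft-margin SVM (LIBSVM via e1071) under leave-one-out cross-validation.
# Patients are the positive class: sensitivity is the fraction of patients
# detected, specificity the fraction of controls.

#' Default C x gamma hyperparameter grid
#'
#' `2^{-5}, 2^{-3}, ..., 2^5` for both the cost C and the kernel width
#' gamma, ordered so that accuracy ties resolve to the smallest C, then
#' the smallest gamma.
#'
#' @return A data.frame with columns `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  v <- 2^seq(-5, 5, by = 2)
  g <- expand.grid(gamma = v, C = v)[, c("C", "gamma")]
  g[order(g$C, g$gamma), , drop = FALSE]
}

#' Confusion metrics against a positive class
#'
#' @param predicted,truth Equal-length label vectors.
#' @param positive_class The label counted as positive (default
#'   "patient").
#' @return A list: `sensitivity`, `specificity`, `accuracy` (percent),
#'   and `counts` ("k/n" strings plus the raw numbers).
#' @export
confusion_metrics <- function(predicted, truth,
                              positive_class = "patient") {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  pos <- truth == positive_class
  if (!any(pos)) stop("no members of the positive class in `truth`")
  if (all(pos)) stop("no members of the negative class in `truth`")
  tp <- sum(pos & predicted == positive_class)
  tn <- sum(!pos & predicted != positive_class)
  n_pos <- sum(pos); n_neg <- sum(!pos)
  list(
    sensitivity = 100 * tp / n_pos,
    specificity = 100 * tn / n_neg,
    accuracy = 100 * (tp + tn) / length(truth),
    counts = list(
      positive = sprintf("%d/%d", tp, n_pos),
      negative = sprintf("%d/%d", tn, n_neg),
      overall = sprintf("%d/%d", tp + tn, length(truth)),
      tp = tp, tn = tn, n_pos = n_pos, n_neg = n_neg))
}

loo_predictions <- function(x, y, C, gamma) {
  n <- length(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i]; ytr <- y[-i]
    mu <- mean(xtr); s <- stats::sd(xtr)
    if (s < .Machine$double.eps) s <- 1
    fit <- e1071::svm(x = matrix((xtr - mu) / s, ncol = 1),
                      y = factor(ytr, levels = levels(y)),
                      kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
    pred[i] <- as.character(predict(fit,
                                    matrix((x[i] - mu) / s, ncol = 1)))
  }
  pred
}

#' Leave-one-out SVM classification from one region's NH
#'
#' For every subject, a Gaussian-kernel SVM is trained on the remaining
#' subjects' region-mean NH (z-scored with training-fold statistics) and
#' predicts the held-out subject. Hyperparameters are chosen from the grid
#' by maximal LOO accuracy, ties broken by smallest C then smallest gamma.
#' The optimism of selecting hyperparameters on the same LOO loop is
#' documented; `nested = TRUE` selects them by an inner LOO inside each
#' training fold instead.
#'
#' @param features Region feature table from [extract_region_means()].
#' @param labels Group label per feature row ("patient"/"control").
#' @param region Name of the feature column to use.
#' @param grid Hyperparameter data.frame with columns `C` and `gamma`
#'   (default [default_svm_grid()]).
#' @param nested Use nested LOO hyperparameter selection (slower).
#' @return An object of class `classification_result`: region, metrics and
#'   counts from [confusion_metrics()], `C`, `gamma`, `predictions`.
#' @export
loo_svm_single_region <- function(features, labels, region,
                                  grid = default_svm_grid(),
                                  nested = FALSE) {
  if (!region %in% names(features))
    stop("region ", region, " not found in the feature table")
  if (is.null(grid) || nrow(grid) == 0L) stop("hyperparameter grid is empty")
  x <- features[[region]]
  y <- factor(labels, levels = c("control", "patient"))
  if (any(table(y) < 3L)) stop("need at least 3 subjects per class")
  if (length(x) != length(y)) stop("features and labels differ in length")

  if (!nested) {
    best <- NULL
    for (gi in seq_len(nrow(grid))) {
      pred <- loo_predictions(x, y, grid$C[gi], grid$gamma[gi])
      acc <- mean(pred == as.character(y))
      if (is.null(best) || acc > best$acc + 1e-12) {
        best <- list(acc = acc, pred = pred, C = grid$C[gi],
                     gamma = grid$gamma[gi])
      }
    }
    pred <- best$pred; Cb <- best$C; gb <- best$gamma
  } else {
    n <- length(x)
    pred <- character(n)
    Cs <- numeric(n); gs <- numeric(n)
    for (i in seq_len(n)) {
      xtr <- x[-i]; ytr <- droplevels(y[-i])
      inner_best <- NULL
      for (gi in seq_len(nrow(grid))) {
        ip <- loo_predictions(xtr, ytr, grid$C[gi], grid$gamma[gi])
        acc <- mean(ip == as.character(ytr))
        if (is.null(inner_best) || acc > inner_best$acc + 1e-12)
          inner_best <- list(acc = acc, C = grid$C[gi],
                             gamma = grid$gamma[gi])
      }
      mu <- mean(xtr); s <- stats::sd(xtr)
      if (s < .Machine$double.eps) s <- 1
      fit <- e1071::svm(x = matrix((xtr - mu) / s, ncol = 1),
                        y = factor(ytr, levels = levels(y)),
                        kernel = "radial", cost = inner_best$C,
                        gamma = inner_best$gamma, scale = FALSE)
      pred[i] <- as.character(predict(fit,
                                      matrix((x[i] - mu) / s, ncol = 1)))
      Cs[i] <- inner_best$C; gs[i] <- inner_best$gamma
    }
    Cb <- stats::median(Cs); gb <- stats::median(gs)
  }
  cm <- confusion_metrics(pred, as.character(y), "patient")
  structure(c(list(region = region, C = Cb, gamma = gb,
                   predictions = pred), cm),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result %s: sens %.2f%% (%s), spec %.2f%% (%s), acc %.2f%% (%s); C=%g gamma=%g>\n",
    x$region, x$sensitivity, x$counts$positive, x$specificity,
    x$counts$negative, x$accuracy, x$counts$overall, x$C, x$gamma))
  invisible(x)
}

#' Classify every region in a feature table
#'
#' @inheritParams loo_svm_single_region
#' @return A data.frame with one row per region (sensitivity, specificity,
#'   accuracy, counts, C, gamma).
#' @export
classify_all_regions <- function(features, labels,
                                 grid = default_svm_grid(),
                                 nested = FALSE) {
  regions <- setdiff(names(features), "subject_id")
  rows <- lapply(regions, function(rg) {
    r <- loo_svm_single_region(features, labels, rg, grid, nested)
    data.frame(region = rg,
               sensitivity = r$sensitivity, sensitivity_counts =
                 r$counts$positive,
               specificity = r$specificity, specificity_counts =
                 r$counts$negative,
               accuracy = r$accuracy, accuracy_counts = r$counts$overall,
               C = r$C, gamma = r$gamma, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
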