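#' Seeded train/test split of a feature table
#'
#' Per-group uniform sampling without replacement into the training set; the
#' remainder is the test set. With the reference cohort sizes (232
#' encephalopathy / 218 normal) and the default 100/100 training draw this
#' reproduces the published 200-train / 250-test protocol (132 + 118 test).
#'
#' @param features A `feature_table`.
#' @param n_train_per_group Named integer vector of training epochs per group.
#' @param seed Integer seed controlling the assignment.
#' @return List with data.frames `train` and `test` (disjoint, exhaustive).
#' @export
split_features <- function(features,
                           n_train_per_group = c(encephalopathy = 100L,
                                                 normal = 100L),
                           seed = 1L) {
  groups <- names(n_train_per_group)
  if (is.null(groups)) stop_input("n_train_per_group must be named by group")
  with_private_seed(seed, {
    train_idx <- integer()
    for (g in groups) {
      idx <- which(features$group == g)
      k <- n_train_per_group[[g]]
      if (length(idx) < k)
        stop_input("group '", g, "' has ", length(idx),
                   " epochs; cannot draw ", k, " for training")
      if (length(idx) == k)
        warning("group '", g, "' contributes no test epochs")
      train_idx <- c(train_idx, sort(sample(idx, k)))
    }
    list(train = features[sort(train_idx), , drop = FALSE],
         test = features[setdiff(seq_len(nrow(features)), train_idx), ,
                         drop = FALSE])
  })
}

#' Train a linear soft-margin SVM on band-energy features
#'
#' Maximal-margin linear separator with hinge loss, solved by deterministic
#' dual coordinate descent (the intercept is absorbed as a constant augmented
#' feature, so it is regularized along with the weights). Encephalopathy is
#' the positive class. Features are the relative band energies in percent, on
#' one common scale, so no standardization is applied.
#'
#' @param train Training `feature_table` rows (both classes present).
#' @param bands Feature subset, drawn from delta/theta/alpha/beta.
#' @param C Soft-margin cost; default 1.
#' @param tol Dual projected-gradient stopping tolerance.
#' @param max_passes Cap on coordinate-descent sweeps.
#' @return Object of class `linear_svm`: `w` (named weights), `b` (intercept),
#'   `bands`, `C`, solver diagnostics.
#' @export
train_linear_svm <- function(train, bands = c("delta", "theta", "alpha", "beta"),
                             C = 1, tol = 1e-6, max_passes = 20000L) {
  bands <- match.arg(bands, c("delta", "theta", "alpha", "beta"),
                     several.ok = TRUE)
  if (length(bands) == 0L) stop_input("feature subset must be non-empty")
  lab <- train$group
  if (length(unique(lab)) < 2L)
    stop_input("training data must contain both classes")
  y <- ifelse(lab == "encephalopathy", 1, -1)
  X <- as.matrix(train[, paste0(bands, "_pct"), drop = FALSE])
  # augmented constant feature carries the intercept; scaled to the percent
  # feature range so the intercept is effectively unregularized
  bias_scale <- 100
  Xa <- cbind(X, bias = bias_scale)
  fit <- .svm_dcd_cpp(Xa, y, C, tol, as.integer(max_passes))
  w <- fit$w
  structure(list(w = stats::setNames(w[seq_along(bands)], bands),
                 b = w[length(w)] * bias_scale, bands = bands, C = C,
                 passes = fit$passes, max_violation = fit$max_violation),
            class = "linear_svm")
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm C=%g> score = %s + %.4g  (%d CD passes)\n", x$C,
              paste(sprintf("%+.4g*%s", x$w, x$bands), collapse = " "),
              x$b, x$passes))
  invisible(x)
}

#' @param object A `linear_svm` model.
#' @param newdata Feature-table rows to score.
#' @param type `"class"` for labels, `"score"` for the decision values.
#' @param ... Unused.
#' @rdname train_linear_svm
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata[, paste0(object$bands, "_pct"), drop = FALSE])
  score <- drop(X %*% object$w) + object$b
  if (type == "score") return(score)
  # boundary tie (score exactly 0) counts as positive
  ifelse(score >= 0, "encephalopathy", "normal")
}

#' Screening performance metrics from confusion-matrix counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/(TP+TN+FP+FN), each in percent. Positive class is encephalopathy.
#'
#' @param TP,TN,FP,FN Nonnegative integer counts.
#' @return List of class `perf_metrics` with the three percentages and the
#'   counts.
#' @examples
#' metrics_from_counts(TP = 121, TN = 105, FP = 13, FN = 11)
#' @export
metrics_from_counts <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_input("confusion counts must be nonnegative integers")
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN,
                 sensitivity_pct = 100 * TP / (TP + FN),
                 specificity_pct = 100 * TN / (TN + FP),
                 accuracy_pct = 100 * (TP + TN) / sum(counts)),
            class = "perf_metrics")
}

#' @export
print.perf_metrics <- function(x, ...) {
  cat(sprintf("TP=%d TN=%d FP=%d FN=%d | sens %.2f%% spec %.2f%% acc %.2f%%\n",
              x$TP, x$TN, x$FP, x$FN, x$sensitivity_pct, x$specificity_pct,
              x$accuracy_pct))
  invisible(x)
}

#' Evaluate a trained model on labelled test epochs
#'
#' @param model A `linear_svm`.
#' @param test Labelled `feature_table` rows.
#' @return A `perf_metrics` object (includes the confusion counts).
#' @export
evaluate_classifier <- function(model, test) {
  if (nrow(test) == 0L) stop_input("test table is empty")
  if (any(!test$group %in% c("normal", "encephalopathy")))
    stop_input("test rows must be labelled normal/encephalopathy")
  pred <- predict(model, test)
  truth_pos <- test$group == "encephalopathy"
  pred_pos <- pred == "encephalopathy"
  metrics_from_counts(TP = sum(truth_pos & pred_pos),
                      TN = sum(!truth_pos & !pred_pos),
                      FP = sum(!truth_pos & pred_pos),
                      FN = sum(truth_pos & !pred_pos))
}

#' Compare SVM performance across band-energy feature subsets
#'
#' Trains and evaluates one linear SVM per feature subset on a single shared
#' train/test split, reporting confusion counts and metrics per subset — the
#' published comparison is {all four bands, delta only, alpha only, beta
#' only}.
#'
#' @param features A labelled `feature_table`.
#' @param subsets Named list of band subsets.
#' @param n_train_per_group,seed Split protocol, see [split_features()].
#' @param C Soft-margin cost.
#' @return data.frame: one row per subset with columns `subset`, `TP`, `TN`,
#'   `FP`, `FN`, `sensitivity_pct`, `specificity_pct`, `accuracy_pct`.
#' @export
run_feature_set_comparison <- function(features,
                                       subsets = list(
                                         all = c("delta", "theta", "alpha", "beta"),
                                         delta = "delta", alpha = "alpha",
                                         beta = "beta"),
                                       n_train_per_group = c(encephalopathy = 100L,
                                                             normal = 100L),
                                       seed = 1L, C = 1) {
  sp <- split_features(features, n_train_per_group, seed = seed)
  rows <- lapply(names(subsets), function(nm) {
    model <- train_linear_svm(sp$train, bands = subsets[[nm]], C = C)
    m <- evaluate_classifier(model, sp$test)
    data.frame(subset = nm, TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN,
               sensitivity_pct = m$sensitivity_pct,
               specificity_pct = m$specificity_pct,
               accuracy_pct = m$accuracy_pct)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
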