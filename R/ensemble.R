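#' Convex blend of two class-probability outputs
#'
#' \deqn{P_{ens} = \omega P_{kNN} + (1 - \omega) P_{BOSSVS}.}
#' At the endpoints the blend reproduces the corresponding base classifier
#' exactly; for any `omega` the rows remain valid probability vectors.
#'
#' @param p_knn,p_bossvs Probability matrices (rows = samples) or vectors
#'   over the same label set, each row summing to 1.
#' @param omega k-NN weight in `[0, 1]`.
#' @return Blended probability matrix.
#' @export
blend <- function(p_knn, p_bossvs, omega) {
  if (is.null(dim(p_knn))) p_knn <- matrix(p_knn, nrow = 1)
  if (is.null(dim(p_bossvs))) p_bossvs <- matrix(p_bossvs, nrow = 1)
  if (!identical(dim(p_knn), dim(p_bossvs)))
    stop_input("probability matrices have different shapes")
  if (!is.null(colnames(p_knn)) && !is.null(colnames(p_bossvs)) &&
      !identical(colnames(p_knn), colnames(p_bossvs)))
    stop_input("probability matrices are over different label sets")
  if (omega < 0 || omega > 1) stop_input("'omega' must lie in [0, 1]")
  if (any(abs(rowSums(p_knn) - 1) > 1e-6) ||
      any(abs(rowSums(p_bossvs) - 1) > 1e-6))
    stop_input("probability rows must sum to 1")
  omega * p_knn + (1 - omega) * p_bossvs
}

# argmax with ties broken toward the lower class index
argmax_class <- function(p, label_set) {
  label_set[apply(p, 1, which.max)]
}

# support-weighted F1 over the classes present in y_true
weighted_f1 <- function(y_true, y_pred, label_set) {
  f1 <- vapply(label_set, function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  support <- vapply(label_set, function(cl) sum(y_true == cl), numeric(1))
  sum(f1 * support) / sum(support)
}

#' Tune the ensemble weight on out-of-fold probabilities
#'
#' Scans `grid` and returns the weight maximizing the weighted F1 of the
#' argmax-blended predictions. Ties resolve toward the smaller weight
#' (favouring the BOSSVS-heavy solution).
#'
#' @param oof_knn,oof_bossvs Out-of-fold probability matrices, rows aligned
#'   with `labels`.
#' @param labels True labels for the rows.
#' @param grid Candidate weights, default 0 to 1 in steps of 0.05.
#' @return The selected weight.
#' @export
tune_weight <- function(oof_knn, oof_bossvs, labels,
                        grid = seq(0, 1, by = 0.05)) {
  if (length(grid) < 1L) stop_input("'grid' must be non-empty")
  labels <- as.factor(labels)
  if (nrow(oof_knn) != length(labels))
    stop_input("probability matrices must be row-aligned with 'labels'")
  label_set <- colnames(oof_knn)
  if (is.null(label_set)) label_set <- levels(labels)
  best_w <- grid[1]
  best_f1 <- -Inf
  for (w in sort(grid)) {
    pred <- argmax_class(blend(oof_knn, oof_bossvs, w), label_set)
    f1 <- weighted_f1(as.character(labels), pred, label_set)
    if (f1 > best_f1 + 1e-12) {
      best_f1 <- f1
      best_w <- w
    }
  }
  best_w
}

#' Classification metrics for a three-class permeability model
#'
#' Accuracy, balanced accuracy (mean per-class recall over classes present
#' in `y_true`), support-weighted precision/recall/F1, a confusion matrix
#' with rows as true classes, and (when probabilities are supplied)
#' one-vs-rest ROC curves with AUC per class via \pkg{pROC}. Classes absent
#' from `y_true` are skipped in ROC computation with a warning.
#'
#' @param y_true,y_pred Aligned label vectors.
#' @param y_proba Optional probability matrix with one column per class.
#' @param label_set Class labels fixing row/column order; defaults to the
#'   probability matrix columns or the sorted union of observed labels.
#' @return List with the metric scalars, `confusion`, and `roc` (per-class
#'   `auc` and curve points) when probabilities were given.
#' @export
classification_metrics <- function(y_true, y_pred, y_proba = NULL,
                                   label_set = NULL) {
  if (length(y_true) != length(y_pred))
    stop_input("'y_true' and 'y_pred' have different lengths")
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (is.null(label_set))
    label_set <- if (!is.null(y_proba) && !is.null(colnames(y_proba)))
      colnames(y_proba) else sort(unique(c(y_true, y_pred)))
  present <- label_set[label_set %in% y_true]
  recall <- vapply(present, function(cl)
    sum(y_true == cl & y_pred == cl) / sum(y_true == cl), numeric(1))
  precision <- vapply(present, function(cl) {
    denom <- sum(y_pred == cl)
    if (denom == 0) 0 else sum(y_true == cl & y_pred == cl) / denom
  }, numeric(1))
  support <- vapply(present, function(cl) sum(y_true == cl), numeric(1))
  conf <- table(factor(y_true, levels = label_set),
                factor(y_pred, levels = label_set),
                dnn = c("true", "predicted"))
  out <- list(
    accuracy = mean(y_true == y_pred),
    balanced_accuracy = mean(recall),
    precision_weighted = sum(precision * support) / sum(support),
    recall_weighted = sum(recall * support) / sum(support),
    f1_weighted = weighted_f1(y_true, y_pred, label_set),
    confusion = conf)
  if (!is.null(y_proba)) {
    if (nrow(y_proba) != length(y_true))
      stop_input("'y_proba' must be row-aligned with 'y_true'")
    roc <- lapply(label_set, function(cl) {
      if (!cl %in% y_true || all(y_true == cl)) {
        warning("ROC undefined for class '", cl, "' (absent or universal); ",
                "skipped", call. = FALSE)
        return(NULL)
      }
      r <- pROC::roc(response = factor(y_true == cl, c(FALSE, TRUE)),
                     predictor = y_proba[, cl], quiet = TRUE,
                     direction = "<")
      list(auc = as.numeric(pROC::auc(r)),
           curve = data.frame(fpr = 1 - r$specificities,
                              tpr = r$sensitivities))
    })
    names(roc) <- label_set
    out$roc <- roc
  }
  out
}
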