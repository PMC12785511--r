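#' Hyperparameter grids for the ensemble's base classifiers
#'
#' Default search spaces for the DTW k-NN classifier (neighbours, vote
#' weighting, Sakoe-Chiba band radius) and the BOSSVS classifier (window
#' size, word length, alphabet size). All values are configurable; pass any
#' subset to keep tuning cheap on small problems.
#'
#' @param n_neighbors,vote_weighting,band_radius Candidate k-NN settings.
#' @return A list of [knn_config()] objects.
#' @export
default_knn_grid <- function(n_neighbors = c(1, 3, 5),
                             vote_weighting = c("uniform",
                                                "inverse_distance"),
                             band_radius = c(5, 10, 25)) {
  g <- expand.grid(k = n_neighbors, w = vote_weighting, b = band_radius,
                   stringsAsFactors = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    knn_config(g$k[i], g$w[i], g$b[i]))
}

#' @rdname default_knn_grid
#' @param window_size,word_length,n_bins Candidate BOSSVS settings.
#' @return A list of [bossvs_config()] objects for `default_bossvs_grid()`.
#' @export
default_bossvs_grid <- function(window_size = c(32, 64, 128),
                                word_length = c(4, 6, 8),
                                n_bins = c(3, 4)) {
  g <- expand.grid(ws = window_size, wl = word_length, nb = n_bins)
  lapply(seq_len(nrow(g)), function(i)
    bossvs_config(g$ws[i], g$wl[i], g$nb[i]))
}

# stratified fold assignment: shuffles within class, assigns round-robin.
# Errors when a class has fewer members than folds.
stratified_folds <- function(labels, k) {
  labels <- as.factor(labels)
  if (min(table(labels)) < k)
    stop_input("stratification impossible: smallest class has ",
               min(table(labels)), " members for ", k, " folds")
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

knn_inner_f1 <- function(D_by_band, train_idx, inner_fold, labels, cfg) {
  band <- as.character(cfg$band_radius)
  pred <- character(length(train_idx))
  for (v in sort(unique(inner_fold))) {
    q <- train_idx[inner_fold == v]
    tr <- train_idx[inner_fold != v]
    if (cfg$n_neighbors > length(tr)) return(-Inf)
    p <- knn_proba_from_dist(D_by_band[[band]][q, tr, drop = FALSE],
                             labels[tr], cfg)
    pred[inner_fold == v] <- argmax_class(p, colnames(p))
  }
  weighted_f1(as.character(labels[train_idx]), pred, levels(labels))
}

bossvs_inner_f1 <- function(X, train_idx, inner_fold, labels, cfg) {
  if (cfg$window_size > ncol(X)) return(-Inf)
  pred <- character(length(train_idx))
  for (v in sort(unique(inner_fold))) {
    q <- train_idx[inner_fold == v]
    tr <- train_idx[inner_fold != v]
    m <- bossvs_fit(X[tr, , drop = FALSE], labels[tr], cfg)
    p <- bossvs_predict_proba(m, X[q, , drop = FALSE])
    pred[inner_fold == v] <- argmax_class(p, colnames(p))
  }
  weighted_f1(as.character(labels[train_idx]), pred, levels(labels))
}

#' Nested stratified cross-validation of the blended trace classifier
#'
#' Outer stratified K-fold (default 5, always capped by the smallest class
#' size) estimates generalization; within each outer training split an
#' inner stratified CV (default up to 3 folds) tunes the k-NN and BOSSVS
#' hyperparameters by weighted F1, out-of-fold probability matrices from
#' the selected base models (refit on inner training splits only) are used
#' to tune the blending weight, and the blended model refit on the full
#' outer-training split is scored on the held-out fold. Pairwise DTW
#' distances are precomputed per band radius (they involve no label
#' information, so this is leakage-free); all label-dependent fitting,
#' including SFA breakpoint learning, happens strictly inside training
#' splits. Fully deterministic for a given `seed`.
#'
#' @param traces Matrix (rows = preprocessed traces) or list of
#'   equal-length numeric vectors.
#' @param labels Class labels, one per trace.
#' @param knn_grid,bossvs_grid Lists of candidate configurations; defaults
#'   [default_knn_grid()] and [default_bossvs_grid()].
#' @param outer_folds,inner_folds Requested fold counts; both are capped by
#'   the smallest class size of the split they act on.
#' @param omega_grid Candidate ensemble weights.
#' @param group Optional grouping vector (e.g. compound id); when supplied,
#'   all traces of a group are kept in the same outer fold.
#' @param seed Integer seed controlling fold assignment.
#' @return An object of class `cv_report`: `per_fold` data frame (metrics,
#'   chosen hyperparameters and weight per fold), `pooled` out-of-fold
#'   metrics with confusion matrix and one-vs-rest ROC/AUC, `predictions`,
#'   and the `seed`.
#' @export
nested_cv <- function(traces, labels,
                      knn_grid = default_knn_grid(),
                      bossvs_grid = default_bossvs_grid(),
                      outer_folds = 5, inner_folds = 3,
                      omega_grid = seq(0, 1, by = 0.05),
                      group = NULL, seed = 42) {
  X <- as_trace_matrix(traces)
  labels <- as.factor(labels)
  if (length(labels) != nrow(X))
    stop_input("'labels' must match the number of traces")
  outer_k <- min(outer_folds, min(table(labels)))
  if (outer_k < 2)
    stop_input("stratification impossible: smallest class has ",
               min(table(labels)), " trace(s)")
  with_local_seed(seed, {
    fold <- if (is.null(group)) {
      stratified_folds(labels, outer_k)
    } else {
      grp <- split(seq_along(labels), group)
      grp_label <- vapply(grp, function(i) as.character(labels[i][1]),
                          character(1))
      gf <- stratified_folds(factor(grp_label, levels(labels)), outer_k)
      f <- integer(length(labels))
      for (g in seq_along(grp)) f[grp[[g]]] <- gf[g]
      f
    }

    bands <- unique(vapply(knn_grid, `[[`, numeric(1), "band_radius"))
    D_by_band <- lapply(bands, function(b) dtw_pairwise_cpp(X, b))
    names(D_by_band) <- as.character(bands)

    all_pred <- character(length(labels))
    all_proba <- matrix(NA_real_, length(labels), nlevels(labels),
                        dimnames = list(NULL, levels(labels)))
    per_fold <- vector("list", outer_k)

    for (of in seq_len(outer_k)) {
      train_idx <- which(fold != of)
      test_idx <- which(fold == of)
      inner_k <- min(inner_folds, min(table(labels[train_idx])))
      if (inner_k < 2)
        stop_input("inner stratification impossible in outer fold ", of)
      inner_fold <- stratified_folds(labels[train_idx], inner_k)

      knn_f1 <- vapply(knn_grid, function(cfg)
        knn_inner_f1(D_by_band, train_idx, inner_fold, labels, cfg),
        numeric(1))
      knn_cfg <- knn_grid[[which.max(knn_f1)]]
      boss_f1 <- vapply(bossvs_grid, function(cfg)
        bossvs_inner_f1(X, train_idx, inner_fold, labels, cfg), numeric(1))
      boss_cfg <- bossvs_grid[[which.max(boss_f1)]]

      # out-of-fold probabilities from the selected configurations,
      # refitting on inner training splits only
      n_tr <- length(train_idx)
      oof_knn <- matrix(NA_real_, n_tr, nlevels(labels))
      oof_boss <- matrix(NA_real_, n_tr, nlevels(labels))
      colnames(oof_knn) <- colnames(oof_boss) <- levels(labels)
      band <- as.character(knn_cfg$band_radius)
      for (v in seq_len(inner_k)) {
        q <- train_idx[inner_fold == v]
        tr <- train_idx[inner_fold != v]
        oof_knn[inner_fold == v, ] <- knn_proba_from_dist(
          D_by_band[[band]][q, tr, drop = FALSE], labels[tr], knn_cfg)
        m <- bossvs_fit(X[tr, , drop = FALSE], labels[tr], boss_cfg)
        oof_boss[inner_fold == v, ] <-
          bossvs_predict_proba(m, X[q, , drop = FALSE])
      }
      omega <- tune_weight(oof_knn, oof_boss, labels[train_idx],
                           grid = omega_grid)

      # refit on the full outer-training split, score the held-out fold
      p_knn <- knn_proba_from_dist(
        D_by_band[[band]][test_idx, train_idx, drop = FALSE],
        labels[train_idx], knn_cfg)
      m_full <- bossvs_fit(X[train_idx, , drop = FALSE],
                           labels[train_idx], boss_cfg)
      p_boss <- bossvs_predict_proba(m_full, X[test_idx, , drop = FALSE])
      p_ens <- blend(p_knn, p_boss, omega)
      pred <- argmax_class(p_ens, colnames(p_ens))
      all_pred[test_idx] <- pred
      all_proba[test_idx, ] <- p_ens

      met <- classification_metrics(labels[test_idx], pred)
      per_fold[[of]] <- data.frame(
        fold = of,
        accuracy = met$accuracy,
        balanced_accuracy = met$balanced_accuracy,
        precision_weighted = met$precision_weighted,
        recall_weighted = met$recall_weighted,
        f1_weighted = met$f1_weighted,
        omega = omega,
        knn_k = knn_cfg$n_neighbors,
        knn_weighting = knn_cfg$vote_weighting,
        knn_band = knn_cfg$band_radius,
        boss_window = boss_cfg$window_size,
        boss_word_length = boss_cfg$word_length,
        boss_bins = boss_cfg$n_bins,
        stringsAsFactors = FALSE)
    }

    pooled <- classification_metrics(labels, all_pred, all_proba)
    structure(list(per_fold = do.call(rbind, per_fold),
                   pooled = pooled,
                   predictions = data.frame(
                     true = as.character(labels), predicted = all_pred,
                     fold = fold, stringsAsFactors = FALSE),
                   probabilities = all_proba,
                   outer_folds = outer_k, inner_folds = inner_folds,
                   seed = seed),
              class = "cv_report")
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Nested stratified CV (", x$outer_folds, " outer folds, seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf(
    "pooled: accuracy %.3f  balanced accuracy %.3f  F1_weighted %.3f\n",
    x$pooled$accuracy, x$pooled$balanced_accuracy, x$pooled$f1_weighted))
  cat("per-fold accuracy:",
      paste(sprintf("%.2f", x$per_fold$accuracy), collapse = " "), "\n")
  cat("chosen omega per fold:",
      paste(sprintf("%.2f", x$per_fold$omega), collapse = " "), "\n")
  invisible(x)
}
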