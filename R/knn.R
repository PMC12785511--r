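#' Configuration of the DTW k-nearest-neighbour classifier
#'
#' @param n_neighbors Number of neighbours (>= 1).
#' @param vote_weighting `"uniform"` (vote fractions) or
#'   `"inverse_distance"` (votes weighted by 1/distance; exact matches at
#'   distance zero share all the weight).
#' @param band_radius Sakoe-Chiba band half-width in samples for the DTW
#'   distance.
#' @return An object of class `knn_config`.
#' @export
knn_config <- function(n_neighbors = 3,
                       vote_weighting = c("uniform", "inverse_distance"),
                       band_radius = 10) {
  vote_weighting <- match.arg(vote_weighting)
  if (n_neighbors < 1) stop_input("'n_neighbors' must be >= 1")
  if (band_radius < 0) stop_input("'band_radius' must be >= 0")
  structure(list(n_neighbors = as.integer(n_neighbors),
                 vote_weighting = vote_weighting,
                 band_radius = band_radius),
            class = "knn_config")
}

# class probabilities from a query-by-train distance matrix.
# dmat: nq x ntrain; labels: factor of length ntrain whose levels define the
# label set. Ties in neighbour distance resolve by stable input order.
knn_proba_from_dist <- function(dmat, labels, cfg) {
  labels <- as.factor(labels)
  k <- cfg$n_neighbors
  usable <- rowSums(is.finite(dmat))
  if (any(usable < k))
    stop_input("n_neighbors = ", k, " exceeds the ", min(usable),
               " usable training samples")
  probs <- t(apply(dmat, 1, function(d) {
    ord <- order(d)[seq_len(k)]
    dd <- d[ord]
    cls <- labels[ord]
    w <- if (cfg$vote_weighting == "uniform") {
      rep(1, k)
    } else if (any(dd == 0)) {
      as.numeric(dd == 0)
    } else {
      1 / dd
    }
    p <- tapply(w, cls, sum, default = 0)
    p / sum(p)
  }))
  colnames(probs) <- levels(labels)
  probs
}

#' DTW k-NN class probabilities for query traces
#'
#' Votes (optionally inverse-distance weighted) over the `n_neighbors`
#' training traces nearest to each query under the band-constrained DTW
#' distance. With `exclude_self = TRUE`, one training sample identical to
#' the query is removed from its neighbour set (leave-one-out logic that
#' avoids trivial self-matches when scoring training data).
#'
#' @param train Matrix of training traces (one row each, equal length) or a
#'   list of equal-length numeric vectors.
#' @param labels Class labels for the training rows; a factor's levels fix
#'   the label set.
#' @param query A single trace, a matrix of traces (rows), or a list.
#' @param cfg A [knn_config()].
#' @param exclude_self Drop one exact-duplicate training sample per query.
#' @return Matrix of class probabilities (queries x classes), rows sum to 1.
#' @export
knn_predict_proba <- function(train, labels, query, cfg = knn_config(),
                              exclude_self = FALSE) {
  train <- as_trace_matrix(train)
  query <- as_trace_matrix(query, width = ncol(train))
  labels <- as.factor(labels)
  if (length(labels) != nrow(train))
    stop_input("'labels' must match the number of training traces")
  dmat <- dtw_cross_cpp(query, train, cfg$band_radius)
  if (exclude_self) {
    for (i in seq_len(nrow(query))) {
      hit <- which(dmat[i, ] == 0 &
                     apply(train, 1, identical, y = query[i, ]))
      if (length(hit)) dmat[i, hit[1]] <- Inf
    }
  }
  knn_proba_from_dist(dmat, labels, cfg)
}

as_trace_matrix <- function(x, width = NULL) {
  if (is.list(x)) {
    len <- unique(lengths(x))
    if (length(len) != 1L)
      stop_input("traces must have equal length")
    x <- do.call(rbind, x)
  } else if (!is.matrix(x)) {
    x <- matrix(x, nrow = 1)
  }
  if (!is.null(width) && ncol(x) != width)
    stop_input("query length ", ncol(x), " differs from training length ",
               width)
  x
}
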