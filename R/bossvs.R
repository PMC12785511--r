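#' Configuration of the BOSSVS classifier
#'
#' @param window_size Sliding-window length in samples.
#' @param word_length Number of real-valued Fourier components kept per
#'   window (must not exceed `window_size`).
#' @param n_bins Alphabet size for per-coefficient quantization (>= 2).
#' @return An object of class `bossvs_config`.
#' @export
bossvs_config <- function(window_size = 64, word_length = 6, n_bins = 4) {
  if (word_length > window_size)
    stop_input("'word_length' must not exceed 'window_size'")
  if (n_bins < 2) stop_input("'n_bins' must be >= 2")
  if (word_length < 1 || window_size < 4)
    stop_input("invalid window/word configuration")
  structure(list(window_size = as.integer(window_size),
                 word_length = as.integer(word_length),
                 n_bins = as.integer(n_bins)),
            class = "bossvs_config")
}

# Symbolic Fourier Approximation features: one row per sliding window
# (stride 1), columns are the first word_length real-valued components
# (interleaved real/imaginary parts of the low-frequency Fourier
# coefficients, DC excluded -- it is zero after per-window normalization).
sfa_features <- function(x, cfg) {
  w <- cfg$window_size
  if (w > length(x))
    stop_input("window_size ", w, " exceeds series length ", length(x))
  n_win <- length(x) - w + 1L
  idx <- outer(seq_len(w) - 1L, seq_len(n_win) - 1L, "+") + 1L
  W <- matrix(x[idx], nrow = w)
  mu <- colMeans(W)
  s <- sqrt(colMeans(W^2) - mu^2)
  s[s == 0] <- Inf  # constant window -> all-zero features
  W <- sweep(sweep(W, 2, mu, "-"), 2, s, "/")
  nc <- ceiling(cfg$word_length / 2)
  Fc <- mvfft(W)[1L + seq_len(nc), , drop = FALSE]
  feats <- matrix(0, nrow = n_win, ncol = 2 * nc)
  feats[, seq(1, 2 * nc, by = 2)] <- t(Re(Fc))
  feats[, seq(2, 2 * nc, by = 2)] <- t(Im(Fc))
  feats[, seq_len(cfg$word_length), drop = FALSE]
}

# per-coefficient quantile breakpoints learned from training windows;
# returns (n_bins - 1) x word_length matrix
sfa_breakpoints <- function(feature_matrix, n_bins) {
  probs <- seq_len(n_bins - 1) / n_bins
  apply(feature_matrix, 2, quantile, probs = probs, names = FALSE)
}

#' SFA word sequence of a series
#'
#' Slides a window (stride 1) over the series, z-normalizes each window,
#' keeps the first `word_length` real-valued Fourier components, quantizes
#' each component into `n_bins` letters with the supplied per-coefficient
#' breakpoints, and concatenates letters into words. Consecutive duplicate
#' words are collapsed (numerosity reduction), so amplitude-scaled copies of
#' a series map to identical word sequences.
#'
#' @param x Numeric series.
#' @param cfg A [bossvs_config()].
#' @param breakpoints `(n_bins - 1) x word_length` matrix of bin edges, as
#'   learned by [bossvs_fit()].
#' @return Character vector of words.
#' @export
sfa_words <- function(x, cfg, breakpoints) {
  feats <- sfa_features(x, cfg)
  breakpoints <- matrix(breakpoints, ncol = cfg$word_length)
  sym <- vapply(seq_len(ncol(feats)), function(j)
    findInterval(feats[, j], breakpoints[, j]), integer(nrow(feats)))
  sym <- matrix(letters[sym + 1L], nrow = nrow(feats))
  words <- apply(sym, 1, paste0, collapse = "")
  rle(words)$values
}

word_counts <- function(words) {
  tab <- table(words)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Fit a BOSSVS model
#'
#' Learns per-coefficient quantile breakpoints from all training windows,
#' converts every training series to SFA word counts, sums counts per
#' class, and weights them by an inverse document frequency over classes,
#' `idf(t) = log(1 + C / df(t))` with `df(t)` the number of classes whose
#' corpus contains word `t`. Words occurring in every class receive the
#' minimal weight.
#'
#' @param train Matrix (rows = traces) or list of equal-length traces.
#' @param labels Class labels; every factor level must be represented.
#' @param cfg A [bossvs_config()].
#' @return An object of class `bossvs_model` with the learned breakpoints,
#'   vocabulary and per-class tf-idf vectors.
#' @export
bossvs_fit <- function(train, labels, cfg = bossvs_config()) {
  train <- as_trace_matrix(train)
  labels <- as.factor(labels)
  if (length(labels) != nrow(train))
    stop_input("'labels' must match the number of training traces")
  if (any(table(labels) == 0))
    stop_input("every class must be represented in the training set")
  feats <- do.call(rbind, lapply(seq_len(nrow(train)), function(i)
    sfa_features(train[i, ], cfg)))
  bp <- sfa_breakpoints(feats, cfg$n_bins)
  counts <- lapply(seq_len(nrow(train)), function(i)
    word_counts(sfa_words(train[i, ], cfg, bp)))
  vocab <- sort(unique(unlist(lapply(counts, names))))
  tf <- matrix(0, nrow = nlevels(labels), ncol = length(vocab),
               dimnames = list(levels(labels), vocab))
  for (i in seq_along(counts))
    tf[as.integer(labels[i]), names(counts[[i]])] <-
      tf[as.integer(labels[i]), names(counts[[i]])] + counts[[i]]
  df <- colSums(tf > 0)
  idf <- log(1 + nlevels(labels) / df)
  structure(list(cfg = cfg, breakpoints = bp, vocab = vocab,
                 idf = idf, class_vectors = sweep(tf, 2, idf, "*"),
                 label_set = levels(labels)),
            class = "bossvs_model")
}

#' BOSSVS class pseudo-probabilities for a series
#'
#' Cosine similarity between the query's term-frequency vector (over the
#' training vocabulary) and each class tf-idf vector, clipped at zero and
#' normalized to sum to one. If every similarity is zero (word-disjoint
#' query) the distribution is uniform. The vector-space model natively
#' yields similarities, not probabilities; this normalization makes them
#' blendable with k-NN vote fractions.
#'
#' @param model A `bossvs_model`.
#' @param x A single trace, matrix of traces (rows), or list.
#' @return Matrix of class probabilities (queries x classes).
#' @export
bossvs_predict_proba <- function(model, x) {
  if (!inherits(model, "bossvs_model"))
    stop_input("'model' must be a fitted bossvs_model")
  x <- as_trace_matrix(x)
  cv <- model$class_vectors
  cnorm <- sqrt(rowSums(cv^2))
  probs <- t(vapply(seq_len(nrow(x)), function(i) {
    cnt <- word_counts(sfa_words(x[i, ], model$cfg, model$breakpoints))
    cnt <- cnt[names(cnt) %in% model$vocab]
    q <- stats::setNames(numeric(length(model$vocab)), model$vocab)
    q[names(cnt)] <- cnt
    qn <- sqrt(sum(q^2))
    sim <- if (qn == 0) numeric(nrow(cv)) else
      pmax(0, drop(cv %*% q) / (cnorm * qn))
    if (sum(sim) == 0) rep(1 / length(sim), length(sim)) else sim / sum(sim)
  }, numeric(nrow(cv))))
  colnames(probs) <- model$label_set
  probs
}
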