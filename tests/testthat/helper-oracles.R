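# Independent oracles used to check the implementation's fast paths.

# DTW by explicit enumeration of all monotone warping paths (with an
# admissible cost cut-off, exact for non-negative point costs).
dtw_bruteforce <- function(x, y, band = Inf) {
  n <- length(x)
  m <- length(y)
  best <- Inf
  recurse <- function(i, j, acc) {
    if (abs(i - j) > band) return(invisible())
    acc <- acc + (x[i] - y[j])^2
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  sqrt(best)
}

# naive sliding-window SFA: plain loops, stats::fft per window
sfa_words_naive <- function(x, window, word_length, breakpoints) {
  n_win <- length(x) - window + 1
  words <- character(n_win)
  for (s in seq_len(n_win)) {
    win <- x[s:(s + window - 1)]
    mu <- mean(win)
    sdv <- sqrt(mean((win - mu)^2))
    win <- if (sdv == 0) rep(0, window) else (win - mu) / sdv
    f <- stats::fft(win)
    vals <- numeric(0)
    k <- 2
    while (length(vals) < word_length) {
      vals <- c(vals, Re(f[k]), Im(f[k]))
      k <- k + 1
    }
    vals <- vals[seq_len(word_length)]
    syms <- vapply(seq_len(word_length), function(j)
      findInterval(vals[j], breakpoints[, j]), integer(1))
    words[s] <- paste0(letters[syms + 1L], collapse = "")
  }
  rle(words)$values
}

# support-weighted F1 written independently of the package's version
weighted_f1_oracle <- function(y_true, y_pred, classes) {
  total <- 0
  for (cl in classes) {
    tp <- sum(y_true == cl & y_pred == cl)
    prec <- if (sum(y_pred == cl) == 0) 0 else tp / sum(y_pred == cl)
    rec <- if (sum(y_true == cl) == 0) 0 else tp / sum(y_true == cl)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    total <- total + f1 * sum(y_true == cl)
  }
  total / length(y_true)
}

# small well-separated trace fixture reused across classifier tests
small_trace_fixture <- function(n_per_class = c(9, 9, 9), seed = 11) {
  sim <- simulate_dataset(n_per_class, seed = seed)
  prep <- t(apply(sim$traces, 1, preprocess_trace, trim_n = 100))
  list(X = prep, labels = sim$labels, manifest = sim$manifest)
}

tiny_knn_grid <- function() default_knn_grid(n_neighbors = c(1, 3),
                                             vote_weighting = "uniform",
                                             band_radius = 10)
tiny_bossvs_grid <- function() default_bossvs_grid(window_size = 64,
                                                   word_length = c(4, 6),
                                                   n_bins = 3)
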