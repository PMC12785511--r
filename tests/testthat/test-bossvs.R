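# two-class fixture with class-specific dominant frequencies: slow versus
# fast sinusoids plus mild noise
sinusoid_fixture <- function(n_per_class = 6, len = 120, seed = 5) {
  set.seed(seed)
  t <- seq_len(len)
  make <- function(freq) t(vapply(seq_len(n_per_class), function(i)
    sin(2 * pi * freq * t / len + runif(1, 0, pi)) + rnorm(len, sd = 0.05),
    numeric(len)))
  X <- rbind(make(2), make(11))
  list(X = X, labels = factor(rep(c("slow", "fast"), each = n_per_class),
                              levels = c("slow", "fast")))
}

test_that("a constant series collapses to a single word", {
  cfg <- bossvs_config(window_size = 8, word_length = 4, n_bins = 3)
  bp <- matrix(c(-0.5, 0.5), nrow = 2, ncol = 4)
  words <- sfa_words(rep(3.2, 30), cfg, bp)
  expect_length(words, 1L)
})

test_that("SFA words match a naive sliding-window oracle", {
  set.seed(31)
  cfg <- bossvs_config(window_size = 8, word_length = 4, n_bins = 3)
  fx <- sinusoid_fixture(3, len = 20, seed = 31)
  model <- bossvs_fit(fx$X, fx$labels, cfg)
  for (i in seq_len(nrow(fx$X))) {
    expect_equal(sfa_words(fx$X[i, ], cfg, model$breakpoints),
                 sfa_words_naive(fx$X[i, ], 8, 4, model$breakpoints))
  }
  # a second configuration with an odd word length
  cfg2 <- bossvs_config(window_size = 10, word_length = 5, n_bins = 4)
  m2 <- bossvs_fit(fx$X, fx$labels, cfg2)
  x <- rnorm(25)
  expect_equal(sfa_words(x, cfg2, m2$breakpoints),
               sfa_words_naive(x, 10, 5, m2$breakpoints))
})

test_that("per-window normalization makes words amplitude-invariant", {
  cfg <- bossvs_config(window_size = 16, word_length = 4, n_bins = 3)
  fx <- sinusoid_fixture(3, seed = 9)
  model <- bossvs_fit(fx$X, fx$labels, cfg)
  x <- fx$X[1, ]
  expect_identical(sfa_words(x, cfg, model$breakpoints),
                   sfa_words(7.5 * x, cfg, model$breakpoints))
})

test_that("idf down-weights words shared by all classes", {
  # overlapping classes: same base waveform, one class adds a mild trend,
  # so much of the vocabulary is common to both corpora
  set.seed(6)
  t <- seq_len(120)
  base <- function() sin(2 * pi * 3 * t / 120 + runif(1, 0, pi)) +
    rnorm(120, sd = 0.05)
  X <- rbind(t(replicate(6, base())),
             t(replicate(6, base() + 0.004 * t)))
  fx <- list(X = X, labels = factor(rep(c("slow", "fast"), each = 6),
                                    levels = c("slow", "fast")))
  model <- bossvs_fit(fx$X, fx$labels, bossvs_config(16, 4, 3))
  df <- colSums(model$class_vectors > 0)
  shared <- names(model$idf)[df == nlevels(fx$labels)]
  expect_gt(length(shared), 0L)
  # words in every class corpus get the smallest possible weight log(1 + 1)
  expect_equal(unname(model$idf[shared]), rep(log(2), length(shared)))
  expect_true(all(model$idf >= log(2)))
})

test_that("classes with disjoint dominant frequencies separate cleanly", {
  fx <- sinusoid_fixture(6)
  cfg <- bossvs_config(window_size = 16, word_length = 4, n_bins = 3)
  model <- bossvs_fit(fx$X, fx$labels, cfg)
  # top-weighted words of the two class vectors are disjoint
  top_words <- function(cls) {
    v <- model$class_vectors[cls, ]
    names(sort(v, decreasing = TRUE))[seq_len(5)]
  }
  expect_length(intersect(top_words("slow"), top_words("fast")), 0L)
  # training series are assigned to their own class
  p <- bossvs_predict_proba(model, fx$X)
  pred <- colnames(p)[apply(p, 1, which.max)]
  expect_equal(pred, as.character(fx$labels))
})

test_that("refitting the same data is deterministic", {
  fx <- sinusoid_fixture(4)
  cfg <- bossvs_config(16, 4, 3)
  m1 <- bossvs_fit(fx$X, fx$labels, cfg)
  m2 <- bossvs_fit(fx$X, fx$labels, cfg)
  expect_identical(m1$breakpoints, m2$breakpoints)
  expect_identical(m1$class_vectors, m2$class_vectors)
})

test_that("prediction falls back to uniform for word-disjoint queries and
           always normalizes", {
  fx <- sinusoid_fixture(4)
  model <- bossvs_fit(fx$X, fx$labels, bossvs_config(16, 4, 3))
  # force a vocabulary mismatch: the query can share no words
  blind <- model
  blind$vocab <- paste0("zz", model$vocab)
  colnames(blind$class_vectors) <- blind$vocab
  names(blind$idf) <- blind$vocab
  p <- bossvs_predict_proba(blind, fx$X[1, ])
  expect_equal(drop(p), c(slow = 0.5, fast = 0.5))
  # normalization property on random series
  set.seed(12)
  Q <- matrix(rnorm(20 * 120), nrow = 20)
  p <- bossvs_predict_proba(model, Q)
  expect_equal(rowSums(p), rep(1, 20))
  expect_true(all(p >= 0))
})

test_that("training-set and configuration guards fire", {
  fx <- sinusoid_fixture(3)
  one_class <- fx$labels
  one_class[] <- "slow"
  expect_error(bossvs_fit(fx$X, one_class, bossvs_config(16, 4, 3)),
               "every class")
  expect_error(bossvs_fit(fx$X[, 1:10], fx$labels, bossvs_config(16, 4, 3)),
               "exceeds series length")
  expect_error(bossvs_config(window_size = 8, word_length = 16), "exceed")
  expect_error(bossvs_config(n_bins = 1), "n_bins")
})
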