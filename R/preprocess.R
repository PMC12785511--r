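#' Preprocess a raw electropherogram trace
#'
#' Standard cleanup before whole-trace classification: non-numeric entries
#' are coerced to NA and removed, the first `trim_n` points are dropped to
#' suppress the injection/early-baseline artifact, and the remainder is
#' z-normalized per sample (mean 0, population SD 1) to remove between-run
#' baseline and scale effects without altering within-run morphology.
#'
#' @param raw Numeric (or character-coercible) vector of amplitudes.
#' @param trim_n Number of leading points to drop (default 100).
#' @return Numeric vector: the cleaned, trimmed, z-normalized trace.
#' @examples
#' preprocess_trace(c(1, 2, 3), trim_n = 0)
#' @export
preprocess_trace <- function(raw, trim_n = 100) {
  x <- suppressWarnings(as.numeric(raw))
  x <- x[is.finite(x)]
  if (length(x) <= trim_n + 2)
    stop_input("trace too short: ", length(x), " usable points with trim_n = ",
               trim_n)
  if (trim_n > 0) x <- x[-seq_len(trim_n)]
  znorm(x)
}

# z-normalization with population SD; constant input maps to zeros
znorm <- function(x, warn = TRUE) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    if (warn) warning("constant trace: z-normalization returns all zeros",
                      call. = FALSE)
    return(rep(0, length(x)))
  }
  (x - mean(x)) / s
}

#' Map log BB to a three-level CNS-permeability class
#'
#' Class 0: poor CNS permeability (log BB <= `low_cut`); class 1: moderate
#' (`low_cut` < log BB < `high_cut`); class 2: good (log BB >= `high_cut`).
#' Default cut-offs -1 and 0.3.
#'
#' @param logbb Numeric vector of log BB values (finite).
#' @param low_cut,high_cut Class boundaries, `low_cut < high_cut`.
#' @return Integer class indices in `{0, 1, 2}`.
#' @examples
#' label_from_logbb(c(-1.3, 0, 1.3))
#' @export
label_from_logbb <- function(logbb, low_cut = -1, high_cut = 0.3) {
  if (low_cut >= high_cut) stop_input("'low_cut' must be below 'high_cut'")
  if (!is.numeric(logbb) || any(!is.finite(logbb)))
    stop_input("'logbb' must be finite")
  ifelse(logbb <= low_cut, 0L, ifelse(logbb >= high_cut, 2L, 1L))
}

#' Dynamic time warping distance with a Sakoe-Chiba band
#'
#' Minimal cumulative squared-difference cost over monotone warping paths
#' restricted to `|i - j| <= band_radius`, square-rooted. Symmetric, zero
#' iff the sequences are identical, and never below the unconstrained DTW
#' distance. For unequal lengths the band must be at least the length
#' difference for a path to exist.
#'
#' @param x,y Non-empty numeric sequences.
#' @param band_radius Band half-width in samples (`Inf` = unconstrained).
#' @return The DTW distance.
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2, 2))
#' @export
dtw_distance <- function(x, y, band_radius = Inf) {
  if (length(x) < 1L || length(y) < 1L)
    stop_input("sequences must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_input("sequences must be finite")
  if (!is.numeric(band_radius) || length(band_radius) != 1L ||
      band_radius < 0)
    stop_input("'band_radius' must be a single non-negative number")
  dtw_dist_cpp(as.numeric(x), as.numeric(y), band_radius)
}
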