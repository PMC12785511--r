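#' Configuration of the electropherogram simulator
#'
#' Emulates the structure of a detector trace from a coated-capillary CEC
#' run: a flat baseline with slow linear drift and Gaussian noise, a sharp
#' injection artifact inside the first `artifact_span` samples (so the
#' default preprocessing trim provably removes it), and one dominant
#' Gaussian analyte peak whose position and width distributions depend on
#' the permeability class. With the default 400-sample trace standing for
#' an 11-minute run, the class peak windows fall inside the 3-11 min
#' migration range. Replicates of a compound share a latent peak
#' position/width and differ by small jitter plus fresh noise.
#'
#' @param length Trace length in samples.
#' @param artifact_span Leading region (samples) containing the injection
#'   artifact; must be below `length`.
#' @param class_position,class_width Per-class mean peak positions and
#'   widths (samples), one value per class.
#' @param position_sd,width_sd Between-compound SD of the latent peak
#'   position and width.
#' @param replicate_jitter SD of the within-compound replicate shift.
#' @param peak_height Analyte peak amplitude.
#' @param noise_sd Additive Gaussian noise SD.
#' @param drift_slope Baseline drift per sample.
#' @param replicates Traces per simulated compound.
#' @return An object of class `trace_sim_config`.
#' @export
trace_sim_config <- function(length = 400, artifact_span = 100,
                             class_position = c(160, 230, 300),
                             class_width = c(7, 14, 26),
                             position_sd = 10, width_sd = 1.5,
                             replicate_jitter = 3,
                             peak_height = 6, noise_sd = 0.3,
                             drift_slope = 0.002, replicates = 3) {
  if (artifact_span >= length)
    stop_input("'artifact_span' must be smaller than 'length'")
  if (length(class_position) != length(class_width))
    stop_input("'class_position' and 'class_width' must have one value ",
               "per class")
  if (noise_sd < 0) stop_input("'noise_sd' must be >= 0")
  if (replicates < 1) stop_input("'replicates' must be >= 1")
  structure(list(length = as.integer(length),
                 artifact_span = as.integer(artifact_span),
                 class_position = class_position,
                 class_width = class_width,
                 position_sd = position_sd, width_sd = width_sd,
                 replicate_jitter = replicate_jitter,
                 peak_height = peak_height, noise_sd = noise_sd,
                 drift_slope = drift_slope,
                 replicates = as.integer(replicates)),
            class = "trace_sim_config")
}

# deterministic trace from explicit latent peak parameters
render_trace <- function(cfg, position, width, noisy = TRUE) {
  t <- seq_len(cfg$length)
  base <- 1 + cfg$drift_slope * t
  spike <- 0.8 * cfg$peak_height *
    exp(-0.5 * ((t - cfg$artifact_span * 0.3) / 2.5)^2)
  peak <- cfg$peak_height * exp(-0.5 * ((t - position) / width)^2)
  noise <- if (noisy && cfg$noise_sd > 0)
    rnorm(cfg$length, sd = cfg$noise_sd) else 0
  base + spike + peak + noise
}

#' Simulate a single electropherogram of a given permeability class
#'
#' @param class_index Class in `{0, 1, 2}` (or more, given a matching
#'   config).
#' @param cfg A [trace_sim_config()].
#' @param seed Optional seed; the draw is deterministic given it.
#' @param latent Optional list with `position` and `width` overriding the
#'   class-conditional draw (used for replicate groups).
#' @return List with `signal`, `class`, and the latent `position`, `width`.
#' @export
simulate_electropherogram <- function(class_index, cfg = trace_sim_config(),
                                      seed = NULL, latent = NULL) {
  nclass <- length(cfg$class_position)
  if (!class_index %in% (seq_len(nclass) - 1L))
    stop_input("'class_index' must be in 0..", nclass - 1)
  draw <- function() {
    if (is.null(latent)) {
      latent <- list(
        position = rnorm(1, cfg$class_position[class_index + 1L],
                         cfg$position_sd),
        width = max(2, rnorm(1, cfg$class_width[class_index + 1L],
                             cfg$width_sd)))
    }
    list(signal = render_trace(cfg, latent$position, latent$width),
         class = as.integer(class_index),
         position = latent$position, width = latent$width)
  }
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Simulate a labelled replicate-structured electropherogram dataset
#'
#' Compounds are assigned to classes; each compound draws a latent peak
#' position/width from its class distribution and contributes
#' `cfg$replicates` traces (the last compound of a class may contribute
#' fewer so the per-class trace counts are met exactly). Replicates share
#' the latent peak up to a small jitter and independent noise, mirroring
#' repeated measurements kept as independent samples.
#'
#' @param n_per_class Integer vector of trace counts per class.
#' @param cfg A [trace_sim_config()].
#' @param seed Seed making the dataset a pure function of
#'   `(n_per_class, cfg, seed)`.
#' @return List with `traces` (matrix, one row per trace), `labels`
#'   (integer classes) and `manifest` (trace id, compound id, class and the
#'   latent ground-truth peak parameters).
#' @export
simulate_dataset <- function(n_per_class, cfg = trace_sim_config(),
                             seed = 1) {
  if (any(n_per_class < 1))
    stop_input("'n_per_class' entries must be >= 1")
  if (length(n_per_class) != length(cfg$class_position))
    stop_input("'n_per_class' must have one count per configured class")
  with_local_seed(seed, {
    rows <- list()
    manifest <- list()
    cid <- 0L
    for (cl in seq_along(n_per_class) - 1L) {
      remaining <- n_per_class[cl + 1L]
      while (remaining > 0L) {
        cid <- cid + 1L
        latent <- list(
          position = rnorm(1, cfg$class_position[cl + 1L], cfg$position_sd),
          width = max(2, rnorm(1, cfg$class_width[cl + 1L], cfg$width_sd)))
        n_rep <- min(cfg$replicates, remaining)
        for (r in seq_len(n_rep)) {
          pos_r <- latent$position + rnorm(1, sd = cfg$replicate_jitter)
          rows[[length(rows) + 1L]] <- render_trace(cfg, pos_r, latent$width)
          manifest[[length(manifest) + 1L]] <- data.frame(
            trace_id = sprintf("trace_%04d", length(rows)),
            compound_id = sprintf("cmpd_%03d", cid),
            class = cl, replicate = r,
            peak_position = pos_r, peak_width = latent$width)
        }
        remaining <- remaining - n_rep
      }
    }
    manifest <- do.call(rbind, manifest)
    list(traces = do.call(rbind, rows),
         labels = manifest$class,
         manifest = manifest)
  })
}

#' Simulate cosolvent titration points from a known aqueous pKa
#'
#' Generates apparent pKa (psKa) readings along a chosen Yasuda-Shedlovsky
#' line that passes through the true aqueous pKa at the pure-water limit,
#' plus optional Gaussian noise, so the extrapolation can be tested against
#' known ground truth.
#'
#' @param true_pka True aqueous pKa.
#' @param noise_sd Gaussian noise SD on each psKa (default 0).
#' @param wt_percents Methanol contents (must have >= 2 distinct values
#'   inside the solvent-property table).
#' @param slope Slope of the generating line against the reciprocal
#'   dielectric constant (typical magnitude for drug-like protolytes).
#' @param seed Seed.
#' @param solvent_table Cosolvent property table.
#' @return Data frame with `methanol_wt_percent` and `pska`.
#' @export
simulate_titration <- function(true_pka, noise_sd = 0,
                               wt_percents = c(30, 40, 50), slope = 120,
                               seed = 1,
                               solvent_table = methanol_water_table()) {
  if (length(unique(wt_percents)) < 2L)
    stop_input("need >= 2 distinct methanol contents for extrapolation")
  props <- solvent_lookup(wt_percents, solvent_table)
  water <- solvent_lookup(0, solvent_table)
  intercept <- true_pka + log10(water$h2o) - slope / water$epsilon
  with_local_seed(seed, {
    pska <- intercept + slope / props$epsilon - log10(props$h2o) +
      rnorm(length(wt_percents), sd = noise_sd)
    data.frame(methanol_wt_percent = wt_percents, pska = pska)
  })
}

#' Simulate a compound table from a known log BB regression
#'
#' Draws predictors uniformly from ranges spanning the reference table
#' (k' in `[-0.05, 0.35]`, log D7.4 in `[-3, 6]`, pKa in `[2.5, 10.5]`) and
#' responses from the linear model plus Gaussian noise, for parameter- and
#' coverage-recovery studies.
#'
#' @param beta Length-4 coefficient vector (intercept, k', log D7.4, pKa).
#' @param noise_sd Residual SD.
#' @param n Number of records (> 4).
#' @param ranges Named list of predictor ranges.
#' @param seed Seed.
#' @return Data frame with `compound_id`, the three predictors and `logbb`.
#' @export
simulate_regression_data <- function(beta = c(-2.45, 0.1, 0.3, 0.27),
                                     noise_sd = 0.5, n = 57,
                                     ranges = list(k_prime = c(-0.05, 0.35),
                                                   logd74 = c(-3, 6),
                                                   pka = c(2.5, 10.5)),
                                     seed = 1) {
  if (length(beta) != 4L) stop_input("'beta' must have 4 coefficients")
  if (n <= 4L) stop_input("'n' must exceed the number of coefficients")
  with_local_seed(seed, {
    d <- data.frame(
      compound_id = sprintf("sim_%03d", seq_len(n)),
      k_prime = runif(n, ranges$k_prime[1], ranges$k_prime[2]),
      logd74 = runif(n, ranges$logd74[1], ranges$logd74[2]),
      pka = runif(n, ranges$pka[1], ranges$pka[2]))
    d$logbb <- beta[1] + beta[2] * d$k_prime + beta[3] * d$logd74 +
      beta[4] * d$pka + rnorm(n, sd = noise_sd)
    d
  })
}
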