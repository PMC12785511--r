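#' Capillary geometry for mobility calculations
#'
#' Describes the fused-silica capillary and applied voltage used to convert a
#' neutral-marker migration time into an electroosmotic mobility. Defaults
#' correspond to a 59.1 cm capillary (49 cm to the detector) run at 20 kV.
#'
#' @param total_length Total capillary length in metres.
#' @param effective_length Inlet-to-detector length in metres; must be
#'   shorter than `total_length`.
#' @param voltage Applied separation voltage in volts.
#' @return An object of class `capillary_geometry`.
#' @examples
#' capillary_geometry()
#' @export
capillary_geometry <- function(total_length = 0.591,
                               effective_length = 0.49,
                               voltage = 20000) {
  check_number(total_length, "total_length", positive = TRUE)
  check_number(effective_length, "effective_length", positive = TRUE)
  check_number(voltage, "voltage", positive = TRUE)
  if (effective_length >= total_length)
    stop_input("'effective_length' must be smaller than 'total_length'")
  structure(list(total_length = total_length,
                 effective_length = effective_length,
                 voltage = voltage),
            class = "capillary_geometry")
}

#' One compound's migration times in coated and uncoated capillary runs
#'
#' Bundles the four migration times entering the retention-factor formula:
#' analyte and electroosmotic-flow (EOF) marker times in the liposome-coated
#' capillary, and the same pair in the uncoated capillary. Times are stored
#' in seconds; pass `unit = "min"` when the instrument software reports
#' minutes.
#'
#' @param compound_id Compound identifier.
#' @param t_r,t_eof Analyte and EOF-marker migration times in the coated
#'   capillary.
#' @param t_r_unc,t_eof_unc The analogous times in the uncoated capillary.
#' @param unit `"s"` (default) or `"min"`.
#' @return An object of class `migration_record` (times in seconds).
#' @examples
#' migration_record("caffeine", t_r = 5.2, t_eof = 4.9,
#'                  t_r_unc = 4.3, t_eof_unc = 4.1, unit = "min")
#' @export
migration_record <- function(compound_id, t_r, t_eof, t_r_unc, t_eof_unc,
                             unit = c("s", "min")) {
  unit <- match.arg(unit)
  times <- list(t_r = t_r, t_eof = t_eof,
                t_r_unc = t_r_unc, t_eof_unc = t_eof_unc)
  for (nm in names(times)) {
    val <- times[[nm]]
    if (length(val) != 1L || !is.numeric(val) || is.na(val) ||
        !is.finite(val) || val <= 0)
      stop_input("migration time '", nm, "' must be a single positive ",
                 "finite number")
  }
  if (unit == "min") times <- lapply(times, function(t) t * 60)
  structure(c(list(compound_id = as.character(compound_id)), times),
            class = "migration_record")
}

#' CEC retention factor k' from coated and uncoated migration times
#'
#' For analytes that are ionized at the running pH, electrophoretic migration
#' dominates and the unretained time cannot be read off a single run; it is
#' reconstructed from the uncoated-capillary mobilities instead. The
#' retention factor is
#' \deqn{k' = t_R \left(\frac{1}{t_{EOF}} + \frac{1}{t_{R}'} -
#'   \frac{1}{t_{EOF}'}\right) - 1,}
#' equivalently \eqn{(t_R - t_0)/t_0} with
#' \eqn{t_0 = (1/t_{EOF} + 1/t_R' - 1/t_{EOF}')^{-1}}: the classical
#' retention factor with the hold-up time corrected for the analyte's own
#' electrophoretic mobility measured in the uncoated capillary. Values are
#' near zero for weakly retained drugs and may be slightly negative.
#'
#' @param rec A [migration_record()].
#' @return Dimensionless retention factor.
#' @examples
#' r <- migration_record("x", 320, 300, 260, 250)
#' retention_factor(r)
#' @export
retention_factor <- function(rec) {
  if (!inherits(rec, "migration_record"))
    stop_input("'rec' must be a migration_record")
  inv_t0 <- 1 / rec$t_eof + 1 / rec$t_r_unc - 1 / rec$t_eof_unc
  if (inv_t0 <= 0)
    stop_input("reconstructed hold-up time is non-positive for '",
               rec$compound_id, "': uncoated-run mobilities are physically ",
               "inconsistent with the coated run")
  rec$t_r * inv_t0 - 1
}

#' Electroosmotic mobility from a neutral-marker migration time
#'
#' \eqn{\mu_{EOF} = L_d L_t / (V t_{EOF})} where \eqn{L_d} is the effective
#' (inlet-to-detector) length, \eqn{L_t} the total length and \eqn{V} the
#' applied voltage.
#'
#' @param t_eof Neutral-marker migration time in seconds.
#' @param geom A [capillary_geometry()].
#' @return Mobility in m^2 s^-1 V^-1.
#' @examples
#' eof_mobility(250.1) # about 5.79e-8
#' @export
eof_mobility <- function(t_eof, geom = capillary_geometry()) {
  if (!inherits(geom, "capillary_geometry"))
    stop_input("'geom' must be a capillary_geometry")
  if (!is.numeric(t_eof) || any(!is.finite(t_eof)) || any(t_eof <= 0))
    stop_input("'t_eof' must be positive and finite")
  geom$effective_length * geom$total_length / (geom$voltage * t_eof)
}

#' Replicate summary: mean, standard deviation and RSD
#'
#' Sample standard deviation uses the n-1 denominator; with a single
#' replicate the SD is defined as 0 and flagged by `n = 1`. The relative
#' standard deviation is `100 * sd / |mean|`.
#'
#' @param values Numeric vector of replicate measurements (length >= 1).
#' @return A list with elements `mean`, `sd`, `rsd_percent` and `n`.
#' @examples
#' summarize_replicates(c(4, 6))
#' @export
summarize_replicates <- function(values) {
  if (length(values) < 1L || !is.numeric(values) || any(!is.finite(values)))
    stop_input("'values' must be a non-empty finite numeric vector")
  m <- mean(values)
  s <- if (length(values) == 1L) 0 else sd(values)
  if (m == 0)
    stop_input("relative standard deviation is undefined for zero mean")
  list(mean = m, sd = s, rsd_percent = 100 * s / abs(m),
       n = length(values))
}

#' Compare electroosmotic mobility between uncoated and coated capillaries
#'
#' Summarizes replicate mobilities per capillary variant and flags EOF
#' suppression (the signature of a successful liposome coating) when the
#' coated-capillary mean mobility falls below the uncoated one.
#'
#' @param uncoated,coated Numeric vectors of replicate mobilities
#'   (m^2 s^-1 V^-1) for the two capillary variants.
#' @return A list with `table` (one row per variant: mean, RSD%, n) and
#'   logical `suppressed`.
#' @examples
#' eof_suppression_report(uncoated = c(5.8e-8, 5.75e-8),
#'                        coated = c(4.7e-8, 4.66e-8))
#' @export
eof_suppression_report <- function(uncoated, coated) {
  su <- summarize_replicates(uncoated)
  sc <- summarize_replicates(coated)
  tab <- data.frame(
    variant = c("uncoated", "coated"),
    mean_mobility = c(su$mean, sc$mean),
    rsd_percent = c(su$rsd_percent, sc$rsd_percent),
    n = c(su$n, sc$n),
    stringsAsFactors = FALSE)
  list(table = tab, suppressed = sc$mean < su$mean)
}

#' Per-compound retention factors from a table of migration runs
#'
#' Takes one row per run (`compound_id`, `variant` in `{coated, uncoated}`,
#' `t_analyte`, `t_eof`, optional `unit` in `{s, min}`), pairs coated and
#' uncoated replicates of each compound by run order, and returns replicate
#' mean, SD (n-1) and count of k' per compound.
#'
#' @param runs A data frame of runs, or a path to a CSV file with the same
#'   columns.
#' @return Data frame with columns `compound_id`, `k_prime_mean`,
#'   `k_prime_sd`, `n`.
#' @export
kprime_table <- function(runs) {
  if (is.character(runs)) runs <- read.csv(runs, stringsAsFactors = FALSE)
  need <- c("compound_id", "variant", "t_analyte", "t_eof")
  miss <- setdiff(need, names(runs))
  if (length(miss))
    stop_input("runs table is missing column(s): ",
               paste(miss, collapse = ", "))
  if (!"unit" %in% names(runs)) runs$unit <- "s"
  bad <- !runs$variant %in% c("coated", "uncoated")
  if (any(bad))
    stop_input("unknown capillary variant in row(s) ",
               paste(which(bad), collapse = ", "))
  out <- lapply(split(runs, runs$compound_id), function(g) {
    co <- g[g$variant == "coated", , drop = FALSE]
    un <- g[g$variant == "uncoated", , drop = FALSE]
    n <- min(nrow(co), nrow(un))
    if (n < 1L)
      stop_input("compound '", g$compound_id[1],
                 "' lacks runs in one capillary variant")
    if (nrow(co) != nrow(un))
      warning("compound '", g$compound_id[1], "': unequal replicate counts; ",
              "pairing the first ", n, " runs of each variant",
              call. = FALSE)
    kp <- vapply(seq_len(n), function(i) {
      retention_factor(migration_record(
        g$compound_id[1],
        t_r = co$t_analyte[i], t_eof = co$t_eof[i],
        t_r_unc = un$t_analyte[i], t_eof_unc = un$t_eof[i],
        unit = co$unit[i]))
    }, numeric(1))
    data.frame(compound_id = g$compound_id[1],
               k_prime_mean = mean(kp),
               k_prime_sd = if (n == 1L) 0 else sd(kp),
               n = n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
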