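#' Methanol-water cosolvent properties at 25 degrees C
#'
#' Handbook constants used by the Yasuda-Shedlovsky extrapolation: relative
#' dielectric constant and molar water concentration for methanol-water
#' mixtures by weight percent methanol. Dielectric constants interpolate the
#' classical conductance-era measurements for methanol-water; water
#' concentrations follow from mixture densities. Pure water is taken as
#' epsilon = 78.3 and [H2O] = 55.3 M. Users with instrument-specific
#' constants can pass their own table to [yasuda_shedlovsky()].
#'
#' @return Data frame with columns `methanol_wt_percent`, `epsilon`,
#'   `h2o_molarity`.
#' @export
methanol_water_table <- function() {
  data.frame(
    methanol_wt_percent = c(0, 30, 40, 50),
    epsilon = c(78.3, 65.0, 60.9, 56.3),
    h2o_molarity = c(55.3, 36.9, 31.0, 25.3))
}

solvent_lookup <- function(wt, table) {
  rng <- range(table$methanol_wt_percent)
  if (any(wt < rng[1] | wt > rng[2]))
    stop_input("methanol wt% outside the solvent-property table range [",
               rng[1], ", ", rng[2], "]")
  list(
    epsilon = approx(table$methanol_wt_percent, table$epsilon, wt)$y,
    h2o = approx(table$methanol_wt_percent, table$h2o_molarity, wt)$y)
}

#' Aqueous pKa by Yasuda-Shedlovsky extrapolation
#'
#' Apparent pKa values (psKa) measured in methanol-water mixtures are
#' regressed, after adding log10 of the mixture's molar water concentration,
#' on the reciprocal dielectric constant:
#' \deqn{psK_a + \log_{10}[H_2O] = a + b/\varepsilon.}
#' The line is evaluated at pure water's \eqn{1/\varepsilon} and
#' \eqn{\log_{10} 55.3} is subtracted to give the aqueous pKa. The returned
#' standard error is the OLS standard error of the extrapolated line value
#' (NA with only two points, where the line has no residual degrees of
#' freedom).
#'
#' @param points Data frame with columns `methanol_wt_percent` and `pska`
#'   (>= 2 rows at distinct wt%).
#' @param solvent_table Cosolvent property table, by default
#'   [methanol_water_table()].
#' @return List with `pka`, `se`, and the underlying `fit` (an `lm`).
#' @examples
#' pts <- simulate_titration(true_pka = 9.1, noise_sd = 0, seed = 1)
#' yasuda_shedlovsky(pts)$pka
#' @export
yasuda_shedlovsky <- function(points, solvent_table = methanol_water_table()) {
  if (!all(c("methanol_wt_percent", "pska") %in% names(points)))
    stop_input("'points' needs columns 'methanol_wt_percent' and 'pska'")
  wt <- points$methanol_wt_percent
  if (length(unique(wt)) < 2L)
    stop_input("Yasuda-Shedlovsky extrapolation needs psKa at >= 2 ",
               "distinct methanol contents")
  props <- solvent_lookup(wt, solvent_table)
  water <- solvent_lookup(0, solvent_table)
  df <- data.frame(x = 1 / props$epsilon,
                   y = points$pska + log10(props$h2o))
  fit <- lm(y ~ x, data = df)
  pr <- predict(fit, newdata = data.frame(x = 1 / water$epsilon),
                se.fit = TRUE)
  se <- if (fit$df.residual > 0) unname(pr$se.fit) else NA_real_
  list(pka = unname(pr$fit) - log10(water$h2o), se = se, fit = fit)
}

#' log P from the octanol-induced pKa shift
#'
#' In a dual-phase potentiometric titration the partitioning of the neutral
#' species into octanol shifts the apparent pKa (poKa) away from the aqueous
#' value: upward for acids, downward for bases. With octanol/water volume
#' ratio `r`,
#' \deqn{\log P = \log_{10}\frac{10^{|poK_a - pK_a|} - 1}{r}.}
#'
#' @param pka_aq Aqueous pKa.
#' @param poka Apparent pKa in the presence of octanol.
#' @param phase_ratio Octanol-to-water volume ratio (> 0).
#' @param kind `"acid"` or `"base"`.
#' @return log P of the neutral species.
#' @examples
#' logp_from_shift(4.2, 6.2, phase_ratio = 1, kind = "acid") # log10(99)
#' @export
logp_from_shift <- function(pka_aq, poka, phase_ratio,
                            kind = c("acid", "base")) {
  kind <- match.arg(kind)
  check_number(pka_aq, "pka_aq")
  check_number(poka, "poka")
  check_number(phase_ratio, "phase_ratio", positive = TRUE)
  shift <- if (kind == "acid") poka - pka_aq else pka_aq - poka
  if (shift <= 0)
    stop_input("poKa shifted in the wrong direction for ", kind,
               ": no octanol partitioning detected")
  if (10^shift <= 1 + 1e-12)
    stop_input("poKa shift too small to resolve partitioning")
  log10((10^shift - 1) / phase_ratio)
}

#' Ionization profile of a drug-like protolyte
#'
#' @param compound_id Identifier.
#' @param kind One of `"monoprotic_acid"`, `"monoprotic_base"`,
#'   `"diprotic_acid"`, `"diprotic_base"`, `"ampholyte"`.
#' @param pka Numeric pKa value(s); one for monoprotic kinds, two otherwise.
#'   For an ampholyte the larger pKa is taken as the basic group and the
#'   smaller as the acidic group, the usual situation for drug ampholytes.
#' @return Object of class `protolyte_spec`.
#' @export
protolyte_spec <- function(compound_id, kind, pka) {
  kinds <- c("monoprotic_acid", "monoprotic_base",
             "diprotic_acid", "diprotic_base", "ampholyte")
  if (!kind %in% kinds)
    stop_input("unknown protolyte kind '", kind, "'")
  n_expected <- if (startsWith(kind, "monoprotic")) 1L else 2L
  if (length(pka) != n_expected)
    stop_input(kind, " needs ", n_expected, " pKa value(s), got ",
               length(pka))
  if (any(!is.finite(pka)) || any(pka <= 0) || any(pka >= 14))
    stop_input("pKa values must lie strictly between 0 and 14")
  structure(list(compound_id = as.character(compound_id), kind = kind,
                 pka = as.numeric(pka)),
            class = "protolyte_spec")
}

# ionized-to-neutral concentration ratio terms at a given pH, under the
# neutral-species-only partition model
ionization_terms <- function(spec, ph) {
  p <- spec$pka
  switch(spec$kind,
    monoprotic_acid = 10^(ph - p[1]),
    monoprotic_base = 10^(p[1] - ph),
    diprotic_acid = {
      ps <- sort(p)
      10^(ph - ps[1]) + 10^(2 * ph - ps[1] - ps[2])
    },
    diprotic_base = {
      ps <- sort(p, decreasing = TRUE)
      10^(ps[1] - ph) + 10^(ps[1] + ps[2] - 2 * ph)
    },
    ampholyte = 10^(ph - min(p)) + 10^(max(p) - ph))
}

#' Distribution coefficient log D at a given pH
#'
#' Under the assumption that only the neutral microspecies partitions into
#' octanol,
#' \deqn{\log D(pH) = \log P - \log_{10}\bigl(1 + \textstyle\sum_i
#'   R_i(pH)\bigr),}
#' where the \eqn{R_i} are ionized-to-neutral concentration ratios from the
#' compound's pKa value(s) (e.g. \eqn{10^{pH - pK_a}} for a monoprotic
#' acid). Compounds whose measured log D reflects ion-pair partitioning will
#' deviate from this model; see [logd_ion_pair_outliers].
#'
#' @param spec A [protolyte_spec()].
#' @param logp log P of the neutral species.
#' @param ph pH value(s), default 7.4.
#' @return log D at each requested pH.
#' @examples
#' logd_at_ph(protolyte_spec("amitriptyline", "monoprotic_base", 9.23),
#'            logp = 4.68)  # 2.84
#' @export
logd_at_ph <- function(spec, logp, ph = 7.4) {
  if (!inherits(spec, "protolyte_spec"))
    stop_input("'spec' must be a protolyte_spec")
  check_number(logp, "logp")
  if (!is.numeric(ph) || any(!is.finite(ph)))
    stop_input("'ph' must be finite")
  logp - log10(1 + ionization_terms(spec, ph))
}

#' Bjerrum curve: mean number of bound protons versus pH
#'
#' Computes \eqn{\bar n(pH)} from the compound's stepwise protonation
#' constants (the pKa values in decreasing order):
#' \deqn{\bar n = \frac{\sum_j j\,10^{\beta_j - j\,pH}}{1 + \sum_j
#'   10^{\beta_j - j\,pH}}, \qquad \beta_j = \sum_{i \le j} pK_{a,(i)}.}
#' The curve is monotonically non-increasing in pH and bounded by the proton
#' count; half-integer plateaus mark the pKa values, which is how dual-phase
#' titration shifts are read off graphically.
#'
#' @param spec A [protolyte_spec()].
#' @param ph Numeric vector of pH values.
#' @return Mean bound protons at each pH.
#' @examples
#' bjerrum_curve(protolyte_spec("promazine", "monoprotic_base", 9.39),
#'               ph = c(7.4, 9.39, 11))
#' @export
bjerrum_curve <- function(spec, ph) {
  if (!inherits(spec, "protolyte_spec"))
    stop_input("'spec' must be a protolyte_spec")
  if (length(ph) < 1L || any(!is.finite(ph)))
    stop_input("'ph' must be a non-empty finite vector")
  pk <- sort(spec$pka, decreasing = TRUE)
  beta <- cumsum(pk)
  vapply(ph, function(h) {
    terms <- 10^(beta - seq_along(beta) * h)
    sum(seq_along(beta) * terms) / (1 + sum(terms))
  }, numeric(1))
}

#' Compounds whose printed log D departs from the neutral-partition model
#'
#' Reference-table compounds for which the log D7.4 recomputed from the
#' printed pKa and log P under the neutral-species-only model differs from
#' the printed log D7.4 by more than 0.15. The instrument software that
#' produced the printed values can include ion-pair partitioning for
#' lipophilic ionized species, which this package deliberately does not
#' model; these compounds are therefore documented rather than force-fitted.
#'
#' @format Character vector of compound identifiers.
#' @export
logd_ion_pair_outliers <- c(
  "desipramine", "indomethacin", "ketorolac", "loperamide",
  "nortriptyline", "paroxetine", "salicylic acid")

#' Batch physicochemical derivation for a compound table
#'
#' Applies [logd_at_ph()] to every monoprotic row of a compound table
#' (columns `compound_id`, `pka`, `logp`, `protolyte`), returning the
#' computed log D alongside any printed value for comparison.
#'
#' @param compounds Data frame as returned by [load_compound_table()].
#' @param ph pH at which to evaluate log D (default 7.4).
#' @return Data frame with `compound_id`, `protolyte`, `logd_computed`, and
#'   `logd_printed` (NA when the input has no `logd74` column).
#' @export
logd_table <- function(compounds, ph = 7.4) {
  mono <- compounds[startsWith(compounds$protolyte, "monoprotic"), ,
                    drop = FALSE]
  ld <- vapply(seq_len(nrow(mono)), function(i) {
    logd_at_ph(protolyte_spec(mono$compound_id[i], mono$protolyte[i],
                              mono$pka[i]),
               logp = mono$logp[i], ph = ph)
  }, numeric(1))
  data.frame(compound_id = mono$compound_id,
             protolyte = mono$protolyte,
             logd_computed = ld,
             logd_printed = if ("logd74" %in% names(mono)) mono$logd74
                            else NA_real_,
             stringsAsFactors = FALSE)
}
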