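test_that("Yasuda-Shedlovsky extrapolation recovers generating lines", {
  # zero-slope line: both points share psKa + log[H2O] = c
  tab <- methanol_water_table()
  c0 <- 9
  pts <- data.frame(methanol_wt_percent = c(30, 50),
                    pska = c0 - log10(tab$h2o_molarity[tab$methanol_wt_percent
                                                       %in% c(30, 50)]))
  res <- yasuda_shedlovsky(pts)
  expect_equal(res$pka, c0 - log10(55.3), tolerance = 1e-10)
  # exactly collinear points reproduce the generating line's water intercept
  sim <- simulate_titration(true_pka = 7.8, noise_sd = 0, slope = 150)
  res <- yasuda_shedlovsky(sim)
  expect_equal(res$pka, 7.8, tolerance = 1e-10)
  expect_lt(res$se, 1e-8)
})

test_that("noisy cosolvent titrations recover the true pKa without bias
           and with the OLS-predicted extrapolation spread", {
  errs <- vapply(1:300, function(i) {
    sim <- simulate_titration(true_pka = 6.5, noise_sd = 0.02, seed = i)
    yasuda_shedlovsky(sim)$pka - 6.5
  }, numeric(1))
  # theoretical SD of the extrapolated line value at the pure-water limit
  tab <- methanol_water_table()
  x <- 1 / tab$epsilon[tab$methanol_wt_percent %in% c(30, 40, 50)]
  x0 <- 1 / 78.3
  se_theory <- 0.02 * sqrt(1 / 3 + (x0 - mean(x))^2 / sum((x - mean(x))^2))
  expect_lt(abs(mean(errs)), 3 * se_theory / sqrt(length(errs)))
  expect_equal(sd(errs), se_theory, tolerance = 0.2)
})

test_that("Yasuda-Shedlovsky input guards", {
  expect_error(yasuda_shedlovsky(
    data.frame(methanol_wt_percent = c(40, 40), pska = c(7, 7.1))),
    "distinct")
  expect_error(yasuda_shedlovsky(
    data.frame(methanol_wt_percent = c(30, 80), pska = c(7, 7.5))),
    "range")
  expect_error(simulate_titration(7, wt_percents = 40), ">= 2")
})

test_that("log P from the octanol pKa shift evaluates and round-trips", {
  expect_equal(logp_from_shift(4, 6, 1, "acid"), log10(99))
  expect_equal(logp_from_shift(9, 7, 0.5, "base"), log10(99 / 0.5))
  expect_error(logp_from_shift(4, 4, 1, "acid"), "wrong direction|shift")
  expect_error(logp_from_shift(4, 3, 1, "acid"), "wrong direction")
  expect_error(logp_from_shift(9, 10, 1, "base"), "wrong direction")
  # synthesize the apparent pKa from known (pKa, logP, r) and invert
  set.seed(3)
  for (i in 1:25) {
    pka <- runif(1, 3, 10)
    logp <- runif(1, 0.5, 5)
    r <- runif(1, 0.1, 2)
    poka_acid <- pka + log10(1 + r * 10^logp)
    expect_equal(logp_from_shift(pka, poka_acid, r, "acid"), logp,
                 tolerance = 1e-10)
    poka_base <- pka - log10(1 + r * 10^logp)
    expect_equal(logp_from_shift(pka, poka_base, r, "base"), logp,
                 tolerance = 1e-10)
  }
})

test_that("log D at pH reproduces printed monoprotic reference values", {
  ami <- protolyte_spec("amitriptyline", "monoprotic_base", 9.23)
  expect_equal(round(logd_at_ph(ami, 4.68), 2), 2.84)
  asa <- protolyte_spec("acetylsalicylic acid", "monoprotic_acid", 3.36)
  expect_equal(round(logd_at_ph(asa, 1.31), 2), -2.73)
  met <- protolyte_spec("metoprolol", "monoprotic_base", 9.50)
  expect_equal(round(logd_at_ph(met, 1.57), 2), -0.53)
  # half-ionized at pH = pKa
  expect_equal(logd_at_ph(ami, 4.68, ph = 9.23), 4.68 - log10(2))
})

test_that("log D respects the neutral-partition model's bounds and
           monotonicity", {
  set.seed(8)
  for (i in 1:30) {
    pka <- runif(1, 3, 11)
    logp <- runif(1, -1, 6)
    kind <- sample(c("monoprotic_acid", "monoprotic_base"), 1)
    spec <- protolyte_spec("x", kind, pka)
    ph <- sort(runif(8, 0.5, 13.5))
    ld <- logd_at_ph(spec, logp, ph)
    expect_true(all(ld <= logp + 1e-12))
    d <- diff(ld)
    if (kind == "monoprotic_acid") expect_true(all(d <= 1e-12))
    else expect_true(all(d >= -1e-12))
    # far on the neutral side log D converges to log P
    ph_neutral <- if (kind == "monoprotic_acid") pka - 6 else pka + 6
    expect_lt(abs(logd_at_ph(spec, logp, ph_neutral) - logp), 1e-6)
  }
})

test_that("diprotic and ampholyte ionization terms extend the model", {
  di <- protolyte_spec("x", "diprotic_acid", c(4, 9))
  # both deprotonations count at high pH
  expect_equal(logd_at_ph(di, 2, ph = 4), 2 - log10(1 + 1 + 10^(-5)),
               tolerance = 1e-12)
  amp <- protolyte_spec("x", "ampholyte", c(6.04, 8.13))
  expect_equal(logd_at_ph(amp, 1, ph = 7),
               1 - log10(1 + 10^(7 - 6.04) + 10^(8.13 - 7)),
               tolerance = 1e-12)
})

test_that("Bjerrum curves hit the protonation landmarks and limits", {
  mono <- protolyte_spec("x", "monoprotic_base", 8.5)
  expect_equal(bjerrum_curve(mono, 8.5), 0.5)
  expect_equal(bjerrum_curve(mono, 8.5 - 3), 1 / (1 + 1e-3),
               tolerance = 1e-12)
  di <- protolyte_spec("x", "diprotic_base", c(9, 4))
  expect_equal(bjerrum_curve(di, 6.5),
               (10^(9 - 6.5) + 2 * 10^(13 - 13)) /
                 (1 + 10^(9 - 6.5) + 10^(13 - 13)), tolerance = 1e-12)
  expect_equal(bjerrum_curve(di, 6.5), 1, tolerance = 1e-2)
  # proton-count limits and monotonicity
  grid <- seq(-4, 18, by = 0.25)
  nbar <- bjerrum_curve(di, grid)
  expect_equal(nbar[1], 2, tolerance = 1e-6)
  expect_equal(nbar[length(nbar)], 0, tolerance = 1e-4)
  expect_true(all(diff(nbar) <= 0))
})

test_that("protolyte specifications are validated", {
  expect_error(protolyte_spec("x", "diprotic_acid", 4), "2 pKa")
  expect_error(protolyte_spec("x", "monoprotic_acid", c(4, 5)), "1 pKa")
  expect_error(protolyte_spec("x", "monoprotic_acid", 15), "between 0 and 14")
  expect_error(protolyte_spec("x", "triprotic", 4), "unknown")
})
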