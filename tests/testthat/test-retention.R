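test_that("retention factor reproduces hand-computed and degenerate cases", {
  # identical runs: no retention at all
  r <- migration_record("a", 250, 250, 250, 250)
  expect_equal(retention_factor(r), 0)
  # coated behaves exactly like uncoated -> zero retention
  r <- migration_record("b", 300, 250, 300, 250)
  expect_equal(retention_factor(r), 0)
  # independent arithmetic
  r <- migration_record("c", t_r = 320, t_eof = 300,
                        t_r_unc = 260, t_eof_unc = 250)
  expect_equal(retention_factor(r), 320 * (1 / 300 + 1 / 260 - 1 / 250) - 1,
               tolerance = 1e-12)
  expect_equal(retention_factor(r), 0.0174359, tolerance = 1e-6)
})

test_that("retention factor matches the (t_R - t0)/t0 formulation and is
           scale invariant and monotone in t_R", {
  set.seed(42)
  for (i in 1:50) {
    t <- sort(runif(4, 100, 600))
    # subtracting the largest time's reciprocal keeps the reconstructed
    # hold-up time positive
    rec <- migration_record("x", t_r = t[3], t_eof = t[2],
                            t_r_unc = t[1], t_eof_unc = t[4])
    k <- retention_factor(rec)
    t0 <- 1 / (1 / rec$t_eof + 1 / rec$t_r_unc - 1 / rec$t_eof_unc)
    expect_equal(k, (rec$t_r - t0) / t0, tolerance = 1e-12)
    # common rescaling of all four times leaves k' unchanged
    s <- runif(1, 0.2, 5)
    rec2 <- migration_record("x", rec$t_r * s, rec$t_eof * s,
                             rec$t_r_unc * s, rec$t_eof_unc * s)
    expect_equal(retention_factor(rec2), k, tolerance = 1e-9)
    # strictly increasing in t_R
    rec3 <- migration_record("x", rec$t_r * 1.01, rec$t_eof,
                             rec$t_r_unc, rec$t_eof_unc)
    expect_gt(retention_factor(rec3), k)
  }
})

test_that("invalid migration inputs fail with the offending field named", {
  expect_error(migration_record("a", -1, 250, 250, 250), "t_r")
  expect_error(migration_record("a", 250, NA, 250, 250), "t_eof")
  expect_error(migration_record("a", 250, 250, 250, Inf), "t_eof_unc")
  # pathological uncoated mobilities: reconstructed hold-up time <= 0
  rec <- migration_record("a", t_r = 300, t_eof = 400,
                          t_r_unc = 500, t_eof_unc = 100)
  expect_error(retention_factor(rec), "non-positive")
})

test_that("minute-unit records convert to seconds", {
  r_min <- migration_record("a", 5, 4.5, 4.2, 4, unit = "min")
  r_sec <- migration_record("a", 300, 270, 252, 240)
  expect_equal(retention_factor(r_min), retention_factor(r_sec))
})

test_that("EOF mobility inverts migration time consistently with the
           reported coated/uncoated means", {
  expect_equal(eof_mobility(250.1), 5.79e-8, tolerance = 1e-3)
  expect_equal(eof_mobility(309.5), 4.68e-8, tolerance = 1e-3)
  # exact inverse proportionality to time and voltage
  expect_equal(eof_mobility(500), eof_mobility(250) / 2)
  g2 <- capillary_geometry(voltage = 40000)
  expect_equal(eof_mobility(250, g2), eof_mobility(250) / 2)
  expect_error(eof_mobility(-3), "positive")
})

test_that("replicate summaries use the n-1 denominator and guard RSD", {
  s <- summarize_replicates(c(5, 5, 5))
  expect_equal(s[c("mean", "sd", "rsd_percent")], list(mean = 5, sd = 0,
                                                       rsd_percent = 0))
  s <- summarize_replicates(c(4, 6))
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$rsd_percent, 100 * sqrt(2) / 5, tolerance = 1e-12)
  s <- summarize_replicates(3.2)
  expect_equal(s[c("mean", "sd", "n")], list(mean = 3.2, sd = 0, n = 1L))
  expect_error(summarize_replicates(numeric(0)), "non-empty")
  expect_error(summarize_replicates(c(-1, 1)), "undefined")
})

test_that("EOF suppression is flagged iff the coated mean drops", {
  expect_false(eof_suppression_report(c(5, 6), c(5, 6))$suppressed)
  rep <- eof_suppression_report(c(5, 6), 0.8 * c(5, 6))
  expect_true(rep$suppressed)
  expect_equal(rep$table$mean_mobility[2] / rep$table$mean_mobility[1], 0.8)
  # replicate sets shaped like the coating-quality comparison (n = 170)
  set.seed(1)
  unc <- 5.79e-8 * (1 + rnorm(170, sd = 0.05))
  coa <- 4.68e-8 * (1 + rnorm(170, sd = 0.05))
  rep <- eof_suppression_report(unc, coa)
  expect_true(rep$suppressed)
  expect_equal(rep$table$n, c(170, 170))
  expect_equal(rep$table$variant, c("uncoated", "coated"))
  expect_lt(max(rep$table$rsd_percent), 10)
})

test_that("per-compound k' tables pair replicates across capillary variants", {
  runs <- data.frame(
    compound_id = rep(c("a", "b"), each = 4),
    variant = rep(c("coated", "coated", "uncoated", "uncoated"), 2),
    t_analyte = c(320, 322, 260, 261, 300, 301, 252, 252),
    t_eof = c(300, 301, 250, 250, 270, 271, 240, 240))
  tab <- kprime_table(runs)
  expect_equal(tab$compound_id, c("a", "b"))
  expect_equal(tab$n, c(2L, 2L))
  k1 <- retention_factor(migration_record("a", 320, 300, 260, 250))
  k2 <- retention_factor(migration_record("a", 322, 301, 261, 250))
  expect_equal(tab$k_prime_mean[1], mean(c(k1, k2)))
  expect_equal(tab$k_prime_sd[1], sd(c(k1, k2)))
  expect_error(kprime_table(runs[runs$variant == "coated", ]), "lacks runs")
})
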