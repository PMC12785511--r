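#' Fit the three-predictor log BB regression
#'
#' Ordinary least squares of in vivo log BB on the CEC retention factor k',
#' the distribution coefficient log D7.4 and the aqueous pKa:
#' \deqn{\log BB = \beta_0 + \beta_1 k' + \beta_2 \log D_{7.4} +
#'   \beta_3 pK_a.}
#' Predictors enter on their natural scales (no standardization). The
#' headline p-value is the overall F-test on (3, n-4) degrees of freedom;
#' per-coefficient t statistics are kept in the summary table.
#'
#' @param records Data frame with numeric columns `k_prime`, `logd74`,
#'   `pka`, `logbb` (>= 5 rows); typically [bbb_compounds()].
#' @return An object of class `logbb_fit`: coefficients, standard errors,
#'   `r2`, `adj_r2`, `f_stat`, `p_value`, residual `sigma`, `n`, residual
#'   df, and the unscaled inverse cross-product matrix used for prediction
#'   intervals.
#' @examples
#' fit <- fit_logbb(bbb_compounds())
#' coef(fit)
#' @export
fit_logbb <- function(records) {
  need <- c("k_prime", "logd74", "pka", "logbb")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_input("records are missing column(s): ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)
  if (!all(vapply(records[need], is.numeric, logical(1))) ||
      !all(complete.cases(records[need])) ||
      !all(vapply(records[need], function(x) all(is.finite(x)), logical(1))))
    stop_input("all of k_prime, logd74, pka, logbb must be finite numerics")
  n <- nrow(records)
  if (n < 5L)
    stop_input("need at least 5 records to fit the 4-coefficient model")
  X <- cbind(`(Intercept)` = 1, k_prime = records$k_prime,
             logd74 = records$logd74, pka = records$pka)
  if (qr(X)$rank < ncol(X))
    stop_input("design matrix is rank deficient (constant or collinear ",
               "predictor)")
  lmfit <- lm(logbb ~ k_prime + logd74 + pka, data = records)
  sm <- summary(lmfit)
  fstat <- unname(sm$fstatistic[1])
  out <- list(
    coefficients = coef(lmfit),
    se = sm$coefficients[, "Std. Error"],
    coef_table = sm$coefficients,
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    f_stat = fstat,
    p_value = pf(fstat, 3, n - 4, lower.tail = FALSE),
    sigma = sm$sigma,
    n = n,
    df_residual = n - 4L,
    xtx_inv = chol2inv(qr.R(qr(X))),
    fitted = unname(lmfit$fitted.values),
    residuals = unname(lmfit$residuals),
    compound_id = if ("compound_id" %in% names(records))
      as.character(records$compound_id) else NULL)
  dimnames(out$xtx_inv) <- list(colnames(X), colnames(X))
  class(out) <- "logbb_fit"
  out
}

#' @export
print.logbb_fit <- function(x, ...) {
  cat("log BB ~ k' + logD7.4 + pKa  (OLS, n =", x$n, ")\n")
  b <- x$coefficients
  cat(sprintf("  logBB = %.2f + %.2f k' + %.2f logD7.4 + %.2f pKa\n",
              b[1], b[2], b[3], b[4]))
  cat(sprintf("  R2 = %.4f  adj R2 = %.4f  F(3,%d) = %.2f  p = %.3g\n",
              x$r2, x$adj_r2, x$df_residual, x$f_stat, x$p_value))
  invisible(x)
}

new_x_row <- function(k_prime, logd74, pka) {
  for (v in list(k_prime, logd74, pka))
    if (any(!is.finite(v))) stop_input("missing or non-finite predictor")
  cbind(1, k_prime, logd74, pka)
}

#' Predict log BB from the fitted regression
#'
#' @param object A `logbb_fit`.
#' @param newdata Data frame with columns `k_prime`, `logd74`, `pka`.
#' @param interval `"none"` or `"prediction"` for a prediction interval for
#'   a new observation.
#' @param level Coverage level of the interval.
#' @param ... Unused.
#' @return Numeric vector of estimates, or a data frame with `fit`, `lwr`,
#'   `upr` when an interval is requested.
#' @export
predict.logbb_fit <- function(object, newdata,
                              interval = c("none", "prediction"),
                              level = 0.95, ...) {
  interval <- match.arg(interval)
  X <- new_x_row(newdata$k_prime, newdata$logd74, newdata$pka)
  est <- drop(X %*% object$coefficients)
  if (interval == "none") return(est)
  hw <- prediction_halfwidth(object, X, level)
  data.frame(fit = est, lwr = est - hw, upr = est + hw)
}

prediction_halfwidth <- function(fit, X, level) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop_input("'level' must lie strictly between 0 and 1")
  lev <- rowSums((X %*% fit$xtx_inv) * X)  # x' (X'X)^-1 x per row
  qt(1 - (1 - level) / 2, fit$df_residual) * fit$sigma * sqrt(1 + lev)
}

#' Prediction interval for a single predictor vector
#'
#' Computes \eqn{\hat y \pm t_{(1-level)/2,\,n-4}\,\hat\sigma
#' \sqrt{1 + x^\top (X^\top X)^{-1} x}}, the interval expected to contain a
#' fresh observation at predictors `x` with the stated probability. The
#' interval widens away from the predictor centroid.
#'
#' @param fit A `logbb_fit`.
#' @param k_prime,logd74,pka Predictor values (vectorized).
#' @param level Coverage level, default 0.95.
#' @return Data frame with `fit`, `lwr`, `upr`.
#' @export
prediction_interval <- function(fit, k_prime, logd74, pka, level = 0.95) {
  if (!inherits(fit, "logbb_fit")) stop_input("'fit' must be a logbb_fit")
  X <- new_x_row(k_prime, logd74, pka)
  est <- drop(X %*% fit$coefficients)
  hw <- prediction_halfwidth(fit, X, level)
  data.frame(fit = est, lwr = est - hw, upr = est + hw)
}

#' Observed-versus-predicted parity data with prediction bounds
#'
#' One row per record: observed log BB, model prediction and the
#' `level`-prediction interval, ready for a parity plot against the 1:1
#' line. OLS guarantees the residuals average to zero.
#'
#' @param fit A `logbb_fit`.
#' @param records Data frame with the predictor columns and `logbb`.
#' @param level Interval coverage, default 0.95.
#' @return Data frame with `compound_id` (if present), `observed`,
#'   `predicted`, `lower`, `upper`.
#' @export
parity_data <- function(fit, records, level = 0.95) {
  pi <- prediction_interval(fit, records$k_prime, records$logd74,
                            records$pka, level = level)
  out <- data.frame(observed = records$logbb,
                    predicted = pi$fit, lower = pi$lwr, upper = pi$upr)
  if ("compound_id" %in% names(records))
    out <- cbind(compound_id = records$compound_id, out,
                 stringsAsFactors = FALSE)
  out
}

#' Serialize a fitted log BB model to structured plain text
#'
#' Stores coefficients, the unscaled inverse cross-product matrix, residual
#' sigma and degrees of freedom as JSON with full double precision, so
#' predictions and prediction intervals reproduce bit-for-bit after a
#' round trip through [read_logbb_fit()].
#'
#' @param fit A `logbb_fit`.
#' @param path Output file path.
#' @export
write_logbb_fit <- function(fit, path) {
  if (!inherits(fit, "logbb_fit")) stop_input("'fit' must be a logbb_fit")
  keep <- fit[c("coefficients", "se", "r2", "adj_r2", "f_stat", "p_value",
                "sigma", "n", "df_residual")]
  keep$xtx_inv <- fit$xtx_inv
  jsonlite::write_json(keep, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_logbb_fit
#' @return `read_logbb_fit()` returns the restored `logbb_fit`.
#' @export
read_logbb_fit <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- c("(Intercept)", "k_prime", "logd74", "pka")
  fit <- list(
    coefficients = stats::setNames(unlist(raw$coefficients), nm),
    se = stats::setNames(unlist(raw$se), nm),
    r2 = raw$r2, adj_r2 = raw$adj_r2, f_stat = raw$f_stat,
    p_value = raw$p_value, sigma = raw$sigma, n = raw$n,
    df_residual = raw$df_residual,
    xtx_inv = matrix(unlist(raw$xtx_inv), 4, 4, byrow = TRUE,
                     dimnames = list(nm, nm)))
  class(fit) <- "logbb_fit"
  fit
}
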