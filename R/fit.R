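# Model re-parameterization by non-linear least squares and the OLS
# validation statistics used to compare predictions with experiments.

#' Fit the solubility model to observations
#'
#' Re-parameterizes the solubility polynomial
#' \eqn{S = \alpha L + \beta |Q|^2 + \gamma |Q| + \delta} against observed
#' solubilities by least squares, using the Levenberg-Marquardt non-linear
#' solver ([minpack.lm::nlsLM()]) started from the shipped defaults. The
#' polynomial is linear in its four coefficients, so when the design matrix
#' \eqn{[L, |Q|^2, |Q|, 1]} has full rank the optimum is the unique global
#' minimizer regardless of initialization; a rank check runs before fitting
#' and names the collinear columns on failure.
#'
#' @param data Data frame of training observations with columns
#'   `lipophilicity`, `abs_net_charge` and `solubility` (see
#'   [generate_solubility_data()] for the synthetic counterpart). At least 5
#'   rows (more observations than coefficients).
#' @param init A [solubility_params()] used as the optimizer start.
#' @param tol Convergence tolerance on relative parameter/cost change
#'   (default `1e-10`).
#' @return An object of class `"solubility_fit"`: fields `params`
#'   (a [solubility_params()]), `se` (per-coefficient standard errors),
#'   `rss`, `sigma` (residual standard deviation), `n`, `fitted`,
#'   `residuals`, plus the underlying `nls` object. Supports `coef()`,
#'   `predict()`, `fitted()`, `residuals()`, `summary()` and `simulate()`.
#' @examples
#' d <- data.frame(lipophilicity = runif(20), abs_net_charge = runif(20, 0, 40))
#' d$solubility <- predict_solubility(d$lipophilicity, d$abs_net_charge)
#' coef(fit_solubility(d))  # recovers the defaults exactly (noiseless)
#' @export
fit_solubility <- function(data, init = solubility_params(), tol = 1e-10) {
  required <- c("lipophilicity", "abs_net_charge", "solubility")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("data lacks column(s): ", paste(missing, collapse = ", "))
  }
  data <- as.data.frame(data)[required]
  if (!all(vapply(data, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(data)))) {
    stop("training observations must be finite numbers")
  }
  if (any(data$abs_net_charge < 0)) stop("abs_net_charge must be >= 0")
  n <- nrow(data)
  if (n < 5) stop("need at least 5 observations to fit 4 coefficients")

  X <- cbind(lipophilicity = data$lipophilicity,
             `abs_net_charge^2` = data$abs_net_charge^2,
             abs_net_charge = data$abs_net_charge,
             intercept = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  fit <- minpack.lm::nlsLM(
    solubility ~ alpha * lipophilicity + beta * abs_net_charge^2 +
      gamma * abs_net_charge + delta,
    data = data,
    start = as.list(unclass(init)),
    control = minpack.lm::nls.lm.control(ftol = tol, ptol = tol,
                                         maxiter = 500))
  est <- coef(fit)
  sm <- summary(fit)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  structure(list(
    params = solubility_params(est[["alpha"]], est[["beta"]],
                               est[["gamma"]], est[["delta"]]),
    se = sm$coefficients[, "Std. Error"],
    rss = rss,
    sigma = sqrt(rss / (n - 4)),
    n = n,
    fitted = as.numeric(stats::fitted(fit)),
    residuals = as.numeric(res),
    data = data,
    nls = fit,
    call = match.call()),
    class = "solubility_fit")
}

#' @export
coef.solubility_fit <- function(object, ...) unclass(object$params)

#' @export
fitted.solubility_fit <- function(object, ...) object$fitted

#' @export
residuals.solubility_fit <- function(object, ...) object$residuals

#' @export
print.solubility_fit <- function(x, ...) {
  cat(sprintf("Solubility model fit (%d observations)\n", x$n))
  print(x$params)
  cat(sprintf("RSS: %.6g   residual sd: %.6g\n", x$rss, x$sigma))
  invisible(x)
}

#' @export
summary.solubility_fit <- function(object, ...) {
  tab <- cbind(Estimate = unclass(object$params),
               `Std. Error` = object$se)
  structure(list(coefficients = tab, rss = object$rss,
                 sigma = object$sigma, n = object$n),
            class = "summary.solubility_fit")
}

#' @export
print.summary.solubility_fit <- function(x, ...) {
  cat(sprintf("Solubility model fit: n = %d, RSS = %.6g, sigma = %.6g\n",
              x$n, x$rss, x$sigma))
  print(x$coefficients)
  invisible(x)
}

#' Predict from a fitted solubility model
#'
#' @param object A `"solubility_fit"`.
#' @param newdata Data frame with columns `lipophilicity` and
#'   `abs_net_charge`; default re-predicts the training observations.
#' @param ... Unused.
#' @return Numeric vector of predicted solubility scores.
#' @export
predict.solubility_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_solubility(newdata$lipophilicity, newdata$abs_net_charge,
                     object$params)
}

#' Simulate responses from a fitted solubility model
#'
#' Draws Gaussian responses around the fitted surface with the residual
#' standard deviation of the fit.
#'
#' @param object A `"solubility_fit"`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @param ... Unused.
#' @return Data frame with `nsim` columns of length `n`.
#' @export
simulate.solubility_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() object$fitted + rnorm(object$n, 0, object$sigma)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  as.data.frame(matrix(sims, ncol = nsim,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Experimental pH series
#'
#' Small container for an experimental observable measured across pH, e.g.
#' an apparent fibril elongation constant (Kapp, 1/h), a lag time (h), or a
#' measured solubility. The orientation flag records whether larger values
#' mean more aggregation, which determines the expected sign of the
#' regression slope against predicted solubility (negative when they do);
#' [validate_predictions()] reports but does not enforce that sign.
#'
#' @param ph Numeric vector of pH values.
#' @param value Observed quantity at each pH.
#' @param label Name of the observable (e.g. `"Kapp"`).
#' @param higher_is_aggregation `TRUE` if larger observed values indicate
#'   more aggregation (a Kapp), `FALSE` if they indicate more solubility.
#' @return Data frame of class `"experimental_series"`.
#' @export
experimental_series <- function(ph, value, label = "observable",
                                higher_is_aggregation = TRUE) {
  stopifnot(length(ph) == length(value), is.numeric(ph), is.numeric(value))
  structure(data.frame(ph = ph, value = value),
            label = label,
            higher_is_aggregation = isTRUE(higher_is_aggregation),
            class = c("experimental_series", "data.frame"))
}

#' Regression statistics between predictions and experiment
#'
#' Ordinary least squares of the experimental values on the predicted
#' solubilities: slope, intercept, \eqn{R^2}, and the two-tailed p-value of
#' the slope from \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of
#' freedom, together with the parameters of the standard 95% confidence
#' band. \eqn{R^2} and the p-value are invariant under affine rescaling of
#' the predictions, so the arbitrary units of the solubility score do not
#' affect the validation.
#'
#' @param predicted Numeric vector of predicted solubility scores.
#' @param experimental An [experimental_series()] or a numeric vector of the
#'   same length as `predicted`.
#' @return An object of class `"solubility_validation"`: `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `expected_sign` (from the
#'   series orientation, `NA` for plain vectors), and the band parameters
#'   `sigma`, `x_bar`, `ss_x`, `t_crit` (95% band: fitted value
#'   \eqn{\pm t_{crit}\,\sigma\sqrt{1/n + (x - \bar x)^2 / SS_x}}), plus the
#'   underlying `lm` fit.
#' @examples
#' v <- validate_predictions(1:6, 2 * (1:6) + 1)
#' v$r_squared  # 1: perfectly collinear
#' @export
validate_predictions <- function(predicted, experimental) {
  expected_sign <- NA
  label <- "observable"
  if (inherits(experimental, "experimental_series")) {
    expected_sign <- if (attr(experimental, "higher_is_aggregation")) -1 else 1
    label <- attr(experimental, "label")
    experimental <- experimental$value
  }
  stopifnot(is.numeric(predicted), is.numeric(experimental))
  if (length(predicted) != length(experimental)) {
    stop("predicted and experimental series differ in length")
  }
  n <- length(predicted)
  if (n < 3) stop("need at least 3 points for a regression")
  if (any(!is.finite(predicted)) || any(!is.finite(experimental))) {
    stop("non-finite values in regression input")
  }
  if (var(predicted) == 0 || var(experimental) == 0) {
    stop("zero variance in ",
         if (var(predicted) == 0) "predicted" else "experimental",
         " values; regression is undefined")
  }
  fit <- lm(experimental ~ predicted)
  # summary.lm warns on an exactly collinear series; that input is legal here
  sm <- suppressWarnings(summary(fit))
  r2 <- sm$r.squared
  r <- sqrt(pmin(r2, 1))
  p <- if (r2 >= 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r2))
    2 * pt(tval, df = n - 2, lower.tail = FALSE)
  }
  cf <- coef(fit)
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = r2, p_value = p, n = n,
                 expected_sign = expected_sign, label = label,
                 sigma = sm$sigma,
                 x_bar = mean(predicted),
                 ss_x = sum((predicted - mean(predicted))^2),
                 t_crit = qt(0.975, df = n - 2),
                 lm = fit),
            class = "solubility_validation")
}

#' @export
print.solubility_validation <- function(x, ...) {
  cat(sprintf("Validation regression (%s on predicted solubility, n = %d)\n",
              x$label, x$n))
  cat(sprintf("  slope %.4g  intercept %.4g  R^2 %.4f  p (two-tailed) %.3g\n",
              x$slope, x$intercept, x$r_squared, x$p_value))
  if (!is.na(x$expected_sign)) {
    ok <- sign(x$slope) == x$expected_sign
    cat(sprintf("  expected slope sign %s: %s\n",
                if (x$expected_sign < 0) "negative" else "positive",
                if (ok) "observed" else "NOT observed"))
  }
  invisible(x)
}
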