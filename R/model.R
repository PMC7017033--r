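# The empirical pH-dependent solubility model.

#' Solubility model coefficients
#'
#' Container for the four coefficients of the solubility model
#' \deqn{S = \alpha L + \beta |Q|^2 + \gamma |Q| + \delta,}
#' where \eqn{L} is the global pH-dependent lipophilicity and \eqn{|Q|} the
#' absolute fractional net charge. The defaults are the published values
#' obtained by non-linear least-squares parameterization on a
#' charge-engineered model IDP: \eqn{\alpha = -97.82}, \eqn{\beta =
#' -0.00747}, \eqn{\gamma = 0.8770}, \eqn{\delta = 38.24}. Scores are in the
#' arbitrary units of that training data; solubility is defined relatively,
#' as the inverse of aggregation propensity, not as a concentration.
#'
#' With \eqn{\beta < 0} the charge response is concave with a maximum at
#' \eqn{|Q|^* = -\gamma / (2\beta)}; increasing net charge first raises
#' solubility, with diminishing returns.
#'
#' @param alpha Coefficient on lipophilicity.
#' @param beta Coefficient on squared absolute net charge.
#' @param gamma Coefficient on absolute net charge.
#' @param delta Intercept.
#' @return A named numeric vector of class `"solubility_params"`.
#' @examples
#' solubility_params()
#' @export
solubility_params <- function(alpha = -97.82, beta = -0.00747,
                              gamma = 0.8770, delta = 38.24) {
  x <- c(alpha = alpha, beta = beta, gamma = gamma, delta = delta)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("model coefficients must be finite numbers")
  }
  structure(x, class = "solubility_params")
}

#' @export
print.solubility_params <- function(x, ...) {
  cat("Solubility model: S = alpha*L + beta*|Q|^2 + gamma*|Q| + delta\n")
  print(unclass(x))
  invisible(x)
}

#' Predict solubility from lipophilicity and net charge
#'
#' Evaluates the solubility polynomial
#' \eqn{S = \alpha L + \beta |Q|^2 + \gamma |Q| + \delta} exactly.
#'
#' @param lipophilicity Global lipophilicity value(s) \eqn{L}.
#' @param abs_net_charge Absolute net charge value(s) \eqn{|Q| \ge 0}.
#' @param params A [solubility_params()] object.
#' @return Numeric solubility score(s), arbitrary units.
#' @examples
#' predict_solubility(0, 0)          # the intercept
#' predict_solubility(0.1, 10)
#' @export
predict_solubility <- function(lipophilicity, abs_net_charge,
                               params = solubility_params()) {
  stopifnot(is.numeric(lipophilicity), is.numeric(abs_net_charge))
  if (any(abs_net_charge < 0)) stop("abs_net_charge must be >= 0")
  params[["alpha"]] * lipophilicity +
    params[["beta"]] * abs_net_charge^2 +
    params[["gamma"]] * abs_net_charge +
    params[["delta"]]
}

#' Predicted solubility of a sequence at given pH values
#'
#' Composes the three pipeline stages: global lipophilicity at each pH
#' ([global_lipophilicity()]), absolute fractional net charge
#' ([net_charge()]), and the solubility polynomial
#' ([predict_solubility()]). The component values are returned alongside the
#' score so the decomposition can be inspected.
#'
#' @inheritParams lipophilicity_profile
#' @param pH Numeric vector of pH values in (0, 14).
#' @param params A [solubility_params()].
#' @param exclude_cys Passed to [net_charge()].
#' @return Data frame with one row per pH: `pH`, `solubility`,
#'   `lipophilicity`, `abs_net_charge`.
#' @examples
#' solubility_at_ph(strrep("QSAGE", 12), pH = c(4, 7.4))
#' @export
solubility_at_ph <- function(seq, pH, params = solubility_params(),
                             scale = lipophilicity_scale(),
                             pka = ionization_table(), window = NULL,
                             exclude_cys = FALSE, allow_x = FALSE) {
  p <- as_protein(seq)
  check_ph(pH)
  L <- vapply(pH, function(ph) {
    global_lipophilicity(p, ph, scale = scale, pka = pka, window = window,
                         allow_x = allow_x)
  }, numeric(1))
  q <- net_charge(p, pH, pka = pka, exclude_cys = exclude_cys)$abs_net_charge
  data.frame(pH = pH,
             solubility = predict_solubility(L, q, params),
             lipophilicity = L,
             abs_net_charge = q)
}

#' Solubility curve over a pH interval
#'
#' Evaluates [solubility_at_ph()] over a regular pH grid, producing a
#' solubility-vs-pH curve with its lipophilicity and net-charge components.
#'
#' @inheritParams solubility_at_ph
#' @param ph_min,ph_max Grid limits, `0 < ph_min < ph_max < 14`.
#' @param step Grid spacing (> 0); the grid is
#'   `seq(ph_min, ph_max, by = step)`.
#' @return A data frame of class `"solubility_curve"` (columns as in
#'   [solubility_at_ph()]) with attributes `id` and `params`.
#' @examples
#' cv <- ph_sweep(strrep("QSAGE", 12), 2, 12, step = 0.5)
#' nrow(cv)  # 21 grid points
#' @export
ph_sweep <- function(seq, ph_min = 2, ph_max = 12, step = 0.1,
                     params = solubility_params(),
                     scale = lipophilicity_scale(),
                     pka = ionization_table(), window = NULL,
                     exclude_cys = FALSE, allow_x = FALSE) {
  p <- as_protein(seq)
  if (!(ph_min > 0 && ph_min < ph_max && ph_max < 14)) {
    stop("require 0 < ph_min < ph_max < 14")
  }
  if (step <= 0) stop("step must be > 0")
  grid <- seq(ph_min, ph_max, by = step)
  if (length(grid) == 0) stop("empty pH grid")
  out <- solubility_at_ph(p, grid, params = params, scale = scale,
                          pka = pka, window = window,
                          exclude_cys = exclude_cys, allow_x = allow_x)
  structure(out, id = p$id, params = params,
            class = c("solubility_curve", "data.frame"))
}

#' @export
print.solubility_curve <- function(x, ...) {
  cat(sprintf("<solubility_curve> %s: %d pH points on [%.3g, %.3g]\n",
              attr(x, "id"), nrow(x), min(x$pH), max(x$pH)))
  print.data.frame(rbind(head(as.data.frame(x), 3),
                         tail(as.data.frame(x), 3)))
  invisible(x)
}

#' Plot a solubility curve
#'
#' @param x A `"solubility_curve"` from [ph_sweep()].
#' @param rescale `"none"` (raw arbitrary units) or `"minmax"` (curve
#'   rescaled to \[0, 1\] over the sweep, convenient for overlaying
#'   proteins).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.solubility_curve <- function(x, rescale = c("none", "minmax"), ...) {
  rescale <- match.arg(rescale)
  y <- x$solubility
  if (rescale == "minmax") y <- (y - min(y)) / (max(y) - min(y))
  graphics::plot(x$pH, y, type = "l", xlab = "pH",
                 ylab = if (rescale == "none") "predicted solubility (a.u.)"
                 else "predicted solubility (min-max scaled)",
                 main = attr(x, "id"), ...)
  invisible(x)
}

#' Per-residue solubility profile at a given pH
#'
#' Applies the solubility polynomial to each sliding-window lipophilicity
#' value (window centers, as in [lipophilicity_profile()]) while using the
#' whole-chain absolute net charge at that pH for the charge terms. Charge
#' is a global property of the chain and is deliberately not localized, so
#' this profile is a region-ranking heuristic: it orders sequence regions by
#' their lipophilic contribution to aggregation at the chosen pH, on the
#' same score scale as the whole-protein prediction. Because the polynomial
#' is linear in lipophilicity, the profile mean equals the whole-protein
#' score at that pH.
#'
#' @inheritParams solubility_at_ph
#' @param pH Scalar pH in (0, 14).
#' @return A data frame of class `"sol_profile"`: `position`, `residue`,
#'   `solubility`; attributes `id`, `pH`, `window`, `abs_net_charge`.
#' @export
residue_solubility_profile <- function(seq, pH, params = solubility_params(),
                                       scale = lipophilicity_scale(),
                                       pka = ionization_table(),
                                       window = NULL, exclude_cys = FALSE,
                                       allow_x = FALSE) {
  p <- as_protein(seq)
  pr <- lipophilicity_profile(p, pH, scale = scale, pka = pka,
                              window = window, allow_x = allow_x)
  q <- net_charge(p, pH, pka = pka, exclude_cys = exclude_cys)$abs_net_charge
  out <- data.frame(position = pr$position, residue = pr$residue,
                    solubility = predict_solubility(pr$lipophilicity, q,
                                                    params))
  structure(out, id = p$id, pH = pH, window = attr(pr, "window"),
            abs_net_charge = q,
            class = c("sol_profile", "data.frame"))
}
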