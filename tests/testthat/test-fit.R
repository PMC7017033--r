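make_design_data <- function(n, seed, params = solubility_params(),
                             noise_sd = 0) {
  set.seed(seed)
  d <- data.frame(lipophilicity = runif(n, -0.6, 0.8),
                  abs_net_charge = runif(n, 0, 60))
  d$solubility <- predict_solubility(d$lipophilicity, d$abs_net_charge,
                                     params) + rnorm(n, 0, noise_sd)
  d
}

test_that("noiseless observations are interpolated to machine accuracy", {
  truth <- solubility_params(-50, -0.01, 1.2, 20)
  d <- make_design_data(30, seed = 1, params = truth)
  fit <- fit_solubility(d)
  expect_equal(unname(coef(fit)), unname(unclass(truth)),
               tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("the Levenberg-Marquardt solution equals the closed-form
           linear-least-squares solution", {
  d <- make_design_data(50, seed = 2, noise_sd = 3)
  fit <- fit_solubility(d)
  ols <- lm(solubility ~ lipophilicity + I(abs_net_charge^2) +
              abs_net_charge, data = d)
  expect_equal(unname(coef(fit)),
               unname(coef(ols))[c(2, 3, 4, 1)], tolerance = 1e-8)
})

test_that("the fit is invariant under observation order", {
  d <- make_design_data(40, seed = 3, noise_sd = 2)
  set.seed(99)
  d2 <- d[sample(nrow(d)), ]
  f1 <- fit_solubility(d)
  f2 <- fit_solubility(d2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)
  expect_equal(f1$rss, f2$rss, tolerance = 1e-10)
})

test_that("estimates fall within three standard errors of the truth at
           the nominal rate", {
  truth <- unclass(solubility_params())
  hits <- 0L
  total <- 0L
  for (seed in 1:200) {
    d <- make_design_data(100, seed = seed, noise_sd = 2)
    fit <- fit_solubility(d)
    inside <- abs(coef(fit) - truth) <= 3 * fit$se
    hits <- hits + sum(inside)
    total <- total + length(inside)
  }
  expect_gte(hits / total, 0.99)
})

test_that("degenerate designs are diagnosed before fitting", {
  d <- make_design_data(20, seed = 4)
  expect_error(fit_solubility(d[1:4, ]), "at least 5")
  d_const <- d
  d_const$abs_net_charge <- 0
  expect_error(fit_solubility(d_const), "rank-deficient")
  d_na <- d
  d_na$solubility[1] <- NA
  expect_error(fit_solubility(d_na), "finite")
})

test_that("adding an observation on the fitted surface cannot raise the RSS", {
  d <- make_design_data(30, seed = 5, noise_sd = 2)
  fit <- fit_solubility(d)
  new_pt <- data.frame(lipophilicity = 0.2, abs_net_charge = 15)
  new_pt$solubility <- predict(fit, new_pt)
  fit2 <- fit_solubility(rbind(d, new_pt))
  expect_lte(fit2$rss, fit$rss + 1e-8)
})

test_that("simulate() reproduces under a seed and predict() honors newdata", {
  d <- make_design_data(30, seed = 6, noise_sd = 1)
  fit <- fit_solubility(d)
  s1 <- simulate(fit, nsim = 2, seed = 7)
  s2 <- simulate(fit, nsim = 2, seed = 7)
  expect_identical(s1, s2)
  nd <- data.frame(lipophilicity = c(0, 1), abs_net_charge = c(0, 10))
  expect_equal(predict(fit, nd),
               predict_solubility(nd$lipophilicity, nd$abs_net_charge,
                                  fit$params), tolerance = 1e-12)
})

test_that("validation regression reproduces closed-form OLS statistics", {
  # perfectly collinear data
  v <- validate_predictions(1:6, 2 * (1:6) + 1)
  expect_equal(v$r_squared, 1, tolerance = 1e-12)
  expect_equal(v$slope, 2, tolerance = 1e-12)
  expect_lt(v$p_value, 1e-10)

  # hand-computable n = 6 dataset: textbook sums of squares
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.3, 11.9)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  tval <- sqrt(r2) * sqrt((6 - 2) / (1 - r2))
  pval <- 2 * pt(tval, df = 4, lower.tail = FALSE)
  v2 <- validate_predictions(x, y)
  expect_equal(v2$slope, slope, tolerance = 1e-12)
  expect_equal(v2$intercept, mean(y) - slope * mean(x), tolerance = 1e-12)
  expect_equal(v2$r_squared, r2, tolerance = 1e-12)
  expect_equal(v2$p_value, pval, tolerance = 1e-12)
  expect_equal(v2$n, 6)

  # confidence band parameters are the standard OLS quantities
  fit <- lm(y ~ x)
  expect_equal(v2$sigma, summary(fit)$sigma, tolerance = 1e-12)
  expect_equal(v2$t_crit, qt(0.975, 4), tolerance = 1e-12)
})

test_that("validation statistics are invariant to affine rescaling of the
           predictions and reject degenerate input", {
  set.seed(8)
  pred <- rnorm(10)
  obs <- 1.5 * pred + rnorm(10, 0, 0.3)
  v1 <- validate_predictions(pred, obs)
  v2 <- validate_predictions(5 * pred - 3, obs)
  expect_equal(v1$r_squared, v2$r_squared, tolerance = 1e-12)
  expect_equal(v1$p_value, v2$p_value, tolerance = 1e-12)

  expect_error(validate_predictions(pred, rep(1, 10)), "zero variance")
  expect_error(validate_predictions(1:2, 1:2), "at least 3")
  expect_error(validate_predictions(1:5, c(1, 2, NA, 4, 5)), "finite")
})

test_that("experimental series carry their orientation into the report", {
  es <- experimental_series(ph = 1:6, value = c(6, 5, 4, 3.2, 2, 1),
                            label = "Kapp", higher_is_aggregation = TRUE)
  v <- validate_predictions(1:6, es)
  expect_equal(v$expected_sign, -1)
  expect_lt(v$slope, 0)  # faster kinetics where predicted solubility is low
  expect_output(print(v), "expected slope sign negative: observed")
})
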