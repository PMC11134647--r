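test_that("saturated models fit perfectly with zero degrees of freedom", {
  set.seed(31)
  d <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  d$y <- 0.5 * d$x1 - 0.3 * d$x2 + rnorm(80)
  fit <- fit_ml(parse_model("y ~ x1 + x2"), d)
  expect_equal(fit$df, 0)
  expect_lte(fit$fml, 1e-8)
  expect_equal(unname(fit$Sigma), unname(fit$S), tolerance = 1e-6)
})

test_that("ML estimates equal per-equation OLS on recursive latent-free models", {
  set.seed(32)
  d <- make_mediation_data(150)
  mod <- mediation_model()
  for (eng in c("auto", "iterative")) {
    fit <- fit_ml(mod, d, engine = eng)
    ols <- c(coef(lm(m ~ x, d))[2], coef(lm(y ~ x + m, d))[2:3])
    est <- fit$params$est[fit$params$kind == "path"]
    expect_lt(max(abs(est - ols)), 1e-6)
    # R-squared equals the per-equation OLS oracle
    expect_equal(unname(fit$r2["m"]), summary(lm(m ~ x, d))$r.squared,
                 tolerance = 1e-6)
    expect_equal(unname(fit$r2["y"]), summary(lm(y ~ x + m, d))$r.squared,
                 tolerance = 1e-6)
  }
})

test_that("one-factor fit to its population covariance recovers the truth", {
  fit <- fit_ml(parse_model("f =~ x1 + x2 + x3"),
                sample_cov = one_factor_sigma(), n = 500)
  loadings <- fit$params$est[fit$params$kind == "loading"]
  expect_lt(max(abs(loadings - c(0.8, 0.6))), 1e-5)
  expect_lte(fit$fml, 1e-10)
  expect_equal(unname(fit$Smat["f", "f"]), 1, tolerance = 1e-4)
  expect_equal(unname(diag(fit$Smat)[2:4]), rep(0.5, 3), tolerance = 1e-4)
})

test_that("fitting a nested restriction never decreases the discrepancy", {
  set.seed(33)
  d <- make_mediation_data(120)
  full <- fit_ml(mediation_model(), d)
  restricted <- fit_ml(parse_model("m ~ x\ny ~ m"), d)  # drops x -> y
  expect_gte(restricted$fml + 1e-12, full$fml)
})

test_that("fit indices match the closed-form worked example and conventions", {
  idx <- fit_indices(list(chi2 = 100, df = 40, chi2_baseline = 1000,
                          df_baseline = 45, n = 401))
  expect_equal(unname(round(idx["CFI"], 4)), 0.9372)
  expect_equal(unname(round(idx["NFI"], 4)), 0.9000)
  expect_equal(unname(round(idx["IFI"], 4)), 0.9375)
  expect_equal(unname(round(idx["RMSEA"], 4)), 0.0612)
  expect_true(attr(idx, "acceptable"))
  # saturated model: CFI 1, RMSEA reported 0
  idx0 <- fit_indices(list(chi2 = 0, df = 0, chi2_baseline = 50,
                           df_baseline = 3, n = 100))
  expect_equal(unname(idx0["CFI"]), 1)
  expect_equal(unname(idx0["RMSEA"]), 0)
  # an adequate women's-model-scale fit is flagged acceptable
  idxw <- fit_indices(list(chi2 = 150, df = 40, chi2_baseline = 3000,
                           df_baseline = 55, n = 1810))
  expect_true(all(attr(idxw, "flags")[c("CFI", "RMSEA")]))
})

test_that("standardized solution has the closed-form and invariance properties", {
  set.seed(34)
  # simple regression: standardized coefficient is the Pearson correlation
  d <- data.frame(x = rnorm(100))
  d$y <- 0.6 * d$x + rnorm(100)
  fit <- fit_ml(parse_model("y ~ x"), d)
  std <- fit$params$std[fit$params$label == "y~x"]
  expect_equal(std, cor(d$x, d$y), tolerance = 1e-6)

  # pre-standardized variables: standardized equals unstandardized
  ds <- as.data.frame(scale(make_mediation_data(400)))
  fs <- fit_ml(mediation_model(), ds)
  paths <- fs$params$kind == "path"
  expect_lt(max(abs(fs$params$std[paths] - fs$params$est[paths])), 1e-6)

  # rescaling one observed predictor leaves its standardized coefficient
  # and the fit indices unchanged
  d2 <- make_mediation_data(300)
  f1 <- fit_ml(mediation_model(), d2)
  d3 <- d2; d3$x <- d3$x * 10
  f2 <- fit_ml(mediation_model(), d3)
  expect_equal(f1$params$std, f2$params$std, tolerance = 1e-6)
  expect_equal(as.numeric(f1$indices), as.numeric(f2$indices),
               tolerance = 1e-6)
  expect_equal(f1$fml, f2$fml, tolerance = 1e-8)
})

test_that("r_squared follows its closed forms", {
  # standardized y = 0.6 x + e with unit total variance: R^2 = 0.36
  S <- matrix(c(1, 0.6, 0.6, 1), 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  fit <- fit_ml(parse_model("y ~ x"), sample_cov = S, n = 200)
  expect_equal(unname(fit$r2["y"]), 0.36, tolerance = 1e-8)
  # near-exact reproduction drives R^2 to 1
  set.seed(35)
  d <- data.frame(x = rnorm(100))
  d$y <- 2 * d$x + rnorm(100, sd = 1e-3)
  # near-singular implied covariance: convergence warning expected and benign
  f2 <- suppressWarnings(fit_ml(parse_model("y ~ x"), d))
  expect_equal(unname(f2$r2["y"]), 1, tolerance = 1e-4)
})

test_that("the fitter validates its inputs", {
  d <- make_mediation_data(60)
  expect_error(fit_ml(mediation_model()), "data or sample_cov")
  expect_error(fit_ml(mediation_model(), d[1:20, ]), "floor")
  expect_error(fit_ml(mediation_model(), d[, 1:2]), "y")
  expect_error(fit_ml(mediation_model(), sample_cov = diag(3)), "n is required")
})

test_that("standard errors follow the inverse-information formula", {
  set.seed(36)
  d <- make_mediation_data(500)
  fit <- fit_ml(mediation_model(), d, engine = "iterative")
  # oracle: OLS standard error of the m ~ x slope (disturbances uncorrelated,
  # saturated exogenous block: the information matrix is block diagonal and
  # the ML SE matches the large-sample OLS SE with 1/(n-1) scaling)
  i <- which(fit$params$label == "m~x")
  ols <- summary(lm(m ~ x, d))
  se_ols <- ols$coefficients[2, 2] * sqrt((500 - 2) / (500 - 1))
  expect_equal(fit$params$se[i], se_ols, tolerance = 0.02)
})
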