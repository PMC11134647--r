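test_that("SES index matches closed-form two-item eigenstructure", {
  # two perfectly correlated items: first component explains everything
  x <- rnorm(30)
  items <- cbind(education = x, wealth = 2 * x + 5)
  s <- ses_index(items)
  expect_equal(s$model$explained, 1.0, tolerance = 1e-12)

  # correlation r: eigenvalues of a 2x2 correlation matrix are 1 +/- r,
  # so explained proportion is (1 + r) / 2
  set.seed(21)
  a <- rnorm(4000); b <- 0.5 * a + sqrt(0.75) * rnorm(4000)
  r <- cor(a, b)
  s2 <- ses_index(cbind(education = a, asset = b))
  expect_equal(s2$model$explained, (1 + r) / 2, tolerance = 1e-10)

  # unit-norm loadings, anchored orientation
  expect_equal(sum(s2$model$loadings^2), 1, tolerance = 1e-12)
  expect_gt(s2$model$loadings["education"], 0)
})

test_that("SES tertiles are lower-closed, monotone and 3/3/3 on 9 distinct scores", {
  set.seed(3)
  items <- cbind(education = 1:9, asset = (1:9) + rnorm(9, sd = 0.01))
  s <- ses_index(items)
  expect_equal(as.vector(table(s$tertile)), c(3, 3, 3))
  # labels are monotone in the score
  o <- order(s$score)
  expect_false(is.unsorted(s$tertile[o]))
})

test_that("SES scores are invariant (up to orientation) under affine item rescaling", {
  set.seed(8)
  items <- matrix(rnorm(150), 50, 3,
                  dimnames = list(NULL, c("education", "car", "rooms")))
  s1 <- ses_index(items)
  items2 <- items
  items2[, "car"] <- 100 * items2[, "car"] - 7
  s2 <- ses_index(items2)
  expect_equal(s1$score, s2$score, tolerance = 1e-8)
  expect_equal(as.character(s1$tertile), as.character(s2$tertile))
})

test_that("SES index validates its inputs", {
  items <- cbind(education = rnorm(20), flat = rep(1, 20), car = rnorm(20))
  expect_warning(s <- ses_index(items), "zero-variance")
  expect_equal(s$model$items, c("education", "car"))
  expect_error(ses_index(cbind(a = 1:2, b = 2:1)), "3 participants")
  expect_error(suppressWarnings(ses_index(cbind(a = rep(1, 5), b = rnorm(5)))))
})

test_that("activity categories follow the documented MET bands", {
  expect_equal(as.character(pa_category(30)), "low")
  expect_equal(as.character(pa_category(45)), "vigorous")
  # gap values closed by continuity into the moderate band
  expect_equal(as.character(pa_category(36.55)), "moderate")
  expect_equal(as.character(pa_category(44.95)), "moderate")
  # boundaries
  expect_equal(as.character(pa_category(c(24, 36.5, 36.6, 44.9))),
               c("low", "low", "moderate", "moderate"))
  expect_warning(lowv <- pa_category(20), "below_range")
  expect_equal(as.character(lowv), "below_range")
  expect_error(pa_category(-1))
  # total monotone step function on [24, Inf)
  grid <- seq(24, 70, by = 0.01)
  codes <- as.integer(pa_category(grid))
  expect_false(any(is.na(codes)))
  expect_false(is.unsorted(codes))
})

test_that("normality screen computes adjusted Fisher-Pearson G1/G2 and flags", {
  # hand-evaluated worked value
  expect_equal(sample_skewness(c(1, 2, 3, 4, 100)), 2.2324, tolerance = 1e-4)
  # symmetric data has zero skewness
  expect_equal(sample_skewness(rep(c(-1, 0, 1), 10)), 0, tolerance = 1e-12)
  tab <- data.frame(sym = rep(c(-1, 0, 1), 10))
  rep1 <- normality_screen(tab, "sym")
  expect_true(rep1$pass)
  # large standard-normal sample passes both thresholds
  set.seed(14)
  tab2 <- data.frame(x = rnorm(5000), heavy = exp(rnorm(5000, sd = 2.5)))
  rep2 <- suppressWarnings(normality_screen(tab2, c("x", "heavy")))
  expect_true(rep2$pass[rep2$variable == "x"])
  expect_true(abs(rep2$skewness[1]) <= 3 && abs(rep2$kurtosis[1]) <= 10)
  # a wildly lognormal variable fails and warns, but does not error
  expect_warning(normality_screen(tab2, "heavy"), "failing")
  expect_false(rep2$pass[rep2$variable == "heavy"])
  # n < 4 reported NA
  rep3 <- normality_screen(data.frame(z = c(1, 2, 3)), "z")
  expect_true(is.na(rep3$skewness))
})
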