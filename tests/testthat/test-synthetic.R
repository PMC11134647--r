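test_that("generation is deterministic and sex configs differ only where documented", {
  cfg <- default_config("male", n = 200)
  t1 <- generate_cohort(cfg, seed = 5)
  t2 <- generate_cohort(cfg, seed = 5)
  expect_identical(t1, t2)
  t3 <- generate_cohort(cfg, seed = 6)
  expect_false(identical(t1$age, t3$age))
  expect_error(generate_cohort(cfg), "seed is mandatory")

  cm <- default_config("male"); cf <- default_config("female")
  expect_equal(cm$exogenous$name, cf$exogenous$name)
  expect_equal(cm$structural$to_sleep, cf$structural$to_sleep)
  expect_false(identical(cm$structural$to_mets, cf$structural$to_mets))
  expect_equal(cm$exogenous$mean[1], 46.62)
  expect_equal(cm$exogenous$sd[1], 8.01)
  expect_equal(cm$structural$sleep_to_mets, 0.050)
  expect_equal(cf$structural$sleep_to_mets, 0.010)
  expect_equal(cm$n, 2125L)
  expect_equal(cf$n, 1810L)
})

test_that("configured marginal moments are recovered within Monte-Carlo error", {
  cfg <- default_config("male", n = 10000)
  cfg$structural$to_sleep[] <- 0
  cfg$structural$to_mets[] <- 0
  cfg$structural$sleep_to_mets <- 0
  cfg$sleep$mean <- 7.06; cfg$sleep$sd <- 1.19
  tab <- generate_cohort(cfg, seed = 51)
  expect_lt(abs(mean(tab$sleep_duration) - 7.06), 3 * 1.19 / sqrt(10000))
  expect_lt(abs(mean(tab$age) - 46.62), 3 * 8.01 / sqrt(10000))
  expect_lt(abs(sd(tab$age) - 8.01), 3 * 8.01 / sqrt(5000))
})

test_that("indicator covariances match the closed-form lambda lambda' V + Theta", {
  cfg <- default_config("male", n = 50000)
  tab <- generate_cohort(cfg, seed = 52)
  ind <- cfg$indicators
  lam_raw <- ind$sd * ind$loading
  Sigma_true <- tcrossprod(lam_raw) + diag(ind$sd^2 * (1 - ind$loading^2))
  Shat <- cov(tab[, ind$name])
  n <- 50000
  for (i in 1:3) for (j in 1:3) {
    mc_se <- sqrt((Sigma_true[i, i] * Sigma_true[j, j] + Sigma_true[i, j]^2) / n)
    expect_lt(abs(Shat[i, j] - Sigma_true[i, j]), 3 * mc_se)
  }
})

test_that("true_effects is the closed-form path-enumeration oracle", {
  cfg <- default_config("male")
  # single product path
  c0 <- cfg
  c0$structural$to_sleep[] <- 0
  c0$structural$to_mets[] <- 0
  c0$structural$to_sleep["nap_duration"] <- 0.5
  c0$structural$sleep_to_mets <- 0.4
  e0 <- true_effects(c0)
  expect_equal(e0$indirect[e0$predictor == "nap_duration"], 0.20,
               tolerance = 1e-12)
  # default config: indirect = a * b for every exogenous predictor
  eff <- true_effects(cfg)
  b <- cfg$structural$sleep_to_mets
  for (v in names(cfg$structural$to_sleep)) {
    expect_equal(eff$indirect[eff$predictor == v],
                 unname(cfg$structural$to_sleep[v] * b), tolerance = 1e-12)
    expect_equal(eff$direct[eff$predictor == v],
                 unname(cfg$structural$to_mets[v]), tolerance = 1e-12)
  }
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-15)
  # zeroing the mediator path kills every indirect effect
  cz <- cfg; cz$structural$sleep_to_mets <- 0
  expect_true(all(true_effects(cz)$indirect == 0))
})

test_that("the minutes variables are censored at zero and invariants hold", {
  tab <- generate_cohort(default_config("female", n = 3000), seed = 53)
  expect_gte(min(tab$sleep_latency), 0)
  expect_gte(min(tab$nap_duration), 0)
  expect_gte(min(tab$night_shift), 0)
  expect_true(all(tab$sleep_duration >= 0 & tab$sleep_duration <= 24))
  expect_true(all(tab$tg > 0))
  expect_equal(as.character(unique(tab$sex)), "female")
})

test_that("the attrition fixture replays the printed cascade exactly", {
  fx <- attrition_fixture()
  expect_equal(nrow(fx), 10047L)
  res <- apply_exclusions(fx, default_exclusion_rules())
  expect_equal(unname(res$report$excluded),
               c(1709L, 194L, 560L, 58L, 125L, 1574L, 800L, 328L, 670L, 94L))
  expect_equal(res$report$final_n, 3935L)
  expect_equal(sum(res$table$sex == "male"), 2125L)
  expect_equal(sum(res$table$sex == "female"), 1810L)
})
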