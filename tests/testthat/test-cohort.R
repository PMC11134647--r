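test_that("read_cohort reads back what was written and enforces the schema", {
  tab <- generate_cohort(default_config("male", n = 25), seed = 11)
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE)
  back <- read_cohort(tmp)
  expect_equal(nrow(back), 25)
  for (col in c("age", "bmi", "wc", "tg", "sleep_duration", "mets_severity"))
    expect_equal(back[[col]], tab[[col]], tolerance = 1e-12)
  expect_equal(as.character(back$sex), as.character(tab$sex))

  # missing mandatory column is a schema error naming the column
  tab2 <- tab[, setdiff(names(tab), "sbp")]
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab2, tmp2, row.names = FALSE)
  expect_error(read_cohort(tmp2), "sbp")

  # column remapping via schema
  tab3 <- tab
  names(tab3)[names(tab3) == "sbp"] <- "systolic_bp"
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab3, tmp3, row.names = FALSE)
  remapped <- read_cohort(tmp3, schema = c(sbp = "systolic_bp"))
  expect_equal(remapped$sbp, tab$sbp, tolerance = 1e-12)

  # empty file is an input error
  tmp4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), tmp4)
  expect_error(read_cohort(tmp4))
})

test_that("unparseable mandatory fields flag rows incomplete, not dropped", {
  tab <- generate_cohort(default_config("female", n = 5), seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  tab$bmi <- as.character(tab$bmi)
  tab$bmi[2] <- "not-a-number"
  utils::write.csv(tab, tmp, row.names = FALSE)
  back <- suppressWarnings(read_cohort(tmp))
  expect_equal(nrow(back), 5)
  expect_false(back$complete[2])
  expect_true(all(back$complete[-2]))
})

test_that("exclusion cascade is sequential, conserving and order-insensitive in its survivor set", {
  # brute-force replay on a small table with overlapping rules
  tab <- data.frame(
    id = 1:10, sex = rep(c("male", "female"), 5),
    cvd = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE),
    smoker = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  rules <- list(exclusion_rule("cvd", ~cvd), exclusion_rule("smoker", ~smoker))
  res <- apply_exclusions(tab, rules)
  # brute force: survivors satisfy no predicate
  expect_equal(res$table$id, tab$id[!(tab$cvd | tab$smoker)])
  expect_equal(unname(res$report$excluded["cvd"]), sum(tab$cvd))
  expect_equal(unname(res$report$excluded["smoker"]),
               sum(tab$smoker & !tab$cvd))
  expect_equal(res$report$initial_n - sum(res$report$excluded),
               res$report$final_n)

  # permuting overlapping rules changes attribution, never the survivor set
  res2 <- apply_exclusions(tab, rev(rules))
  expect_equal(sort(res2$table$id), sort(res$table$id))
  expect_equal(res2$report$final_n, res$report$final_n)
  expect_equal(unname(res2$report$excluded["smoker"]), sum(tab$smoker))

  # overlap-permitting counting keeps the survivor set, not the counts
  res3 <- apply_exclusions(tab, rules, sequential = FALSE)
  expect_equal(sort(res3$table$id), sort(res$table$id))
  expect_equal(unname(res3$report$excluded["smoker"]), sum(tab$smoker))

  # empty rule list leaves the table unchanged
  res4 <- apply_exclusions(tab, list())
  expect_equal(res4$report$final_n, nrow(tab))
  expect_equal(res4$table, tab)

  # unknown field in a predicate is a configuration error
  expect_error(apply_exclusions(tab, list(exclusion_rule("bad", ~nosuch))),
               "nosuch")
})

test_that("attrition conservation holds across random rule sets", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 50
    tab <- data.frame(a = runif(n) < 0.3, b = runif(n) < 0.2,
                      c = runif(n) < 0.4)
    rules <- list(exclusion_rule("a", ~a), exclusion_rule("b", ~b),
                  exclusion_rule("c", ~c))
    rep_out <- apply_exclusions(tab, rules)$report
    expect_equal(rep_out$initial_n - sum(rep_out$excluded), rep_out$final_n)
  }
})

test_that("compare_means matches the pooled-t hand computation and conventions", {
  r <- compare_means(c(1, 2, 3), c(4, 5, 6), method = "pooled")
  expect_equal(r$statistic, -3.6742346, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p.value, 0.0213127, tolerance = 1e-4)

  # identical groups
  r0 <- compare_means(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  # zero variance in both groups, equal means -> p = 1 by convention
  rz <- compare_means(c(2, 2, 2), c(2, 2))
  expect_equal(rz$p.value, 1)

  # pooled and Welch agree for equal variance and equal n
  set.seed(1)
  x <- rnorm(40); y <- rnorm(40)
  rp <- compare_means(x, y, "pooled"); rw <- compare_means(x, y, "welch")
  expect_equal(rp$statistic, rw$statistic, tolerance = 1e-3)
  expect_equal(rp$p.value, rw$p.value, tolerance = 1e-3)

  expect_error(compare_means(1, c(1, 2)), "two")
})

test_that("compare_proportions is Pearson chi-square without correction", {
  # MetS-by-sex 2x2 from the cohort's descriptive counts
  r <- compare_proportions(rbind(c(422, 1703), c(600, 1210)))
  expect_equal(r$chi2, 89.797, tolerance = 1e-3)
  expect_lt(r$p.value, 0.001)
  expect_equal(r$df, 1)

  # perfectly proportional table
  r0 <- compare_proportions(rbind(c(10, 20), c(20, 40)))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p.value, 1)

  # df from dimensions
  expect_equal(compare_proportions(rbind(c(5, 6, 7), c(8, 9, 10)))$df, 2)

  expect_error(compare_proportions(rbind(c(0, 0), c(1, 2))), "marginal")

  # brute force sum (O-E)^2/E on random tables up to 4x4
  set.seed(2)
  for (rep in 1:10) {
    r <- sample(2:4, 1); k <- sample(2:4, 1)
    tab <- matrix(sample(1:30, r * k, replace = TRUE), r, k)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(compare_proportions(tab)$chi2, sum((tab - E)^2 / E),
                 tolerance = 1e-10)
  }
})

test_that("describe_by_sex reports means, percentages and p-values correctly", {
  tab <- generate_cohort(default_config("male", n = 60), seed = 5)
  tab2 <- generate_cohort(default_config("female", n = 40), seed = 6)
  both <- rbind(tab, tab2)
  d <- describe_by_sex(both, c("age", "residence"))
  # reported means equal direct column means
  expect_equal(d$male_mean[d$variable == "age"],
               mean(both$age[both$sex == "male"]))
  expect_equal(d$female_mean[d$variable == "age"],
               mean(both$age[both$sex == "female"]))
  # percentages within a categorical variable sum to 100 per sex
  res_rows <- d$variable == "residence"
  expect_equal(sum(d$male_pct[res_rows]), 100, tolerance = 0.1)
  expect_equal(sum(d$female_pct[res_rows]), 100, tolerance = 0.1)
  # single-sex table reports NA comparisons
  d1 <- describe_by_sex(tab, c("age"))
  expect_true(is.na(d1$p.value[d1$variable == "age"]))
  # all-missing variable warns and reports NA
  both$ghost <- NA_real_
  expect_warning(dg <- describe_by_sex(both, "ghost"), "missing")
  expect_true(is.na(dg$overall[dg$variable == "ghost"]))
})
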