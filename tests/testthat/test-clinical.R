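# Contingency tests, correlation, product-limit survival, log-rank.

test_that("Pearson chi-squared matches hand cases and the df formula", {
  r <- contingency_test(matrix(10, 2, 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- contingency_test(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(r2$statistic, 20)
  expect_identical(r2$df, 1L)

  r3 <- contingency_test(matrix(c(5, 3, 2, 4, 6, 1), 2, 3))
  expect_identical(r3$df, 2L)

  expect_warning(r4 <- contingency_test(matrix(c(5, 3, 0, 0, 2, 4), 2, 3)),
                 "empty")
  expect_identical(r4$dims, c(2L, 2L))
  expect_error(suppressWarnings(
    contingency_test(matrix(c(5, 0, 3, 0), 2, 2))), "below 2x2")
  expect_error(contingency_test(matrix(c(-1, 2, 3, 4), 2, 2)), ">= 0")
})

test_that("the statistic equals the textbook sum((o-e)^2/e) on random
           tables", {
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 8) + 1, 2, 3)
    expect_equal(contingency_test(tab)$statistic, oracle_pearson_chisq(tab))
  }
})

test_that("Yates correction is available behind its flag", {
  tab <- matrix(c(8, 2, 3, 9), 2, 2)
  plain <- contingency_test(tab)$statistic
  yates <- contingency_test(tab, correct = TRUE)$statistic
  expect_lt(yates, plain)
})

test_that("clinical breakdown reproduces stratum percentages from counts
           and excludes missing values per parameter", {
  # age strata sized like a large CRC cohort: 213/240 hypo under 65,
  # 268/287 at 65 and over
  n1 <- 240; n2 <- 287
  calls <- pair_ratio(c(rep(0.2, 213), rep(1, 27), rep(0.2, 268), rep(1, 19)),
                      rep(1, n1 + n2),
                      patient_id = sprintf("P%03d", 1:(n1 + n2)))
  clin <- clinical_table(sprintf("P%03d", 1:(n1 + n2)),
                         age = c(rep(50, n1), rep(70, n2)))
  bd <- clinical_breakdown(calls, clin, "age")
  young <- bd$rows[bd$rows$stratum == "<65", ]
  expect_identical(young$n, 240L)
  expect_lt(abs(young$pct_hypo - 88.8), 0.1)
  old <- bd$rows[bd$rows$stratum == ">=65", ]
  expect_lt(abs(old$pct_hypo - 93.4), 0.1)
  expect_s3_class(bd$test, "contingency_result")

  # a missing covariate drops the patient from this breakdown only
  clin2 <- clinical_table(c("a", "b", "c"), age = c(50, NA, 70))
  calls2 <- pair_ratio(c(0.2, 0.2, 1), c(1, 1, 1),
                       patient_id = c("a", "b", "c"))
  bd2 <- clinical_breakdown(calls2, clin2, "age")
  expect_identical(bd2$n_missing, 1L)
  expect_identical(sum(bd2$rows$n), 2L)
  expect_error(clinical_breakdown(calls2, clin2, "shoe_size"),
               "'arg' should be one of|unknown clinical parameter")
})

test_that("identical class rates across strata give a null association", {
  set.seed(17)
  p_values <- vapply(1:30, function(i) {
    n <- 200
    calls <- pair_ratio(ifelse(runif(n) < 0.7, 0.2, 1), rep(1, n),
                        patient_id = sprintf("P%03d", 1:n))
    clin <- clinical_table(sprintf("P%03d", 1:n),
                           sex = sample(c("male", "female"), n, TRUE))
    bd <- clinical_breakdown(calls, clin, "sex")
    if (is.null(bd$test)) NA_real_ else bd$test$p_value
  }, numeric(1))
  p_values <- p_values[!is.na(p_values)]
  # under the null, small p-values are no more frequent than their level
  expect_lt(mean(p_values < 0.05), 0.25)
  expect_gt(mean(p_values), 0.3)
})

test_that("correlations match the direct covariance formula and flag
           degenerate input", {
  x <- 1:6
  r1 <- methylation_expression_correlation(x, 2 * x)
  expect_equal(r1$r, 1)
  expect_equal(r1$rho, 1)
  r2 <- methylation_expression_correlation(x, -x)
  expect_equal(r2$r, -1)

  mx <- c(1, 2, 3, 4, 5); my <- c(2, 1, 5, 4, 6)
  res <- methylation_expression_correlation(mx, my)
  hand_r <- sum((mx - mean(mx)) * (my - mean(my))) /
    sqrt(sum((mx - mean(mx))^2) * sum((my - mean(my))^2))
  expect_equal(res$r, hand_r)
  expect_identical(res$n, 5L)

  flat <- methylation_expression_correlation(rep(0.5, 5), 1:5)
  expect_true(flat$undefined)
  expect_true(is.na(flat$r))
  expect_error(methylation_expression_correlation(1:2, 1:2), "at least 3")
})

test_that("the product-limit curve matches hand computation and the
           empirical survival function without censoring", {
  none <- km_estimate(c(3, 5, 8), c(FALSE, FALSE, FALSE))
  expect_true(all(none$survival == 1))

  one <- km_estimate(c(5, 6, 7, 8), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(km_survival_at(one, 5), 0.75)

  # times (2, 3+, 5, 7): risk sets 4, 2, 1 at the event times
  mix <- km_estimate(c(2, 3, 5, 7), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(km_survival_at(mix, c(2, 5, 7)),
               c(3 / 4, 3 / 4 * 1 / 2, 0))

  set.seed(9)
  t_all <- rexp(40, 0.1)
  km <- km_estimate(t_all, rep(TRUE, 40))
  emp <- vapply(km$time, function(tt) mean(t_all > tt), numeric(1))
  expect_equal(km$survival, emp)
  expect_equal(km$survival, oracle_km(t_all, rep(TRUE, 40))$survival)

  expect_error(km_estimate(c(-1, 2), c(TRUE, TRUE)), "negative")
})

test_that("log-rank matches the risk-set enumeration oracle and is
           label-symmetric", {
  ta <- c(2, 4, 6); ea <- c(TRUE, TRUE, FALSE)
  tb <- c(1, 3, 5); eb <- c(TRUE, FALSE, TRUE)
  lr <- logrank_test(ta, ea, tb, eb)
  expect_equal(lr$statistic, oracle_logrank(ta, ea, tb, eb))
  swapped <- logrank_test(tb, eb, ta, ea)
  expect_equal(swapped$statistic, lr$statistic)
  expect_equal(swapped$p_value, lr$p_value)

  same <- logrank_test(ta, ea, ta, ea)
  expect_equal(same$statistic, 0, tolerance = 1e-12)

  no_ev <- logrank_test(c(1, 2), c(FALSE, FALSE), c(3, 4), c(FALSE, FALSE))
  expect_false(no_ev$defined)
  expect_true(is.na(no_ev$statistic))
  expect_error(logrank_test(numeric(0), logical(0), 1, TRUE), "nonempty")
})

test_that("survival stratification by call supports clinical subgroups", {
  sim <- generate_clinical_survival(survival_sim_config(
    n_patients = 200, hypo_fraction = 0.6, hazard_ratio_hypo = 2.5,
    censor_rate = 0.2, seed = 12))
  all_p <- survival_by_call(sim$calls, sim$clinical)
  expect_lt(all_p$logrank$p_value, 0.05)
  expect_equal(all_p$logrank$n_a + all_p$logrank$n_b, 200)
  male <- survival_by_call(sim$calls, sim$clinical, subgroup = "male")
  expect_lt(male$logrank$n_a + male$logrank$n_b, 200)
  expect_identical(male$subgroup, "male")
})
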