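test_that("Pearson statistic matches the published 2x2 and trivial cases", {
  res <- suppressWarnings(pearson_chi_square(matrix(c(0, 4, 7, 10), 2)))
  expect_equal(round(res$statistic, 3), 2.471)
  expect_equal(res$df, 1)

  res2 <- suppressWarnings(pearson_chi_square(matrix(c(1, 3, 14, 3), 2)))
  expect_equal(round(res2$statistic, 3), 5.219)

  res3 <- pearson_chi_square(matrix(5, 2, 2))
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
})

test_that("all-zero categories are dropped before computing df", {
  m <- rbind(s0 = c(1, 8), s1 = c(0, 5), s2 = c(0, 0), s3 = c(3, 4))
  colnames(m) <- c("implantitis", "mucositis")
  res <- suppressWarnings(pearson_chi_square(m))
  expect_equal(res$df, 2)
  expect_equal(res$dropped_rows, "s2")
  expect_equal(round(res$statistic, 3), 4.118)
  expect_error(pearson_chi_square(matrix(c(5, 0, 5, 0), 2)), "Degenerate")
})

test_that("statistic equals the brute-force double loop on random tables", {
  set.seed(2024)
  for (rep in 1:60) {
    nr <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    O <- matrix(sample(0:8, nr * nc, replace = TRUE) + 1L, nr, nc)
    res <- suppressWarnings(pearson_chi_square(O))
    expect_equal(res$statistic, chisq_loop(O), tolerance = 1e-9)
  }
})

test_that("statistic is invariant to permutation and transposition", {
  set.seed(7)
  O <- matrix(sample(1:9, 12, replace = TRUE), 3, 4)
  base <- suppressWarnings(pearson_chi_square(O))$statistic
  expect_equal(suppressWarnings(pearson_chi_square(O[sample(3), sample(4)]))$statistic,
               base)
  expect_equal(suppressWarnings(pearson_chi_square(t(O)))$statistic, base)
})

test_that("upper-tail probabilities match the published values and an integral oracle", {
  expect_equal(round(chi_square_p(5.219, 1), 3), 0.022)
  expect_equal(round(chi_square_p(5.868, 2), 3), 0.053)
  expect_equal(chi_square_p(0, 3), 1.0)
  for (df in c(1, 2, 5)) {
    q <- stats::qchisq(0.95, df)
    expect_equal(chi_square_p(q, df), 0.05, tolerance = 1e-6)
    expect_equal(chi_square_p(q, df), chisq_upper_num(q, df),
                 tolerance = 1e-6)
  }
  # strictly decreasing in the statistic for fixed df
  qs <- seq(0.1, 20, by = 0.1)
  expect_true(all(diff(chi_square_p(qs, 2)) < 0))
  expect_error(chi_square_p(3, 0), "positive integer")
  expect_error(chi_square_p(-1, 1), ">= 0")
})

test_that("two-proportion z-test uses pooled variance, two-sided", {
  eq <- two_proportion_test(5, 10, 5, 10)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(two_proportion_test(9, 21, 9, 21)$p_value, 1)

  far <- two_proportion_test(10, 10, 0, 10)
  expect_lt(far$p_value, 0.001)
  # cross-check against the uncorrected chi-square equivalence z^2 = X^2
  ref <- suppressWarnings(
    stats::prop.test(c(7, 3), c(12, 15), correct = FALSE))
  got <- two_proportion_test(7, 12, 3, 15)
  expect_equal(got$z^2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  expect_error(two_proportion_test(1, 0, 1, 2), "at least one")
  expect_error(two_proportion_test(3, 2, 1, 2), "exceed")
})

test_that("contingency tables cross-tabulate cohort factors by diagnosis", {
  fx <- study_fixture()
  ct <- build_contingency(fx, "sex")
  expect_equal(rownames(ct$observed), c("F", "M"))
  expect_equal(unname(ct$observed[, "peri_implantitis"]), c(0, 4))
  expect_equal(unname(ct$observed[, "mucositis"]), c(7, 10))

  pdl <- build_contingency(fx, "pdl_history")
  expect_equal(unname(pdl$observed[, "mucositis"]), c(8, 5, 0, 4))
  res <- suppressWarnings(pearson_chi_square(pdl))
  expect_equal(res$dropped_rows, "Score 2")
  expect_equal(res$df, 2)

  expect_error(build_contingency(fx[0, ], "sex"), "[Ee]mpty")
  expect_error(build_contingency(fx, "shoe_size"), "Unknown cohort factor")
})

test_that("cohort proportions report counts and one-decimal percentages", {
  fx <- study_fixture()
  plaque <- cohort_proportions(fx, "plaque_status")
  expect_equal(plaque$n[plaque$level == "Score 1"], 9L)
  expect_equal(plaque$pct[plaque$level == "Score 1"], 42.9)
  ging <- cohort_proportions(fx, "gingival_status")
  expect_equal(ging$n[ging$level == "Score 0"], 11L)
  expect_equal(ging$pct[ging$level == "Score 0"], 52.4)
  one <- cohort_proportions(make_record(), "sex")
  expect_equal(one$pct[one$level == "M"], 100.0)
  expect_error(cohort_proportions(make_record()[0, ], "sex"), "[Ee]mpty")
})

test_that("evaluate_cohort skips degenerate factors and flags small cells", {
  fx <- study_fixture()
  ev <- evaluate_cohort(fx)
  tests <- tidy(ev)
  degen <- tests$factor[is.na(tests$statistic)]
  expect_setequal(degen, c("suppuration", "diabetes", "residual_cement"))
  expect_true(all(tests$min_expected[!is.na(tests$min_expected)] > 0))
  g <- glance(ev)
  expect_equal(g$n_implants, 21L)
  expect_equal(g$n_patients, 13L)
  expect_equal(g$n_significant, 2L)  # alcohol and risk-category rows
})
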