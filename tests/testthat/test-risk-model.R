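test_that("periodontal history/compliance scoring matches the rubric rows", {
  cases <- list(
    list(hist = FALSE, comp = TRUE, score = 0L, pct = 0),
    list(hist = FALSE, comp = FALSE, score = 1L, pct = 2.5),
    list(hist = TRUE, comp = TRUE, score = 2L, pct = 7.5),
    list(hist = TRUE, comp = FALSE, score = 3L, pct = 12.5))
  for (cs in cases) {
    got <- score_periodontal_history(cs$hist, cs$comp)
    expect_equal(got$score, cs$score)
    expect_equal(got$percentage, cs$pct)
  }
})

test_that("index scoring maps 0:3 to 0/2.5/5/7.5 for both indices", {
  expect_equal(score_index(0:3, "plaque_status")$percentage,
               c(0, 2.5, 5.0, 7.5))
  expect_equal(score_index(0:3, "gingival_status")$percentage,
               c(0, 2.5, 5.0, 7.5))
  expect_error(score_index(5), "0-3")
  expect_error(score_index(-1), "0-3")
  expect_error(score_index(1.5), "0-3")
})

test_that("glucose banding uses half-open intervals at the printed edges", {
  expect_equal(score_diabetes(95)$percentage, 0)
  expect_equal(score_diabetes(130)$percentage, 10.0)
  expect_equal(score_diabetes(109.5)$percentage, 2.5)
  # band edges: each lower edge belongs to its band
  edges <- c(102, 110, 118, 126, 134)
  expect_equal(score_diabetes(edges)$percentage, c(2.5, 5.0, 7.5, 10.0, 12.5))
  expect_equal(score_diabetes(edges - 0.001)$percentage,
               c(0, 2.5, 5.0, 7.5, 10.0))
  expect_error(score_diabetes(-5), ">= 0")
})

test_that("smoking bands follow nonsmoker/former/current cigarette counts", {
  expect_equal(score_smoking("nonsmoker")$percentage, 0)
  expect_equal(score_smoking("former")$percentage, 2.5)
  expect_equal(score_smoking("current", 9)$percentage, 5.0)
  expect_equal(score_smoking("current", 10)$percentage, 7.5)
  expect_equal(score_smoking("current", 19)$percentage, 7.5)
  expect_equal(score_smoking("current", 20)$percentage, 10.0)
  expect_equal(score_smoking("current", 21)$percentage, 12.5)
  expect_error(score_smoking("current"), "cigarettes_per_day")
  expect_error(score_smoking("pipe"), "status")
})

test_that("binary factors weigh 12.5 (cement, overload) or 10 (alcohol)", {
  expect_equal(score_binary_factor("residual_cement", TRUE)$percentage, 12.5)
  expect_equal(score_binary_factor("occlusal_overload", TRUE)$percentage, 12.5)
  expect_equal(score_binary_factor("other_alcohol", TRUE)$percentage, 10.0)
  for (f in c("residual_cement", "occlusal_overload", "other_alcohol")) {
    expect_equal(score_binary_factor(f, FALSE)$percentage, 0)
  }
  expect_error(score_binary_factor("suppuration", TRUE), "must be one of")
})

test_that("keratinized width of 2 mm or more is sufficient", {
  expect_equal(score_keratinized_width(3.0)$percentage, 0)
  expect_equal(score_keratinized_width(1.0)$percentage, 12.5)
  expect_equal(score_keratinized_width(2.0)$percentage, 0)
  expect_equal(score_keratinized_width(1.999)$percentage, 12.5)
  expect_error(score_keratinized_width(-1), ">= 0")
})

test_that("risk categories partition the total range at 25 and 50", {
  expect_equal(as.character(categorize_risk(c(0, 24.9, 25, 37.5, 50, 50.1, 95))),
               c("low", "low", "moderate", "moderate", "moderate",
                 "high", "high"))
  expect_error(categorize_risk(-1), ">= 0")
  expect_error(categorize_risk(101), "\\[0, 100\\]")
  # every representable total maps to exactly one category
  totals <- seq(0, 100, by = 2.5)
  cats <- categorize_risk(totals)
  expect_false(anyNA(cats))
  expect_false(is.unsorted(as.integer(cats)))
})

test_that("assess_risk sums the nine parameter percentages", {
  zero <- assess_risk(make_record())
  expect_equal(zero$total_percentage, 0)
  expect_equal(as.character(zero$category), "low")

  maxed <- assess_risk(make_max_record())
  expect_equal(maxed$total_percentage, 100)
  expect_equal(as.character(maxed$category), "high")

  mixed <- assess_risk(make_record(
    periodontal_history = TRUE, compliant = FALSE, mpi = 2L, mgi = 1L,
    random_glucose_mg_dl = 95, smoking_status = "former",
    occlusal_overload = TRUE, keratinized_width_mm = 1, alcohol = TRUE))
  expect_equal(mixed$total_percentage, 57.5)
  expect_equal(as.character(mixed$category), "high")
})

test_that("totals are multiples of 2.5 within the rubric range for arbitrary records", {
  set.seed(42)
  spec <- cohort_spec(n_patients = 40, seed = 99)
  cohort <- generate_cohort(spec)
  prof <- assess_risk(cohort)
  expect_true(all(prof$total_percentage >= 0 & prof$total_percentage <= 100))
  expect_true(all(abs(prof$total_percentage / 2.5 -
                        round(prof$total_percentage / 2.5)) < 1e-12))
  # total equals the sum of the per-parameter contributions, exactly
  long <- tidy(prof)
  sums <- tapply(long$percentage, long$implant_id, sum)
  expect_equal(as.numeric(sums[prof$implant_id]), prof$total_percentage)
})

test_that("raising any single parameter never lowers the total or category", {
  base <- make_record(mpi = 1L, mgi = 1L, random_glucose_mg_dl = 105,
                      smoking_status = "former")
  for (par in names(parameter_levels())) {
    setters <- parameter_levels()[[par]]
    totals <- vapply(setters, function(s) {
      assess_risk(s(base))$total_percentage
    }, numeric(1))
    cats <- vapply(setters, function(s) {
      as.integer(assess_risk(s(base))$category)
    }, integer(1))
    expect_false(is.unsorted(totals), info = par)
    expect_false(is.unsorted(cats), info = par)
  }
})

test_that("per-parameter validation errors name the parameter", {
  expect_error(assess_risk(make_record(mpi = 7L)), "mpi")
  expect_error(assess_risk(make_record(mgi = 7L)), "0-3")
})
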