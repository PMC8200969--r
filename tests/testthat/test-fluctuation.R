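test_that("delta fluctuation equals brute-force max - min, with invariances", {
  expect_identical(delta_fluctuation(c(10, 10, 10)), 0)
  expect_identical(delta_fluctuation(c(12.0, 9.5, 10.1)), 2.5)
  expect_error(delta_fluctuation(c(1, 2)), "three")
  set.seed(31)
  for (i in 1:1000) {
    v <- rnorm(3, 0, 10)
    brute <- max(v[1], v[2], v[3]) - min(v[1], v[2], v[3])
    expect_identical(delta_fluctuation(v), brute)
  }
  # translation invariance and positive scaling
  v <- c(4.2, 7.9, 5.5)
  expect_equal(delta_fluctuation(v + 100), delta_fluctuation(v))
  expect_equal(delta_fluctuation(3 * v), 3 * delta_fluctuation(v))
})

test_that("incomplete days are skipped and reported, never imputed", {
  rec <- make_records("S1", days = 1:3, value = function(g) 10 + g$study_day)
  rec <- rec[!(rec$study_day == 2 & rec$timepoint == "evening_wash"), ]
  tab <- delta_fluctuation_table(rec, "pore_area")
  expect_identical(tab$study_day, c(1L, 3L))
  expect_identical(tab$delta, c(0, 0))
  inc <- attr(tab, "incomplete")
  expect_identical(inc$study_day, 2L)
  expect_identical(inc$n_present, 2L)
})

test_that("weekly averages are subject-first and reorder-invariant", {
  # one subject, 7 identical days: weekly mean is the daily value
  r1 <- make_records("S1", days = 1:7, value = 42)
  w1 <- weekly_average(r1, "pore_area")
  expect_equal(w1$mean_au[w1$week_index == -4], rep(42, 3))
  expect_true(all(is.na(w1$mean_au[w1$week_index != -4])))

  # unequal day counts: subject means 10 and 20 -> grand mean 15
  r2 <- rbind(make_records("A", days = 1:6, value = 10),
              make_records("B", days = 1:2, value = 20))
  w2 <- weekly_average(r2, "pore_area")
  expect_equal(w2$mean_au[w2$week_index == -4], rep(15, 3))
  expect_equal(w2$n_subjects[w2$week_index == -4], rep(2L, 3))

  # permuting days within subjects leaves the table unchanged
  set.seed(32)
  r3 <- make_records("A", days = 1:7,
                     value = function(g) g$study_day + runif(nrow(g)))
  shuf <- r3[sample(nrow(r3)), ]
  expect_equal(weekly_average(r3, "pore_area"),
               weekly_average(shuf, "pore_area"))
})

test_that("baseline timepoint comparison needs 6 subjects and finds nulls", {
  # identical values across timepoints: no pair significant
  rec <- make_records(sprintf("S%d", 1:8), days = c(1, 8, 15, 22), value = 50)
  res <- compare_timepoints_baseline(rec, "pore_area")
  expect_length(res, 3L)
  expect_false(any(vapply(res, function(r) r$significant, logical(1))))
  # five subjects: insufficient-data error
  rec5 <- make_records(sprintf("S%d", 1:5), days = c(1, 8),
                       value = function(g) rnorm(nrow(g), 50))
  expect_error(compare_timepoints_baseline(rec5, "pore_area"),
               "insufficient")
})

test_that("simulated cohorts recover the generated timepoint ordering", {
  rec <- generate_cohort(cohort_params(seed = 33), mode = "values")
  for (m in c("pore_area", "roughness")) {
    wa <- weekly_average(rec, m)
    for (wk in -4:-1) {
      cell <- wa[wa$week_index == wk, ]
      expect_identical(cell$timepoint[which.max(cell$mean_au)],
                       "morning_wake")
    }
  }
  wa <- weekly_average(rec, "redness")
  for (wk in -4:-1) {
    cell <- wa[wa$week_index == wk, ]
    expect_identical(cell$timepoint[which.max(cell$mean_au)], "evening_wash")
  }
})

test_that("treatment effects and delta-fluctuation reduction are detected", {
  rec <- generate_cohort(cohort_params(seed = 34), mode = "values")
  te <- treatment_effect(rec, "pore_area")
  expect_named(te, c("morning_wake", "morning_wash", "evening_wash",
                     "delta_fluctuation"))
  # direction: week-4 morning_wake mean below baseline (delta = -8 au)
  mw <- te$morning_wake
  expect_true(mw$significant)
  expect_lt(mw$statistic, mw$n_pairs_or_groups * (mw$n_pairs_or_groups + 1) / 4)
  expect_true(te$delta_fluctuation$significant)
  # pooled-baseline option runs
  tp <- treatment_effect(rec, "pore_area", baseline = "pooled")
  expect_true(tp$morning_wake$significant)
})

test_that("between-study comparison uses Welch on subject baseline means", {
  ra <- generate_cohort(cohort_params(n_subjects = 20, seed = 35),
                        mode = "values")
  expect_identical(compare_studies(ra, ra, "pore_area")$statistic, 0)
  mods <- dermaflux:::default_metric_models()
  mods$pore_area$mu <- 130
  rb <- generate_cohort(cohort_params(n_subjects = 20, metric_models = mods,
                                      seed = 36), mode = "values")
  cmp <- compare_studies(ra, rb, "pore_area")
  expect_true(cmp$significant)
  expect_identical(cmp$method, "welch_t")
  tiny <- make_records(c("A", "B"), days = 1, value = 1)
  expect_error(compare_studies(tiny, ra, "pore_area"), "insufficient")
})
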