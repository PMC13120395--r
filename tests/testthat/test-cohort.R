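test_that("bundled cohort reads with the expected group structure", {
  expect_s3_class(table1, "cohort")
  expect_equal(nrow(table1), 30)
  expect_equal(sum(table1$exposure == "exposed"), 20)
  expect_equal(sum(table1$exposure == "non_exposed"), 10)
  expect_false(any(duplicated(table1$cat_id)))
})

test_that("reader accepts report-style headers and exposure spellings", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c(
    "Cat ID,Exposure,Age,Sex,Smoker Owners (n),Cigarettes/Day",
    "1,Exposed,1,M,1,6",
    "2,Non-exposed,5,F,0,0"
  ), tf)
  coh <- read_cohort_table(tf)
  expect_equal(coh$exposure, c("exposed", "non_exposed"))
  expect_equal(coh$smoker_owners, c(1, 0))
  # optional columns absent stay absent, not zero
  expect_false("cotinine_ng_ml" %in% names(coh))
})

test_that("header-only file yields an empty but valid cohort", {
  tf <- tempfile(fileext = ".csv")
  writeLines("cat_id,exposure,age,sex,smoker_owners,cigarettes_per_day", tf)
  coh <- read_cohort_table(tf)
  expect_equal(nrow(coh), 0)
  expect_error(summarize_exposure(coh), class = "oralcyto_domain_error")
})

test_that("schema and validation errors are specific", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("cat_id,exposure,age,sex", "1,exposed,1,M"), tf)
  expect_error(read_cohort_table(tf), "smoker_owners",
               class = "oralcyto_schema_error")
  # non-exposed with a smoker owner violates the consistency invariant
  tf2 <- tempfile(fileext = ".csv")
  writeLines(c(
    "cat_id,exposure,age,sex,smoker_owners,cigarettes_per_day",
    "1,Non-exposed,2,F,1,0"
  ), tf2)
  expect_error(read_cohort_table(tf2), class = "oralcyto_validation_error")
  # duplicate ids
  df <- data.frame(cat_id = c("a", "a"), exposure = "exposed", age = 1,
                   sex = "M", smoker_owners = 1, cigarettes_per_day = 5)
  expect_error(cohort(df), "duplicate", class = "oralcyto_validation_error")
  # non-parsable numeric cell names the row
  tf3 <- tempfile(fileext = ".csv")
  writeLines(c(
    "cat_id,exposure,age,sex,smoker_owners,cigarettes_per_day",
    "1,exposed,1,M,1,5",
    "2,exposed,abc,M,1,5"
  ), tf3)
  expect_error(read_cohort_table(tf3), "row 2",
               class = "oralcyto_validation_error")
})

test_that("cohort CSV write/read round-trips all fields exactly", {
  coh <- generate_cohort(cohort_config(n_exposed = 5, n_non_exposed = 3,
                                       seed = 42))
  tf <- tempfile(fileext = ".csv")
  write_cohort_table(coh, tf)
  back <- read_cohort_table(tf, provenance = attr(coh, "provenance"))
  expect_equal(as.data.frame(back), as.data.frame(coh), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("inflammation scoring follows the printed thresholds", {
  expect_equal(inflammation_score_from_count(15), 1L)
  expect_equal(inflammation_score_from_count(100), 2L)
  expect_equal(inflammation_score_from_count(101), 3L)
  expect_equal(inflammation_score_from_count(0), 0L)
  expect_equal(inflammation_score_from_count(30), 2L) # 30-100 inclusive
  expect_equal(inflammation_score_from_count(29.9), 1L)
  expect_error(inflammation_score_from_count(-1), class = "oralcyto_domain_error")
  # step function, monotone non-decreasing
  grid <- seq(0, 150, by = 0.5)
  sc <- inflammation_score_from_count(grid)
  expect_true(all(diff(sc) >= 0))
  expect_true(all(sc %in% 0:3))
})

test_that("exposure summary counts match the bundled cohort and sum to group sizes", {
  s <- summarize_exposure(table1)
  expect_equal(unname(s$exposed$by_smoker_owners[["1"]]), 16)
  expect_equal(unname(s$exposed$by_smoker_owners[["2"]]), 4)
  expect_equal(unname(s$exposed$by_sex[["F"]]), 7)
  expect_equal(unname(s$non_exposed$by_sex[["F"]]), 6)
  expect_equal(sum(s$exposed$by_smoker_owners), s$exposed$n)
  expect_equal(sum(s$non_exposed$by_sex), s$non_exposed$n)
  # singleton cohort
  one <- cohort(data.frame(cat_id = "x", exposure = "exposed", age = 2,
                           sex = "F", smoker_owners = 2,
                           cigarettes_per_day = 9))
  expect_equal(unname(summarize_exposure(one)$exposed$by_smoker_owners[["2"]]), 1)
})
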