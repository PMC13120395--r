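test_that("median and IQR use linear-interpolation quantiles", {
  a <- median_iqr(age_exposed)
  expect_equal(a$median, 1.5)
  expect_equal(a$iqr, 4.0)
  b <- median_iqr(age_non)
  expect_equal(b$median, 4.5)
  expect_equal(b$iqr, 2.5)
  cg <- median_iqr(cigs_exposed)
  expect_equal(cg$median, 8.5)
  expect_equal(cg$iqr, 4.0)
  s <- median_iqr(5)
  expect_equal(s$median, 5)
  expect_equal(s$iqr, 0)
  expect_error(median_iqr(numeric(0)), class = "oralcyto_domain_error")
})

test_that("Mann-Whitney exact mode matches full rank enumeration", {
  # complete separation at n1 = n2 = 3: U = 9, two-sided p = 0.1
  mw <- mann_whitney_u(c(4, 5, 6), c(1, 2, 3))
  expect_equal(mw$U, 9)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
  # identical tied samples: distribution is symmetric, p = 1
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$p, 1)
  # exact p equals brute-force enumeration for assorted small samples
  set.seed(31)
  for (rep in 1:8) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    v <- sample(1:100, n1 + n2) # distinct values, no ties
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y)$p, mann_whitney_p_brute(x, y),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), class = "oralcyto_domain_error")
})

test_that("tied large-sample comparisons use the corrected normal approximation", {
  mw <- mann_whitney_u(cigs_exposed, cigs_non)
  expect_equal(mw$method, "normal_approx")
  expect_lt(mw$p, 0.001)
  expect_gt(mann_whitney_u(age_exposed, age_non)$p, 0.05)
})

test_that("Cliff's delta equals brute-force pair counting and is antisymmetric", {
  expect_equal(cliffs_delta(age_exposed, age_non), -0.25)
  expect_equal(cliffs_delta(cigs_exposed, cigs_non), 1)
  expect_equal(cliffs_delta(c(2, 2, 2), c(2, 2, 2)), 0)
  set.seed(7)
  for (rep in 1:10) {
    x <- sample(0:5, sample(2:8, 1), replace = TRUE)
    y <- sample(0:5, sample(2:8, 1), replace = TRUE)
    expect_equal(cliffs_delta(x, y), cliffs_delta_brute(x, y))
    expect_equal(cliffs_delta(x, y), -cliffs_delta(y, x))
  }
})

test_that("bootstrap delta CI degenerates correctly and brackets the estimate", {
  # disjoint supports: every resample gives delta = 1
  ci <- bootstrap_delta_ci(c(5, 6, 7), c(1, 2), reps = 1000, seed = 3)
  expect_equal(c(ci$lo, ci$hi), c(1, 1))
  # single observations: only one attainable delta
  ci1 <- bootstrap_delta_ci(3, 1, reps = 1000, seed = 3)
  expect_equal(c(ci1$lo, ci1$hi), c(1, 1))
  # age comparison: interval brackets the point estimate, reproducibly
  ci2 <- bootstrap_delta_ci(age_exposed, age_non, reps = 2000, seed = 9)
  d <- cliffs_delta(age_exposed, age_non)
  expect_lte(ci2$lo, d)
  expect_gte(ci2$hi, d)
  ci3 <- bootstrap_delta_ci(age_exposed, age_non, reps = 2000, seed = 9)
  expect_identical(ci2, ci3)
})

test_that("Fisher's exact test reports cross-product odds ratios", {
  f <- fisher_exact(matrix(c(7, 13, 6, 4), nrow = 2, byrow = TRUE))
  expect_equal(f$odds_ratio, 28 / 78)
  expect_equal(round(f$odds_ratio, 3), 0.359)
  expect_gt(f$p, 0.05)
  # printed-style interval (Woolf) and the exact conditional alternative
  expect_equal(round(f$or_ci, 2), c(0.08, 1.71))
  fe <- fisher_exact(matrix(c(7, 13, 6, 4), 2, byrow = TRUE),
                     ci_method = "exact")
  expect_lt(fe$or_ci[1], fe$odds_ratio)
  expect_gt(fe$or_ci[2], fe$odds_ratio)
  m <- fisher_exact(matrix(c(13, 7, 4, 6), nrow = 2, byrow = TRUE))
  expect_equal(round(m$odds_ratio, 2), 2.79)
  # orientation reciprocity
  expect_equal(f$odds_ratio * m$odds_ratio, 1)
  # null table
  nul <- fisher_exact(matrix(1, 2, 2))
  expect_equal(nul$odds_ratio, 1)
  expect_equal(nul$p, 1)
  # degenerate tables
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               class = "oralcyto_domain_error")
  z <- fisher_exact(matrix(c(3, 0, 1, 2), 2, byrow = TRUE))
  expect_true(z$zero_cell)
  expect_true(is.infinite(z$odds_ratio))
})

test_that("Spearman rho uses midranks with exact small-sample p", {
  expect_equal(spearman_rho(1:6, c(2, 4, 6, 8, 10, 12))$rho, 1)
  expect_equal(spearman_rho(1:5, -(1:5))$rho, -1)
  s <- spearman_rho(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, 0.8)
  expect_equal(s$method, "exact")
  # exact p equals full permutation enumeration at small n
  set.seed(13)
  for (rep in 1:5) {
    x <- sample(1:50, 6); y <- sample(1:50, 6)
    expect_equal(spearman_rho(x, y)$p, spearman_p_brute(x, y),
                 tolerance = 1e-10)
  }
  # listwise deletion of missing pairs
  s2 <- spearman_rho(c(1, 2, NA, 4, 5), c(2, 4, 1, 8, NA))
  expect_equal(s2$n, 3)
  expect_error(spearman_rho(1:2, 2:3), class = "oralcyto_domain_error")
})

test_that("Fisher-z interval matches the closed form and its edge cases", {
  ci <- fisher_z_ci(0.85, 13)
  expect_equal(round(c(ci$lo, ci$hi), 2), c(0.56, 0.95))
  # symmetric about zero at rho = 0
  c0 <- fisher_z_ci(0, 7)
  expect_equal(c0$lo, -c0$hi)
  # width shrinks with n
  w <- function(n) { ci <- fisher_z_ci(0.5, n); ci$hi - ci$lo }
  expect_true(w(10) > w(100))
  expect_true(w(100) > w(10000))
  expect_lt(w(1e6), 0.01)
  # degenerate |rho| = 1
  d <- fisher_z_ci(1, 13)
  expect_true(d$degenerate)
  expect_equal(c(d$lo, d$hi), c(1, 1))
  expect_error(fisher_z_ci(0.5, 3), class = "oralcyto_domain_error")
  # interval always contains rho
  set.seed(5)
  for (rep in 1:20) {
    r <- stats::runif(1, -0.99, 0.99); n <- sample(4:50, 1)
    ci <- fisher_z_ci(r, n)
    expect_true(ci$lo <= r && r <= ci$hi)
  }
})

test_that("correlation matrix is symmetric with unit diagonal", {
  coh <- generate_cohort(cohort_config(seed = 8))
  cm <- correlation_matrix(coh)
  expect_equal(cm$rho, t(cm$rho))
  expect_equal(unname(diag(cm$rho)), rep(1, 5))
  expect_equal(cm$n, 13)
  # perfect coupling with no noise: cotinine-N/C cell is 1
  c1 <- generate_cohort(cohort_config(coupling_strength = 1, seed = 4))
  cm1 <- correlation_matrix(c1)
  expect_equal(cm1$rho["cotinine_ng_ml", "case_nc_ratio"], 1)
  # missing columns are named in the error
  expect_error(correlation_matrix(table1), "cotinine",
               class = "oralcyto_domain_error")
})

test_that("cohort report assembles every baseline row", {
  rep_ <- cohort_stats_report(table1, boot_reps = 500, seed = 2)
  expect_setequal(rep_$comparisons$variable,
                  c("age", "smoker_owners", "cigarettes_per_day"))
  expect_equal(rep_$groups, c(exposed = 20, non_exposed = 10))
  expect_equal(round(rep_$sex$female$odds_ratio, 3), 0.359)
  one_group <- cohort(data.frame(cat_id = "a", exposure = "exposed", age = 1,
                                 sex = "M", smoker_owners = 1,
                                 cigarettes_per_day = 2))
  expect_error(cohort_stats_report(one_group), class = "oralcyto_domain_error")
})
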