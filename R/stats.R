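# Nonparametric statistical battery for two-group exposure studies:
# median/IQR summaries, Mann-Whitney U, Cliff's delta with bootstrap CI,
# Fisher's exact test with odds ratios, Spearman rho with Fisher-z CI,
# and the exposed-cohort correlation matrix.

#' Median and interquartile range
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile` type 7) throughout the package.
#'
#' @param values non-empty numeric vector (missing values are an error;
#'   drop them upstream).
#' @return list with `median`, `iqr`, `q1`, `q3`.
#' @export
median_iqr <- function(values) {
  if (length(values) == 0 || anyNA(values)) {
    stop_oralcyto("values must be non-empty and non-missing",
                  "oralcyto_domain_error")
  }
  q <- .quartiles(values)
  list(median = q[2], iqr = q[3] - q[1], q1 = q[1], q3 = q[3])
}

#' Two-sided Mann-Whitney U test
#'
#' The U statistic counts pairs where `x` exceeds `y`, with ties counted as
#' half (midrank convention). The p-value is exact (full rank-permutation
#' distribution) when both samples have at most `exact_max` observations and
#' there are no ties across the pooled sample; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_max largest per-group size for which the exact distribution
#'   is used (default 8).
#' @return list with `U`, `p`, `n1`, `n2`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 8) {
  if (length(x) == 0 || length(y) == 0) {
    stop_oralcyto("both samples must be non-empty", "oralcyto_domain_error")
  }
  n1 <- length(x); n2 <- length(y)
  # U via midranks: U = R1 - n1(n1+1)/2 where R1 is the rank sum of x
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  use_exact <- !ties && n1 <= exact_max && n2 <= exact_max
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value
  )
  list(U = U, p = p, n1 = n1, n2 = n2,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Cliff's delta effect size
#'
#' delta = (#pairs x_i > y_j - #pairs x_i < y_j) / (n1 * n2), computed
#' exactly over all pairs. Ranges over [-1, 1]; 1 means complete separation
#' with `x` above `y`.
#'
#' @param x,y non-empty numeric samples.
#' @return a single number in [-1, 1].
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop_oralcyto("both samples must be non-empty", "oralcyto_domain_error")
  }
  mean(sign(outer(x, y, "-")))
}

#' Percentile bootstrap confidence interval for Cliff's delta
#'
#' Resamples `x` and `y` independently with replacement, recomputes delta on
#' each replicate, and returns the percentile interval.
#'
#' @param x,y non-empty numeric samples.
#' @param reps number of bootstrap replicates (default 10000).
#' @param seed integer seed for the resampling stream.
#' @param level confidence level (default 0.95).
#' @return list with `lo`, `hi`, `reps`, `level`.
#' @export
bootstrap_delta_ci <- function(x, y, reps = 10000, seed = 1, level = 0.95) {
  stopifnot(is_count(reps))
  n1 <- length(x); n2 <- length(y)
  set.seed(seed)
  deltas <- vapply(seq_len(reps), function(i) {
    cliffs_delta(x[sample.int(n1, n1, replace = TRUE)],
                 y[sample.int(n2, n2, replace = TRUE)])
  }, numeric(1))
  a <- (1 - level) / 2
  q <- stats::quantile(deltas, c(a, 1 - a), type = 7, names = FALSE)
  list(lo = q[1], hi = q[2], reps = reps, level = level)
}

#' Fisher's exact test on a 2x2 table with odds-ratio effect size
#'
#' The p-value follows the probability-ordering two-sided rule (the sum of
#' probabilities of all tables no more likely than the observed one, under
#' the hypergeometric null). The odds-ratio point estimate is the sample
#' cross-product ratio (a*d)/(b*c), not the conditional maximum-likelihood
#' estimate. Two interval conventions are offered: `"woolf"` (normal
#' approximation on the log cross-product OR; the convention under which
#' the package's worked examples print) and `"exact"` (exact conditional
#' interval from the noncentral hypergeometric likelihood).
#'
#' @param table 2x2 matrix of non-negative integer counts; both margins must
#'   be positive.
#' @param ci_method `"woolf"` or `"exact"`.
#' @param level confidence level (default 0.95).
#' @return list with `table`, `odds_ratio`, `or_ci` (length-2), `p`,
#'   `zero_cell` flag and `ci_method`.
#' @export
fisher_exact <- function(table, ci_method = c("woolf", "exact"), level = 0.95) {
  ci_method <- match.arg(ci_method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop_oralcyto("table must be a 2x2 matrix of non-negative integers",
                  "oralcyto_domain_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_oralcyto("both margins of the 2x2 table must be positive",
                  "oralcyto_domain_error")
  }
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  zero_cell <- any(table == 0)
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c_)
  }
  ft <- stats::fisher.test(table, conf.level = level)
  if (ci_method == "exact") {
    ci <- as.numeric(ft$conf.int)
  } else {
    if (zero_cell) {
      ci <- c(NA_real_, NA_real_) # Woolf CI undefined with a zero cell
    } else {
      se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
      z <- stats::qnorm(1 - (1 - level) / 2)
      ci <- exp(log(or) + c(-1, 1) * z * se)
    }
  }
  list(table = table, odds_ratio = or, or_ci = ci, p = ft$p.value,
       zero_cell = zero_cell, ci_method = ci_method)
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks. Pairs with a missing value in
#' either variable are dropped listwise. The p-value is exact (permutation
#' distribution of the rank statistic) when n <= 10 and there are no ties,
#' and otherwise uses the t approximation.
#'
#' @param x,y paired numeric vectors.
#' @return list with `rho`, `n`, `p`, `method`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop_oralcyto("x and y must be paired (equal length)", "oralcyto_domain_error")
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    stop_oralcyto("need at least 3 complete pairs", "oralcyto_domain_error")
  }
  rho <- stats::cor(rank(x), rank(y))
  ties <- any(duplicated(x)) || any(duplicated(y))
  use_exact <- !ties && n <= 10
  p <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = use_exact)$p.value
  )
  list(rho = rho, n = n, p = p,
       method = if (use_exact) "exact" else "t_approx")
}

#' Fisher-z confidence interval for a correlation
#'
#' z = atanh(rho); the interval is tanh(z +/- z_crit / sqrt(n - 3)).
#' At |rho| = 1 the transform degenerates and the interval collapses to the
#' point +/-1, flagged in the result.
#'
#' @param rho correlation in [-1, 1].
#' @param n sample size (>= 4).
#' @param level confidence level (default 0.95).
#' @return list with `lo`, `hi`, `degenerate` flag.
#' @export
fisher_z_ci <- function(rho, n, level = 0.95) {
  if (!is.numeric(rho) || abs(rho) > 1) {
    stop_oralcyto("rho must be in [-1, 1]", "oralcyto_domain_error")
  }
  if (n < 4) {
    stop_oralcyto("n must be at least 4", "oralcyto_domain_error")
  }
  if (abs(rho) == 1) {
    return(list(lo = rho, hi = rho, degenerate = TRUE))
  }
  z <- atanh(rho)
  hw <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  list(lo = tanh(z - hw), hi = tanh(z + hw), degenerate = FALSE)
}

#' Two-group comparison of a continuous variable
#'
#' Bundles the per-group median [IQR] summary, the two-sided Mann-Whitney U
#' test, and Cliff's delta with its percentile bootstrap interval.
#'
#' @param x,y numeric samples for the two groups (e.g. exposed, non-exposed).
#' @param variable label for reporting.
#' @param boot_reps bootstrap replicates for the delta CI.
#' @param seed bootstrap seed.
#' @return list of class `group_comparison`.
#' @export
compare_groups <- function(x, y, variable = "value", boot_reps = 10000,
                           seed = 1) {
  mw <- mann_whitney_u(x, y)
  delta <- cliffs_delta(x, y)
  ci <- bootstrap_delta_ci(x, y, reps = boot_reps, seed = seed)
  if (!(ci$lo <= delta && delta <= ci$hi)) {
    warning("bootstrap pathology: Cliff's delta outside its own bootstrap CI")
  }
  structure(list(
    variable = variable,
    n1 = length(x), n2 = length(y),
    summary1 = median_iqr(x), summary2 = median_iqr(y),
    U = mw$U, p = mw$p, p_method = mw$method,
    cliffs_delta = delta, delta_ci = c(ci$lo, ci$hi)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: %.2f [%.2f] vs %.2f [%.2f]; U = %.1f, p = %.3g; Cliff's d = %.2f (95%% CI [%.2f, %.2f])\n",
    x$variable, x$summary1$median, x$summary1$iqr,
    x$summary2$median, x$summary2$iqr,
    x$U, x$p, x$cliffs_delta, x$delta_ci[1], x$delta_ci[2]
  ))
  invisible(x)
}

#' Baseline comparison report for a two-group cohort
#'
#' Reproduces the standard baseline table of an exposure study: per-group
#' median [IQR] with Mann-Whitney U and Cliff's delta for each continuous
#' covariate, and Fisher's exact test with odds ratios for sex in both
#' orientations (female-reference and male-reference rows).
#'
#' @param x a [cohort()] object containing both exposure groups.
#' @param variables continuous columns to compare; defaults to age,
#'   smoker_owners, cigarettes_per_day plus case_nc_ratio when present.
#' @param boot_reps,seed bootstrap settings for the delta intervals.
#' @return list with `comparisons` (data.frame), `sex` (list of two
#'   [fisher_exact()] results) and `groups`.
#' @export
cohort_stats_report <- function(x, variables = NULL, boot_reps = 10000,
                                seed = 1) {
  stopifnot(inherits(x, "cohort"))
  g1 <- as.data.frame(x)[x$exposure == "exposed", , drop = FALSE]
  g2 <- as.data.frame(x)[x$exposure == "non_exposed", , drop = FALSE]
  if (nrow(g1) == 0 || nrow(g2) == 0) {
    stop_oralcyto("both exposure groups must be non-empty for comparisons",
                  "oralcyto_domain_error")
  }
  if (is.null(variables)) {
    variables <- c("age", "smoker_owners", "cigarettes_per_day")
    if ("case_nc_ratio" %in% names(x) && any(!is.na(x$case_nc_ratio))) {
      variables <- c(variables, "case_nc_ratio")
    }
    if ("cotinine_ng_ml" %in% names(x) && any(!is.na(x$cotinine_ng_ml))) {
      variables <- c(variables, "cotinine_ng_ml")
    }
  }
  rows <- lapply(seq_along(variables), function(i) {
    v <- variables[i]
    xv <- g1[[v]][!is.na(g1[[v]])]
    yv <- g2[[v]][!is.na(g2[[v]])]
    cmp <- compare_groups(xv, yv, variable = v, boot_reps = boot_reps,
                          seed = split_seed(seed, i))
    data.frame(
      variable = v, n_exposed = cmp$n1, n_non_exposed = cmp$n2,
      median_exposed = cmp$summary1$median, iqr_exposed = cmp$summary1$iqr,
      median_non_exposed = cmp$summary2$median,
      iqr_non_exposed = cmp$summary2$iqr,
      U = cmp$U, p = cmp$p, cliffs_delta = cmp$cliffs_delta,
      delta_lo = cmp$delta_ci[1], delta_hi = cmp$delta_ci[2],
      stringsAsFactors = FALSE
    )
  })
  # sex 2x2: rows = exposed / non-exposed, columns = (reference sex, other)
  f_e <- sum(g1$sex == "F"); m_e <- sum(g1$sex == "M")
  f_n <- sum(g2$sex == "F"); m_n <- sum(g2$sex == "M")
  sex <- list(
    female = fisher_exact(matrix(c(f_e, m_e, f_n, m_n), nrow = 2, byrow = TRUE)),
    male   = fisher_exact(matrix(c(m_e, f_e, m_n, f_n), nrow = 2, byrow = TRUE))
  )
  list(comparisons = do.call(rbind, rows), sex = sex,
       groups = c(exposed = nrow(g1), non_exposed = nrow(g2)))
}

#' Spearman correlation matrix over the exposed cohort
#'
#' Restricts the cohort to exposed records listwise-complete on the five
#' study variables (urinary cotinine, case N/C ratio, inflammation score,
#' dysplasia grade, age) and returns the symmetric matrix of Spearman rho
#' and p-values.
#'
#' @param x a [cohort()] object.
#' @param variables columns to correlate (default the five study variables).
#' @return list with `rho` and `p` matrices and `n` (complete cases).
#' @export
correlation_matrix <- function(x, variables = c(
  "cotinine_ng_ml", "case_nc_ratio", "inflammation_score",
  "dysplasia_grade", "age"
)) {
  stopifnot(inherits(x, "cohort"))
  df <- as.data.frame(x)[x$exposure == "exposed", , drop = FALSE]
  missing_cols <- setdiff(variables, names(df))
  if (length(missing_cols) > 0) {
    stop_oralcyto(
      sprintf("cohort lacks column(s): %s", paste(missing_cols, collapse = ", ")),
      "oralcyto_domain_error"
    )
  }
  df <- df[stats::complete.cases(df[, variables]), variables, drop = FALSE]
  if (nrow(df) < 4) {
    stop_oralcyto(
      sprintf("need >= 4 listwise-complete exposed records, have %d", nrow(df)),
      "oralcyto_domain_error"
    )
  }
  k <- length(variables)
  rho <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(p) <- list(variables, variables)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      s <- spearman_rho(df[[i]], df[[j]])
      rho[i, j] <- rho[j, i] <- s$rho
      p[i, j] <- p[j, i] <- s$p
    }
  }
  list(rho = rho, p = p, n = nrow(df))
}
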