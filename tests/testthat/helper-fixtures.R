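# Shared fixtures: the bundled 30-cat cohort's columns, brute-force oracles,
# and small synthetic batches built in code.

table1 <- read_cohort_table(example_cohort_path())
age_exposed <- table1$age[table1$exposure == "exposed"]
age_non <- table1$age[table1$exposure == "non_exposed"]
cigs_exposed <- table1$cigarettes_per_day[table1$exposure == "exposed"]
cigs_non <- table1$cigarettes_per_day[table1$exposure == "non_exposed"]
smokers_exposed <- table1$smoker_owners[table1$exposure == "exposed"]
smokers_non <- table1$smoker_owners[table1$exposure == "non_exposed"]

# Cliff's delta by explicit double loop (independent of the vectorized path)
cliffs_delta_brute <- function(x, y) {
  gt <- 0; lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1 else if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (no ties assumed)
mann_whitney_p_brute <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  Us <- apply(splits, 2, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  mu <- n1 * n2 / 2
  mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
}

# exact Spearman p by enumeration of all permutations (small n, no ties)
spearman_p_brute <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- stats::cor(rx, ry)
  perms <- NULL
  gen <- function(v, acc) {
    if (length(v) == 0) {
      perms[[length(perms) + 1]] <<- acc
    } else {
      for (i in seq_along(v)) gen(v[-i], c(acc, v[i]))
    }
  }
  gen(seq_len(n), integer(0))
  rhos <- vapply(perms, function(p) stats::cor(rx, ry[p]), numeric(1))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# segment a batch of clean generated tiles, returning per-tile metrics
segment_clean_batch <- function(n, seed0 = 1, nc_range = c(0.12, 0.8),
                                params = seg_params()) {
  out <- data.frame(accepted = logical(n), dice_nuc = NA_real_,
                    dice_cyt = NA_real_, rel_err = NA_real_)
  for (s in seq_len(n)) {
    set.seed(seed0 * 10000 + s)
    tnc <- stats::runif(1, nc_range[1], nc_range[2])
    tl <- generate_cell_tile(tnc, seed = seed0 * 20000 + s)
    sg <- segment_tile(tl$pixels, params = params, seed = s)
    q <- qc_filter_tile(tl, sg)
    out$accepted[s] <- q$accepted
    if (q$accepted) {
      out$dice_nuc[s] <- dice_coefficient(sg$nucleus_mask, tl$truth$nucleus_mask)
      out$dice_cyt[s] <- dice_coefficient(sg$cytoplasm_mask, tl$truth$cytoplasm_mask)
      out$rel_err[s] <- abs(sg$a_nucleus / sg$a_cytoplasm / tl$truth$true_nc_ratio - 1)
    }
  }
  out
}
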