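# Per-cell N/C ratio computation and case-level aggregation.

#' Nucleus-to-cytoplasm area ratio
#'
#' N/C = A_nucleus / A_cytoplasm, with areas in pixels. The ratio is a
#' quotient, so the physical pixel size cancels; [px_to_um2()] is provided
#' for reporting areas in physical units.
#'
#' @param a_nucleus nucleus pixel area (>= 0).
#' @param a_cytoplasm cytoplasm pixel area (> 0).
#' @return the ratio, vectorized over inputs.
#' @export
nc_ratio <- function(a_nucleus, a_cytoplasm) {
  if (any(a_nucleus < 0)) {
    stop_oralcyto("a_nucleus must be >= 0", "oralcyto_domain_error")
  }
  if (any(a_cytoplasm <= 0)) {
    stop_oralcyto("a_cytoplasm must be > 0 (anucleate or empty cells are rejected by QC)",
                  "oralcyto_domain_error")
  }
  a_nucleus / a_cytoplasm
}

#' Convert a pixel area to square micrometres
#'
#' @param px pixel count.
#' @param microns_per_px physical pixel pitch (default 0.14 um/px, a 40x
#'   whole-slide scan).
#' @return area in um^2.
#' @export
px_to_um2 <- function(px, microns_per_px = 0.14) {
  px * microns_per_px^2
}

#' Aggregate per-cell ratios to a case-level N/C ratio
#'
#' The case-level N/C ratio is the median over all quantified cells of the
#' animal's slides (for an even count, the mean of the two central order
#' statistics). By default two slides of 250 cells each are expected; a
#' different count is a soft deviation reported as a warning, not an error.
#'
#' @param cells data.frame with at least a numeric `nc_ratio` column (one
#'   row per quantified cell), or a bare numeric vector of ratios.
#' @param cat_id animal identifier.
#' @param n_wsis number of slides the cells came from (default 2).
#' @param expected_cells_per_wsi soft expectation used for the warning.
#' @return list of class `case_morphometry`: `cat_id`, `n_cells`, `n_wsis`,
#'   `case_nc_ratio`, `q1`, `q3`.
#' @export
aggregate_case <- function(cells, cat_id, n_wsis = 2,
                           expected_cells_per_wsi = 250) {
  ratios <- if (is.data.frame(cells)) cells$nc_ratio else cells
  if (length(ratios) == 0) {
    stop_oralcyto("no cells to aggregate", "oralcyto_domain_error")
  }
  if (anyNA(ratios)) {
    stop_oralcyto("nc_ratio contains missing values", "oralcyto_domain_error")
  }
  expected <- n_wsis * expected_cells_per_wsi
  if (length(ratios) != expected) {
    warning(sprintf("case %s: %d cells from %d slides (expected %d)",
                    cat_id, length(ratios), n_wsis, expected))
  }
  q <- .quartiles(ratios)
  structure(list(
    cat_id = cat_id, n_cells = length(ratios), n_wsis = n_wsis,
    case_nc_ratio = q[2], q1 = q[1], q3 = q[3]
  ), class = "case_morphometry")
}

#' Stratified case-level N/C summaries
#'
#' Summarizes case-level N/C ratios per stratum of an ordinal covariate
#' (inflammation score, dysplasia grade) or exposure group: n, median and
#' quartiles (linear-interpolation convention). Empty strata are skipped
#' with a warning.
#'
#' @param x a [cohort()] with a `case_nc_ratio` column.
#' @param by stratifying column: `"inflammation_score"`,
#'   `"dysplasia_grade"` or `"exposure"`.
#' @return data.frame with columns `stratum`, `n`, `median`, `q1`, `q3`.
#' @export
stratify_morphometry <- function(x, by = c("inflammation_score",
                                           "dysplasia_grade", "exposure")) {
  by <- match.arg(by)
  stopifnot(inherits(x, "cohort"))
  if (!"case_nc_ratio" %in% names(x) || all(is.na(x$case_nc_ratio))) {
    stop_oralcyto("cohort has no case_nc_ratio values", "oralcyto_domain_error")
  }
  if (!by %in% names(x)) {
    stop_oralcyto(sprintf("cohort lacks column %s", by), "oralcyto_domain_error")
  }
  df <- as.data.frame(x)
  miss <- is.na(df[[by]]) | is.na(df$case_nc_ratio)
  if (any(miss)) {
    warning(sprintf("%d record(s) without %s or case_nc_ratio skipped", sum(miss), by))
    df <- df[!miss, , drop = FALSE]
  }
  levels_ <- if (by == "exposure") c("exposed", "non_exposed") else
    sort(unique(df[[by]]))
  rows <- lapply(levels_, function(s) {
    v <- df$case_nc_ratio[df[[by]] == s]
    if (length(v) == 0) {
      warning(sprintf("empty stratum %s = %s skipped", by, s))
      return(NULL)
    }
    q <- .quartiles(v)
    data.frame(stratum = as.character(s), n = length(v), median = q[2],
               q1 = q[1], q3 = q[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
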