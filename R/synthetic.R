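# Synthetic MGG-like smear generation: single-cell tiles with exact
# ground-truth compartment masks, clutter tiles for QC testing, whole
# synthetic slides, and cohort-level generation with a controlled
# cotinine / N-C rank coupling.

#' Stain profile for synthetic smear rendering
#'
#' Describes the three colour classes of a Romanowsky-type (May-Grunwald-
#' Giemsa) smear: dark violet nuclei, pale blue-grey basophilic cytoplasm and
#' a near-white background. Rendering samples each pixel from the class mean
#' with per-channel Gaussian spread plus global additive noise. The profile
#' is valid only if the three class means are mutually separable in CIELAB
#' (minimum pairwise distance >= `min_lab_margin`) and ordered in lightness
#' as L(nucleus) < L(cytoplasm) < L(background).
#'
#' @param nucleus,cytoplasm,background mean RGB triples on the 0-255 scale.
#' @param nucleus_sd,cytoplasm_sd,background_sd per-channel standard
#'   deviations (length 1 or 3).
#' @param noise_sd additive global pixel noise (0-255 scale).
#' @param min_lab_margin minimum pairwise CIELAB distance between class means.
#' @return an object of class `stain_profile`.
#' @export
stain_profile <- function(nucleus = c(70, 40, 110),
                          cytoplasm = c(180, 185, 215),
                          background = c(245, 245, 248),
                          nucleus_sd = 6, cytoplasm_sd = 6, background_sd = 2,
                          noise_sd = 8, min_lab_margin = 15) {
  expand3 <- function(x) if (length(x) == 1) rep(x, 3) else x
  p <- list(
    nucleus = list(mean = nucleus, sd = expand3(nucleus_sd)),
    cytoplasm = list(mean = cytoplasm, sd = expand3(cytoplasm_sd)),
    background = list(mean = background, sd = expand3(background_sd)),
    noise_sd = noise_sd, min_lab_margin = min_lab_margin
  )
  means <- rbind(nucleus, cytoplasm, background)
  lab <- grDevices::convertColor(means / 255, from = "sRGB", to = "Lab")
  d <- as.matrix(stats::dist(lab))
  if (min(d[upper.tri(d)]) < min_lab_margin) {
    stop_oralcyto(
      sprintf("stain class means closer than %g in CIELAB", min_lab_margin),
      "oralcyto_parameter_error"
    )
  }
  if (!(lab[1, 1] < lab[2, 1] && lab[2, 1] < lab[3, 1])) {
    stop_oralcyto("lightness must satisfy L(nucleus) < L(cytoplasm) < L(background)",
                  "oralcyto_parameter_error")
  }
  structure(p, class = "stain_profile")
}

# logical mask of an ellipse with centre (cx, cy) [row, col], semi-axes
# (a, b) and rotation theta, on a dim x dim grid
.ellipse_mask <- function(cx, cy, a, b, theta, dim = 256) {
  rows <- matrix(seq_len(dim), dim, dim)
  cols <- matrix(seq_len(dim), dim, dim, byrow = TRUE)
  dx <- rows - cx
  dy <- cols - cy
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

# render a class map (0 background, 1 cytoplasm, 2 nucleus) to an RGB tile
# (integer array, 0-255); consumes RNG state
.render_classmap <- function(classmap, stain) {
  dim <- nrow(classmap)
  n <- length(classmap)
  img <- array(0, dim = c(dim, dim, 3))
  classes <- list(stain$background, stain$cytoplasm, stain$nucleus)
  idx <- as.vector(classmap) + 1L
  for (ch in 1:3) {
    mu <- vapply(classes, function(cl) cl$mean[ch], numeric(1))[idx]
    sd <- vapply(classes, function(cl) cl$sd[ch], numeric(1))[idx]
    val <- mu + stats::rnorm(n, 0, sd) + stats::rnorm(n, 0, stain$noise_sd)
    img[, , ch] <- matrix(pmin(pmax(round(val), 0), 255), dim, dim)
  }
  storage.mode(img) <- "integer"
  img
}

.truth_from_classmap <- function(classmap, cell_count) {
  nuc <- classmap == 2L
  cyt <- classmap == 1L
  list(
    nucleus_mask = nuc,
    cytoplasm_mask = cyt,
    true_nc_ratio = if (sum(cyt) > 0) sum(nuc) / sum(cyt) else NA_real_,
    cell_count = cell_count
  )
}

# draw one cell's geometry: returns class map contribution masks
# target_nc is the nucleus / cytoplasm pixel ratio, so the nucleus occupies
# a fraction f = target_nc / (1 + target_nc) of the whole-cell ellipse
.draw_cell <- function(target_nc, tile_size, cell_area, centre_jitter = 20,
                       border_margin = 4) {
  area <- stats::runif(1, cell_area[1], cell_area[2])
  ecc <- stats::runif(1, 1, 2)
  a <- sqrt(area * ecc / pi)
  b <- a / ecc
  theta <- stats::runif(1, 0, pi)
  max_ext <- a # outermost reach of the rotated ellipse is <= major semi-axis
  limit <- tile_size / 2 - max_ext - border_margin
  jit <- min(centre_jitter, max(limit, 0))
  cx <- tile_size / 2 + stats::runif(1, -jit, jit)
  cy <- tile_size / 2 + stats::runif(1, -jit, jit)
  f <- target_nc / (1 + target_nc)
  s <- sqrt(f)
  cell <- .ellipse_mask(cx, cy, a, b, theta, tile_size)
  nuc <- .ellipse_mask(cx, cy, a * s, b * s, theta, tile_size)
  list(cell = cell, nucleus = nuc, centre = c(cx, cy), axes = c(a, b),
       theta = theta)
}

#' Generate a single-cell synthetic tile with ground truth
#'
#' Draws one nucleated epithelial cell (an ellipse-within-ellipse geometry
#' with random eccentricity in [1, 2] and random rotation) fully inside a
#' square tile, renders it under a stain profile, and returns the RGB tile
#' together with exact nucleus / cytoplasm ground-truth masks. The nucleus
#' axes are solved so the realized mask-pixel area ratio is within 3%
#' relative error of `target_nc` (a discretization retry adjusts the nucleus
#' scale if needed).
#'
#' @param target_nc target nucleus-to-cytoplasm area ratio, in (0, 1).
#' @param stain a [stain_profile()].
#' @param seed integer seed; identical inputs give bit-identical tiles.
#' @param tile_size tile side in pixels (default 256).
#' @param cell_area admissible whole-cell pixel area range.
#' @return list with `pixels` (tile_size x tile_size x 3 integer array,
#'   0-255) and `truth` (masks, `true_nc_ratio`, `cell_count`).
#' @export
generate_cell_tile <- function(target_nc, stain = stain_profile(), seed = 1,
                               tile_size = 256, cell_area = c(5000, 11000)) {
  if (!is.numeric(target_nc) || target_nc <= 0 || target_nc >= 1) {
    stop_oralcyto("target_nc must be in (0, 1)", "oralcyto_parameter_error")
  }
  if (sqrt(cell_area[2] * 2 / pi) + 6 > tile_size / 2) {
    stop_oralcyto("cell_area too large for tile size", "oralcyto_parameter_error")
  }
  # the nucleus must clear the minimum-area debris floor at the smallest cell
  if (cell_area[1] * target_nc / (1 + target_nc) < 4) {
    stop_oralcyto("target_nc geometrically unattainable with configured cell sizes",
                  "oralcyto_parameter_error")
  }
  set.seed(seed)
  geom <- .draw_cell(target_nc, tile_size, cell_area)
  cell <- geom$cell
  nuc <- geom$nucleus
  # discretization correction: rescale the nucleus until the pixel ratio is
  # within 3% relative error of the target
  for (i in 1:6) {
    realized <- sum(nuc) / sum(cell & !nuc)
    if (abs(realized / target_nc - 1) <= 0.03) break
    adj <- sqrt(target_nc / realized)
    f <- target_nc / (1 + target_nc)
    s <- sqrt(f) * adj
    nuc <- .ellipse_mask(geom$centre[1], geom$centre[2],
                         geom$axes[1] * s, geom$axes[2] * s,
                         geom$theta, tile_size)
  }
  classmap <- matrix(0L, tile_size, tile_size)
  classmap[cell] <- 1L
  classmap[nuc] <- 2L
  list(
    pixels = .render_classmap(classmap, stain),
    truth = .truth_from_classmap(classmap, cell_count = 1L)
  )
}

CLUTTER_KINDS <- c("acellular", "overlap", "debris", "border_cut",
                   "inflammatory_aggregate")

#' Generate a clutter tile exhibiting a named artefact
#'
#' Produces tiles of the kinds excluded by tile quality control: acellular
#' fields, overlapping cells, debris, border-clipped cells (incomplete
#' cytoplasmic contours) and inflammatory aggregates. The returned
#' `truth$cell_count` reflects the kind (0 for acellular/debris, 2 for
#' overlap, the aggregate size for inflammatory aggregates).
#'
#' @param kind one of `"acellular"`, `"overlap"`, `"debris"`,
#'   `"border_cut"`, `"inflammatory_aggregate"`.
#' @param stain a [stain_profile()].
#' @param seed integer seed.
#' @param tile_size tile side in pixels.
#' @return same structure as [generate_cell_tile()].
#' @export
generate_clutter_tile <- function(kind, stain = stain_profile(), seed = 1,
                                  tile_size = 256) {
  kind <- match.arg(kind, CLUTTER_KINDS)
  set.seed(seed)
  classmap <- matrix(0L, tile_size, tile_size)
  cell_count <- 0L
  if (kind == "acellular") {
    # background only
  } else if (kind == "border_cut") {
    # one cell whose cytoplasm is clipped by the tile edge
    area <- stats::runif(1, 6000, 11000)
    ecc <- stats::runif(1, 1, 2)
    a <- sqrt(area * ecc / pi); b <- a / ecc
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, -b / 2, b / 2) # centre at/over the top edge
    cy <- stats::runif(1, a + 6, tile_size - a - 6)
    cell <- .ellipse_mask(cx, cy, a, b, theta, tile_size)
    nuc <- .ellipse_mask(cx, cy, a * 0.45, b * 0.45, theta, tile_size)
    classmap[cell] <- 1L
    classmap[nuc] <- 2L
    cell_count <- 1L
  } else if (kind == "overlap") {
    # two cells with intersecting cytoplasm but distinct nuclei
    target <- stats::runif(1, 0.2, 0.4)
    for (k in 0:1) {
      area <- stats::runif(1, 6000, 9000)
      ecc <- stats::runif(1, 1, 1.6)
      a <- sqrt(area * ecc / pi); b <- a / ecc
      theta <- stats::runif(1, 0, pi)
      cx <- tile_size / 2 + (k - 0.5) * a * 1.2
      cy <- tile_size / 2 + stats::runif(1, -8, 8)
      cell <- .ellipse_mask(cx, cy, a, b, theta, tile_size)
      s <- sqrt(target / (1 + target))
      nuc <- .ellipse_mask(cx, cy, a * s, b * s, theta, tile_size)
      classmap[cell & classmap == 0L] <- 1L
      classmap[nuc] <- 2L
    }
    cell_count <- 2L
  } else if (kind == "debris") {
    # dark specks well below any plausible nucleus area
    n_specks <- sample(8:16, 1)
    for (i in seq_len(n_specks)) {
      r <- stats::runif(1, 1, 3)
      cx <- stats::runif(1, 8, tile_size - 8)
      cy <- stats::runif(1, 8, tile_size - 8)
      classmap[.ellipse_mask(cx, cy, r, r, 0, tile_size)] <- 2L
    }
    cell_count <- 0L
  } else { # inflammatory_aggregate
    n_cells <- sample(5:9, 1)
    centre <- c(tile_size / 2, tile_size / 2) + stats::runif(2, -20, 20)
    for (i in seq_len(n_cells)) {
      r <- stats::runif(1, 7, 10)
      ang <- stats::runif(1, 0, 2 * pi)
      d <- stats::runif(1, 12, 45)
      cx <- centre[1] + d * cos(ang); cy <- centre[2] + d * sin(ang)
      cx <- min(max(cx, r + 4), tile_size - r - 4)
      cy <- min(max(cy, r + 4), tile_size - r - 4)
      classmap[.ellipse_mask(cx, cy, r, r, 0, tile_size)] <- 2L
    }
    cell_count <- n_cells
  }
  list(
    pixels = .render_classmap(classmap, stain),
    truth = .truth_from_classmap(classmap, cell_count = cell_count)
  )
}

#' Generate a synthetic whole-slide tile set
#'
#' Draws `n_tiles` tiles for one slide: per-cell target N/C values are
#' sampled around `case_nc_center` with multiplicative lognormal dispersion,
#' and a configurable fraction of tiles is replaced by clutter tiles (cycled
#' over the clutter kinds) to exercise quality control. Per-tile seeds are
#' derived from `seed` with [split_seed()], so the whole set is reproducible.
#'
#' @param case_nc_center central N/C ratio of the case, in (0, 1).
#' @param dispersion lognormal sigma of per-cell targets (default 0.15).
#' @param n_tiles number of tiles (>= 1).
#' @param stain a [stain_profile()].
#' @param seed integer root seed for this slide.
#' @param clutter_fraction fraction of tiles replaced by clutter;
#'   `round(clutter_fraction * n_tiles)` tiles exactly.
#' @param slide_id label stored with the tiles.
#' @return list with `tiles` (each: `pixels`, `truth`, `is_clutter`, `kind`,
#'   `target_nc`) and `true_nc` (realized truth ratios of the cell tiles).
#' @export
generate_synthetic_wsi <- function(case_nc_center, dispersion = 0.15,
                                   n_tiles = 250, stain = stain_profile(),
                                   seed = 1, clutter_fraction = 0,
                                   slide_id = "wsi") {
  stopifnot(is_count(n_tiles))
  n_clutter <- round(clutter_fraction * n_tiles)
  set.seed(split_seed(seed, 0))
  clutter_pos <- if (n_clutter > 0) sort(sample.int(n_tiles, n_clutter)) else integer(0)
  kinds <- rep_len(CLUTTER_KINDS, max(n_clutter, 1))
  targets <- pmin(pmax(case_nc_center * exp(stats::rnorm(n_tiles, 0, dispersion)),
                       0.05), 0.9)
  tiles <- vector("list", n_tiles)
  ki <- 0
  for (i in seq_len(n_tiles)) {
    tseed <- split_seed(seed, i)
    if (i %in% clutter_pos) {
      ki <- ki + 1
      tl <- generate_clutter_tile(kinds[ki], stain, seed = tseed)
      tiles[[i]] <- list(pixels = tl$pixels, truth = tl$truth,
                         is_clutter = TRUE, kind = kinds[ki],
                         target_nc = NA_real_, slide_id = slide_id)
    } else {
      tl <- generate_cell_tile(targets[i], stain, seed = tseed)
      tiles[[i]] <- list(pixels = tl$pixels, truth = tl$truth,
                         is_clutter = FALSE, kind = "cell",
                         target_nc = targets[i], slide_id = slide_id)
    }
  }
  true_nc <- vapply(tiles[!vapply(tiles, `[[`, logical(1), "is_clutter")],
                    function(t) t$truth$true_nc_ratio, numeric(1))
  list(tiles = tiles, true_nc = true_nc)
}

#' Assemble a tile set into a single slide raster
#'
#' Lays tiles out row-major on a background-coloured canvas, for testing
#' slide-level operations (tissue masking, tiling) against known content.
#'
#' @param tiles list of tiles as produced by [generate_synthetic_wsi()].
#' @param ncol tiles per row (default: square-ish layout).
#' @param stain stain profile supplying the background colour.
#' @return list with `pixels` (H x W x 3 integer array) and `origins`
#'   (0-based top-left row/col of each tile).
#' @export
assemble_slide <- function(tiles, ncol = ceiling(sqrt(length(tiles))),
                           stain = stain_profile()) {
  n <- length(tiles)
  ts <- dim(tiles[[1]]$pixels)[1]
  nrow_ <- ceiling(n / ncol)
  canvas <- array(0L, dim = c(nrow_ * ts, ncol * ts, 3))
  for (ch in 1:3) canvas[, , ch] <- as.integer(round(stain$background$mean[ch]))
  origins <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol
    c_ <- (i - 1) %% ncol
    canvas[r * ts + seq_len(ts), c_ * ts + seq_len(ts), ] <- tiles[[i]]$pixels
    origins[i, ] <- c(r * ts, c_ * ts)
  }
  storage.mode(canvas) <- "integer"
  list(pixels = canvas, origins = origins)
}

#' Configuration for synthetic cohort generation
#'
#' Defaults describe the study conditions the generator emulates: 20 exposed
#' and 10 non-exposed cats; non-exposed case N/C tight and uniform on
#' [0.215, 0.236]; exposed case N/C right-skewed (scaled Beta) on
#' [0.24, 0.85]; exposed urinary cotinine heavy-tailed lognormal coupled to
#' the true case N/C through a Gaussian copula whose population Spearman
#' correlation equals `coupling_strength`; non-exposed cotinine near
#' baseline. Cotinine is generated for a subset of animals
#' (13 exposed / 8 non-exposed by default) and missing elsewhere.
#' Inflammation scores and dysplasia grades are assigned by thresholding the
#' true case N/C at `inflammation_cuts` / `dysplasia_cuts`.
#'
#' @param n_exposed,n_non_exposed group sizes.
#' @param exposed_nc list: Beta shape1/shape2 and range min/max.
#' @param non_exposed_nc list: uniform range min/max.
#' @param cotinine_exposed,cotinine_non_exposed lognormal meanlog/sdlog.
#' @param coupling_strength target population Spearman correlation between
#'   cotinine and true case N/C in the exposed group, in [0, 1].
#' @param n_cotinine named vector: how many animals per group have cotinine.
#' @param inflammation_cuts,dysplasia_cuts increasing cutpoints on true case
#'   N/C giving ordinal scores 0-3.
#' @param tiles_per_wsi,wsis_per_cat imaging plan per animal.
#' @param dispersion per-cell N/C lognormal sigma within a slide.
#' @param clutter_fraction fraction of clutter tiles per slide.
#' @param seed root seed; all randomness derives from it via [split_seed()].
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_exposed = 20, n_non_exposed = 10,
                          exposed_nc = list(shape1 = 1.3, shape2 = 3.2,
                                            min = 0.24, max = 0.85),
                          non_exposed_nc = list(min = 0.215, max = 0.236),
                          cotinine_exposed = list(meanlog = log(60), sdlog = 1.1),
                          cotinine_non_exposed = list(meanlog = log(2), sdlog = 0.5),
                          coupling_strength = 0.85,
                          n_cotinine = c(exposed = 13, non_exposed = 8),
                          inflammation_cuts = c(0.24, 0.46, 0.52),
                          dysplasia_cuts = c(0.35, 0.50, 0.70),
                          tiles_per_wsi = 250, wsis_per_cat = 2,
                          dispersion = 0.15, clutter_fraction = 0,
                          seed = 1) {
  if (!is_count(n_exposed) || !is_count(n_non_exposed)) {
    stop_oralcyto("group sizes must be positive integers", "oralcyto_parameter_error")
  }
  if (!is.numeric(coupling_strength) || coupling_strength < 0 ||
      coupling_strength > 1) {
    stop_oralcyto("coupling_strength must be in [0, 1]", "oralcyto_parameter_error")
  }
  n_cotinine <- c(
    exposed = min(n_cotinine[["exposed"]], n_exposed),
    non_exposed = min(n_cotinine[["non_exposed"]], n_non_exposed)
  )
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws true case-level N/C ratios per group, couples exposed cotinine to
#' N/C through a Gaussian copula (copula correlation
#' r = 2 sin(pi * rho_s / 6), so the population Spearman correlation equals
#' `coupling_strength` exactly), assigns inflammation scores and dysplasia
#' grades by thresholding true N/C, and draws the remaining demographics.
#' Returns a [cohort()] whose `case_nc_ratio` column holds the generator
#' truth, together with a per-slide imaging plan (`attr(, "wsi_plan")`)
#' from which tile sets can be produced with [generate_synthetic_wsi()].
#'
#' @param config a [cohort_config()].
#' @return a [cohort()] with attributes `wsi_plan` (data.frame of cat_id,
#'   wsi index, per-slide seed, case centre) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  ne <- config$n_exposed; nn <- config$n_non_exposed
  # exposed: copula draw -> (N/C, cotinine)
  set.seed(split_seed(config$seed, 1))
  z1 <- stats::rnorm(ne)
  r <- 2 * sin(pi * config$coupling_strength / 6)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(ne)
  p <- config$exposed_nc
  nc_e <- p$min + (p$max - p$min) * stats::qbeta(stats::pnorm(z1), p$shape1, p$shape2)
  ce <- config$cotinine_exposed
  cot_e <- stats::qlnorm(stats::pnorm(z2), ce$meanlog, ce$sdlog)
  # non-exposed
  set.seed(split_seed(config$seed, 2))
  q <- config$non_exposed_nc
  nc_n <- stats::runif(nn, q$min, q$max)
  cn <- config$cotinine_non_exposed
  cot_n <- stats::qlnorm(stats::runif(nn), cn$meanlog, cn$sdlog)
  # cotinine availability subset (mirrors incomplete urine sampling)
  set.seed(split_seed(config$seed, 3))
  have_e <- sort(sample.int(ne, config$n_cotinine[["exposed"]]))
  have_n <- sort(sample.int(nn, config$n_cotinine[["non_exposed"]]))
  cot_e[setdiff(seq_len(ne), have_e)] <- NA
  cot_n[setdiff(seq_len(nn), have_n)] <- NA
  # demographics
  set.seed(split_seed(config$seed, 4))
  age <- sample(1:5, ne + nn, replace = TRUE)
  sex <- sample(c("M", "F"), ne + nn, replace = TRUE)
  smoker_owners <- c(sample(1:2, ne, replace = TRUE, prob = c(0.8, 0.2)),
                     rep(0, nn))
  cigs <- c(sample(4:11, ne, replace = TRUE), rep(0, nn))
  nc <- c(nc_e, nc_n)
  score_from_cuts <- function(v, cuts) as.integer(findInterval(v, cuts))
  df <- data.frame(
    cat_id = sprintf("syn%02d", seq_len(ne + nn)),
    exposure = c(rep("exposed", ne), rep("non_exposed", nn)),
    age = age, sex = sex, smoker_owners = smoker_owners,
    cigarettes_per_day = cigs,
    cotinine_ng_ml = c(cot_e, cot_n),
    inflammation_score = score_from_cuts(nc, config$inflammation_cuts),
    dysplasia_grade = score_from_cuts(nc, config$dysplasia_cuts),
    case_nc_ratio = nc,
    stringsAsFactors = FALSE
  )
  out <- cohort(df, provenance = "synthetic")
  plan <- do.call(rbind, lapply(seq_len(ne + nn), function(i) {
    data.frame(
      cat_id = df$cat_id[i],
      wsi = seq_len(config$wsis_per_cat),
      seed = vapply(seq_len(config$wsis_per_cat),
                    function(w) split_seed(config$seed, 100 + i, w), integer(1)),
      case_nc_center = nc[i],
      dispersion = config$dispersion,
      n_tiles = config$tiles_per_wsi,
      clutter_fraction = config$clutter_fraction,
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "wsi_plan") <- plan
  attr(out, "config") <- config
  out
}
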