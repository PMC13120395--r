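# Run configuration, manifests, tile I/O and the three orchestration
# commands: simulate, morphometry, stats.

#' Full run configuration
#'
#' All tunables of the pipeline in one object, hashed into the run manifest
#' so that identical settings across slides (and across reruns) can be
#' asserted. Defaults: 256 px non-overlapping tiles, 250 analysed tiles per
#' slide, two slides per animal, three-cluster CIELAB segmentation, 10000
#' bootstrap replicates.
#'
#' @param tile_size,stride tiling geometry in pixels.
#' @param tiles_per_wsi analysed tiles per slide.
#' @param wsis_per_cat slides per animal.
#' @param seg a [seg_params()].
#' @param cohort a [cohort_config()] (used by [cmd_simulate()]).
#' @param stain a [stain_profile()] (used by [cmd_simulate()]).
#' @param boot_reps bootstrap replicates for effect-size intervals.
#' @param microns_per_px physical pixel pitch for area reporting.
#' @param allow_fewer accept slides with fewer than `tiles_per_wsi` valid
#'   tiles instead of raising an insufficiency error.
#' @param skip_bad skip unreadable tile images (with a record) instead of
#'   failing the run.
#' @param seed root seed for every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(tile_size = 256, stride = 256, tiles_per_wsi = 250,
                       wsis_per_cat = 2, seg = seg_params(),
                       cohort = cohort_config(), stain = stain_profile(),
                       boot_reps = 10000, microns_per_px = 0.14,
                       allow_fewer = FALSE, skip_bad = FALSE, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Digest of a run configuration
#'
#' Serializes the configuration to canonical JSON and returns its MD5
#' digest. Serializing and reloading a config yields an identical hash.
#'
#' @param config a [run_config()] (or any serializable list).
#' @return hex digest string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                           digits = 15)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

# strip S3 classes recursively so JSON serialization is structural
unclass_deep <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_deep)
  } else {
    if (is.object(x)) unclass(x) else x
  }
}

# write the run manifest; omits wall-clock state so equal settings give
# byte-equal manifests
write_manifest <- function(out_dir, config, inputs = character()) {
  manifest <- list(
    package = "oralcyto",
    version = as.character(utils::packageVersion("oralcyto")),
    config = unclass_deep(config),
    config_hash = config_hash(config),
    seed = config$seed,
    input_digests = if (length(inputs)) {
      stats::setNames(as.vector(tools::md5sum(inputs)), basename(inputs))
    } else NULL
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 15, pretty = TRUE)
  invisible(manifest)
}

#' Write / read an RGB tile as PNG
#'
#' Tiles are stored as ordinary 8-bit RGB PNGs; masks as 1-bit grayscale.
#' The row/column array convention of the package round-trips exactly.
#'
#' @param pixels H x W x 3 integer array (0-255), or logical matrix for
#'   masks.
#' @param path output path.
#' @return `path` (write) / the array (read), invisibly for the writer.
#' @export
write_tile_png <- function(pixels, path) {
  if (is.logical(pixels) || length(dim(pixels)) == 2) {
    img <- EBImage::Image(t(pixels * 1))
  } else {
    img <- EBImage::Image(aperm(pixels / 255, c(2, 1, 3)), colormode = "Color")
  }
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @rdname write_tile_png
#' @export
read_tile_png <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2) {
    t(a) > 0.5
  } else {
    out <- aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
    storage.mode(out) <- "integer"
    out
  }
}

#' Simulate a cohort with slides to disk
#'
#' Generates a synthetic cohort ([generate_cohort()]) and renders every
#' animal's slides as tile sets: per slide a directory of tile PNGs,
#' ground-truth nucleus/cytoplasm mask PNGs, and a JSON sidecar recording
#' tile origins (0-based, row-major), truth N/C values and clutter flags.
#' Writes the cohort CSV and a run manifest. Fully deterministic given the
#' configuration seed.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory (created if needed).
#' @param write_masks also write truth mask PNGs (default TRUE).
#' @return invisibly, the generated [cohort()].
#' @export
cmd_simulate <- function(config = run_config(), out_dir, write_masks = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop_oralcyto(sprintf("cannot create output directory %s", out_dir),
                  "oralcyto_io_error")
  }
  coh <- generate_cohort(config$cohort)
  write_cohort_table(coh, file.path(out_dir, "cohort.csv"))
  plan <- attr(coh, "wsi_plan")
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    wdir <- file.path(out_dir, "wsis", p$cat_id, sprintf("wsi%d", p$wsi))
    dir.create(wdir, recursive = TRUE, showWarnings = FALSE)
    wsi <- generate_synthetic_wsi(
      case_nc_center = p$case_nc_center, dispersion = p$dispersion,
      n_tiles = p$n_tiles, stain = config$stain, seed = p$seed,
      clutter_fraction = p$clutter_fraction,
      slide_id = sprintf("%s_wsi%d", p$cat_id, p$wsi)
    )
    ncol_ <- ceiling(sqrt(p$n_tiles))
    records <- vector("list", length(wsi$tiles))
    for (j in seq_along(wsi$tiles)) {
      tl <- wsi$tiles[[j]]
      file_ <- sprintf("tile_%04d.png", j)
      write_tile_png(tl$pixels, file.path(wdir, file_))
      if (write_masks) {
        write_tile_png(tl$truth$nucleus_mask,
                       file.path(wdir, sprintf("tile_%04d_nucleus.png", j)))
        write_tile_png(tl$truth$cytoplasm_mask,
                       file.path(wdir, sprintf("tile_%04d_cytoplasm.png", j)))
      }
      records[[j]] <- list(
        file = file_,
        origin = c(((j - 1) %/% ncol_) * config$tile_size,
                   ((j - 1) %% ncol_) * config$tile_size),
        true_nc = tl$truth$true_nc_ratio,
        is_clutter = tl$is_clutter,
        kind = tl$kind
      )
    }
    sidecar <- list(
      slide_id = sprintf("%s_wsi%d", p$cat_id, p$wsi),
      cat_id = p$cat_id, wsi = p$wsi,
      tile_size = config$tile_size, stride = config$stride,
      seed = p$seed, tiles = records
    )
    jsonlite::write_json(sidecar, file.path(wdir, "sidecar.json"),
                         auto_unbox = TRUE, digits = 15, pretty = TRUE)
  }
  write_manifest(out_dir, config)
  invisible(coh)
}

#' Segment and quantify one slide's tile set in memory
#'
#' The core engine behind [cmd_morphometry()]: segments every tile, applies
#' tile QC, samples the required number of accepted tiles (seeded), and
#' returns per-cell morphometry plus the QC audit. When ground truth is
#' attached to the tiles, per-cell truth comparison (Dice overlap, relative
#' N/C error) and the QC-vs-truth confusion summary are included.
#'
#' @param tiles list of tiles: each needs `pixels`, optionally `truth`,
#'   `is_clutter`, `kind`.
#' @param config a [run_config()].
#' @param slide_id slide label.
#' @param seed seed for tile sampling and clustering restarts.
#' @param n_required tiles to quantify; defaults to `config$tiles_per_wsi`.
#' @return list with `cells` (data.frame), `qc` (data.frame, one row per
#'   tile), `n_accepted`, and `confusion` (when truth flags present).
#' @export
process_wsi_tiles <- function(tiles, config = run_config(), slide_id = "slide",
                              seed = config$seed,
                              n_required = config$tiles_per_wsi) {
  segs <- vector("list", length(tiles))
  qc <- vector("list", length(tiles))
  for (i in seq_along(tiles)) {
    segs[[i]] <- segment_tile(tiles[[i]]$pixels, params = config$seg,
                              seed = split_seed(seed, 7, i))
    qc[[i]] <- qc_filter_tile(tiles[[i]], segs[[i]])
  }
  accepted <- vapply(qc, `[[`, logical(1), "accepted")
  qc_df <- data.frame(
    slide_id = slide_id, tile = seq_along(tiles), accepted = accepted,
    reasons = vapply(qc, function(q) paste(q$reasons, collapse = ";"),
                     character(1)),
    nucleus_count = vapply(qc, `[[`, integer(1), "nucleus_count"),
    stringsAsFactors = FALSE
  )
  n_take <- n_required
  if (sum(accepted) < n_required) {
    if (!config$allow_fewer) {
      stop_oralcyto(
        sprintf("slide %s: only %d accepted tiles, %d required",
                slide_id, sum(accepted), n_required),
        "oralcyto_insufficiency_error"
      )
    }
    n_take <- sum(accepted)
  }
  take_idx <- which(accepted)
  if (n_take < length(take_idx)) {
    set.seed(split_seed(seed, 8))
    take_idx <- sort(sample(take_idx, n_take))
  }
  has_truth <- length(tiles) > 0 && !is.null(tiles[[1]]$truth)
  rows <- lapply(take_idx, function(i) {
    s <- segs[[i]]
    row <- data.frame(
      slide_id = slide_id, tile = i,
      a_nucleus = s$a_nucleus, a_cytoplasm = s$a_cytoplasm,
      nc_ratio = nc_ratio(s$a_nucleus, s$a_cytoplasm),
      stringsAsFactors = FALSE
    )
    if (has_truth && !is.null(tiles[[i]]$truth$nucleus_mask)) {
      tr <- tiles[[i]]$truth
      row$dice_nucleus <- dice_coefficient(s$nucleus_mask, tr$nucleus_mask)
      row$dice_cytoplasm <- dice_coefficient(s$cytoplasm_mask, tr$cytoplasm_mask)
      row$true_nc <- tr$true_nc_ratio
      row$nc_rel_error <- abs(row$nc_ratio / tr$true_nc_ratio - 1)
    }
    row
  })
  confusion <- NULL
  is_clutter <- vapply(tiles, function(t) isTRUE(t$is_clutter), logical(1))
  if (has_truth && any(is_clutter)) {
    kind <- vapply(tiles, function(t) if (is.null(t$kind)) "cell" else t$kind,
                   character(1))
    confusion <- as.data.frame(table(kind = kind, accepted = accepted))
  }
  list(cells = do.call(rbind, rows), qc = qc_df, n_accepted = sum(accepted),
       confusion = confusion)
}

# read one slide directory written by cmd_simulate
.read_wsi_dir <- function(wdir, skip_bad = FALSE, read_masks = TRUE) {
  sidecar <- jsonlite::read_json(file.path(wdir, "sidecar.json"),
                                 simplifyVector = FALSE)
  tiles <- list()
  skipped <- character(0)
  for (rec in sidecar$tiles) {
    path <- file.path(wdir, rec$file)
    px <- tryCatch(read_tile_png(path), error = function(e) NULL)
    if (is.null(px)) {
      if (!skip_bad) {
        stop_oralcyto(sprintf("unreadable tile image: %s", path),
                      "oralcyto_io_error")
      }
      skipped <- c(skipped, path)
      next
    }
    truth <- NULL
    npath <- file.path(wdir, sub("\\.png$", "_nucleus.png", rec$file))
    cpath <- file.path(wdir, sub("\\.png$", "_cytoplasm.png", rec$file))
    if (read_masks && file.exists(npath) && file.exists(cpath)) {
      nuc <- read_tile_png(npath)
      cyt <- read_tile_png(cpath)
      truth <- list(nucleus_mask = nuc, cytoplasm_mask = cyt,
                    true_nc_ratio = if (is.null(rec$true_nc)) NA_real_ else rec$true_nc,
                    cell_count = NA_integer_)
    } else if (!is.null(rec$true_nc)) {
      truth <- list(nucleus_mask = NULL, cytoplasm_mask = NULL,
                    true_nc_ratio = rec$true_nc, cell_count = NA_integer_)
    }
    tiles[[length(tiles) + 1]] <- list(
      pixels = px,
      origin = unlist(rec$origin),
      truth = truth,
      is_clutter = isTRUE(rec$is_clutter),
      kind = if (is.null(rec$kind)) "cell" else rec$kind,
      slide_id = sidecar$slide_id
    )
  }
  list(tiles = tiles, sidecar = sidecar, skipped = skipped)
}

#' Run the morphometry pipeline over simulated or stored slides
#'
#' Walks `in_dir/wsis/<cat>/<wsi>/` directories (the [cmd_simulate()]
#' layout), runs QC + segmentation + morphometry per slide, aggregates
#' per-animal case medians, and writes `per_cell.csv`, `cases.csv`,
#' `qc_summary.csv` and a manifest into `out_dir`. When truth sidecars are
#' present the per-cell table carries Dice and N/C error columns.
#'
#' @param in_dir directory containing a `wsis/` tree (and optionally
#'   `cohort.csv`).
#' @param config a [run_config()]; `allow_fewer` and `skip_bad` control
#'   error handling.
#' @param out_dir writable output directory.
#' @return invisibly, a list with `cells`, `cases`, `qc`, `skipped`.
#' @export
cmd_morphometry <- function(in_dir, config = run_config(), out_dir) {
  wsis_root <- file.path(in_dir, "wsis")
  if (!dir.exists(wsis_root)) {
    stop_oralcyto(sprintf("no wsis/ directory under %s", in_dir),
                  "oralcyto_io_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cat_dirs <- list.dirs(wsis_root, recursive = FALSE)
  all_cells <- list(); all_qc <- list(); skipped <- character(0)
  cases <- list()
  for (cdir in cat_dirs) {
    cat_id <- basename(cdir)
    wsi_dirs <- list.dirs(cdir, recursive = FALSE)
    cat_cells <- list()
    for (wdir in wsi_dirs) {
      rd <- .read_wsi_dir(wdir, skip_bad = config$skip_bad)
      skipped <- c(skipped, rd$skipped)
      res <- process_wsi_tiles(rd$tiles, config = config,
                               slide_id = rd$sidecar$slide_id,
                               seed = split_seed(config$seed,
                                                 as.integer(rd$sidecar$seed %% 100000)))
      cells <- res$cells
      cells$cat_id <- cat_id
      cat_cells[[wdir]] <- cells
      all_cells[[wdir]] <- cells
      all_qc[[wdir]] <- res$qc
    }
    cc <- do.call(rbind, cat_cells)
    agg <- suppressWarnings(
      aggregate_case(cc, cat_id, n_wsis = length(wsi_dirs),
                     expected_cells_per_wsi = config$tiles_per_wsi)
    )
    row <- data.frame(cat_id = agg$cat_id, n_cells = agg$n_cells,
                      n_wsis = agg$n_wsis, case_nc_ratio = agg$case_nc_ratio,
                      q1 = agg$q1, q3 = agg$q3, stringsAsFactors = FALSE)
    if ("true_nc" %in% names(cc)) {
      # per-case truth: median of per-tile truth equals the intended target
      row$true_case_nc <- stats::median(cc$true_nc)
    }
    cases[[cat_id]] <- row
  }
  cells_df <- do.call(rbind, all_cells)
  qc_df <- do.call(rbind, all_qc)
  cases_df <- do.call(rbind, cases)
  rownames(cells_df) <- rownames(qc_df) <- rownames(cases_df) <- NULL
  utils::write.csv(cells_df, file.path(out_dir, "per_cell.csv"), row.names = FALSE)
  utils::write.csv(cases_df, file.path(out_dir, "cases.csv"), row.names = FALSE)
  reason_tab <- table(unlist(strsplit(qc_df$reasons[qc_df$reasons != ""], ";")))
  qc_summary <- data.frame(
    n_tiles = nrow(qc_df), n_accepted = sum(qc_df$accepted),
    reason = c("accepted", names(reason_tab)),
    count = c(sum(qc_df$accepted), as.integer(reason_tab)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(qc_summary, file.path(out_dir, "qc_summary.csv"),
                   row.names = FALSE)
  write_manifest(out_dir, config)
  invisible(list(cells = cells_df, cases = cases_df, qc = qc_df,
                 skipped = skipped))
}

#' Statistical report for a cohort
#'
#' Emits the baseline-comparison table (continuous covariates by exposure
#' group with Mann-Whitney U, Cliff's delta and bootstrap CI), the sex
#' Fisher tests in both orientations, exposure summary counts, and -- when
#' cotinine and the cytology scores are available -- the exposed-cohort
#' Spearman correlation matrix. All outputs are written as CSV/JSON into
#' `out_dir` and returned.
#'
#' @param cohort_csv path to a cohort CSV, or a [cohort()] object.
#' @param out_dir writable output directory.
#' @param config a [run_config()] (bootstrap replicates and seed).
#' @return invisibly, a list with `report`, `correlation` (or NULL) and
#'   `exposure_summary`.
#' @export
cmd_stats <- function(cohort_csv, out_dir, config = run_config()) {
  coh <- if (inherits(cohort_csv, "cohort")) cohort_csv else
    read_cohort_table(cohort_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- cohort_stats_report(coh, boot_reps = config$boot_reps,
                                seed = config$seed)
  utils::write.csv(report$comparisons, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE)
  sex_json <- lapply(report$sex, function(f) {
    list(table = as.vector(f$table), odds_ratio = f$odds_ratio,
         or_ci = f$or_ci, p = f$p, ci_method = f$ci_method)
  })
  jsonlite::write_json(sex_json, file.path(out_dir, "sex_fisher.json"),
                       auto_unbox = TRUE, digits = 15, pretty = TRUE)
  corr <- NULL
  have_cols <- all(c("cotinine_ng_ml", "case_nc_ratio", "inflammation_score",
                     "dysplasia_grade") %in% names(coh))
  if (have_cols) {
    corr <- tryCatch(correlation_matrix(coh), oralcyto_domain_error = function(e) {
      message("correlation matrix skipped: ", conditionMessage(e))
      NULL
    })
  } else {
    message("correlation matrix skipped: cotinine or cytology columns absent")
  }
  if (!is.null(corr)) {
    utils::write.csv(corr$rho, file.path(out_dir, "correlation_rho.csv"))
    utils::write.csv(corr$p, file.path(out_dir, "correlation_p.csv"))
  }
  expo <- summarize_exposure(coh)
  jsonlite::write_json(
    lapply(expo, function(g) list(
      n = g$n,
      by_smoker_owners = as.list(stats::setNames(as.integer(g$by_smoker_owners),
                                                 names(g$by_smoker_owners))),
      by_sex = as.list(stats::setNames(as.integer(g$by_sex), names(g$by_sex)))
    )),
    file.path(out_dir, "exposure_summary.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  write_manifest(out_dir, config,
                 inputs = if (is.character(cohort_csv)) cohort_csv else character(0))
  invisible(list(report = report, correlation = corr,
                 exposure_summary = expo))
}
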