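# Slide tiling, tissue masking, tile quality control and seeded sampling of
# valid epithelial tiles.

#' Compute a tissue mask for a slide
#'
#' Separates tissue from the near-white, low-saturation background on the
#' HSV saturation channel, reduced by block averaging at `downsample`.
#' The default threshold is global Otsu on the saturation channel; when the
#' channel is essentially unimodal (range below `unimodal_range`), or when
#' `threshold_method = "fixed"`, a fixed saturation floor is used instead.
#'
#' @param slide H x W x 3 RGB array (0-255).
#' @param downsample integer block size (>= 1); the mask has dimensions
#'   `ceiling(dim(slide) / downsample)`.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold saturation floor used by the fixed method and the
#'   unimodal fallback.
#' @param unimodal_range saturation range below which Otsu is abandoned.
#' @return list of class `tissue_mask`: logical `mask`, `downsample`,
#'   `threshold`, `method`, `tissue_fraction`.
#' @export
compute_tissue_mask <- function(slide, downsample = 8,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0.15,
                                unimodal_range = 0.05) {
  threshold_method <- match.arg(threshold_method)
  d <- dim(slide)
  if (length(d) != 3 || d[3] != 3 || d[1] == 0 || d[2] == 0) {
    stop_oralcyto("slide must be a non-empty H x W x 3 array", "oralcyto_parameter_error")
  }
  if (!is_count(downsample) || downsample > min(d[1:2])) {
    stop_oralcyto("downsample must be a positive integer no larger than the slide",
                  "oralcyto_parameter_error")
  }
  mx <- pmax(slide[, , 1], slide[, , 2], slide[, , 3])
  mn <- pmin(slide[, , 1], slide[, , 2], slide[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  # block-average downsample (pad the ragged edge by repeating the last row/col)
  nr <- ceiling(d[1] / downsample); nc <- ceiling(d[2] / downsample)
  ridx <- pmin(rep(seq_len(nr), each = downsample)[seq_len(d[1])], nr)
  cidx <- pmin(rep(seq_len(nc), each = downsample)[seq_len(d[2])], nc)
  g <- rowsum(sat, ridx)                 # sum over row blocks -> nr x W
  g <- t(rowsum(t(g), cidx))             # sum over col blocks -> nr x nc
  counts <- tabulate(ridx, nr) %o% tabulate(cidx, nc)
  sat_ds <- g / counts
  method <- threshold_method
  if (threshold_method == "otsu" &&
      (max(sat_ds) - min(sat_ds)) < unimodal_range) {
    method <- "fixed_fallback"
  }
  thr <- if (method == "otsu") {
    EBImage::otsu(EBImage::Image(sat_ds), range = c(0, 1))
  } else {
    fixed_threshold
  }
  mask <- sat_ds > thr
  structure(list(
    mask = mask, downsample = downsample, threshold = thr, method = method,
    tissue_fraction = mean(mask)
  ), class = "tissue_mask")
}

#' Subdivide a slide into square tiles
#'
#' Enumerates half-open windows `[r, r + size) x [c, c + size)` row-major at
#' the given stride, with 0-based origins. Edge regions smaller than a full
#' tile are discarded, so for an H x W slide (H, W >= size) the count is
#' `floor((H - size)/stride + 1) * floor((W - size)/stride + 1)`.
#'
#' @param slide H x W x 3 RGB array (0-255).
#' @param tile_size tile side in pixels (default 256).
#' @param stride step between tile origins (default `tile_size`, a partition).
#' @param slide_id label attached to each tile.
#' @return list of tiles, each `pixels` (tile_size^2 x 3 array), `origin`
#'   (0-based row, col) and `slide_id`; empty (with a warning) when the
#'   slide is smaller than one tile.
#' @export
tile_image <- function(slide, tile_size = 256, stride = tile_size,
                       slide_id = "slide") {
  stopifnot(is_count(stride), is_count(tile_size))
  d <- dim(slide)
  if (d[1] < tile_size || d[2] < tile_size) {
    warning(sprintf("slide %s (%d x %d) smaller than one %d px tile; no tiles",
                    slide_id, d[1], d[2], tile_size))
    return(list())
  }
  r0 <- seq(0, d[1] - tile_size, by = stride)
  c0 <- seq(0, d[2] - tile_size, by = stride)
  tiles <- vector("list", length(r0) * length(c0))
  i <- 0
  for (r in r0) {
    for (c_ in c0) {
      i <- i + 1
      tiles[[i]] <- list(
        pixels = slide[r + seq_len(tile_size), c_ + seq_len(tile_size), ,
                       drop = FALSE],
        origin = c(row = r, col = c_), slide_id = slide_id
      )
    }
  }
  tiles
}

#' Restrict tiles to tissue-containing regions
#'
#' Keeps tiles whose footprint overlaps the tissue mask by at least
#' `min_tissue_fraction`.
#'
#' @param tiles list from [tile_image()].
#' @param tissue a `tissue_mask` from [compute_tissue_mask()].
#' @param min_tissue_fraction minimum overlapping tissue fraction.
#' @return the filtered tile list.
#' @export
tiles_in_tissue <- function(tiles, tissue, min_tissue_fraction = 0.05) {
  keep <- vapply(tiles, function(t) {
    ts <- dim(t$pixels)[1]
    ds <- tissue$downsample
    r <- (t$origin[1] %/% ds) + seq_len(max(1, ts %/% ds))
    c_ <- (t$origin[2] %/% ds) + seq_len(max(1, ts %/% ds))
    r <- r[r <= nrow(tissue$mask)]; c_ <- c_[c_ <= ncol(tissue$mask)]
    mean(tissue$mask[r, c_]) >= min_tissue_fraction
  }, logical(1))
  tiles[keep]
}

#' Quality-control decision for one tile
#'
#' Applies the programmatic analogue of expert tile screening: a tile is
#' accepted only if it shows exactly one intact, clearly defined nucleated
#' epithelial cell. Rejection codes: `acellular` (no nuclear pixels),
#' `debris` (nuclear specks all below the minimum area), `multiple_cells`
#' (more than one plausible nucleus, covering overlaps and inflammatory
#' aggregates), `border_contact` (the selected cell touches the tile edge,
#' i.e. an incomplete cytoplasmic contour) and `low_contrast` (colour
#' clustering degenerate or cluster centres closer than the CIELAB margin).
#'
#' @param tile a tile (list with `pixels`) or a bare pixel array; only used
#'   for reporting, the decision is made on `seg`.
#' @param seg the tile's [segment_tile()] result.
#' @return list of class `tile_qc`: `accepted`, `reasons` (character),
#'   `nucleus_count`.
#' @export
qc_filter_tile <- function(tile, seg) {
  stopifnot(inherits(seg, "cell_segmentation"))
  reasons <- character(0)
  if (seg$status == "low_contrast") reasons <- c(reasons, "low_contrast")
  if (seg$status == "acellular") reasons <- c(reasons, "acellular")
  if (seg$status == "debris") reasons <- c(reasons, "debris")
  if (seg$status == "ok") {
    if (seg$nucleus_count > 1) reasons <- c(reasons, "multiple_cells")
    if (seg$border_contact) reasons <- c(reasons, "border_contact")
    # a cell whose cytoplasm could not be delineated at all
    if (seg$a_cytoplasm == 0 && length(reasons) == 0) {
      reasons <- c(reasons, "low_contrast")
    }
  }
  structure(list(
    accepted = length(reasons) == 0,
    reasons = reasons,
    nucleus_count = seg$nucleus_count
  ), class = "tile_qc")
}

#' Sample a fixed number of QC-accepted tiles
#'
#' Uniform seeded sampling without replacement among accepted tiles. If
#' fewer tiles than `n_required` were accepted, an insufficiency error
#' reporting the accepted count is raised (by default a fixed number of
#' valid epithelial tiles per slide enters morphometry).
#'
#' @param tiles list of tiles.
#' @param accepted logical vector marking QC-accepted tiles.
#' @param n_required number of tiles to keep (>= 1).
#' @param seed sampling seed.
#' @return list of `n_required` accepted tiles, in sampled order.
#' @export
sample_valid_tiles <- function(tiles, accepted, n_required, seed = 1) {
  stopifnot(is_count(n_required), length(accepted) == length(tiles))
  idx <- which(accepted)
  if (length(idx) < n_required) {
    stop_oralcyto(
      sprintf("only %d accepted tiles, %d required", length(idx), n_required),
      "oralcyto_insufficiency_error"
    )
  }
  set.seed(seed)
  tiles[sample(idx, n_required)]
}
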