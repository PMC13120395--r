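# Per-tile nucleus/cytoplasm segmentation: CIELAB conversion, K-means
# colour clustering, lightness-ranked compartment assignment, morphological
# refinement, and connected-component isolation of the primary cell.

#' Convert an RGB tile to CIELAB
#'
#' Standard sRGB -> CIELAB conversion under the D65 reference white
#' (via `grDevices::convertColor`). L is in [0, 100].
#'
#' @param pixels H x W x 3 array of 8-bit RGB values (0-255).
#' @return H x W x 3 numeric array with channels L, a, b.
#' @export
rgb_to_cielab <- function(pixels) {
  d <- dim(pixels)
  stopifnot(length(d) == 3, d[3] == 3)
  m <- cbind(as.vector(pixels[, , 1]), as.vector(pixels[, , 2]),
             as.vector(pixels[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  array(lab, dim = d)
}

# deterministic farthest-point (maximin) seeding: darkest pixel, brightest
# pixel, then points maximizing the distance to the nearest chosen centre;
# lands one seed per colour class even when class sizes are very unbalanced
.maximin_init <- function(X, k) {
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[which.min(X[, 1]), ]
  centers[2, ] <- X[which.max(X[, 1]), ]
  d2 <- pmin(rowSums(sweep(X, 2, centers[1, ])^2),
             rowSums(sweep(X, 2, centers[2, ])^2))
  if (k > 2) {
    for (j in 3:k) {
      centers[j, ] <- X[which.max(d2), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
    }
  }
  centers
}

# k-means++ seeding: first centre uniform, then points with probability
# proportional to squared distance from the nearest chosen centre
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) {
      centers[j, ] <- X[sample.int(n, 1), ]
    } else {
      centers[j, ] <- X[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' K-means colour clustering of a CIELAB tile
#'
#' Clusters pixels in (L, a, b) space. Centres are fitted on a random pixel
#' subsample with `n_init` k-means++ seeded restarts (best within-cluster
#' sum of squares wins), then every pixel is assigned to its nearest fitted
#' centre; the combination is deterministic given `seed`. The k-means++
#' seeding is what lets minority classes -- a small or edge-clipped nucleus
#' among tens of thousands of background pixels -- reliably claim a centre.
#' A tile without at least `k` distinct colours raises a degeneracy error
#' (classed `oralcyto_degenerate`; tile QC maps it to a rejection).
#'
#' @param lab H x W x 3 CIELAB array from [rgb_to_cielab()].
#' @param k number of clusters (default 3).
#' @param seed integer seed.
#' @param n_init number of k-means++ restarts.
#' @param sample_px number of pixels subsampled for centre fitting; all
#'   pixels are used when the tile is smaller.
#' @return list with `labels` (H x W integer matrix in 1..k) and `centers`
#'   (k x 3 matrix, CIELAB).
#' @export
kmeans_segment <- function(lab, k = 3, seed = 1, n_init = 5,
                           sample_px = 6000) {
  d <- dim(lab)
  X <- cbind(as.vector(lab[, , 1]), as.vector(lab[, , 2]),
             as.vector(lab[, , 3]))
  set.seed(seed)
  idx <- if (nrow(X) > sample_px) sample.int(nrow(X), sample_px) else seq_len(nrow(X))
  Xs <- X[idx, , drop = FALSE]
  inits <- c(list(.maximin_init(Xs, k)),
             lapply(seq_len(max(n_init - 1, 1)), function(r) .kmeanspp_init(Xs, k)))
  fits <- lapply(inits, function(ini) {
    tryCatch(stats::kmeans(Xs, centers = ini, iter.max = 300),
             error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) {
    stop_oralcyto("tile has fewer distinct colours than clusters",
                  "oralcyto_degenerate")
  }
  # best restart by WCSS; near-ties (within 5%) broken toward the solution
  # with the best-separated centres, which protects minority clusters from
  # being absorbed into a split of the dominant background class
  wcss <- vapply(fits, `[[`, numeric(1), "tot.withinss")
  cand <- which(wcss <= min(wcss) * 1.05)
  sep <- vapply(fits[cand], function(f) {
    dd <- stats::dist(f$centers)
    min(dd)
  }, numeric(1))
  best <- fits[[cand[which.max(sep)]]]
  centers <- best$centers
  # nearest-centre assignment for all pixels
  d2 <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
    outer(rep(1, nrow(X)), rowSums(centers^2))
  labels <- matrix(max.col(-d2, ties.method = "first"), d[1], d[2])
  colnames(centers) <- c("L", "a", "b")
  list(labels = labels, centers = centers)
}

#' Map colour clusters to cell compartments
#'
#' With k = 3 clusters, ranks centres by lightness L ascending: the darkest
#' cluster is the nucleus, the middle one the cytoplasm, the lightest the
#' background. Exact L ties are broken by chroma sqrt(a^2 + b^2): the more
#' chromatic centre is taken as nucleus.
#'
#' @param centers k x 3 CIELAB centre matrix from [kmeans_segment()].
#' @return named integer vector giving the cluster index of `nucleus`,
#'   `cytoplasm` and `background`.
#' @export
assign_compartments <- function(centers) {
  if (nrow(centers) != 3) {
    stop_oralcyto("default compartment assignment requires k = 3 clusters; supply a custom mapping for other k",
                  "oralcyto_config_error")
  }
  chroma <- sqrt(centers[, 2]^2 + centers[, 3]^2)
  ord <- order(centers[, 1], -chroma) # darkest first; ties: high chroma first
  c(nucleus = ord[1], cytoplasm = ord[2], background = ord[3])
}

#' Morphological refinement of compartment masks
#'
#' Applies, per compartment, a morphological opening (disc radius `r_open`)
#' followed by closing (disc radius `r_close`), and fills interior holes of
#' the nucleus mask. Any overlap introduced by the operations is resolved in
#' favour of the nucleus so the masks stay disjoint.
#'
#' @param nucleus_mask,cytoplasm_mask logical matrices.
#' @param r_open,r_close disc radii in pixels (0 disables the step).
#' @param fill_holes fill holes inside the nucleus mask (default TRUE).
#' @return list with refined logical `nucleus_mask` and `cytoplasm_mask`.
#' @export
refine_masks <- function(nucleus_mask, cytoplasm_mask, r_open = 1,
                         r_close = 2, fill_holes = TRUE) {
  refine <- function(m) {
    x <- m * 1
    if (r_open > 0) x <- EBImage::opening(x, EBImage::makeBrush(2 * r_open + 1, "disc"))
    if (r_close > 0) x <- EBImage::closing(x, EBImage::makeBrush(2 * r_close + 1, "disc"))
    x
  }
  nuc <- refine(nucleus_mask)
  cyt <- refine(cytoplasm_mask)
  if (fill_holes) nuc <- EBImage::fillHull(nuc)
  nuc <- as.matrix(nuc) > 0.5
  cyt <- as.matrix(cyt) > 0.5 & !nuc # nucleus wins overlaps
  list(nucleus_mask = nuc, cytoplasm_mask = cyt)
}

#' Label connected components with 8-connectivity
#'
#' Wraps `EBImage::bwlabel` (4-connectivity) and merges labels that touch
#' diagonally, yielding 8-connected components relabelled 1..n.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  n <- max(lab)
  if (n <= 1) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour label pairs
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (row in seq_len(nrow(pairs))) {
    a <- find(pairs[row, 1]); b <- find(pairs[row, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- matrix(0L, nr, nc)
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Isolate the primary cell from refined compartment masks
#'
#' Computes 8-connected components of the nucleus mask, discards components
#' below `min_nucleus_area` (debris), and selects the largest remaining
#' nucleus. Its cytoplasm is the set of cytoplasm pixels belonging to the
#' same connected cell region (the component of the nucleus-or-cytoplasm
#' union containing the selected nucleus). The result carries the signals
#' tile QC needs: the count of plausible nuclei, border contact of the
#' selected cell, and a status code.
#'
#' @param nucleus_mask,cytoplasm_mask refined logical matrices.
#' @param min_nucleus_area smallest pixel area accepted as a nucleus.
#' @return object of class `cell_segmentation`: selected `nucleus_mask` and
#'   `cytoplasm_mask`, pixel areas `a_nucleus` / `a_cytoplasm`,
#'   `nucleus_count`, `selected_component_id`, `border_contact`, and
#'   `status` (`"ok"`, `"acellular"` or `"debris"`).
#' @export
select_primary_cell <- function(nucleus_mask, cytoplasm_mask,
                                min_nucleus_area = 80) {
  empty <- function(status) {
    structure(list(
      nucleus_mask = nucleus_mask & FALSE, cytoplasm_mask = cytoplasm_mask & FALSE,
      a_nucleus = 0L, a_cytoplasm = 0L, nucleus_count = 0L,
      selected_component_id = NA_integer_, border_contact = FALSE,
      status = status, cluster_centers = NULL
    ), class = "cell_segmentation")
  }
  if (!any(nucleus_mask)) return(empty("acellular"))
  comps <- label_components(nucleus_mask)
  areas <- tabulate(comps[comps > 0])
  valid <- which(areas >= min_nucleus_area)
  if (length(valid) == 0) return(empty("debris"))
  sel <- valid[which.max(areas[valid])]
  sel_nuc <- comps == sel
  # cell region: component of the nucleus|cytoplasm union holding this nucleus
  union_lab <- label_components(nucleus_mask | cytoplasm_mask)
  region_id <- union_lab[which(sel_nuc)[1]]
  sel_cyt <- cytoplasm_mask & (union_lab == region_id)
  nr <- nrow(nucleus_mask); nc <- ncol(nucleus_mask)
  on_border <- function(m) any(m[1, ]) || any(m[nr, ]) || any(m[, 1]) || any(m[, nc])
  structure(list(
    nucleus_mask = sel_nuc, cytoplasm_mask = sel_cyt,
    a_nucleus = sum(sel_nuc), a_cytoplasm = sum(sel_cyt),
    nucleus_count = length(valid), selected_component_id = sel,
    border_contact = on_border(sel_nuc) || on_border(sel_cyt),
    status = "ok", cluster_centers = NULL
  ), class = "cell_segmentation")
}

#' Segmentation parameters
#'
#' Bundles the tunables of the per-tile segmentation stage. These are held
#' fixed across all slides of a run.
#'
#' @param k number of colour clusters.
#' @param n_init K-means restarts.
#' @param sample_px pixels subsampled for centre fitting.
#' @param r_open,r_close morphology disc radii.
#' @param fill_holes fill nucleus holes.
#' @param min_nucleus_area debris floor in pixels.
#' @param min_lab_margin minimum CIELAB distance between cluster centres
#'   below which a tile is flagged low-contrast.
#' @return list of class `seg_params`.
#' @export
seg_params <- function(k = 3, n_init = 5, sample_px = 6000, r_open = 1,
                       r_close = 2, fill_holes = TRUE, min_nucleus_area = 80,
                       min_lab_margin = 15) {
  structure(as.list(environment()), class = "seg_params")
}

#' Segment one tile end to end
#'
#' Runs the full per-tile chain: CIELAB conversion, K-means clustering,
#' lightness-ranked compartment assignment, morphological refinement and
#' primary-cell isolation. Tiles whose colour structure cannot support the
#' three-compartment model are not an error; they come back with a status
#' code for tile QC: `"acellular"` when even the darkest cluster is
#' background-like (no nuclear material anywhere), `"low_contrast"` when
#' nucleus and cytoplasm clusters are closer than the CIELAB margin, or when
#' the cytoplasm cluster collapses onto the background while a single bare
#' nucleus remains (no delineable cytoplasmic contour).
#'
#' @param pixels H x W x 3 RGB array (0-255).
#' @param params a [seg_params()].
#' @param seed integer seed for the clustering restarts.
#' @return a `cell_segmentation` (see [select_primary_cell()]) with
#'   `cluster_centers` attached; `status` may also be `"low_contrast"`.
#' @export
segment_tile <- function(pixels, params = seg_params(), seed = 1) {
  lab <- rgb_to_cielab(pixels)
  flat <- function(status, centers = NULL) {
    structure(list(
      nucleus_mask = NULL, cytoplasm_mask = NULL, a_nucleus = 0L,
      a_cytoplasm = 0L, nucleus_count = 0L,
      selected_component_id = NA_integer_, border_contact = FALSE,
      status = status, cluster_centers = centers
    ), class = "cell_segmentation")
  }
  km <- tryCatch(
    kmeans_segment(lab, k = params$k, seed = seed, n_init = params$n_init,
                   sample_px = params$sample_px),
    oralcyto_degenerate = function(e) NULL
  )
  if (is.null(km)) {
    # (near-)uniform tile: a bright one is an acellular field
    return(flat(if (stats::median(lab[, , 1]) > 80) "acellular" else "low_contrast"))
  }
  comp <- assign_compartments(km$centers)
  ctr <- km$centers
  d_nb <- sqrt(sum((ctr[comp[["nucleus"]], ] - ctr[comp[["background"]], ])^2))
  d_nc <- sqrt(sum((ctr[comp[["nucleus"]], ] - ctr[comp[["cytoplasm"]], ])^2))
  d_cb <- sqrt(sum((ctr[comp[["cytoplasm"]], ] - ctr[comp[["background"]], ])^2))
  m <- params$min_lab_margin
  if (d_nb < m) {
    # all clusters collapse: a uniformly bright field has no cells at all
    status <- if (ctr[comp[["background"]], 1] > 80) "acellular" else "low_contrast"
    return(flat(status, ctr))
  }
  if (d_nc < m) {
    # nuclear and cytoplasmic material not separable
    return(flat("low_contrast", ctr))
  }
  cyto_is_background <- d_cb < m
  ref <- refine_masks(km$labels == comp[["nucleus"]],
                      if (cyto_is_background) km$labels == 0L else
                        km$labels == comp[["cytoplasm"]],
                      r_open = params$r_open, r_close = params$r_close,
                      fill_holes = params$fill_holes)
  seg <- select_primary_cell(ref$nucleus_mask, ref$cytoplasm_mask,
                             min_nucleus_area = params$min_nucleus_area)
  if (cyto_is_background && seg$status == "ok" && seg$nucleus_count == 1) {
    # a lone bare nucleus with no separable cytoplasm: contour not delineable
    seg$status <- "low_contrast"
  }
  seg$cluster_centers <- km$centers
  seg
}

#' Dice overlap coefficient between two binary masks
#'
#' 2|A and B| / (|A| + |B|); 1 for identical non-empty masks. Returns NA if
#' both masks are empty.
#'
#' @param a,b logical matrices of equal dimension.
#' @return a number in [0, 1], or NA.
#' @export
dice_coefficient <- function(a, b) {
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(NA_real_)
  2 * sum(a & b) / (sa + sb)
}
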