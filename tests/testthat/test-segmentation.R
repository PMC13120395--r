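test_that("sRGB to CIELAB hits the reference points", {
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- c(255, 255, 255)
  px[1, 2, ] <- c(0, 0, 0)
  px[1, 3, ] <- c(119, 119, 119)
  lab <- rgb_to_cielab(px)
  expect_equal(lab[1, 1, 1], 100, tolerance = 1e-6)
  expect_lt(max(abs(lab[1, 1, 2:3])), 0.5)
  expect_equal(lab[1, 2, 1], 0, tolerance = 1e-6)
  expect_lt(max(abs(lab[1, 3, 2:3])), 0.5)
  expect_true(lab[1, 3, 1] > 0 && lab[1, 3, 1] < 100)
})

test_that("k-means recovers a noiseless three-colour tile exactly", {
  stain0 <- stain_profile(nucleus_sd = 0, cytoplasm_sd = 0, background_sd = 0,
                          noise_sd = 0)
  tl <- generate_cell_tile(0.3, stain = stain0, seed = 5)
  km <- kmeans_segment(rgb_to_cielab(tl$pixels), k = 3, seed = 1)
  comp <- assign_compartments(km$centers)
  expect_identical(km$labels == comp[["nucleus"]], tl$truth$nucleus_mask)
  expect_identical(km$labels == comp[["cytoplasm"]], tl$truth$cytoplasm_mask)
  # determinism
  km2 <- kmeans_segment(rgb_to_cielab(tl$pixels), k = 3, seed = 1)
  expect_identical(km$labels, km2$labels)
})

test_that("noisy tiles are labelled with at least 98% truth agreement", {
  agree <- vapply(1:8, function(s) {
    tl <- generate_cell_tile(0.35, seed = 400 + s)
    km <- kmeans_segment(rgb_to_cielab(tl$pixels), seed = s)
    comp <- assign_compartments(km$centers)
    truthmap <- matrix(0L, 256, 256)
    truthmap[tl$truth$cytoplasm_mask] <- 1L
    truthmap[tl$truth$nucleus_mask] <- 2L
    predmap <- matrix(0L, 256, 256)
    predmap[km$labels == comp[["cytoplasm"]]] <- 1L
    predmap[km$labels == comp[["nucleus"]]] <- 2L
    mean(predmap == truthmap)
  }, numeric(1))
  expect_true(all(agree >= 0.98))
})

test_that("a single-colour tile raises a degeneracy error", {
  lab <- rgb_to_cielab(array(200L, dim = c(64, 64, 3)))
  expect_error(kmeans_segment(lab, k = 3, seed = 1),
               class = "oralcyto_degenerate")
})

test_that("compartment assignment ranks by lightness with chroma tie-break", {
  ctr <- cbind(L = c(30, 70, 95), a = c(30, 5, 0), b = c(-30, -10, 0))
  comp <- assign_compartments(ctr)
  expect_equal(unname(comp[["nucleus"]]), 1)
  expect_equal(unname(comp[["background"]]), 3)
  # equal lightness: higher chroma becomes the nucleus
  ctr2 <- cbind(L = c(50, 50, 95), a = c(40, 5, 0), b = c(0, 0, 0))
  expect_equal(unname(assign_compartments(ctr2)[["nucleus"]]), 1)
  expect_error(assign_compartments(ctr[1:2, ]), class = "oralcyto_config_error")
})

test_that("morphological refinement removes specks, fills holes, stays disjoint", {
  nuc <- matrix(FALSE, 64, 64)
  nuc[20:40, 20:40] <- TRUE
  nuc[30, 30] <- FALSE          # interior hole
  nuc[5, 5] <- TRUE             # isolated speck
  cyt <- matrix(FALSE, 64, 64)
  cyt[15:45, 15:45] <- TRUE
  cyt[20:40, 20:40] <- FALSE
  r <- refine_masks(nuc, cyt, r_open = 1, r_close = 2)
  expect_false(r$nucleus_mask[5, 5])
  expect_true(r$nucleus_mask[30, 30])
  expect_false(any(r$nucleus_mask & r$cytoplasm_mask))
  # refinement barely perturbs clean generated masks
  tl <- generate_cell_tile(0.3, seed = 9)
  r2 <- refine_masks(tl$truth$nucleus_mask, tl$truth$cytoplasm_mask)
  changed <- mean(r2$nucleus_mask != tl$truth$nucleus_mask |
                  r2$cytoplasm_mask != tl$truth$cytoplasm_mask)
  expect_lt(changed, 0.02)
})

test_that("component labelling is 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE # diagonal chain
  m[5, 5] <- TRUE                                    # separate component
  lab <- label_components(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[2, 2], lab[3, 3])
  expect_false(lab[5, 5] == lab[1, 1])
})

test_that("primary-cell selection recovers areas and flags pathologies", {
  tl <- generate_cell_tile(0.28, seed = 15)
  seg <- segment_tile(tl$pixels, seed = 2)
  expect_equal(seg$status, "ok")
  expect_equal(seg$nucleus_count, 1L)
  expect_lt(abs(seg$a_nucleus / sum(tl$truth$nucleus_mask) - 1), 0.05)
  expect_lt(abs(seg$a_cytoplasm / sum(tl$truth$cytoplasm_mask) - 1), 0.05)
  expect_false(any(seg$nucleus_mask & seg$cytoplasm_mask))
  expect_equal(seg$a_nucleus, sum(seg$nucleus_mask))
  expect_equal(seg$a_cytoplasm, sum(seg$cytoplasm_mask))
  # two-nucleus tile reports both
  ov <- generate_clutter_tile("overlap", seed = 4)
  sov <- segment_tile(ov$pixels, seed = 2)
  expect_equal(sov$nucleus_count, 2L)
  # empty masks signal acellular
  em <- select_primary_cell(matrix(FALSE, 32, 32), matrix(FALSE, 32, 32))
  expect_equal(em$status, "acellular")
})

test_that("segmentation is deterministic end to end", {
  tl <- generate_cell_tile(0.4, seed = 77)
  s1 <- segment_tile(tl$pixels, seed = 10)
  s2 <- segment_tile(tl$pixels, seed = 10)
  expect_identical(s1$nucleus_mask, s2$nucleus_mask)
  expect_identical(s1$cluster_centers, s2$cluster_centers)
  expect_identical(s1$a_cytoplasm, s2$a_cytoplasm)
})

test_that("dice coefficient behaves at the boundaries", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2)
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  expect_true(is.na(dice_coefficient(a & FALSE, a & FALSE)))
})
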