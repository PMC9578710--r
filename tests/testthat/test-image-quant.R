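make_disk_image <- function(n, centers, r, value = 1, bg = 0) {
  X <- matrix(seq_len(n), n, n)
  Y <- matrix(seq_len(n), n, n, byrow = TRUE)
  img <- matrix(bg, n, n)
  for (k in seq_len(nrow(centers)))
    img[(X - centers[k, 1])^2 + (Y - centers[k, 2])^2 <= r^2] <- value
  img
}

test_that("bright nuclei on black background segment to the truth disks", {
  n <- 128
  centers <- rbind(c(35, 40), c(90, 80), c(40, 100))
  nuc <- make_disk_image(n, centers, r = 10)
  truth <- nuc > 0
  set.seed(1)
  noisy <- pmax(nuc + matrix(rnorm(n * n, 0, 0.03), n), 0)
  eff <- make_disk_image(n, centers, r = 22, value = 0.5)
  masks <- segment_channels(noisy, eff, boundary_margin = 0)
  dice <- 2 * sum(masks$nuclear_mask & truth) /
    (sum(masks$nuclear_mask) + sum(truth))
  expect_gte(dice, 0.95)
  expect_equal(masks$n_nuclei, 3)
  # mask-set invariants
  expect_true(all(masks$nuclear_mask[masks$nuclear_mask] ==
                    masks$cell_mask[masks$nuclear_mask]))
  expect_false(any(masks$cytoplasm_mask & masks$nuclear_mask))
})

test_that("a blank image yields empty masks and zero objects", {
  blank <- matrix(0, 64, 64)
  masks <- segment_channels(blank, blank)
  expect_equal(masks$n_nuclei, 0)
  expect_false(any(masks$nuclear_mask))
})

test_that("touching cells with distinct nuclei give two nuclear objects", {
  n <- 96
  centers <- rbind(c(40, 48), c(66, 48))  # cells overlap, nuclei apart
  nuc <- make_disk_image(n, centers, r = 8)
  eff <- make_disk_image(n, centers, r = 16, value = 0.6)
  masks <- segment_channels(nuc, eff)
  expect_equal(masks$n_nuclei, 2)
})

test_that("classifier shape mismatches are rejected", {
  bad <- function(image) matrix(0.5, 2, 2)
  expect_error(segment_channels(matrix(0, 8, 8), matrix(0, 8, 8),
                                classifier = bad), "shape")
})

test_that("NCR is the ratio of compartment means and scale-invariant", {
  n <- 64
  masks <- structure(list(
    nuclear_mask = make_disk_image(n, rbind(c(32, 32)), 8) > 0,
    cell_mask = make_disk_image(n, rbind(c(32, 32)), 20) > 0,
    cytoplasm_mask = make_disk_image(n, rbind(c(32, 32)), 20) > 0 &
      !(make_disk_image(n, rbind(c(32, 32)), 8) > 0),
    n_nuclei = 1L), class = "mask_set")
  uniform <- matrix(3, n, n)
  expect_equal(ncr_for_fov(uniform, masks)$ncr, 1)
  img <- matrix(100, n, n)
  img[masks$nuclear_mask] <- 200
  rec <- ncr_for_fov(img, masks, fov_id = 7, channel = "TAZ")
  expect_equal(rec$ncr, 2)
  expect_equal(rec$cell_count, 1)
  expect_equal(rec$channel, "TAZ")
  expect_equal(ncr_for_fov(5 * img, masks)$ncr, rec$ncr)
  empty <- masks
  empty$cytoplasm_mask[] <- FALSE
  expect_error(ncr_for_fov(img, empty), "undefined NCR")
})

test_that("density split uses the mean cell count with at-or-above high rule", {
  recs <- data.frame(cell_count = c(10, 30), ncr = c(2, 1))
  sp <- density_split(recs)
  expect_equal(sp$mean_cell_count, 20)
  expect_equal(nrow(sp$low), 1)
  expect_equal(nrow(sp$high), 1)
  ties <- data.frame(cell_count = rep(50, 4), ncr = 1:4)
  sp2 <- density_split(ties)
  expect_equal(nrow(sp2$low), 0)
  expect_equal(nrow(sp2$high), 4)
  expect_error(density_split(recs[0, ]), "2 NCR records")
})

test_that("density-coupled synthetic NCR records separate low from high density", {
  recs <- synth_ncr_records(n_fov = 120, seed = 4)
  sp <- density_split(recs)
  expect_gt(median(sp$low$ncr), median(sp$high$ncr))
})

test_that("PLA counting assigns constructed dots to the right compartments", {
  n <- 220
  nuc <- make_disk_image(n, rbind(c(110, 110)), r = 25, value = 0.8)
  dots <- matrix(0, n, n)
  put_dot <- function(img, r, c) {
    img[(r - 1):(r + 1), (c - 1):(c + 1)] <- 1
    img
  }
  # 3 dots inside the nucleus
  for (rc in list(c(105, 105), c(118, 112), c(110, 122)))
    dots <- put_dot(dots, rc[1], rc[2])
  # 2 dots in the 30-pass dilation ring (25 < d <= 55 px from center)
  for (rc in list(c(110, 150), c(70, 110)))
    dots <- put_dot(dots, rc[1], rc[2])
  res <- pla_count(nuc, dots, dilate_iterations = 30,
                   prob_threshold = 0.5)
  expect_equal(res$n_nuclei, 1)
  expect_equal(res$dots_nuclear, 3)
  expect_equal(res$dots_cytoplasmic, 2)
  expect_equal(res$dots_unassigned, 0)
  expect_equal(res$dots_per_nucleus, 3)
  # degenerate dilation: no ring, so no cytoplasmic dots
  res0 <- pla_count(nuc, dots, dilate_iterations = 0,
                    prob_threshold = 0.5)
  expect_equal(res0$dots_cytoplasmic, 0)
  expect_equal(res0$dots_nuclear, 3)
  expect_equal(res0$dots_unassigned, 2)
  # compartment counts always partition the total
  expect_equal(res0$dots_nuclear + res0$dots_cytoplasmic +
                 res0$dots_unassigned, res0$dots_total)
})

test_that("zero nuclei flags the PLA record and leaves dots unassigned", {
  n <- 64
  dots <- make_disk_image(n, rbind(c(20, 20)), 2)
  res <- pla_count(matrix(0, n, n), dots, prob_threshold = 0.5)
  expect_true(res$flagged)
  expect_equal(res$dots_nuclear, 0)
  expect_true(is.na(res$dots_per_nucleus))
})

test_that("PLA rates are recovered across seeded scenes", {
  lam_nuc <- 8; lam_cyt <- 4; n_nuclei <- 4
  got_nuc <- got_cyt <- true_nuc <- true_cyt <- 0
  for (s in 1:20) {
    sc <- synth_pla_scene(n_nuclei = n_nuclei, lambda_nuclear = lam_nuc,
                          lambda_cyto = lam_cyt, grid = 320,
                          dilate_iterations = 20, seed = s)
    res <- pla_count(sc$nuclei_image, sc$dot_image,
                     dilate_iterations = 20, dot_area = c(3, 60))
    got_nuc <- got_nuc + res$dots_nuclear
    got_cyt <- got_cyt + res$dots_cytoplasmic
    true_nuc <- true_nuc + sc$truth$dots_nuclear
    true_cyt <- true_cyt + sc$truth$dots_cytoplasmic
  }
  expect_lt(abs(got_nuc / (20 * n_nuclei * lam_nuc) - 1), 0.15)
  expect_lt(abs(got_cyt / (20 * n_nuclei * lam_cyt) - 1), 0.15)
  expect_lt(abs(got_nuc / true_nuc - 1), 0.15)
  expect_lt(abs(got_cyt / true_cyt - 1), 0.15)
})

test_that("IHC tiles below the tissue cutoff are excluded, densities recovered", {
  tile_full <- list(id = 1, image = matrix(0.2, 100, 100),
                    tissue = matrix(TRUE, 100, 100))
  tile_bare <- list(id = 2, image = matrix(0.2, 100, 100),
                    tissue = matrix(FALSE, 100, 100))
  out <- ihc_quantify(list(tile_full, tile_bare), pixel_size_um = 10)
  expect_false(out$excluded[1])
  expect_true(out$excluded[2])
  expect_true(is.na(out$density[2]))
  expect_error(ihc_quantify(list(tile_full)), "pixel_size_um")

  # 5 nuclei on a fully-tissue 1 mm^2 tile -> density 5 per mm^2
  img <- matrix(0.2, 200, 200)
  for (ctr in list(c(30, 30), c(80, 150), c(120, 60), c(160, 160),
                   c(50, 100)))
    img[(ctr[1] - 2):(ctr[1] + 2), (ctr[2] - 2):(ctr[2] + 2)] <- 0.9
  tile <- list(id = 3, image = img, tissue = matrix(TRUE, 200, 200))
  out2 <- ihc_quantify(list(tile), pixel_size_um = 5,
                       prob_threshold = 0.6)
  expect_equal(out2$positive_nuclei, 5)
  expect_equal(out2$density, 5)
})

test_that("IHC density ranks are recovered on a synthetic slide", {
  syn <- synth_ihc_tiles(n_tiles = 30, densities = c(2, 10, 50),
                         tissue_fractions = c(0.7, 0.9, 1), seed = 8)
  out <- ihc_quantify(syn$tiles, pixel_size_um = 5)
  keep <- !out$excluded
  rho <- cor(out$density[keep], syn$truth$density[keep],
             method = "spearman")
  expect_gte(rho, 0.9)
})

test_that("tile density is stable under 2x binning of the classification", {
  syn <- synth_ihc_tiles(n_tiles = 6, densities = 20,
                         tissue_fractions = 1, seed = 3)
  out1 <- ihc_quantify(syn$tiles, pixel_size_um = 5)
  bin2 <- function(m) {
    n <- nrow(m) %/% 2
    0.25 * (m[2 * (1:n) - 1, 2 * (1:n) - 1] + m[2 * (1:n), 2 * (1:n) - 1] +
              m[2 * (1:n) - 1, 2 * (1:n)] + m[2 * (1:n), 2 * (1:n)])
  }
  tiles2 <- lapply(syn$tiles, function(tl)
    list(id = tl$id, image = bin2(tl$image), tissue = bin2(tl$tissue) > 0.5))
  out2 <- ihc_quantify(tiles2, pixel_size_um = 10,
                       nucleus_area = c(2, 200))
  expect_equal(mean(out2$density) / mean(out1$density), 1, tolerance = 0.1)
})

test_that("focus score separates sharp from blurred images", {
  set.seed(2)
  sharp <- matrix(runif(64 * 64), 64)
  blurred <- as.matrix(EBImage::gblur(sharp, sigma = 4))
  expect_gt(focus_score(sharp), 10 * focus_score(blurred))
})
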