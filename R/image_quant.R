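#' Segment nuclear and effector channels into compartment masks
#'
#' Runs the pixel classifier on the nuclear (H2B) channel and on one
#' effector channel, thresholds both probability maps (Otsu by default),
#' removes small objects, and assembles a mask set with the invariants
#' nuclear subset-of cell and cytoplasm = cell minus nuclear.
#'
#' @param nuclear_channel Matrix: nuclear marker intensities.
#' @param effector_channel Matrix: effector (YAP or TAZ) intensities,
#'   used as the foreground/cell channel.
#' @param classifier Pixel classifier (see [baseline_classifier()]).
#' @param min_nucleus_area Minimum nucleus object size in pixels.
#' @param min_cell_area Minimum foreground object size in pixels.
#' @param prob_threshold Optional fixed threshold instead of Otsu.
#' @param boundary_margin Safety margin in pixels around the nuclear
#'   boundary: the nuclear mask is eroded by this much and the
#'   cytoplasm additionally excludes the same band around nuclei, so
#'   compartment intensity means are not contaminated by mixed boundary
#'   pixels (default 1; 0 disables).
#' @return A list of class `mask_set`: `nuclear_mask`, `cell_mask`,
#'   `cytoplasm_mask` (logical matrices), `n_nuclei`.
#' @export
segment_channels <- function(nuclear_channel, effector_channel,
                             classifier = baseline_classifier(),
                             min_nucleus_area = 20, min_cell_area = 20,
                             prob_threshold = NULL, boundary_margin = 1) {
  nuc_p <- classifier(nuclear_channel)
  eff_p <- classifier(effector_channel)
  if (!all(dim(nuc_p) == dim(nuclear_channel)) ||
      !all(dim(eff_p) == dim(effector_channel)))
    stop("classifier output shape does not match the input image",
         call. = FALSE)
  nuclear <- filter_objects(threshold_prob_map(nuc_p, prob_threshold),
                            min_area = min_nucleus_area)
  cell <- filter_objects(threshold_prob_map(eff_p, prob_threshold),
                         min_area = min_cell_area)
  cell <- cell | nuclear          # nuclei are always part of the cell
  nuc_core <- nuclear
  nuc_band <- nuclear
  if (boundary_margin > 0) {
    nuc_core <- !dilate_mask(!nuclear, boundary_margin)
    nuc_band <- dilate_mask(nuclear, boundary_margin)
  }
  structure(list(
    nuclear_mask = nuc_core,
    cell_mask = cell,
    cytoplasm_mask = cell & !nuc_band,
    n_nuclei = label_objects(nuclear)$n
  ), class = "mask_set")
}

#' Nuclear/cytoplasmic ratio of one field of view
#'
#' Mean effector intensity over nuclear pixels divided by the mean over
#' cytoplasmic pixels, together with the number of labelled nuclei (the
#' cell count of the FOV).
#'
#' @param effector_channel Intensity matrix.
#' @param masks A `mask_set` from [segment_channels()].
#' @param fov_id Identifier carried into the record.
#' @param channel Label (e.g. `"YAP"` or `"TAZ"`).
#' @return A one-row data frame (`ncr_record`): `fov_id`, `channel`,
#'   `cell_count`, `mean_nuclear_intensity`, `mean_cytoplasmic_intensity`,
#'   `ncr`.
#' @export
ncr_for_fov <- function(effector_channel, masks, fov_id = 1L,
                        channel = "YAP") {
  stopifnot(inherits(masks, "mask_set"))
  if (!any(masks$nuclear_mask))
    stop("undefined NCR: empty nuclear mask in FOV ", fov_id,
         call. = FALSE)
  if (!any(masks$cytoplasm_mask))
    stop("undefined NCR: empty cytoplasm mask in FOV ", fov_id,
         call. = FALSE)
  mn <- mean(effector_channel[masks$nuclear_mask])
  mc <- mean(effector_channel[masks$cytoplasm_mask])
  data.frame(fov_id = fov_id, channel = channel,
             cell_count = masks$n_nuclei,
             mean_nuclear_intensity = mn,
             mean_cytoplasmic_intensity = mc,
             ncr = mn / mc)
}

#' Split NCR records at the mean cell count
#'
#' Stratifies per-FOV records into low- and high-density groups at the
#' arithmetic mean of `cell_count`; records strictly below the mean are
#' "low", records at or above it are "high".
#'
#' @param records Data frame of NCR records (needs a `cell_count`
#'   column), >= 2 rows.
#' @return List with `low`, `high` (data frames) and `mean_cell_count`.
#' @examples
#' recs <- data.frame(cell_count = c(10, 30), ncr = c(1.5, 0.8))
#' density_split(recs)$mean_cell_count
#' @export
density_split <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2)
    stop("need at least 2 NCR records", call. = FALSE)
  m <- mean(records$cell_count)
  list(low = records[records$cell_count < m, , drop = FALSE],
       high = records[records$cell_count >= m, , drop = FALSE],
       mean_cell_count = m)
}

#' Count proximity-ligation dots per subcellular compartment
#'
#' Segments nuclei and dots, builds a pseudo-cytoplasm by dilating the
#' nuclear mask (`dilate_iterations` passes of a 3x3 square structuring
#' element, applied as one dilation with a square brush of width
#' `2 * iterations + 1`) and subtracting the nuclei, then assigns each
#' dot by the position of its centroid: nuclear, cytoplasmic (in the
#' dilation ring) or unassigned.
#'
#' @param nuclei_image Matrix: nuclear stain (DAPI).
#' @param dot_image Matrix: PLA signal channel, co-registered.
#' @param dilate_iterations Dilation passes used for the
#'   pseudo-cytoplasm ring (default 30).
#' @param classifier Pixel classifier for the nuclear channel.
#' @param dot_classifier Pixel classifier for the dot channel; the
#'   default smooths at the diffraction-limited dot scale so nearby
#'   dots are not merged away.
#' @param min_nucleus_area Minimum nucleus size, px.
#' @param dot_area Allowed dot size range in px, `c(min, max)`.
#' @param prob_threshold Optional fixed threshold instead of Otsu.
#' @param split_merged Estimate the multiplicity of fused dot blobs from
#'   their area relative to the median blob (default TRUE; needs >= 3
#'   blobs in the image).
#' @param image_id Identifier carried into the result.
#' @return A one-row data frame (`pla_result`): `image_id`, `n_nuclei`,
#'   `dots_nuclear`, `dots_cytoplasmic`, `dots_unassigned`,
#'   `dots_total`, `dots_per_nucleus`, `flagged` (TRUE when no nuclei
#'   were found).
#' @export
pla_count <- function(nuclei_image, dot_image, dilate_iterations = 30,
                      classifier = baseline_classifier(),
                      dot_classifier = baseline_classifier(sigma = 0.5),
                      min_nucleus_area = 20, dot_area = c(1, 80),
                      prob_threshold = NULL, split_merged = TRUE,
                      image_id = 1L) {
  if (!all(dim(nuclei_image) == dim(dot_image)))
    stop("nuclei and dot images must be co-registered (same size)",
         call. = FALSE)
  nuc_mask <- filter_objects(
    threshold_prob_map(classifier(nuclei_image), prob_threshold),
    min_area = min_nucleus_area)
  n_nuclei <- label_objects(nuc_mask)$n

  dot_mask <- filter_objects(
    threshold_prob_map(dot_classifier(dot_image), prob_threshold),
    min_area = dot_area[1], max_area = dot_area[2])
  dots <- label_objects(dot_mask)

  ring <- dilate_mask(nuc_mask, dilate_iterations) & !nuc_mask

  n_in <- 0L; n_ring <- 0L; n_out <- 0L
  n_total <- 0L
  if (dots$n > 0) {
    rc <- cbind(pmin(pmax(round(dots$centroids[, "row"]), 1),
                     nrow(nuc_mask)),
                pmin(pmax(round(dots$centroids[, "col"]), 1),
                     ncol(nuc_mask)))
    # touching dots fuse into one blob; split multiplicity by area
    # relative to the median (single-dot) blob size
    areas <- tabulate(dots$labels[dots$labels > 0], nbins = dots$n)
    mult <- if (split_merged && dots$n >= 3)
      pmax(1L, as.integer(round(areas / stats::median(areas))))
    else rep(1L, dots$n)
    in_nuc <- nuc_mask[rc]
    in_ring <- ring[rc]
    n_in <- sum(mult[in_nuc])
    n_ring <- sum(mult[!in_nuc & in_ring])
    n_total <- sum(mult)
    n_out <- n_total - n_in - n_ring
  }
  data.frame(image_id = image_id, n_nuclei = n_nuclei,
             dots_nuclear = n_in, dots_cytoplasmic = n_ring,
             dots_unassigned = n_out, dots_total = n_total,
             dots_per_nucleus = if (n_nuclei > 0) n_in / n_nuclei
                                else NA_real_,
             flagged = n_nuclei == 0)
}

#' Binary dilation by repeated 3x3 passes
#'
#' `iterations` passes of an 8-connected 3x3 square structuring element
#' (equivalently a single dilation with a square brush of width
#' `2 * iterations + 1`).
#'
#' @param mask Logical matrix.
#' @param iterations Number of dilation passes (0 returns the mask).
#' @return Dilated logical matrix.
#' @export
dilate_mask <- function(mask, iterations) {
  if (iterations <= 0) return(mask)
  k <- matrix(1, 2 * iterations + 1, 2 * iterations + 1)
  as.matrix(EBImage::imageData(
    EBImage::dilate(EBImage::Image(mask * 1), k))) > 0
}

#' Quantify nuclear positivity on immunohistochemistry tiles
#'
#' For each tile: compute the tissue fraction from its tissue mask,
#' exclude tiles below the cutoff, run the classifier on the stain
#' channel, threshold the probability map, count positive nuclei
#' (connected components in a size window) and normalize the count to
#' the tissue area of the tile.
#'
#' @param tiles List of tiles; each a list with `image` (stain-channel
#'   matrix) and `tissue` (logical tissue mask of the same size),
#'   optionally `id`.
#' @param classifier Pixel classifier.
#' @param tissue_fraction_cutoff Minimum tissue fraction (default 0.5)
#'   for a tile to be quantified.
#' @param prob_threshold Probability cutoff for positivity (default
#'   0.5; a fixed cutoff is used because tiles with few or no positive
#'   nuclei have no bimodal histogram for Otsu to split). `NULL`
#'   switches to Otsu per tile.
#' @param pixel_size_um Physical pixel size of the tiles, um/px
#'   (required: density is per tissue-mm^2).
#' @param nucleus_area Allowed positive-nucleus size range, px.
#' @return Data frame with one row per tile: `tile_id`,
#'   `tissue_fraction`, `excluded`, `positive_nuclei`, `density`
#'   (positive nuclei per tissue-mm^2; `NA` for excluded tiles).
#' @export
ihc_quantify <- function(tiles,
                         classifier = baseline_classifier(sigma = 1,
                                                          rescale = FALSE),
                         tissue_fraction_cutoff = 0.5,
                         prob_threshold = 0.5, pixel_size_um = NULL,
                         nucleus_area = c(5, 500)) {
  if (is.null(pixel_size_um) || !is.numeric(pixel_size_um) ||
      pixel_size_um <= 0)
    stop("pixel_size_um is required: tile density is per tissue-mm^2",
         call. = FALSE)
  rows <- lapply(seq_along(tiles), function(i) {
    tile <- tiles[[i]]
    id <- if (!is.null(tile$id)) tile$id else i
    tf <- mean(tile$tissue)
    tile_mm2 <- prod(dim(tile$image)) * (pixel_size_um / 1000)^2
    if (tf < tissue_fraction_cutoff) {
      return(data.frame(tile_id = id, tissue_fraction = tf,
                        excluded = TRUE, positive_nuclei = NA_integer_,
                        density = NA_real_))
    }
    pmap <- classifier(tile$image)
    pos <- filter_objects(threshold_prob_map(pmap, prob_threshold),
                          min_area = nucleus_area[1],
                          max_area = nucleus_area[2])
    n <- label_objects(pos & tile$tissue)$n
    data.frame(tile_id = id, tissue_fraction = tf, excluded = FALSE,
               positive_nuclei = n, density = n / (tf * tile_mm2))
  })
  do.call(rbind, rows)
}

#' Variance-of-Laplacian focus score
#'
#' Optional prescreen for out-of-focus or artifactual images: the
#' variance of the 4-neighbour Laplacian of the (max-normalized) image.
#' Sharp images score high; a caller-chosen threshold excludes blurry
#' fields.
#'
#' @param image Intensity matrix.
#' @return Scalar focus score.
#' @export
focus_score <- function(image) {
  img <- normalize_to_max(as.matrix(image))
  nr <- nrow(img); nc <- ncol(img)
  up <- img[c(1, seq_len(nr - 1)), ]
  dn <- img[c(seq(2, nr), nr), ]
  lf <- img[, c(1, seq_len(nc - 1))]
  rt <- img[, c(seq(2, nc), nc)]
  stats::var(as.vector(up + dn + lf + rt - 4 * img))
}
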