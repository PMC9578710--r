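# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification of a synthetic confocal scene
#'
#' Defaults emulate the live-cell acquisition geometry (512 x 512 px
#' FOV at 1.24 um/px covering about 0.4 mm^2) at a reduced grid for
#' desk-scale runs; the physical pixel size is preserved.
#'
#' @param grid Scene edge length in pixels.
#' @param pixel_size Physical pixel size, um/px.
#' @param n_cells Number of cells to place.
#' @param cell_radius Range (um) of cell semi-axes.
#' @param nucleus_radius Range (um) of nucleus semi-axes; must be below
#'   `cell_radius`.
#' @param gain Photon gain applied before Poisson sampling.
#' @param read_noise_sd Gaussian read noise (in field units).
#' @param background Constant background (field units).
#' @param poisson Apply Poisson shot noise?
#' @param seed Integer seed; identical specs with identical seeds give
#'   identical scenes.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(grid = 256, pixel_size = 1.24, n_cells = 8,
                       cell_radius = c(12, 18), nucleus_radius = c(5, 8),
                       gain = 1000, read_noise_sd = 0.005,
                       background = 0.01, poisson = TRUE, seed = 1) {
  if (max(nucleus_radius) >= min(cell_radius))
    stop("nucleus radius range must lie below the cell radius range",
         call. = FALSE)
  if (gain < 0 || background < 0 || read_noise_sd < 0)
    stop("gain, background and read noise must be >= 0", call. = FALSE)
  structure(list(grid = grid, pixel_size = pixel_size, n_cells = n_cells,
                 cell_radius = cell_radius,
                 nucleus_radius = nucleus_radius, gain = gain,
                 read_noise_sd = read_noise_sd, background = background,
                 poisson = poisson, seed = seed),
            class = "scene_spec")
}

#' Generate a cell geometry from a scene specification
#'
#' Places `n_cells` non-overlapping elliptical cells fully inside the
#' field of view, each with a concentric (slightly offset) elliptical
#' nucleus kept at least two pixels away from the cell boundary, so
#' that no nucleus pixel ever touches exterior. Placement uses bounded
#' rejection sampling and is deterministic given the spec seed.
#'
#' @param spec A [scene_spec()].
#' @param max_tries Rejection-sampling budget per cell.
#' @return A [compartment_geometry()] with attribute `truth`: list with
#'   `cell_labels` and `nucleus_labels` (instance-label matrices),
#'   `n_cells` and per-cell `centers`.
#' @export
synth_geometry <- function(spec, max_tries = 200) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    n <- spec$grid
    px <- spec$pixel_size
    xy <- expand.grid(row = seq_len(n), col = seq_len(n))
    X <- matrix(xy$row, n, n)
    Y <- matrix(xy$col, n, n)
    cell_lab <- matrix(0L, n, n)
    nuc_lab <- matrix(0L, n, n)
    centers <- matrix(NA_real_, spec$n_cells, 2)
    placed <- list()
    for (k in seq_len(spec$n_cells)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        a <- stats::runif(1, spec$cell_radius[1], spec$cell_radius[2]) / px
        b <- stats::runif(1, spec$cell_radius[1], spec$cell_radius[2]) / px
        th <- stats::runif(1, 0, pi)
        rmax <- max(a, b)
        if (2 * rmax + 4 >= n) next
        cx <- stats::runif(1, rmax + 2, n - rmax - 2)
        cy <- stats::runif(1, rmax + 2, n - rmax - 2)
        clash <- FALSE
        for (p in placed) {
          if (sqrt((cx - p$cx)^2 + (cy - p$cy)^2) < rmax + p$rmax + 2) {
            clash <- TRUE; break
          }
        }
        if (clash) next
        an <- stats::runif(1, spec$nucleus_radius[1],
                           spec$nucleus_radius[2]) / px
        bn <- stats::runif(1, spec$nucleus_radius[1],
                           spec$nucleus_radius[2]) / px
        # nucleus must stay >= 2 px inside the cell ellipse
        slack <- min(a, b) - max(an, bn) - 2
        if (slack < 0) next
        off <- stats::runif(1, 0, 0.5 * slack)
        ang <- stats::runif(1, 0, 2 * pi)
        ncx <- cx + off * cos(ang)
        ncy <- cy + off * sin(ang)
        dx <- X - cx; dy <- Y - cy
        u <- dx * cos(th) + dy * sin(th)
        v <- -dx * sin(th) + dy * cos(th)
        in_cell <- (u / a)^2 + (v / b)^2 <= 1
        dxn <- X - ncx; dyn <- Y - ncy
        un <- dxn * cos(th) + dyn * sin(th)
        vn <- -dxn * sin(th) + dyn * cos(th)
        in_nuc <- (un / an)^2 + (vn / bn)^2 <= 1
        cell_lab[in_cell] <- k
        nuc_lab[in_nuc & in_cell] <- k
        centers[k, ] <- c(cx, cy)
        placed[[k]] <- list(cx = cx, cy = cy, rmax = rmax)
        ok <- TRUE
        break
      }
      if (!ok)
        stop("infeasible packing: could not place cell ", k, " after ",
             max_tries, " tries", call. = FALSE)
    }
    labels <- matrix(0L, n, n)
    labels[cell_lab > 0L] <- 1L
    labels[nuc_lab > 0L] <- 2L
    g <- compartment_geometry(labels, pixel_size = px)
    attr(g, "truth") <- list(cell_labels = cell_lab,
                             nucleus_labels = nuc_lab,
                             n_cells = spec$n_cells, centers = centers)
    g
  })
}

#' Render a noisy multi-channel fluorescence scene
#'
#' Builds the imaging channels from concentration fields: the nuclear
#' marker channel is uniform inside nuclei, the effector channel is the
#' total-fluorescence observable (U + P per pixel, both phospho-forms
#' carry the tag). Each channel is scaled by the gain, Poisson-sampled
#' (optionally), and perturbed by Gaussian read noise on top of a
#' constant background.
#'
#' @param field Effector intensity matrix, or a `simulation_result`
#'   (its total fluorescence is used).
#' @param geometry The scene's [compartment_geometry()].
#' @param spec A [scene_spec()] providing gain/noise/background.
#' @param seed Seed for the noise draws (default: the spec seed).
#' @return List with `channels` (list of matrices `h2b`, `effector`)
#'   and `truth` (noiseless compartment means and their NCR).
#' @export
render_fluorescence <- function(field, geometry, spec,
                                seed = spec$seed) {
  stopifnot(inherits(spec, "scene_spec"),
            inherits(geometry, "compartment_geometry"))
  if (inherits(field, "simulation_result")) field <- total_fluorescence(field)
  if (!all(dim(field) == dim(geometry$labels)))
    stop("field dimensions do not match the geometry", call. = FALSE)
  lab <- geometry$labels
  h2b <- matrix(0, nrow(lab), ncol(lab))
  h2b[lab == 2L] <- 1
  render1 <- function(f) {
    signal <- spec$gain * (f + spec$background)
    out <- if (spec$poisson) {
      matrix(stats::rpois(length(signal), signal), nrow(signal))
    } else signal
    if (spec$read_noise_sd > 0)
      out <- out + stats::rnorm(length(out), 0,
                                spec$read_noise_sd * spec$gain)
    pmax(out, 0)
  }
  channels <- with_seed(seed, list(h2b = render1(h2b),
                                   effector = render1(field)))
  truth <- list(
    mean_nuclear = mean(field[lab == 2L]),
    mean_cytoplasmic = mean(field[lab == 1L]),
    ncr = mean(field[lab == 2L]) / mean(field[lab == 1L])
  )
  list(channels = channels, truth = truth)
}

#' Synthetic proximity-ligation scene
#'
#' Circular nuclei with Poisson-placed diffraction-limited dots inside
#' the nuclei and inside the pseudo-cytoplasm ring (the
#' `dilate_iterations`-pass dilation of the nuclear mask minus the
#' nuclei). Ground truth records the exact placed counts per
#' compartment.
#'
#' @param n_nuclei Number of nuclei.
#' @param lambda_nuclear,lambda_cyto Expected dots per nucleus placed in
#'   the nucleus / in its ring.
#' @param grid Scene edge, px.
#' @param nucleus_radius_px Range of nucleus radii, px.
#' @param dilate_iterations Ring width in dilation passes (default 30).
#' @param dot_radius_px Rendered dot radius, px.
#' @param noise_sd Gaussian background noise sd.
#' @param seed Integer seed.
#' @return List with `nuclei_image`, `dot_image`, and `truth`
#'   (`dots_nuclear`, `dots_cytoplasmic`, `n_nuclei`, `nuc_mask`).
#' @export
synth_pla_scene <- function(n_nuclei = 6, lambda_nuclear = 8,
                            lambda_cyto = 4, grid = 400,
                            nucleus_radius_px = c(16, 22),
                            dilate_iterations = 30, dot_radius_px = 2,
                            noise_sd = 0.02, seed = 1) {
  if (lambda_nuclear < 0 || lambda_cyto < 0)
    stop("dot rates must be >= 0", call. = FALSE)
  with_seed(seed, {
    n <- grid
    X <- matrix(seq_len(n), n, n)
    Y <- matrix(seq_len(n), n, n, byrow = TRUE)
    nuc_mask <- matrix(FALSE, n, n)
    centers <- matrix(NA_real_, n_nuclei, 3)
    margin <- max(nucleus_radius_px) + dilate_iterations + 3
    for (k in seq_len(n_nuclei)) {
      for (try in 1:200) {
        r <- stats::runif(1, nucleus_radius_px[1], nucleus_radius_px[2])
        cx <- stats::runif(1, margin, n - margin)
        cy <- stats::runif(1, margin, n - margin)
        if (k > 1) {
          d <- sqrt((cx - centers[seq_len(k - 1), 1])^2 +
                    (cy - centers[seq_len(k - 1), 2])^2)
          if (any(d < 2 * (max(nucleus_radius_px) + dilate_iterations) + 4))
            next
        }
        centers[k, ] <- c(cx, cy, r)
        nuc_mask <- nuc_mask | ((X - cx)^2 + (Y - cy)^2 <= r^2)
        break
      }
      if (anyNA(centers[k, ]))
        stop("could not place nucleus ", k, "; reduce n_nuclei or ring",
             call. = FALSE)
    }
    ring <- dilate_mask(nuc_mask, dilate_iterations) & !nuc_mask

    place_dots <- function(region_mask, lambda_total) {
      n_dots <- stats::rpois(1, lambda_total)
      if (n_dots == 0) return(matrix(numeric(0), 0, 2))
      idx <- which(region_mask)
      pick <- sample(idx, n_dots, replace = TRUE)
      cbind(row = ((pick - 1) %% n) + 1, col = ((pick - 1) %/% n) + 1)
    }
    dots_nuc <- place_dots(nuc_mask, lambda_nuclear * n_nuclei)
    dots_cyt <- place_dots(ring, lambda_cyto * n_nuclei)

    dot_image <- matrix(0, n, n)
    stamp <- function(img, pts) {
      for (i in seq_len(nrow(pts))) {
        rr <- pts[i, 1]; cc <- pts[i, 2]
        w <- ceiling(dot_radius_px)
        ri <- max(1, rr - w):min(n, rr + w)
        ci <- max(1, cc - w):min(n, cc + w)
        d2 <- outer((ri - rr)^2, (ci - cc)^2, "+")
        img[ri, ci] <- pmax(img[ri, ci], (d2 <= dot_radius_px^2) * 1)
      }
      img
    }
    dot_image <- stamp(dot_image, dots_nuc)
    dot_image <- stamp(dot_image, dots_cyt)
    dot_image <- pmax(dot_image +
                        stats::rnorm(n * n, 0, noise_sd), 0)
    nuclei_image <- pmax(nuc_mask * 0.8 +
                           stats::rnorm(n * n, 0, noise_sd), 0)
    list(nuclei_image = nuclei_image, dot_image = dot_image,
         truth = list(dots_nuclear = nrow(dots_nuc),
                      dots_cytoplasmic = nrow(dots_cyt),
                      n_nuclei = n_nuclei, nuc_mask = nuc_mask))
  })
}

#' Synthetic immunohistochemistry tiles
#'
#' Each tile contains a smooth random tissue blob occupying a target
#' fraction of the tile, brown-like positive nuclei placed at a given
#' density inside the tissue, and background noise. Defaults follow the
#' tile contract of 1 mm^2 per tile (200 x 200 px at 5 um/px here).
#'
#' @param n_tiles Number of tiles.
#' @param densities Per-tile positive-nuclei densities (per tissue-mm^2),
#'   recycled to `n_tiles`.
#' @param tissue_fractions Per-tile target tissue fractions in \[0, 1\],
#'   recycled.
#' @param tile_px Tile edge, px.
#' @param pixel_size_um Physical pixel size, um/px.
#' @param nucleus_radius_px Rendered positive-nucleus radius.
#' @param noise_sd Gaussian noise sd.
#' @param seed Integer seed.
#' @return List with `tiles` (each: `id`, `image`, `tissue`) and
#'   `truth` (data frame: `tile_id`, `tissue_fraction`,
#'   `positive_nuclei`, `density`).
#' @export
synth_ihc_tiles <- function(n_tiles = 30, densities = c(2, 10, 50),
                            tissue_fractions = c(0.6, 0.8, 1),
                            tile_px = 200, pixel_size_um = 5,
                            nucleus_radius_px = 3, noise_sd = 0.02,
                            seed = 1) {
  if (any(densities < 0)) stop("densities must be >= 0", call. = FALSE)
  densities <- rep_len(densities, n_tiles)
  tissue_fractions <- rep_len(tissue_fractions, n_tiles)
  tile_mm2 <- (tile_px * pixel_size_um / 1000)^2
  with_seed(seed, {
    tiles <- vector("list", n_tiles)
    truth <- vector("list", n_tiles)
    for (i in seq_len(n_tiles)) {
      frac <- tissue_fractions[i]
      if (frac >= 1) {
        tissue <- matrix(TRUE, tile_px, tile_px)
      } else {
        # smooth noise thresholded at the right quantile -> exact fraction
        field <- as.matrix(EBImage::gblur(
          matrix(stats::rnorm(tile_px^2), tile_px), sigma = tile_px / 8))
        tissue <- field >= stats::quantile(field, 1 - frac)
      }
      n_pos <- stats::rpois(1, densities[i] * mean(tissue) * tile_mm2)
      img <- matrix(0.02, tile_px, tile_px)
      img[tissue] <- 0.25
      if (n_pos > 0) {
        idx <- which(tissue)
        pick <- sample(idx, n_pos, replace = FALSE)
        rr <- ((pick - 1) %% tile_px) + 1
        cc <- ((pick - 1) %/% tile_px) + 1
        w <- nucleus_radius_px
        for (k in seq_len(n_pos)) {
          ri <- max(1, rr[k] - w):min(tile_px, rr[k] + w)
          ci <- max(1, cc[k] - w):min(tile_px, cc[k] + w)
          d2 <- outer((ri - rr[k])^2, (ci - cc[k])^2, "+")
          img[ri, ci][d2 <= w^2] <- 0.9
        }
      }
      img <- pmax(img + stats::rnorm(tile_px^2, 0, noise_sd), 0)
      tiles[[i]] <- list(id = i, image = img, tissue = tissue)
      truth[[i]] <- data.frame(tile_id = i, tissue_fraction = mean(tissue),
                               positive_nuclei = n_pos,
                               density = n_pos / (mean(tissue) * tile_mm2))
    }
    list(tiles = tiles, truth = do.call(rbind, truth))
  })
}

#' Synthetic expression time course with staggered signature peaks
#'
#' Emulates an in-vivo injury time course: signature genes follow a
#' log-time Gaussian activity bump centred at their signature's peak
#' time, non-signature genes are pure noise, replicates are independent
#' perturbations, and a control group sits at time 0. Values are on
#' log2 scale.
#'
#' @param signatures Named list; each element a list with `n_genes` and
#'   `peak_hr`, optionally `responsive_fraction` (genes carrying the
#'   bump; the rest are flat) and `amplitude`.
#' @param times_hr Post-treatment sampling times (hours).
#' @param replicates Animals per group.
#' @param n_control Control animals (time 0).
#' @param amplitude Default bump height (log2 units).
#' @param width Bump width in log2-time units.
#' @param noise_sd Per-sample Gaussian noise sd (log2 units).
#' @param n_noise_genes Unrelated noise genes added to the matrix.
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples, log2), `sample_times`
#'   (hours; 0 = control), `sample_sheet` (data frame: sample, time,
#'   group), `signatures` (named list of gene-id vectors) and `truth`
#'   (peak hour per signature).
#' @export
synth_expression_timecourse <- function(
    signatures = list(ROS = list(n_genes = 23, peak_hr = 9),
                      AKT = list(n_genes = 28, peak_hr = 18),
                      YAP = list(n_genes = 23, peak_hr = 36)),
    times_hr = c(6, 12, 24, 48, 96, 192, 384),
    replicates = 4, n_control = 4, amplitude = 2, width = 1,
    noise_sd = 0.3, n_noise_genes = 100, seed = 1) {
  stopifnot(all(vapply(signatures, function(s)
    s$peak_hr >= min(times_hr) && s$peak_hr <= max(times_hr), logical(1))))
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  with_seed(seed, {
    sample_times <- c(rep(0, n_control),
                      rep(times_hr, each = replicates))
    samples <- paste0("s", seq_along(sample_times), "_t", sample_times)
    gene_sets <- list()
    rows <- list()
    for (nm in names(signatures)) {
      sg <- signatures[[nm]]
      amp <- if (!is.null(sg$amplitude)) sg$amplitude else amplitude
      rf <- if (!is.null(sg$responsive_fraction)) sg$responsive_fraction
            else 1
      ids <- sprintf("%s_%02d", nm, seq_len(sg$n_genes))
      gene_sets[[nm]] <- ids
      n_resp <- round(rf * sg$n_genes)
      for (gi in seq_len(sg$n_genes)) {
        a <- if (gi <= n_resp) amp else 0
        mu <- ifelse(sample_times > 0,
                     a * exp(-(log2(sample_times / sg$peak_hr))^2 /
                               (2 * width^2)),
                     0)
        rows[[ids[gi]]] <- mu + stats::rnorm(length(mu), 0, noise_sd)
      }
    }
    for (gi in seq_len(n_noise_genes)) {
      rows[[sprintf("NOISE_%03d", gi)]] <-
        stats::rnorm(length(sample_times), 0, noise_sd)
    }
    mat <- do.call(rbind, rows)
    colnames(mat) <- samples
    sheet <- data.frame(sample = samples, time = sample_times,
                        group = ifelse(sample_times == 0, "control",
                                       "treated"))
    list(matrix = mat, sample_times = sample_times, sample_sheet = sheet,
         signatures = gene_sets,
         truth = lapply(signatures, function(s) s$peak_hr))
  })
}

#' Synthetic per-FOV NCR records with density-dependent shuttling
#'
#' Emulates the density dependence of nuclear localization: the nuclear
#' phosphorylation/dephosphorylation ratio increases with local cell
#' count through a logistic map, the well-mixed steady state of the
#' alternative topology converts that ratio into an NCR, and
#' multiplicative log-normal noise models FOV-to-FOV variability. This
#' is a fixture device for testing density stratification, not a
#' mechanistic claim.
#'
#' @param n_fov Number of fields of view.
#' @param count_range Range of cells per FOV.
#' @param r_range Ratio range spanned by the logistic coupling.
#' @param noise_sd Log-normal sd of the NCR noise.
#' @param base_params `shuttle_params` used for the well-mixed map.
#' @param seed Integer seed.
#' @param channel Channel label for the records.
#' @return Data frame of NCR records (`fov_id`, `channel`,
#'   `cell_count`, `ncr`).
#' @export
synth_ncr_records <- function(n_fov = 100, count_range = c(20, 300),
                              r_range = c(0.1, 0.9), noise_sd = 0.1,
                              base_params = shuttle_params(),
                              seed = 1, channel = "YAP") {
  net <- shuttle_topology("alternative")
  vols <- list(V_cyt = 1000, V_nuc = 200)
  with_seed(seed, {
    counts <- round(stats::runif(n_fov, count_range[1], count_range[2]))
    mid <- mean(count_range)
    scale <- diff(count_range) / 8
    r <- r_range[1] + diff(r_range) / (1 + exp(-(counts - mid) / scale))
    ncr <- vapply(r, function(ri) {
      wellmixed_steady_state(net, set_phospho_ratio(base_params, ri),
                             vols, membrane_area = 50)$ncr
    }, numeric(1))
    ncr <- ncr * exp(stats::rnorm(n_fov, 0, noise_sd))
    data.frame(fov_id = seq_len(n_fov), channel = channel,
               cell_count = counts, ncr = ncr)
  })
}
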