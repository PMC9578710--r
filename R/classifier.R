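#' Pixel classifiers for foreground/background segmentation
#'
#' The published pipelines rely on interactively trained pixel
#' classifiers; here the classifier is a pluggable contract: any
#' `function(image)` returning a per-pixel foreground probability in
#' \[0, 1\] with the image's dimensions.
#'
#' `baseline_classifier()` is the deterministic default: Gaussian
#' smoothing of the channel followed by rescaling to \[0, 1\], so that a
#' subsequent Otsu threshold separates foreground from background.
#'
#' `rf_classifier()` is an optional trainable backend: a random forest
#' on standard pixel features (intensity, Gaussian blurs at several
#' scales, local gradient magnitude) fitted from labelled pixels.
#'
#' @param sigma Gaussian smoothing radius in pixels.
#' @param rescale Min-max rescale the smoothed image to \[0, 1\]
#'   (default)? With `rescale = FALSE` the smoothed intensities are
#'   clamped to \[0, 1\] instead, which keeps the probability scale
#'   absolute -- appropriate when images share a calibrated intensity
#'   range and some may contain no foreground at all.
#' @return A classifier function.
#' @examples
#' cls <- baseline_classifier(sigma = 2)
#' p <- cls(matrix(runif(64), 8))
#' range(p)
#' @export
baseline_classifier <- function(sigma = 2, rescale = TRUE) {
  force(sigma); force(rescale)
  function(image) {
    img <- as.matrix(image)
    sm <- if (sigma > 0) as.matrix(EBImage::gblur(img, sigma = sigma))
          else img
    if (!rescale) return(pmin(pmax(sm, 0), 1))
    rng <- range(sm)
    if (diff(rng) == 0) return(matrix(0, nrow(sm), ncol(sm)))
    (sm - rng[1]) / diff(rng)
  }
}

#' @rdname baseline_classifier
#' @param train_images List of training images (matrices).
#' @param train_labels List of logical matrices (TRUE = foreground)
#'   matching `train_images`.
#' @param sigmas Feature blur scales in pixels.
#' @param ntree Forest size.
#' @param max_pixels Training pixels subsampled per image.
#' @export
rf_classifier <- function(train_images, train_labels, sigmas = c(1, 2, 4),
                          ntree = 50, max_pixels = 5000) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("rf_classifier requires the randomForest package", call. = FALSE)
  feats <- function(img) {
    f <- list(intensity = as.vector(img))
    for (s in sigmas)
      f[[paste0("blur", s)]] <- as.vector(as.matrix(
        EBImage::gblur(img, sigma = s)))
    gx <- img - img[c(1, seq_len(nrow(img) - 1)), ]
    gy <- img - img[, c(1, seq_len(ncol(img) - 1))]
    f$grad <- as.vector(sqrt(gx^2 + gy^2))
    as.data.frame(f)
  }
  xs <- list(); ys <- list()
  for (i in seq_along(train_images)) {
    fx <- feats(as.matrix(train_images[[i]]))
    fy <- factor(as.vector(train_labels[[i]]), levels = c(FALSE, TRUE))
    if (nrow(fx) > max_pixels) {
      keep <- seq(1, nrow(fx), length.out = max_pixels)
      fx <- fx[keep, ]; fy <- fy[keep]
    }
    xs[[i]] <- fx; ys[[i]] <- fy
  }
  fit <- randomForest::randomForest(do.call(rbind, xs), unlist(ys),
                                    ntree = ntree)
  function(image) {
    img <- as.matrix(image)
    p <- predict(fit, feats(img), type = "prob")[, "TRUE"]
    matrix(p, nrow(img), ncol(img))
  }
}

#' Threshold a probability map into a binary mask
#'
#' Otsu's method on the probability map by default, or a fixed cutoff.
#'
#' @param pmap Probability matrix in \[0, 1\].
#' @param threshold Fixed cutoff; `NULL` uses Otsu.
#' @return Logical matrix.
#' @export
threshold_prob_map <- function(pmap, threshold = NULL) {
  pmap <- as.matrix(pmap)
  if (any(pmap < 0 | pmap > 1))
    stop("probability map must lie in [0, 1]", call. = FALSE)
  if (is.null(threshold)) {
    if (diff(range(pmap)) == 0) return(matrix(FALSE, nrow(pmap), ncol(pmap)))
    threshold <- EBImage::otsu(EBImage::Image(pmap), range = c(0, 1))
  }
  pmap > threshold
}

# drop connected components below min_area / above max_area pixels
filter_objects <- function(mask, min_area = 0, max_area = Inf) {
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  m <- as.matrix(EBImage::imageData(lab))
  if (max(m) == 0) return(mask & FALSE)
  sizes <- tabulate(m[m > 0])
  bad <- which(sizes < min_area | sizes > max_area)
  out <- m > 0
  if (length(bad)) out[m %in% bad] <- FALSE
  out
}

# label objects, return list(labels = integer matrix, n, centroids)
label_objects <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  m <- as.matrix(EBImage::imageData(lab))
  n <- max(m)
  cent <- NULL
  if (n > 0) {
    idx <- which(m > 0, arr.ind = TRUE)
    lv <- m[m > 0]
    cent <- cbind(row = as.numeric(tapply(idx[, 1], lv, mean)),
                  col = as.numeric(tapply(idx[, 2], lv, mean)))
  }
  list(labels = m, n = n, centroids = cent)
}
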