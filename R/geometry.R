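#' Pixel geometry of a cell: exterior / cytoplasm / nucleus
#'
#' Wraps a per-pixel label map (0 = exterior, 1 = cytoplasm, 2 = nucleus)
#' on a regular grid with a physical pixel size, and derives the
#' membrane face lists: every 4-adjacent (cytoplasm, nucleus) pixel pair
#' is a nuclear-membrane face, every (cytoplasm, exterior) pair a
#' plasma-membrane face. The nucleus must be wrapped in cytoplasm: a
#' nucleus pixel 4-adjacent to exterior is rejected.
#'
#' @param labels Integer matrix with values in \{0, 1, 2\}.
#' @param pixel_size Pixel edge length in um (> 0).
#' @return An object of class `compartment_geometry` with elements
#'   `labels`, `pixel_size`, `nuclear_faces` and `plasma_faces` (4-column
#'   matrices: row/col of the cytoplasm pixel, row/col of the other
#'   pixel), plus derived `areas` (per-compartment physical area, um^2)
#'   and `membrane_length` (nuclear membrane length, um).
#' @examples
#' lab <- matrix(0L, 32, 32)
#' lab[8:25, 8:25] <- 1L
#' lab[14:19, 14:19] <- 2L
#' g <- compartment_geometry(lab, pixel_size = 1.24)
#' g$areas
#' @export
compartment_geometry <- function(labels, pixel_size) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2))
    stop("labels must be 0 (exterior), 1 (cytoplasm) or 2 (nucleus)",
         call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a positive scalar (um/px)", call. = FALSE)
  if (!any(labels == 1L) || !any(labels == 2L))
    stop("geometry must contain at least one cytoplasm and one nucleus pixel",
         call. = FALSE)

  faces <- adjacent_pairs(labels)
  if (nrow(faces$nuc_ext) > 0)
    stop("invalid geometry: nucleus pixel touches exterior", call. = FALSE)

  structure(list(
    labels = labels,
    pixel_size = pixel_size,
    nuclear_faces = faces$cyt_nuc,
    plasma_faces = faces$cyt_ext,
    areas = c(cytoplasm = sum(labels == 1L) * pixel_size^2,
              nucleus = sum(labels == 2L) * pixel_size^2),
    membrane_length = nrow(faces$cyt_nuc) * pixel_size
  ), class = "compartment_geometry")
}

# all 4-adjacent cross-compartment pixel pairs, classified by label pair
adjacent_pairs <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- list()
  # vertical neighbours (i, j) - (i + 1, j)
  a <- labels[-nr, , drop = FALSE]; b <- labels[-1, , drop = FALSE]
  idx <- which(a != b, arr.ind = TRUE)
  if (nrow(idx)) {
    pairs[[1]] <- cbind(idx[, 1], idx[, 2], idx[, 1] + 1L, idx[, 2],
                        a[idx], b[idx])
  }
  # horizontal neighbours (i, j) - (i, j + 1)
  a <- labels[, -nc, drop = FALSE]; b <- labels[, -1, drop = FALSE]
  idx <- which(a != b, arr.ind = TRUE)
  if (nrow(idx)) {
    pairs[[2]] <- cbind(idx[, 1], idx[, 2], idx[, 1], idx[, 2] + 1L,
                        a[idx], b[idx])
  }
  m <- do.call(rbind, pairs)
  if (is.null(m)) m <- matrix(integer(0), 0, 6)
  sel <- function(la, lb) {
    keep <- (m[, 5] == la & m[, 6] == lb)
    swap <- (m[, 5] == lb & m[, 6] == la)
    out <- rbind(m[keep, c(1, 2, 3, 4), drop = FALSE],
                 m[swap, c(3, 4, 1, 2), drop = FALSE])
    colnames(out) <- c("row_a", "col_a", "row_b", "col_b")
    out
  }
  list(cyt_nuc = sel(1L, 2L), cyt_ext = sel(1L, 0L), nuc_ext = sel(2L, 0L))
}

#' @export
print.compartment_geometry <- function(x, ...) {
  cat("Compartment geometry ", nrow(x$labels), "x", ncol(x$labels),
      " px at ", x$pixel_size, " um/px\n", sep = "")
  cat("  cytoplasm ", sum(x$labels == 1L), " px (",
      format(x$areas["cytoplasm"], digits = 4), " um^2), nucleus ",
      sum(x$labels == 2L), " px (", format(x$areas["nucleus"], digits = 4),
      " um^2)\n", sep = "")
  cat("  nuclear membrane: ", nrow(x$nuclear_faces), " faces (",
      format(x$membrane_length, digits = 4), " um)\n", sep = "")
  invisible(x)
}

#' Read / write a geometry as a label image plus YAML sidecar
#'
#' The label map is stored as a single-channel image (PNG or TIFF) with
#' pixel values 0, 1, 2 and the pixel size in a `.yaml` sidecar next to
#' it.
#'
#' @param geometry A `compartment_geometry`.
#' @param path Image file path (`.png` or `.tif`/`.tiff`).
#' @return `read_geometry` returns a `compartment_geometry`.
#' @export
write_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "compartment_geometry"))
  img <- geometry$labels / 2  # PNG/TIFF writers expect [0, 1]
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  } else stop("unsupported geometry image format: ", ext, call. = FALSE)
  yaml::write_yaml(list(pixel_size = geometry$pixel_size),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
         else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else stop("unsupported geometry image format: ", ext, call. = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  compartment_geometry(matrix(as.integer(round(img * 2)), nrow(img)),
                       pixel_size = side$pixel_size)
}
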