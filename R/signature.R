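#' Per-gene z-score normalization of an expression matrix
#'
#' Each gene (row) is centred and scaled across all samples using the
#' n-1 standard deviation. Genes with zero variance are set to all-zero
#' z-scores and flagged.
#'
#' @param mat Numeric matrix, genes x samples, with unique rownames.
#' @return Matrix of z-scores with attribute `flagged_genes` (character
#'   vector of zero-variance genes).
#' @examples
#' z <- zscore_matrix(rbind(g1 = c(1, 3), g2 = c(5, 5)))
#' z["g1", ]
#' attr(z, "flagged_genes")
#' @export
zscore_matrix <- function(mat) {
  if (!is.matrix(mat) || is.null(rownames(mat)) ||
      anyDuplicated(rownames(mat)))
    stop("mat must be a matrix with unique gene rownames", call. = FALSE)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, stats::sd)
  flagged <- rownames(mat)[sdv == 0 | !is.finite(sdv)]
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf  # zero-variance rows -> z = 0
  z <- (mat - mu) / sdv
  attr(z, "flagged_genes") <- flagged
  z
}

#' Fold-change pre-filter for signature genes
#'
#' Keeps the signature genes whose maximal absolute fold change versus
#' the control-sample mean, across all non-control samples, exceeds
#' `fc_threshold`. Used to trim large signatures to their responsive
#' members before scoring.
#'
#' @param mat Expression matrix (genes x samples).
#' @param signature_genes Character vector of signature gene ids.
#' @param control_samples Column names (or indices) of the control
#'   group; must be non-empty.
#' @param fc_threshold Fold-change cutoff (default 2, i.e. genes must
#'   move more than 2-fold in either direction).
#' @param log2_scale Is `mat` on log2 scale (default TRUE)? On log2
#'   scale the fold change is `2^(x - mean(control))`; on linear scale
#'   `x / mean(control)`.
#' @return Character vector of retained genes. Signature genes absent
#'   from the matrix are dropped with a warning.
#' @export
fc_filter <- function(mat, signature_genes, control_samples,
                      fc_threshold = 2, log2_scale = TRUE) {
  if (length(control_samples) == 0)
    stop("control_samples must be non-empty", call. = FALSE)
  missing <- setdiff(signature_genes, rownames(mat))
  if (length(missing))
    warning("signature genes absent from matrix, dropped: ",
            paste(missing, collapse = ", "))
  genes <- intersect(signature_genes, rownames(mat))
  if (!length(genes)) return(character(0))
  ctrl_idx <- if (is.character(control_samples))
    match(control_samples, colnames(mat)) else control_samples
  if (anyNA(ctrl_idx)) stop("unknown control samples", call. = FALSE)
  other <- setdiff(seq_len(ncol(mat)), ctrl_idx)
  keep <- vapply(genes, function(g) {
    ctrl <- mean(mat[g, ctrl_idx])
    fc <- if (log2_scale) 2^(mat[g, other] - ctrl)
          else mat[g, other] / ctrl
    max(pmax(fc, 1 / fc)) > fc_threshold
  }, logical(1))
  genes[keep]
}

#' Temporal expression index of a gene signature
#'
#' Per time point: replicate z-scores are averaged into one value per
#' gene, values greater than `z_threshold` (strictly) are summed, and
#' the sum is normalized by the number of signature genes. The index
#' tracks how strongly and when a signature is switched on.
#'
#' @param z Z-score matrix from [zscore_matrix()] (genes x samples).
#' @param signature_genes Character vector of signature gene ids.
#' @param sample_times Numeric vector of length `ncol(z)`: the time
#'   point of each sample (replicates share a value).
#' @param z_threshold Strict inclusion threshold on the z-score
#'   (default 0.5).
#' @param average `"before"` (default): average replicates per
#'   (gene, time) before thresholding; `"after"`: threshold each
#'   replicate, then average.
#' @param name Signature name carried into the result.
#' @return Object of class `signature_index`: list with `name`,
#'   `times`, `index` (one value per unique time, in time order) and
#'   `n_signature_genes` (genes used for normalization).
#' @examples
#' z <- rbind(gA = c(-1, 1), gB = c(1, -1))
#' colnames(z) <- c("t1", "t2")
#' expression_index(z, c("gA", "gB"), sample_times = c(6, 12))$index
#' @export
expression_index <- function(z, signature_genes, sample_times,
                             z_threshold = 0.5,
                             average = c("before", "after"),
                             name = "signature") {
  average <- match.arg(average)
  if (length(sample_times) != ncol(z))
    stop("sample_times must have one entry per column of z", call. = FALSE)
  genes <- intersect(signature_genes, rownames(z))
  if (!length(genes))
    stop("no signature genes found in matrix; missing: ",
         paste(signature_genes, collapse = ", "), call. = FALSE)
  dropped <- setdiff(signature_genes, genes)
  if (length(dropped))
    warning("signature genes absent from matrix, dropped: ",
            paste(dropped, collapse = ", "))
  times <- sort(unique(sample_times))
  n_sig <- length(genes)
  idx <- vapply(times, function(t) {
    cols <- which(sample_times == t)
    if (average == "before") {
      zt <- rowMeans(z[genes, cols, drop = FALSE])
      sum(zt[zt > z_threshold]) / n_sig
    } else {
      mean(vapply(cols, function(cc) {
        zc <- z[genes, cc]
        sum(zc[zc > z_threshold]) / n_sig
      }, numeric(1)))
    }
  }, numeric(1))
  structure(list(name = name, times = times, index = idx,
                 n_signature_genes = n_sig),
            class = "signature_index")
}

#' @export
print.signature_index <- function(x, ...) {
  cat("Expression index for signature \"", x$name, "\" (",
      x$n_signature_genes, " genes)\n", sep = "")
  print(stats::setNames(round(x$index, 4), x$times))
  invisible(x)
}

#' @export
plot.signature_index <- function(x, ...) {
  graphics::plot(x$times, x$index, type = "b", xlab = "time",
                 ylab = "expression index", main = x$name, ...)
  invisible(x)
}

#' Time of maximal signature activity
#'
#' Arg-max of the index over time points; ties are broken towards the
#' earliest time and flagged.
#'
#' @param series A `signature_index`, or a numeric vector of index
#'   values with `times` supplied.
#' @param times Time points (needed when `series` is a bare vector).
#' @return The peak time, with attribute `tie` (logical).
#' @examples
#' s <- structure(list(times = c(6, 12, 24), index = c(0, 1, 0.5),
#'                     name = "x", n_signature_genes = 2),
#'                class = "signature_index")
#' peak_time(s)
#' @export
peak_time <- function(series, times = NULL) {
  if (inherits(series, "signature_index")) {
    times <- series$times
    vals <- series$index
  } else {
    vals <- series
    if (is.null(times) || length(times) != length(vals))
      stop("supply times matching the index values", call. = FALSE)
  }
  if (diff(range(vals)) == 0)
    stop("no peak: the index series is constant", call. = FALSE)
  mx <- max(vals)
  at <- which(vals >= mx - 1e-12)
  out <- times[at[1]]
  attr(out, "tie") <- length(at) > 1
  out
}

#' Read a signature gene list from a text file (one gene per line)
#'
#' @param path File path; lines starting with `#` and blank lines are
#'   ignored.
#' @return Character vector of gene identifiers.
#' @export
read_signature <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
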