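# Preprocessing: containers, Gaussian smoothing, min-max normalization.

MODALITIES <- c("flair", "t1", "t1c", "t2")

#' Bundle four co-registered modality volumes
#'
#' A `modality_stack` holds the four MR sequences of one subject (Flair, T1,
#' T1c, T2) on a single voxel grid.
#'
#' @param flair,t1,t1c,t2 Numeric 3D arrays of one common shape.
#' @param subject_id Subject identifier string.
#' @return An object of class `modality_stack`.
#' @export
modality_stack <- function(flair, t1, t1c, t2, subject_id = "subject") {
  vols <- list(flair = flair, t1 = t1, t1c = t1c, t2 = t2)
  shapes <- lapply(vols, dim)
  for (m in MODALITIES) {
    if (length(shapes[[m]]) != 3L)
      stop("modality '", m, "' is not a 3D array")
    if (!identical(shapes[[m]], shapes$flair))
      stop("shape mismatch across modalities: flair is ",
           paste(shapes$flair, collapse = "x"), " but ", m, " is ",
           paste(shapes[[m]], collapse = "x"))
    if (!all(is.finite(vols[[m]])))
      stop("modality '", m, "' contains non-finite values")
  }
  structure(list(volumes = vols, shape = dim(flair),
                 subject_id = subject_id),
            class = "modality_stack")
}

#' @export
print.modality_stack <- function(x, ...) {
  cat("<modality_stack> subject:", x$subject_id,
      " shape:", paste(x$shape, collapse = "x"), "\n")
  for (m in MODALITIES) {
    v <- x$volumes[[m]]
    cat(sprintf("  %-5s range [%.4g, %.4g]\n", m, min(v), max(v)))
  }
  invisible(x)
}

#' Validate an integer label volume (classes 0-4)
#'
#' Tissue classes follow the BraTS convention: 0 normal tissue, 1 necrotic
#' core, 2 edema, 3 non-enhancing core, 4 enhancing core.
#'
#' @param labels Integer-valued 3D array.
#' @param shape Optional companion stack shape to check against.
#' @return `labels` as an integer array of class `label_volume`.
#' @export
label_volume <- function(labels, shape = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  vals <- unique(as.integer(labels))
  bad <- setdiff(vals, 0:4)
  if (length(bad))
    stop("unexpected label class(es) ", paste(sort(bad), collapse = ", "),
         "; expected labels in {0,1,2,3,4}")
  if (!is.null(shape) && !identical(dim(labels), as.integer(shape)))
    stop("label volume shape ", paste(dim(labels), collapse = "x"),
         " does not match stack shape ", paste(shape, collapse = "x"))
  out <- array(as.integer(labels), dim = dim(labels))
  class(out) <- c("label_volume", class(out))
  out
}

.reflect_idx <- function(i, n) {
  # symmetric (edge-repeating) reflection of out-of-range indices
  i <- ifelse(i < 1L, 1L - i, i)
  ifelse(i > n, 2L * n + 1L - i, i)
}

.shift_reflect <- function(vol, off, axis) {
  n <- dim(vol)[axis]
  idx <- .reflect_idx(seq_len(n) + off, n)
  switch(axis, vol[idx, , , drop = FALSE], vol[, idx, , drop = FALSE],
         vol[, , idx, drop = FALSE])
}

.sep_filter <- function(vol, kernel, axis) {
  k <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim = dim(vol))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * .shift_reflect(vol, j - k - 1L, axis)
  out
}

#' Gaussian smoothing of a 3D volume
#'
#' Separable Gaussian filter with a discrete kernel truncated at 3 sigma and
#' renormalized to unit sum; volume borders use reflect padding so total
#' intensity is preserved away from edges. `sigma = 0` is the identity.
#'
#' @param volume Numeric 3D array.
#' @param sigma Standard deviation in voxels, >= 0.
#' @return Smoothed array of the same shape.
#' @export
gaussian_smooth <- function(volume, sigma = 0.5) {
  if (length(dim(volume)) != 3L) stop("volume must be a 3D array")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  k <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(seq(-k, k), sd = sigma)
  kern <- kern / sum(kern)
  out <- volume
  for (axis in 1:3) out <- .sep_filter(out, kern, axis)
  out
}

#' Min-max normalization to [0, 1]
#'
#' Maps intensities linearly so that the volume minimum becomes 0 and the
#' maximum becomes 1: X* = (X - X_min) / (X_max - X_min).
#'
#' @param volume Numeric 3D array with at least two distinct values.
#' @param mask Optional logical array; when given, X_min/X_max are computed
#'   over `mask` voxels only (e.g. brain-only statistics).
#' @return Normalized array (clipped to \[0, 1\] when a mask is used).
#' @export
minmax_normalize <- function(volume, mask = NULL) {
  vals <- if (is.null(mask)) volume else volume[mask]
  lo <- min(vals); hi <- max(vals)
  if (!is.finite(lo) || !is.finite(hi))
    stop("volume contains non-finite values")
  if (hi <= lo)
    stop("degenerate input: constant volume (X_max = X_min), cannot normalize")
  out <- (volume - lo) / (hi - lo)
  if (!is.null(mask)) out <- pmin(pmax(out, 0), 1)
  array(out, dim = dim(volume))
}

#' Smooth and normalize all modalities of a stack
#'
#' Applies, in order, Gaussian smoothing then min-max normalization to each
#' modality volume.
#'
#' @param stack A [modality_stack()].
#' @param sigma Gaussian sigma in voxels (default 0.5).
#' @param brain_only If TRUE, normalization statistics use only voxels with
#'   nonzero raw intensity (the brain mask proxy); default FALSE uses the
#'   whole volume.
#' @return A preprocessed `modality_stack` with all values in \[0, 1\].
#' @export
preprocess_stack <- function(stack, sigma = 0.5, brain_only = FALSE) {
  stopifnot(inherits(stack, "modality_stack"))
  vols <- lapply(stack$volumes, function(v) {
    mask <- if (brain_only) v != 0 else NULL
    minmax_normalize(gaussian_smooth(v, sigma), mask = mask)
  })
  out <- stack
  out$volumes <- vols
  out$preprocessed <- TRUE
  out
}
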