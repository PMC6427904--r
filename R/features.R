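# Assembly of the 62-column per-voxel feature table.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults.
#'
#' @param sigma Gaussian smoothing sigma in voxels.
#' @param brain_only Use brain-only (nonzero) normalization statistics.
#' @param boundary Central-difference boundary rule ("onesided" or "zero").
#' @param ray Ray geometry, a [ray_config()].
#' @param percentiles Histogram-bound percentiles for ray normalization.
#' @param cs_angles,cs_radii Geometry of the original context-sensitive set.
#' @param n_trees Random-forest tree count.
#' @param f_list Dimension-sweep feature counts (default 62 - 5n, n = 0..12).
#' @return A list of class `gx_config`.
#' @export
gx_config <- function(sigma = 0.5, brain_only = FALSE, boundary = "onesided",
                      ray = ray_config(), percentiles = c(0.01, 0.99),
                      cs_angles = c(0, pi / 2, pi, 2 * pi / 3),
                      cs_radii = c(10, 20), n_trees = 100L,
                      f_list = 62L - 5L * (0:12)) {
  structure(list(sigma = sigma, brain_only = brain_only, boundary = boundary,
                 ray = ray, percentiles = percentiles, cs_angles = cs_angles,
                 cs_radii = cs_radii, n_trees = as.integer(n_trees),
                 f_list = as.integer(f_list)),
            class = "gx_config")
}

.voxel_grid <- function(shape) {
  as.matrix(expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                        z = seq_len(shape[3])))
}

#' Extract the 62 registry features at chosen voxels
#'
#' The stack is smoothed and normalized first (unless `preprocessed = TRUE`),
#' gradient-group features are computed as full volumes and sampled at the
#' voxels, and context-sensitive/CCS ray features are computed per voxel.
#'
#' @param stack A [modality_stack()].
#' @param voxels Integer n x 3 matrix of 1-based voxel indices, or NULL for
#'   every voxel.
#' @param config A [gx_config()].
#' @param preprocessed Set TRUE when `stack` is already smoothed+normalized.
#' @return Numeric n x 62 matrix, columns in registry order.
#' @export
extract_features <- function(stack, voxels = NULL, config = gx_config(),
                             preprocessed = FALSE) {
  stopifnot(inherits(stack, "modality_stack"))
  if (!preprocessed)
    stack <- preprocess_stack(stack, config$sigma, config$brain_only)
  if (is.null(voxels)) voxels <- .voxel_grid(stack$shape)
  voxels <- matrix(as.integer(voxels), ncol = 3L)
  maps <- gradient_feature_maps(stack, config$boundary)
  flat <- (voxels[, 1] - 1L) + dim(stack$volumes$flair)[1] *
    ((voxels[, 2] - 1L) + dim(stack$volumes$flair)[2] * (voxels[, 3] - 1L)) + 1L
  grad <- vapply(maps, function(m) m[flat], numeric(nrow(voxels)))
  if (nrow(voxels) == 1L) grad <- matrix(grad, nrow = 1L,
                                         dimnames = list(NULL, names(maps)))
  bounds <- lapply(stack$volumes[CS_MODALITIES], histogram_bounds,
                   percentiles = config$percentiles)
  cs <- original_cs_features(stack, voxels, bounds = bounds,
                             angles = config$cs_angles,
                             radii = config$cs_radii)
  ccs <- ccs_features(stack, voxels, config = config$ray, bounds = bounds)
  out <- cbind(grad, cs, ccs)
  reg <- feature_names()
  missing <- setdiff(reg, colnames(out))
  if (length(missing))
    stop("internal error: features missing from extraction: ",
         paste(missing, collapse = ", "))
  out[, reg, drop = FALSE]
}

#' Build a labeled per-voxel feature table
#'
#' @param stack A [modality_stack()].
#' @param labels A [label_volume()] aligned with the stack.
#' @param voxels Integer n x 3 voxel index matrix (NULL = all voxels).
#' @param config A [gx_config()].
#' @param preprocessed Set TRUE when `stack` is already preprocessed.
#' @return A data.frame: subject_id, x, y, z, the 62 features, `label`.
#' @export
feature_table <- function(stack, labels, voxels = NULL, config = gx_config(),
                          preprocessed = FALSE) {
  if (is.null(voxels)) voxels <- .voxel_grid(stack$shape)
  voxels <- matrix(as.integer(voxels), ncol = 3L)
  feats <- extract_features(stack, voxels, config, preprocessed)
  lab <- labels[voxels]
  out <- data.frame(subject_id = stack$subject_id, x = voxels[, 1],
                    y = voxels[, 2], z = voxels[, 3], check.names = FALSE)
  out <- cbind(out, as.data.frame(feats, check.names = FALSE))
  out$label <- as.integer(lab)
  out
}

.table_features <- function(table) {
  as.matrix(table[, feature_names(), drop = FALSE])
}
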