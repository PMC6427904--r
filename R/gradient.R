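# Gradient-based features: central differences, 3D gradient magnitude (GM),
# in-plane 2D gradient magnitudes, cube-neighborhood mean/variance of GM per
# modality (rMean/rVar) and pooled across modalities (seqMean/seqVar).

.AXIS_IDX <- c(x = 1L, y = 2L, z = 3L)

#' Central-difference derivative along one axis
#'
#' Interior voxels use (I(p+1) - I(p-1)) / 2; boundary voxels use one-sided
#' (forward/backward) differences by default so the map is defined
#' volume-wide, or zero with `boundary = "zero"`.
#'
#' @param volume Numeric 3D array; the chosen axis must have length >= 3.
#' @param axis "x", "y" or "z" (array dimensions 1, 2, 3).
#' @param boundary "onesided" (default) or "zero".
#' @return Array of the same shape.
#' @export
central_difference <- function(volume, axis = c("x", "y", "z"),
                               boundary = c("onesided", "zero")) {
  axis <- match.arg(axis)
  boundary <- match.arg(boundary)
  a <- .AXIS_IDX[[axis]]
  n <- dim(volume)[a]
  if (n < 3L) stop("axis ", axis, " has length ", n, "; need >= 3")
  slab <- function(idx) switch(a, volume[idx, , , drop = FALSE],
                               volume[, idx, , drop = FALSE],
                               volume[, , idx, drop = FALSE])
  fwd <- slab(c(2:n, n))     # I(p+1), clamped
  bwd <- slab(c(1L, 1:(n - 1L)))
  out <- (fwd - bwd) / 2
  assign_slab <- function(out, idx, val) {
    switch(a,
           { out[idx, , ] <- val; out },
           { out[, idx, ] <- val; out },
           { out[, , idx] <- val; out })
  }
  if (boundary == "onesided") {
    # clamped fwd/bwd above give half the one-sided difference at the ends
    out <- assign_slab(out, 1L, 2 * .slab3(out, a, 1L))
    out <- assign_slab(out, n, 2 * .slab3(out, a, n))
  } else {
    out <- assign_slab(out, 1L, 0)
    out <- assign_slab(out, n, 0)
  }
  out
}

.slab3 <- function(vol, a, idx) {
  switch(a, vol[idx, , , drop = FALSE], vol[, idx, , drop = FALSE],
         vol[, , idx, drop = FALSE])
}

#' 3D gradient magnitude
#'
#' sqrt(Gx^2 + Gy^2 + Gz^2) with central-difference directional gradients.
#'
#' @inheritParams central_difference
#' @return Array of the same shape (the GM feature map).
#' @export
gradient_magnitude_3d <- function(volume, boundary = "onesided") {
  gx <- central_difference(volume, "x", boundary)
  gy <- central_difference(volume, "y", boundary)
  gz <- central_difference(volume, "z", boundary)
  sqrt(gx^2 + gy^2 + gz^2)
}

#' Gradient2D feature maps (12)
#'
#' For each modality and each coordinate plane (xy, xz, yz), the in-plane 2D
#' gradient magnitude sqrt(d1^2 + d2^2) of the two plane-axis central
#' differences.
#'
#' @param stack A preprocessed [modality_stack()].
#' @param boundary Boundary rule passed to [central_difference()].
#' @return Named list of 12 arrays, registry-ordered.
#' @export
gradient2d_features <- function(stack, boundary = "onesided") {
  stopifnot(inherits(stack, "modality_stack"))
  planes <- list(xy = c("x", "y"), xz = c("x", "z"), yz = c("y", "z"))
  out <- list()
  for (m in MODALITIES) {
    v <- stack$volumes[[m]]
    d <- list(x = central_difference(v, "x", boundary),
              y = central_difference(v, "y", boundary),
              z = central_difference(v, "z", boundary))
    for (pl in names(planes)) {
      ax <- planes[[pl]]
      out[[paste0("g2d_", m, "_", pl)]] <- sqrt(d[[ax[1]]]^2 + d[[ax[2]]]^2)
    }
  }
  out
}

.box_mean <- function(vol, size) {
  k <- (size - 1L) %/% 2L
  out <- vol
  for (axis in 1:3) {
    acc <- array(0, dim = dim(vol))
    for (off in -k:k) acc <- acc + .shift_reflect(out, off, axis)
    out <- acc / size
  }
  out
}

#' Cube-neighborhood mean and variance of a feature map
#'
#' Per-voxel mean and population variance over the size^3 cube centered at
#' each voxel (reflect padding at borders).
#'
#' @param map Numeric 3D array (typically a GM map).
#' @param size Cube edge length, one of 3, 5, 7.
#' @return List with elements `mean` and `var` (arrays of the same shape).
#' @export
cube_stats <- function(map, size) {
  if (!(length(size) == 1L && size %in% CUBE_SIZES))
    stop("cube size must be one of ", paste(CUBE_SIZES, collapse = ", "))
  m1 <- .box_mean(map, size)
  m2 <- .box_mean(map^2, size)
  list(mean = m1, var = pmax(m2 - m1^2, 0))
}

#' Sequence-pooled cube statistics (seqMean / seqVar)
#'
#' Mean and population variance pooled over the 4 x size^3 values of the cube
#' neighborhood taken across all four modalities' GM maps.
#'
#' @param gm_maps Named list of the four GM arrays (flair, t1, t1c, t2).
#' @param size Cube edge length, one of 3, 5, 7.
#' @return List with elements `mean` and `var`.
#' @export
seq_stats <- function(gm_maps, size) {
  stopifnot(length(gm_maps) == 4L)
  shp <- dim(gm_maps[[1]])
  for (g in gm_maps)
    if (!identical(dim(g), shp)) stop("GM map shape mismatch")
  m1 <- Reduce(`+`, lapply(gm_maps, .box_mean, size = size)) / 4
  m2 <- Reduce(`+`, lapply(gm_maps, function(g) .box_mean(g^2, size))) / 4
  list(mean = m1, var = pmax(m2 - m1^2, 0))
}

#' All 46 gradient-group feature maps (Gradient2D + Gradient3D)
#'
#' @param stack A preprocessed [modality_stack()].
#' @param boundary Boundary rule for central differences.
#' @return Named list of 46 arrays in registry order.
#' @export
gradient_feature_maps <- function(stack, boundary = "onesided") {
  out <- gradient2d_features(stack, boundary)
  gm <- lapply(stack$volumes, gradient_magnitude_3d, boundary = boundary)
  for (m in MODALITIES) out[[paste0("GM_", m)]] <- gm[[m]]
  stats <- list()
  for (m in MODALITIES)
    for (s in CUBE_SIZES) stats[[paste0(m, "_", s)]] <- cube_stats(gm[[m]], s)
  for (m in MODALITIES)
    for (s in CUBE_SIZES)
      out[[paste0("rMean_", m, "_", s)]] <- stats[[paste0(m, "_", s)]]$mean
  for (m in MODALITIES)
    for (s in CUBE_SIZES)
      out[[paste0("rVar_", m, "_", s)]] <- stats[[paste0(m, "_", s)]]$var
  sq <- lapply(CUBE_SIZES, function(s) seq_stats(gm, s))
  names(sq) <- CUBE_SIZES
  for (s in CUBE_SIZES) out[[paste0("seqMean_", s)]] <- sq[[as.character(s)]]$mean
  for (s in CUBE_SIZES) out[[paste0("seqVar_", s)]] <- sq[[as.character(s)]]$var
  out
}
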