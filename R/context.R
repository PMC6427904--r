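# Context-sensitive ray features from T1 and Flair axial slices.
#
# Every voxel sends out in-plane rays; each ray's mean intensity is
# normalized by robust histogram bounds (H_min, H_max) of the modality and
# clipped to [0, 1]. The original context-sensitive set uses 4 fixed angles
# at radii {10, 20}; the circular (CCS) set sweeps n_beta directions over a
# ladder of radii pooled into 6 radius bands.

#' Ray geometry configuration
#'
#' Angles are `beta0 + n * 2*pi/n_beta` for `n = 0..n_beta-1`; radii are
#' `r0 + n * r_step` for `n = 1..n_r`. When `r_step` is NULL it defaults to
#' `(r_max - r_min) / n_r`. The package default (`r0 = 8`, `r_step = 2`,
#' `n_r = 6`) yields 8 rays on the 6 even-integer circles 10..20.
#'
#' @param beta0 Initial angle, radians.
#' @param n_beta Number of ray directions (>= 1).
#' @param r0 Initial radius (voxels); the first generated radius is
#'   `r0 + r_step`.
#' @param r_min,r_max Radius range delimiting the band structure.
#' @param n_r Number of radii.
#' @param r_step Radius increment; NULL means `(r_max - r_min) / n_r`.
#' @param n_bands Number of equal-width radius bands over \[r_min, r_max\].
#' @return An object of class `ray_config`.
#' @export
ray_config <- function(beta0 = 0, n_beta = 8L, r0 = 8, r_min = 10, r_max = 20,
                       n_r = 6L, r_step = 2, n_bands = 6L) {
  if (n_beta < 1L) stop("n_beta must be >= 1")
  if (n_r < 1L) stop("n_r must be >= 1")
  if (!(r_max > r_min && r_min >= 0)) stop("need r_max > r_min >= 0")
  if (is.null(r_step)) r_step <- (r_max - r_min) / n_r
  structure(list(beta0 = beta0, n_beta = as.integer(n_beta),
                 beta_step = 2 * pi / n_beta, r0 = r0, r_min = r_min,
                 r_max = r_max, n_r = as.integer(n_r), r_step = r_step,
                 n_bands = as.integer(n_bands)),
            class = "ray_config")
}

#' Enumerate the (angle, radius) ray set of a configuration
#'
#' @param config A [ray_config()].
#' @return A data.frame with columns `angle` (wrapped to \[0, 2*pi)) and
#'   `radius`, radius-major order, `n_beta * n_r` rows.
#' @export
generate_rays <- function(config) {
  stopifnot(inherits(config, "ray_config"))
  angles <- (config$beta0 + (seq_len(config$n_beta) - 1L) * config$beta_step) %% (2 * pi)
  radii <- config$r0 + seq_len(config$n_r) * config$r_step
  data.frame(angle = rep(angles, times = config$n_r),
             radius = rep(radii, each = config$n_beta))
}

#' Robust histogram bounds of a volume
#'
#' H_min / H_max are robust intensity percentiles (default 1st / 99th) of the
#' brain voxels (nonzero intensity), used to normalize per-ray mean
#' intensities.
#'
#' @param volume Numeric 3D array (normalized modality volume).
#' @param percentiles Length-2 probabilities, default `c(0.01, 0.99)`.
#' @param n_bins Histogram bin count kept for diagnostics (does not affect
#'   the percentile bounds).
#' @return List with `h_min`, `h_max`, `percentiles`, `n_bins`.
#' @export
histogram_bounds <- function(volume, percentiles = c(0.01, 0.99),
                             n_bins = 64L) {
  vals <- volume[volume != 0]
  if (length(vals) == 0L) vals <- as.vector(volume)
  if (length(unique(vals)) < 2L)
    stop("degenerate input: volume has fewer than 2 distinct brain values")
  q <- unname(quantile(vals, probs = percentiles, names = FALSE))
  if (q[2] <= q[1]) {                      # heavy ties: fall back to range
    q <- range(vals)
  }
  list(h_min = q[1], h_max = q[2], percentiles = percentiles,
       n_bins = as.integer(n_bins))
}

#' Normalized mean intensity along one in-plane ray
#'
#' Samples the axial slice of `volume` at unit steps `t = 1..floor(radius)`
#' along direction `angle` from `center` (nearest-voxel sampling,
#' out-of-bounds samples dropped; a fully out-of-bounds ray returns the
#' background value 0), then normalizes the mean as
#' `(m - h_min)/(h_max - h_min)` clipped to \[0, 1\].
#'
#' @param volume Numeric 3D array.
#' @param center Integer voxel index `c(x, y, z)` (1-based).
#' @param angle Ray direction, radians, in the axial (x, y) plane.
#' @param radius Ray length in voxels.
#' @param bounds A [histogram_bounds()] result.
#' @return Scalar in \[0, 1\].
#' @export
ray_mean <- function(volume, center, angle, radius, bounds) {
  .ray_mean_cpp(as.double(volume), as.integer(dim(volume)),
                as.integer(center), angle, radius,
                bounds$h_min, bounds$h_max)
}

.radius_band <- function(radii, r_min, r_max, n_bands) {
  # equal-width bands over [r_min, r_max]; radii at r_min fall in band 1
  b <- ceiling((radii - r_min) / (r_max - r_min) * n_bands)
  pmin(pmax(as.integer(b), 1L), as.integer(n_bands))
}

.ray_features_at <- function(volume, voxels, angles, radii, bands, n_bands,
                             bounds) {
  .ray_band_features_cpp(as.double(volume), as.integer(dim(volume)),
                         voxels, as.double(angles), as.double(radii),
                         as.integer(bands), as.integer(n_bands),
                         bounds$h_min, bounds$h_max)
}

#' Circular context-sensitive (CCS) features
#'
#' For each of T1 and Flair, rays over all configured directions and radii
#' are pooled into `n_bands` equal-width radius bands; each feature is the
#' mean of the normalized per-ray means in its (modality, band) cell:
#' 2 x 6 = 12 features under the default configuration.
#'
#' @param stack A preprocessed [modality_stack()].
#' @param voxels Integer matrix (n x 3) of 1-based voxel indices.
#' @param config A [ray_config()].
#' @param bounds Named list of [histogram_bounds()] per modality
#'   (`flair`, `t1`); computed from the stack when NULL.
#' @return An n x 12 matrix with registry CCS column names.
#' @export
ccs_features <- function(stack, voxels, config = ray_config(), bounds = NULL) {
  stopifnot(inherits(stack, "modality_stack"), is.matrix(voxels))
  rays <- generate_rays(config)
  radii <- unique(rays$radius)
  if (length(radii) < config$n_bands)
    stop("ray configuration yields ", length(radii),
         " distinct radii; need >= ", config$n_bands, " for the radius bands")
  angles <- unique(rays$angle)
  bands <- .radius_band(radii, config$r_min, config$r_max, config$n_bands)
  if (is.null(bounds))
    bounds <- lapply(stack$volumes[CS_MODALITIES], histogram_bounds)
  voxels <- matrix(as.integer(voxels), ncol = 3L)
  out <- NULL
  for (m in CS_MODALITIES) {
    f <- .ray_features_at(stack$volumes[[m]], voxels, angles, radii, bands,
                          config$n_bands, bounds[[m]])
    colnames(f) <- paste0("ccs_", m, "_b", seq_len(config$n_bands))
    out <- cbind(out, f)
  }
  out
}

#' Original context-sensitive features
#'
#' For T1 and Flair and each radius r in {10, 20}, the mean of the
#' normalized ray means over the four fixed angles {0, pi/2, pi, 2*pi/3}:
#' 4 features.
#'
#' @inheritParams ccs_features
#' @param angles The four fixed ray angles.
#' @param radii The two ray radii.
#' @return An n x 4 matrix with registry column names.
#' @export
original_cs_features <- function(stack, voxels, bounds = NULL,
                                 angles = c(0, pi / 2, pi, 2 * pi / 3),
                                 radii = c(10, 20)) {
  stopifnot(inherits(stack, "modality_stack"), is.matrix(voxels))
  if (is.null(bounds))
    bounds <- lapply(stack$volumes[CS_MODALITIES], histogram_bounds)
  voxels <- matrix(as.integer(voxels), ncol = 3L)
  out <- NULL
  for (m in CS_MODALITIES) {
    # one band per radius: features indexed by radius, pooled over angles
    f <- .ray_features_at(stack$volumes[[m]], voxels, angles, radii,
                          seq_along(radii), length(radii), bounds[[m]])
    colnames(f) <- paste0("cs_", m, "_r", radii)
    out <- cbind(out, f)
  }
  out
}
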