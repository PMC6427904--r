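# Independent brute-force oracles and small fixtures shared by the tests.
# Every oracle is a direct loop/enumeration implementation, deliberately
# kept separate from the package's vectorized / compiled code paths.

rand_volume <- function(shape, seed) {
  set.seed(seed)
  array(runif(prod(shape)), shape)
}

# per-voxel triple-loop 3D gradient magnitude (interior voxels only)
oracle_gm_interior <- function(vol) {
  d <- dim(vol)
  out <- array(NA_real_, d)
  for (x in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (z in 2:(d[3] - 1)) {
    gx <- (vol[x + 1, y, z] - vol[x - 1, y, z]) / 2
    gy <- (vol[x, y + 1, z] - vol[x, y - 1, z]) / 2
    gz <- (vol[x, y, z + 1] - vol[x, y, z - 1]) / 2
    out[x, y, z] <- sqrt(gx^2 + gy^2 + gz^2)
  }
  out
}

# explicit cube-neighborhood mean/variance at one interior voxel
oracle_cube_stats_at <- function(map, size, vox) {
  k <- (size - 1) / 2
  vals <- c()
  for (dx in -k:k) for (dy in -k:k) for (dz in -k:k)
    vals <- c(vals, map[vox[1] + dx, vox[2] + dy, vox[3] + dz])
  c(mean = mean(vals), var = mean(vals^2) - mean(vals)^2)
}

# pooled 4 x size^3 sequence statistics at one interior voxel
oracle_seq_stats_at <- function(maps, size, vox) {
  vals <- unlist(lapply(maps, function(m) {
    k <- (size - 1) / 2
    v <- c()
    for (dx in -k:k) for (dy in -k:k) for (dz in -k:k)
      v <- c(v, m[vox[1] + dx, vox[2] + dy, vox[3] + dz])
    v
  }))
  c(mean = mean(vals), var = mean(vals^2) - mean(vals)^2)
}

# per-sample loop ray mean (same sampling convention, independent code)
oracle_ray_mean <- function(vol, center, angle, radius, hmin, hmax) {
  d <- dim(vol)
  samples <- c()
  for (t in seq_len(floor(radius + 1e-9))) {
    x <- center[1] + floor(t * cos(angle) + 0.5)
    y <- center[2] + floor(t * sin(angle) + 0.5)
    if (x >= 1 && x <= d[1] && y >= 1 && y <= d[2])
      samples <- c(samples, vol[x, y, center[3]])
  }
  if (!length(samples)) return(0)
  min(max((mean(samples) - hmin) / (hmax - hmin), 0), 1)
}

# entropy-based MI in bits: H(x) + H(y) - H(x, y)
oracle_mi <- function(x, y) {
  H <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  H(x) + H(y) - H(paste(x, y))
}

# mu +/- sigma 3-level discretization, written independently
oracle_discretize <- function(v) {
  mu <- sum(v) / length(v)
  s <- sqrt(sum((v - mu)^2) / length(v))
  vapply(v, function(a) {
    if (s > 0 && a < mu - s) 1L else if (s > 0 && a > mu + s) 3L else 2L
  }, integer(1))
}

# exhaustive per-step greedy argmax of the incremental mRMR objective
oracle_mrmr_greedy <- function(features, labels, k = ncol(features)) {
  disc <- apply(features, 2, oracle_discretize)
  p <- ncol(features)
  rel <- vapply(seq_len(p), function(j) oracle_mi(disc[, j], labels),
                numeric(1))
  sel <- integer(0)
  phis <- list()
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), sel)
    phi <- vapply(cand, function(j) {
      red <- if (!length(sel)) 0
             else mean(vapply(sel, function(s) oracle_mi(disc[, j], disc[, s]),
                              numeric(1)))
      rel[j] - red
    }, numeric(1))
    sel <- c(sel, cand[which.max(phi)])
    phis[[step]] <- stats::setNames(phi, colnames(features)[cand])
  }
  list(order = colnames(features)[sel], phis = phis)
}

# maps a 3-level code in 0:2 to values that mu +/- sigma splits cleanly
tri <- function(code) c(-3, 0, 3)[code + 1L]

# small, fast phantom for unit tests
small_phantom <- function(seed = 1L, cohort = "HGG", shape = c(24L, 24L, 24L)) {
  generate_phantom(phantom_spec(
    shape = shape, seed = seed, cohort = cohort,
    radii = list(brain = 10, edema = 6, core = 4.5, enhancing = 3.2,
                 necrosis = 2)))
}

# small cohort of prepared subjects for pipeline tests
small_cohort_subjects <- function(n = 6L, seed = 11L, hgg_fraction = 1) {
  cohort <- generate_cohort(n, seed = seed, hgg_fraction = hgg_fraction,
                            shape = c(24L, 24L, 24L),
                            radii = list(brain = 10, edema = 6, core = 4.5,
                                         enhancing = 3.2, necrosis = 2))
  lapply(cohort, function(s)
    prepare_subject(s$stack, s$labels, cohort = s$cohort))
}
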