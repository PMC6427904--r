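# context_features: ray geometry, histogram bounds, ray means, CS/CCS sets.

test_that("generate_rays follows the angle/radius ladder equations", {
  cfg <- ray_config(beta0 = 0, n_beta = 4, r0 = 10, r_min = 10, r_max = 20,
                    n_r = 5, r_step = NULL)
  rays <- generate_rays(cfg)
  expect_equal(sort(unique(rays$angle)), c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(sort(unique(rays$radius)), c(12, 14, 16, 18, 20))
  expect_identical(nrow(rays), 20L)
  cfg <- ray_config(n_beta = 8, n_r = 6)
  expect_identical(nrow(generate_rays(cfg)), 48L)
  # default geometry: 8 rays on the even circles 10..20
  expect_equal(sort(unique(generate_rays(ray_config())$radius)),
               c(10, 12, 14, 16, 18, 20))
  expect_error(ray_config(n_beta = 0), "n_beta")
  expect_error(ray_config(n_r = 0), "n_r")
  expect_error(ray_config(r_min = 5, r_max = 5), "r_max")
})

test_that("histogram_bounds returns robust percentiles of brain voxels", {
  set.seed(33)
  v <- array(runif(40^3), c(40, 40, 40))
  b <- histogram_bounds(v)
  expect_lt(abs(b$h_min - 0.01), 0.005)
  expect_lt(abs(b$h_max - 0.99), 0.005)
  two <- array(rep(c(0.2, 0.8), 500), c(10, 10, 10))
  b2 <- histogram_bounds(two)
  expect_equal(b2$h_min, 0.2, tolerance = 0.01)
  expect_equal(b2$h_max, 0.8, tolerance = 0.01)
  expect_error(histogram_bounds(array(0.5, c(5, 5, 5))), "degenerate")
})

test_that("ray_mean matches the per-sample loop oracle", {
  bounds <- list(h_min = 0, h_max = 1)
  const <- array(0.42, c(30, 30, 5))
  for (ang in c(0, 0.7, pi / 2, 2.5))
    expect_equal(ray_mean(const, c(15, 15, 3), ang, 8, bounds), 0.42)
  # ray fully outside the volume -> background 0
  expect_equal(ray_mean(const, c(30, 30, 3), pi / 4, 5, bounds), 0)
  # bright bar on dark background, plus random volumes, vs oracle
  bar <- array(0.1, c(30, 30, 3)); bar[20:22, , ] <- 0.9
  set.seed(44)
  for (i in 1:50) {
    vol <- if (i <= 25) bar else array(runif(30 * 30 * 3), c(30, 30, 3))
    ctr <- c(sample(5:26, 1), sample(5:26, 1), sample(1:3, 1))
    ang <- runif(1, 0, 2 * pi)
    rad <- runif(1, 3, 12)
    expect_equal(ray_mean(vol, ctr, ang, rad, bounds),
                 oracle_ray_mean(vol, ctr, ang, rad, 0, 1),
                 tolerance = 1e-10)
  }
})

test_that("ccs_features: count, constant case, annulus localization", {
  ph <- small_phantom(seed = 21)
  pp <- preprocess_stack(ph$stack)
  vox <- cbind(12L, 12L, 12L)
  f <- ccs_features(pp, vox)
  expect_identical(ncol(f), 12L)
  expect_identical(colnames(f), feature_names("CCS"))
  expect_true(all(f >= 0 & f <= 1))
  # constant volume -> every feature equals the constant
  const <- array(0.3, c(50, 50, 5))
  st <- modality_stack(const, const, const, const)
  fc <- ccs_features(st, cbind(25L, 25L, 3L),
                     bounds = list(flair = list(h_min = 0, h_max = 1),
                                   t1 = list(h_min = 0, h_max = 1)))
  expect_equal(unname(as.vector(fc)), rep(0.3, 12), tolerance = 1e-12)
  # bright annulus at radius ~15 lights up the mid bands only
  ann <- array(0, c(61, 61, 3))
  ix <- slice.index(ann, 1); iy <- slice.index(ann, 2)
  rr <- sqrt((ix - 31)^2 + (iy - 31)^2)
  ann[rr >= 14 & rr <= 16] <- 1
  st <- modality_stack(ann, ann, ann, ann)
  fa <- ccs_features(st, cbind(31L, 31L, 2L),
                     bounds = list(flair = list(h_min = 0, h_max = 1),
                                   t1 = list(h_min = 0, h_max = 1)))
  # rays are cumulative from the center, so bands ending before the annulus
  # see nothing and the per-sample fraction peaks at the band just past it
  bands <- fa[1, paste0("ccs_flair_b", 1:6)]
  expect_equal(unname(bands[1:2]), c(0, 0))
  expect_identical(unname(which.max(bands)), 4L)
  expect_gt(bands[4], bands[6])
  # config with too few radii for the bands errors
  expect_error(ccs_features(st, cbind(31L, 31L, 2L),
                            config = ray_config(n_r = 3, r_step = 2)),
               "radii")
})

test_that("original_cs_features: count, constant case, CCS consistency", {
  const <- array(0.55, c(50, 50, 5))
  st <- modality_stack(const, const, const, const)
  bounds01 <- list(flair = list(h_min = 0, h_max = 1),
                   t1 = list(h_min = 0, h_max = 1))
  f <- original_cs_features(st, cbind(25L, 25L, 3L), bounds = bounds01)
  expect_identical(ncol(f), 4L)
  expect_identical(colnames(f), feature_names("ContextSensitive"))
  expect_equal(unname(as.vector(f)), rep(0.55, 4), tolerance = 1e-12)
  # cross-implementation consistency: CCS run with matched single-radius,
  # 4-angle geometry reproduces the original features
  set.seed(9)
  vol <- array(runif(40 * 40 * 3), c(40, 40, 3))
  st <- modality_stack(vol, vol, vol, vol)
  vox <- cbind(c(20L, 15L), c(20L, 25L), c(2L, 2L))
  orig <- original_cs_features(st, vox, bounds = bounds01,
                               angles = c(0, pi / 2, pi, 3 * pi / 2),
                               radii = c(10, 20))
  cfg <- ray_config(beta0 = 0, n_beta = 4, r0 = 0, r_min = 9, r_max = 11,
                    n_r = 1, r_step = 10, n_bands = 1)
  ccs10 <- ccs_features(st, vox, config = cfg, bounds = bounds01)
  expect_equal(unname(ccs10[, "ccs_flair_b1"]), unname(orig[, "cs_flair_r10"]),
               tolerance = 1e-12)
  expect_equal(unname(ccs10[, "ccs_t1_b1"]), unname(orig[, "cs_t1_r10"]),
               tolerance = 1e-12)
})

test_that("CCS features are deterministic and 90-degree rotation invariant", {
  ph <- small_phantom(seed = 22)
  pp <- preprocess_stack(ph$stack)
  vox <- cbind(c(12L, 10L), c(12L, 14L), c(12L, 12L))
  f1 <- ccs_features(pp, vox)
  f2 <- ccs_features(pp, vox)
  expect_identical(f1, f2)
  # rotate the axial planes by 90 degrees; with angles on the pi/2 grid the
  # direction-pooled features are unchanged
  n <- 41L
  set.seed(10)
  vol <- array(runif(n * n * 3), c(n, n, 3))
  rot <- array(0, c(n, n, 3))
  for (z in 1:3) rot[, , z] <- t(vol[, , z])[, n:1]   # (x,y) -> (y, n+1-x)
  stA <- modality_stack(vol, vol, vol, vol)
  stB <- modality_stack(rot, rot, rot, rot)
  cfg <- ray_config(beta0 = 0, n_beta = 4, r0 = 2, r_min = 3, r_max = 15,
                    n_r = 6, r_step = 2, n_bands = 6)
  c0 <- (n + 1L) / 2L
  fA <- ccs_features(stA, cbind(c0, c0, 2L), config = cfg,
                     bounds = list(flair = list(h_min = 0, h_max = 1),
                                   t1 = list(h_min = 0, h_max = 1)))
  fB <- ccs_features(stB, cbind(c0, c0, 2L), config = cfg,
                     bounds = list(flair = list(h_min = 0, h_max = 1),
                                   t1 = list(h_min = 0, h_max = 1)))
  expect_equal(fA, fB, tolerance = 1e-6)
})
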