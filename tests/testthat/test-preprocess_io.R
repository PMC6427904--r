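# preprocess_io: volume I/O, smoothing, normalization.

test_that("NIfTI and MetaImage volumes round-trip bit-exactly", {
  vol <- rand_volume(c(7, 6, 5), seed = 42)
  for (ext in c("nii", "nii.gz", "mha")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_volume(vol, path, datatype = "float64")
    back <- read_volume(path)
    expect_identical(dim(back), dim(vol))
    expect_identical(as.vector(back), as.vector(vol), label = ext)
    unlink(path)
  }
})

test_that("integer datatypes round-trip label volumes", {
  set.seed(1)
  lab <- array(sample(0:4, 4 * 5 * 6, replace = TRUE), c(4, 5, 6))
  for (dt in c("uint8", "int16", "int32")) {
    path <- tempfile(fileext = ".nii")
    write_nifti(lab, path, datatype = dt)
    expect_identical(as.integer(read_nifti(path)), as.vector(lab))
    unlink(path)
  }
})

test_that("our NIfTI writer is readable by nibabel (independent oracle)", {
  vol <- rand_volume(c(5, 4, 3), seed = 7)
  path <- tempfile(fileext = ".nii")
  write_nifti(vol, path, datatype = "float64")
  out <- tempfile(fileext = ".txt")
  script <- sprintf(
    "import nibabel, numpy; img = nibabel.load('%s'); d = numpy.asarray(img.dataobj); open('%s','w').write(' '.join(str(x) for x in [*d.shape, float(d.sum()), float(d[2,1,0])]))",
    path, out)
  status <- system2("python", c("-c", shQuote(script)))
  expect_identical(status, 0L)
  vals <- as.numeric(strsplit(readLines(out, warn = FALSE), " ")[[1]])
  expect_identical(vals[1:3], c(5, 4, 3))
  expect_equal(vals[4], sum(vol), tolerance = 1e-12)
  expect_equal(vals[5], vol[3, 2, 1], tolerance = 1e-12)
  unlink(c(path, out))
})

test_that("load_subject loads a four-modality subject with labels", {
  ph <- small_phantom(seed = 3)
  dir <- tempfile()
  dir.create(dir)
  paths <- lapply(stats::setNames(MODALITIES <- c("flair", "t1", "t1c", "t2"),
                                  MODALITIES), function(m) {
    p <- file.path(dir, paste0(m, ".nii.gz"))
    write_nifti(ph$stack$volumes[[m]], p)
    p
  })
  lp <- file.path(dir, "labels.nii")
  write_nifti(ph$labels, lp, datatype = "int16")
  sub <- load_subject(paths, lp, subject_id = "s1")
  expect_s3_class(sub$stack, "modality_stack")
  expect_identical(sub$stack$shape, c(24L, 24L, 24L))
  expect_identical(as.vector(sub$stack$volumes$t1c),
                   as.vector(ph$stack$volumes$t1c))
  expect_identical(as.vector(sub$labels), as.vector(ph$labels))
  unlink(dir, recursive = TRUE)
})

test_that("shape mismatches and bad labels are rejected", {
  a <- array(0, c(10, 10, 10)); b <- array(0, c(10, 10, 9))
  expect_error(modality_stack(a, a, a, b), "shape mismatch")
  bad <- array(5L, c(3, 3, 3))
  expect_error(label_volume(bad), "unexpected label class")
  expect_error(label_volume(array(0L, c(3, 3, 3)), shape = c(4, 3, 3)),
               "does not match")
  dir <- tempfile(); dir.create(dir)
  p10 <- file.path(dir, "a.nii"); p9 <- file.path(dir, "b.nii")
  write_nifti(a, p10); write_nifti(b, p9)
  expect_error(load_subject(list(flair = p10, t1 = p10, t1c = p10, t2 = p9)),
               "shape mismatch")
  expect_error(load_subject(list(flair = p10, t1 = p10, t1c = p10,
                                 t2 = file.path(dir, "nope.nii"))),
               "not found")
  unlink(dir, recursive = TRUE)
})

test_that("gaussian_smooth fixes constants, identity at sigma 0, unit mass", {
  const <- array(3.7, c(8, 8, 8))
  expect_equal(gaussian_smooth(const, 1.2), const)
  v <- rand_volume(c(6, 6, 6), seed = 5)
  expect_identical(gaussian_smooth(v, 0), v)
  expect_error(gaussian_smooth(v, -1), "sigma")
  imp <- array(0, c(9, 9, 9)); imp[5, 5, 5] <- 1
  expect_equal(sum(gaussian_smooth(imp, 1)), 1, tolerance = 1e-6)
})

test_that("minmax_normalize follows the min-max formula and its properties", {
  v <- array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2))
  nv <- minmax_normalize(v)
  expect_equal(sort(unique(as.vector(nv))), c(0, 0.5, 1))
  expect_equal(range(nv), c(0, 1))
  w <- rand_volume(c(5, 5, 5), seed = 8)
  w[1] <- 0; w[2] <- 1                     # already spanning [0, 1]
  expect_equal(minmax_normalize(w), w)
  expect_error(minmax_normalize(array(1, c(3, 3, 3))), "constant")
  # idempotence and affine invariance
  x <- rand_volume(c(5, 4, 6), seed = 9)
  nx <- minmax_normalize(x)
  expect_equal(minmax_normalize(nx), nx)
  expect_equal(minmax_normalize(2.5 * x + 7), nx)
})

test_that("smoothed constant-plus-impulse normalizes to [0,1] with one peak", {
  v <- array(1, c(9, 9, 9)); v[5, 5, 5] <- 2
  out <- minmax_normalize(gaussian_smooth(v, 0.5))
  expect_true(all(out >= 0 & out <= 1))
  expect_identical(sum(out == 1), 1L)
  expect_identical(which(out == 1), which(v == 2))
})

test_that("preprocess_stack smooths then normalizes each modality to [0,1]", {
  ph <- small_phantom(seed = 12)
  pp <- preprocess_stack(ph$stack, sigma = 0.5)
  for (m in c("flair", "t1", "t1c", "t2")) {
    v <- pp$volumes[[m]]
    expect_equal(range(v), c(0, 1))
    expect_equal(v, minmax_normalize(gaussian_smooth(ph$stack$volumes[[m]], 0.5)))
  }
})

test_that("cohort manifests round-trip through the readers", {
  dir <- tempfile()
  manifest <- generate_cohort(2, seed = 5, hgg_fraction = 1,
                              shape = c(16L, 16L, 16L),
                              radii = list(brain = 6.5, edema = 4, core = 3,
                                           enhancing = 2.2, necrosis = 1.4),
                              dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  cohort <- load_cohort(file.path(dir, "manifest.json"))
  expect_length(cohort, 2)
  regen <- generate_cohort(2, seed = 5, hgg_fraction = 1,
                           shape = c(16L, 16L, 16L),
                           radii = list(brain = 6.5, edema = 4, core = 3,
                                        enhancing = 2.2, necrosis = 1.4))
  for (i in 1:2) {
    expect_identical(as.vector(cohort[[i]]$labels),
                     as.vector(regen[[i]]$labels))
    expect_identical(as.vector(cohort[[i]]$stack$volumes$flair),
                     as.vector(regen[[i]]$stack$volumes$flair))
  }
  unlink(dir, recursive = TRUE)
})
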