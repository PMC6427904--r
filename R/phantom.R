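# Multi-modal nested-ellipsoid phantoms with the 5-class tumor anatomy:
# 0 normal tissue (brain ellipsoid), 2 edema shell, 3 non-enhancing core
# shell, 4 enhancing rim, 1 necrotic center. Outside the brain the intensity
# is exactly 0 (air). LGG-like phantoms lack the enhancing class (its shell
# is absorbed into the non-enhancing core).

.DEFAULT_MEANS <- rbind(
  # class x modality mean intensities in [0, 1]; chosen so edema is
  # brightest in Flair, enhancing brightest in T1c, necrosis dark in
  # T1/T1c and bright in T2 -- the radiological contrasts the features use.
  `0` = c(flair = 0.35, t1 = 0.55, t1c = 0.50, t2 = 0.40),
  `1` = c(flair = 0.45, t1 = 0.25, t1c = 0.20, t2 = 0.80),
  `2` = c(flair = 0.85, t1 = 0.45, t1c = 0.45, t2 = 0.75),
  `3` = c(flair = 0.60, t1 = 0.35, t1c = 0.40, t2 = 0.60),
  `4` = c(flair = 0.65, t1 = 0.50, t1c = 0.90, t2 = 0.55))

#' Phantom specification
#'
#' @param shape Volume shape (default 48^3).
#' @param seed Integer seed for the noise field.
#' @param means 5 x 4 class-by-modality mean-intensity table in \[0, 1\]
#'   (rows = classes 0..4, columns flair/t1/t1c/t2).
#' @param noise_sd Additive Gaussian noise sd (default 0.05).
#' @param center Common ellipsoid center (default volume center).
#' @param radii Named list of ellipsoid radii `brain`, `edema`, `core`,
#'   `enhancing`, `necrosis` (strictly decreasing).
#' @param cohort "HGG" (all five classes) or "LGG" (no enhancing class).
#' @param subject_id Identifier string.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L), seed = 1L,
                         means = .DEFAULT_MEANS, noise_sd = 0.05,
                         center = (shape + 1) / 2,
                         radii = list(brain = 20, edema = 11, core = 8,
                                      enhancing = 5.5, necrosis = 3.5),
                         cohort = c("HGG", "LGG"),
                         subject_id = "phantom") {
  cohort <- match.arg(cohort)
  r <- unlist(radii[c("brain", "edema", "core", "enhancing", "necrosis")])
  if (any(diff(r) >= 0))
    stop("non-nested radii: need brain > edema > core > enhancing > necrosis")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(means < 0 | means > 1)) stop("mean intensities must lie in [0, 1]")
  structure(list(shape = as.integer(shape), seed = as.integer(seed),
                 means = means, noise_sd = noise_sd, center = center,
                 radii = radii, cohort = cohort, subject_id = subject_id),
            class = "phantom_spec")
}

.ellipsoid_mask <- function(shape, center, radius) {
  if (length(radius) == 1L) radius <- rep(radius, 3L)
  dx2 <- ((seq_len(shape[1]) - center[1]) / radius[1])^2
  dy2 <- ((seq_len(shape[2]) - center[2]) / radius[2])^2
  dz2 <- ((seq_len(shape[3]) - center[3]) / radius[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

#' Generate one phantom subject
#'
#' @param spec A [phantom_spec()].
#' @return List with `stack` ([modality_stack()], raw intensities in
#'   \[0, 1\]) and `labels` ([label_volume()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$shape
  brain <- .ellipsoid_mask(shp, spec$center, spec$radii$brain)
  labels <- array(0L, shp)
  labels[.ellipsoid_mask(shp, spec$center, spec$radii$edema)] <- 2L
  labels[.ellipsoid_mask(shp, spec$center, spec$radii$core)] <- 3L
  enh <- if (spec$cohort == "HGG") 4L else 3L
  labels[.ellipsoid_mask(shp, spec$center, spec$radii$enhancing)] <- enh
  labels[.ellipsoid_mask(shp, spec$center, spec$radii$necrosis)] <- 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  vols <- list()
  for (m in MODALITIES) {
    v <- array(0, shp)
    for (cl in 0:4) {
      sel <- brain & labels == cl
      n <- sum(sel)
      if (n == 0L) next
      v[sel] <- spec$means[as.character(cl), m] +
        if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0
    }
    v <- pmin(pmax(v, 0), 1)
    v[!brain] <- 0
    vols[[m]] <- array(v, shp)
  }
  list(stack = modality_stack(vols$flair, vols$t1, vols$t1c, vols$t2,
                              subject_id = spec$subject_id),
       labels = label_volume(labels, shp))
}

#' Generate a phantom cohort
#'
#' Produces `n_subjects` phantoms with per-subject geometry jitter
#' (ellipsoid centers and radii perturbed uniformly within +/-10%) and
#' distinct noise seeds. With `dir` given, volumes are written as NIfTI and
#' a manifest JSON usable by [load_cohort()] is returned (and written);
#' otherwise stacks stay in memory.
#'
#' @param n_subjects Number of phantoms (>= 1).
#' @param seed Master seed.
#' @param hgg_fraction Fraction of HGG-like subjects (the first
#'   `round(n * hgg_fraction)` subjects; the rest are LGG-like without the
#'   enhancing class).
#' @param shape Volume shape.
#' @param noise_sd Noise level.
#' @param jitter Geometry jitter fraction (default 0.1).
#' @param radii Base ellipsoid radii before jitter (see [phantom_spec()]).
#' @param dir Optional output directory for NIfTI files + manifest.
#' @return With `dir`: the manifest list (invisibly written to
#'   `manifest.json`). Without: a list of `list(stack, labels, cohort,
#'   spec)` per subject.
#' @export
generate_cohort <- function(n_subjects, seed = 1L, hgg_fraction = 0.8,
                            shape = c(48L, 48L, 48L), noise_sd = 0.05,
                            jitter = 0.1,
                            radii = list(brain = 20, edema = 11, core = 8,
                                         enhancing = 5.5, necrosis = 3.5),
                            dir = NULL) {
  stopifnot(n_subjects >= 1L)
  n_hgg <- round(n_subjects * hgg_fraction)
  base_radii <- radii
  base_center <- (shape + 1) / 2
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sseed <- seed * 1000L + i
    rng <- .seeded_rng(sseed)
    jit <- .runif_jitter(rng, 9L, jitter)
    radii <- Map(function(r, j) r * (1 + j), base_radii,
                 as.list(jit[1:5] * c(0.3, 1, 1, 1, 1)))
    # keep nesting: clamp each radius below its parent
    radii$edema <- min(radii$edema, radii$brain * 0.9)
    radii$core <- min(radii$core, radii$edema * 0.9)
    radii$enhancing <- min(radii$enhancing, radii$core * 0.9)
    radii$necrosis <- min(radii$necrosis, radii$enhancing * 0.9)
    center <- base_center + jit[6:8] * 20   # +/- 2 voxels at 10% jitter
    cohort <- if (i <= n_hgg) "HGG" else "LGG"
    spec <- phantom_spec(shape = shape, seed = sseed, noise_sd = noise_sd,
                         center = center, radii = radii, cohort = cohort,
                         subject_id = sprintf("phantom_%03d", i))
    ph <- generate_phantom(spec)
    subjects[[i]] <- list(stack = ph$stack, labels = ph$labels,
                          cohort = cohort, spec = spec)
  }
  names(subjects) <- vapply(subjects, function(s) s$stack$subject_id,
                            character(1))
  if (is.null(dir)) return(subjects)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(subjects, function(s) {
    id <- s$stack$subject_id
    paths <- lapply(stats::setNames(MODALITIES, MODALITIES), function(m) {
      p <- file.path(dir, paste0(id, "_", m, ".nii.gz"))
      write_nifti(s$stack$volumes[[m]], p, datatype = "float64")
      p
    })
    lp <- file.path(dir, paste0(id, "_labels.nii.gz"))
    write_nifti(s$labels, lp, datatype = "int16")
    list(subject_id = id, cohort = s$cohort, paths = paths, label_path = lp)
  })
  names(manifest) <- NULL
  write_manifest(manifest, file.path(dir, "manifest.json"))
  manifest
}

.runif_jitter <- function(rng, n, jitter) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$state)
  rng$state <- rng$state + 1L
  runif(n, -jitter, jitter)
}
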