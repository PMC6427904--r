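# Pipeline: ROI detection, class-balanced sampling, subject-level k-fold
# cross-validation, full-volume prediction.

#' Detect the tumor region of interest
#'
#' Plane-sweep from both ends of each axis to the first plane containing a
#' nonzero label: the minimal axis-aligned cuboid covering every labeled
#' voxel. Intervals are half-open `[lo, hi)` in 1-based voxel coordinates,
#' i.e. voxels `lo..hi-1` are inside.
#'
#' @param labels Integer label array with at least one nonzero voxel.
#' @return A list of class `roi_box` with `lo` and `hi` (length-3 integer
#'   vectors).
#' @export
detect_roi <- function(labels) {
  nz <- which(labels != 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) stop("all-zero label volume: no ROI to detect")
  lo <- apply(nz, 2L, min)
  hi <- apply(nz, 2L, max) + 1L
  structure(list(lo = as.integer(lo), hi = as.integer(hi)),
            class = "roi_box")
}

#' Voxel index matrix of an ROI box
#'
#' @param roi A `roi_box`.
#' @return Integer n x 3 matrix of 1-based voxel indices inside the box.
#' @export
roi_voxels <- function(roi) {
  as.matrix(expand.grid(x = roi$lo[1]:(roi$hi[1] - 1L),
                        y = roi$lo[2]:(roi$hi[2] - 1L),
                        z = roi$lo[3]:(roi$hi[3] - 1L)))
}

#' Logical mask of an ROI box
#'
#' @param roi A `roi_box`.
#' @param shape Volume shape.
#' @return Logical 3D array, TRUE inside the box.
#' @export
roi_mask <- function(roi, shape) {
  m <- array(FALSE, shape)
  m[roi$lo[1]:(roi$hi[1] - 1L), roi$lo[2]:(roi$hi[2] - 1L),
    roi$lo[3]:(roi$hi[3] - 1L)] <- TRUE
  m
}

#' Class-balanced voxel sampling
#'
#' Records the least-frequent class count m inside the table and samples
#' exactly m rows per class uniformly without replacement.
#'
#' @param table A [feature_table()] data.frame with a `label` column.
#' @param seed Integer RNG seed (sampling is deterministic given it).
#' @param classes Classes that must be present (default all of 0..4); a
#'   class in `classes` absent from the table is an error naming it.
#' @return The balanced subset of `table` (m rows per class).
#' @export
balanced_sample <- function(table, seed = 1L, classes = 0:4) {
  present <- sort(unique(table$label))
  missing <- setdiff(classes, present)
  if (length(missing))
    stop("class(es) absent in ROI: {", paste(missing, collapse = ", "), "}")
  counts <- table(factor(table$label, levels = classes))
  m <- min(counts)
  rng <- .seeded_rng(seed)
  idx <- unlist(lapply(classes, function(cl) {
    rows <- which(table$label == cl)
    rows[.sample_n(rng, length(rows), m)]
  }))
  table[idx, , drop = FALSE]
}

# Local deterministic RNG so sampling does not disturb the global .Random.seed.
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- as.integer(seed)
  env
}

.sample_n <- function(rng, n, size) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$state)
  rng$state <- rng$state + 1L
  sample.int(n, size)
}

#' Precompute per-subject pipeline data
#'
#' Preprocesses the stack, detects the ROI, and builds the labeled feature
#' table of every ROI voxel — the unit consumed by [cross_validate()] and
#' [dimension_sweep()].
#'
#' @param stack A [modality_stack()].
#' @param labels A [label_volume()].
#' @param config A [gx_config()].
#' @param cohort Cohort tag, "HGG" or "LGG".
#' @return A list of class `gx_subject` with `subject_id`, `cohort`, `roi`,
#'   `table` (ROI feature table), `shape`.
#' @export
prepare_subject <- function(stack, labels, config = gx_config(),
                            cohort = "HGG") {
  roi <- detect_roi(labels)
  vox <- roi_voxels(roi)
  tab <- feature_table(stack, labels, vox, config)
  structure(list(subject_id = stack$subject_id, cohort = cohort, roi = roi,
                 table = tab, shape = dim(labels)),
            class = "gx_subject")
}

.fold_assignment <- function(ids, k, seed) {
  rng <- .seeded_rng(seed)
  perm <- ids[.sample_n(rng, length(ids), length(ids))]
  # sizes differ by at most one ("roughly equal parts")
  sizes <- rep(length(ids) %/% k, k) + (seq_len(k) <= length(ids) %% k)
  fold <- rep(seq_len(k), times = sizes)[match(ids, perm)]
  names(fold) <- ids
  fold
}

.train_fold_table <- function(subjects, seed) {
  tabs <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    balanced_sample(s$table, seed = seed + i,
                    classes = sort(unique(s$table$label)))
  })
  do.call(rbind, tabs)
}

.subject_prediction <- function(model, subject, features = NULL) {
  tab <- subject$table
  X <- .table_features(tab)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  pred_lab <- predict_class(model, X)
  pred <- array(0L, subject$shape)
  pred[cbind(tab$x, tab$y, tab$z)] <- pred_lab
  truth <- array(0L, subject$shape)
  truth[cbind(tab$x, tab$y, tab$z)] <- tab$label
  evaluate_segmentation(pred, truth, domain = cbind(tab$x, tab$y, tab$z))
}

.mean_reports <- function(reports, cohorts) {
  # mean of per-subject metrics per (cohort filter, region); undefined (NA)
  # cells are skipped, so LGG enhancing stays NA when no subject defines it
  all_cohorts <- list(`HGG&LGG` = c("HGG", "LGG"), HGG = "HGG", LGG = "LGG")
  rows <- list()
  for (cn in names(all_cohorts)) {
    keep <- which(cohorts %in% all_cohorts[[cn]])
    if (!length(keep)) next
    for (rg in REGIONS) {
      vals <- vapply(reports[keep], function(rep) {
        r <- rep[rep$region == rg, ]
        c(r$dice, r$ppv, r$sensitivity, r$specificity)
      }, numeric(4))
      m <- rowMeans(matrix(vals, nrow = 4L), na.rm = TRUE)
      m[is.nan(m)] <- NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(cohort = cn, region = rg, dice = m[1], ppv = m[2],
                   sensitivity = m[3], specificity = m[4])
    }
  }
  do.call(rbind, rows)
}

#' Subject-level k-fold cross-validation
#'
#' Subjects are shuffled deterministically under `seed` and split into k
#' roughly equal folds (no subject appears in more than one test fold). For
#' each fold a forest is trained on the pooled class-balanced samples of the
#' other folds and every ROI voxel of the held-out subjects is predicted and
#' evaluated; the final outcome is the mean over subjects and folds, with
#' HGG / LGG / combined cohort filters.
#'
#' @param subjects List of [prepare_subject()] results.
#' @param k Number of folds (default 5); must not exceed the subject count.
#' @param config A [gx_config()].
#' @param features Optional feature-name subset (default all 62).
#' @param seed Master seed controlling folds, sampling and forests.
#' @return A list of class `gx_cv`: `folds` (per-fold subject ids and mean
#'   report), `per_subject` reports, `mean` (cohort x region metric table),
#'   `fold_of` (fold assignment).
#' @export
cross_validate <- function(subjects, k = 5L, config = gx_config(),
                           features = NULL, seed = 1L) {
  if (length(subjects) < k)
    stop("fewer subjects (", length(subjects), ") than folds (", k, ")")
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  names(subjects) <- ids
  fold_of <- .fold_assignment(ids, k, seed)
  reports <- vector("list", length(ids))
  names(reports) <- ids
  folds <- list()
  for (f in seq_len(k)) {
    test_ids <- ids[fold_of[ids] == f]
    train_ids <- setdiff(ids, test_ids)
    train_tab <- .train_fold_table(subjects[train_ids], seed = seed * 1000L + f)
    X <- .table_features(train_tab)
    if (!is.null(features)) X <- X[, features, drop = FALSE]
    model <- train_forest(X, train_tab$label, n_trees = config$n_trees,
                          seed = seed * 100L + f)
    for (id in test_ids)
      reports[[id]] <- .subject_prediction(model, subjects[[id]], features)
    cohorts_f <- vapply(subjects[test_ids], `[[`, character(1), "cohort")
    folds[[f]] <- list(test_ids = test_ids,
                       mean = .mean_reports(reports[test_ids], cohorts_f))
  }
  cohorts <- vapply(subjects, `[[`, character(1), "cohort")
  structure(list(folds = folds, per_subject = reports,
                 mean = .mean_reports(reports, cohorts), fold_of = fold_of),
            class = "gx_cv")
}

#' Predict a full label volume
#'
#' Applies a trained forest voxel-wise. With `roi` given, only voxels inside
#' the box are classified (the method's operating domain); everything
#' outside is labeled 0.
#'
#' @param model A `gx_forest`.
#' @param stack A [modality_stack()].
#' @param config A [gx_config()].
#' @param roi Optional `roi_box` restricting prediction.
#' @return An integer label array of the stack's shape.
#' @export
predict_volume <- function(model, stack, config = gx_config(), roi = NULL) {
  vox <- if (is.null(roi)) .voxel_grid(stack$shape) else roi_voxels(roi)
  feats <- extract_features(stack, vox, config)
  feats <- feats[, model$feature_names, drop = FALSE]
  pred <- array(0L, stack$shape)
  pred[vox] <- predict_class(model, feats)
  pred
}
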