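# Subject-level I/O: load a 4-modality stack (+ labels), subject manifests.

#' Load one subject's modality volumes and labels
#'
#' @param modality_paths Named list/vector with entries `flair`, `t1`, `t1c`,
#'   `t2`, each a `.nii`, `.nii.gz` or `.mha` path.
#' @param label_path Optional path to the integer label volume.
#' @param subject_id Subject identifier (defaults to the flair file stem).
#' @return A list with elements `stack` ([modality_stack()]) and `labels`
#'   ([label_volume()] or NULL).
#' @export
load_subject <- function(modality_paths, label_path = NULL,
                         subject_id = NULL) {
  modality_paths <- as.list(modality_paths)
  missing_mods <- setdiff(MODALITIES, names(modality_paths))
  if (length(missing_mods))
    stop("missing modality path(s): ", paste(missing_mods, collapse = ", "))
  for (p in unlist(modality_paths[MODALITIES]))
    if (!file.exists(p)) stop("file not found: ", p)
  vols <- lapply(modality_paths[MODALITIES], read_volume)
  if (is.null(subject_id))
    subject_id <- sub("\\.(nii(\\.gz)?|mha)$", "",
                      basename(modality_paths$flair))
  stack <- modality_stack(vols$flair, vols$t1, vols$t1c, vols$t2,
                          subject_id = subject_id)
  labels <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) stop("file not found: ", label_path)
    labels <- label_volume(read_volume(label_path), shape = stack$shape)
  }
  list(stack = stack, labels = labels)
}

#' Write a subject manifest
#'
#' The manifest is a JSON array of subjects mapping `subject_id` to modality
#' file paths, the label path, and a cohort tag (HGG/LGG).
#'
#' @param subjects A list of subject records (lists with `subject_id`,
#'   `paths` (named flair/t1/t1c/t2), `label_path`, `cohort`).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(subjects, path) {
  jsonlite::write_json(subjects, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a subject manifest
#'
#' @param path Manifest JSON path.
#' @return A list of subject records.
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Load every subject of a manifest
#'
#' @param manifest A manifest list (from [read_manifest()]) or a path.
#' @return A named list of `list(stack, labels, cohort)` per subject.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  out <- lapply(manifest, function(rec) {
    sub <- load_subject(rec$paths, rec$label_path, rec$subject_id)
    sub$cohort <- rec$cohort %||% "HGG"
    sub
  })
  names(out) <- vapply(manifest, function(r) r$subject_id, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
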