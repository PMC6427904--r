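# Region-composite evaluation: complete / core / enhancing tumor masks,
# confusion counts, and Dice / PPV / sensitivity / specificity.

REGIONS <- c("complete", "core", "enhancing")
.REGION_CLASSES <- list(complete = c(1L, 2L, 3L, 4L), core = c(1L, 3L, 4L),
                        enhancing = 4L)

#' Composite evaluation region masks
#'
#' complete tumor = classes \{1,2,3,4\}; tumor core = \{1,3,4\};
#' enhancing tumor = \{4\}.
#'
#' @param labels Integer label array (classes 0..4).
#' @return Named list of three logical arrays.
#' @export
region_masks <- function(labels) {
  lapply(.REGION_CLASSES, function(cls) array(labels %in% cls, dim(labels)))
}

#' Voxel-wise confusion counts
#'
#' @param pred_mask,truth_mask Logical arrays/vectors of one shape.
#' @return Named integer vector (TP, FP, FN, TN).
#' @export
confusion_counts <- function(pred_mask, truth_mask) {
  if (!identical(dim(pred_mask), dim(truth_mask)) ||
      length(pred_mask) != length(truth_mask))
    stop("mask shape mismatch")
  p <- as.logical(pred_mask)
  t <- as.logical(truth_mask)
  c(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Segmentation metrics from confusion counts
#'
#' Dice = TP / (((TP+FP) + (TP+FN)) / 2); PPV = TP / (TP+FP);
#' sensitivity = TP / (TP+FN); specificity = TN / (FP+TN). A metric whose
#' denominator is zero is reported as NA (undefined, the "-" convention),
#' not as 0.
#'
#' @param TP,FP,FN,TN Nonnegative counts (or a named vector as first arg).
#' @return Named numeric vector (dice, ppv, sensitivity, specificity).
#' @export
seg_metrics <- function(TP, FP = NULL, FN = NULL, TN = NULL) {
  if (is.null(FP)) {
    v <- TP
    TP <- v[["TP"]]; FP <- v[["FP"]]; FN <- v[["FN"]]; TN <- v[["TN"]]
  }
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(dice = safe(TP, ((TP + FP) + (TP + FN)) / 2),
    ppv = safe(TP, TP + FP),
    sensitivity = safe(TP, TP + FN),
    specificity = safe(TN, FP + TN))
}

#' Evaluate a predicted label volume against the truth
#'
#' Computes confusion counts and the four metrics for each composite region
#' over the evaluation domain (by default the subject's detected ROI;
#' `domain = NULL` evaluates the whole volume). For a truth with no
#' enhancing voxels (LGG) the enhancing row's overlap metrics are undefined
#' (NA), matching the "-" reporting convention.
#'
#' @param pred Predicted label array.
#' @param truth Ground-truth label array.
#' @param domain Optional logical array or n x 3 voxel index matrix limiting
#'   the evaluated voxels.
#' @return A data.frame of class `evaluation_report`: one row per region
#'   with TP/FP/FN/TN and the four metrics.
#' @export
evaluate_segmentation <- function(pred, truth, domain = NULL) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  sel <- if (is.null(domain)) TRUE else domain
  rows <- lapply(REGIONS, function(rg) {
    cls <- .REGION_CLASSES[[rg]]
    cc <- confusion_counts(array(pred %in% cls, dim(pred))[sel],
                           array(truth %in% cls, dim(truth))[sel])
    mt <- seg_metrics(cc)
    data.frame(region = rg, TP = cc[["TP"]], FP = cc[["FP"]], FN = cc[["FN"]],
               TN = cc[["TN"]], dice = mt[["dice"]], ppv = mt[["ppv"]],
               sensitivity = mt[["sensitivity"]],
               specificity = mt[["specificity"]])
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_report", class(out))
  out
}
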