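# mRMR feature ranking: mu +/- sigma three-level discretization, plug-in
# mutual information (bits), greedy incremental MID selection
# (relevance I(x; c) minus mean redundancy with the already-selected set).

#' Three-level discretization of a continuous column
#'
#' Splits at mu - sigma and mu + sigma (population sigma) into levels
#' low / mid / high — the convention of classic mRMR preprocessing.
#'
#' @param column Numeric vector with finite values.
#' @return Integer vector with values in \{1, 2, 3\} (1 = low); a
#'   zero-variance column collapses to a single level with a warning.
#' @export
discretize <- function(column) {
  stopifnot(all(is.finite(column)))
  mu <- mean(column)
  s <- sqrt(mean((column - mu)^2))
  if (s == 0) {
    warning("zero-variance column discretized to a single level")
    return(rep(2L, length(column)))
  }
  out <- rep(2L, length(column))
  out[column < mu - s] <- 1L
  out[column > mu + s] <- 3L
  out
}

#' Plug-in mutual information between two categorical columns
#'
#' MI in bits from the empirical joint distribution:
#' sum p(x,y) log2( p(x,y) / (p(x) p(y)) ).
#'
#' @param x,y Equal-length categorical (integer/factor) vectors.
#' @return Nonnegative scalar, bits.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) == 0L) stop("empty input")
  joint <- table(x, y) / length(x)
  px <- rowSums(joint)
  py <- colSums(joint)
  outer_p <- outer(px, py)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' Greedy mRMR feature ranking
#'
#' Step 1 selects the feature maximizing relevance I(x; c); each subsequent
#' step adds the unselected feature maximizing
#' I(x; c) - (1/|S|) * sum over selected s of I(x; s)
#' (the incremental mutual-information-difference form of the set objective
#' Phi = D - R). Ties break deterministically by column (registry) order.
#'
#' @param features Numeric matrix or data.frame of feature columns.
#' @param labels Class label vector.
#' @param k Number of features to rank (default all).
#' @return A list of class `mrmr_result`: `order` (feature names), `score`
#'   (Phi at each step), `relevance` (D term), `redundancy` (R term),
#'   `discretization` ("mu_pm_sigma_3level").
#' @export
mrmr_rank <- function(features, labels, k = NULL) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (p == 0L || nrow(features) == 0L) stop("empty feature table")
  if (is.null(k)) k <- p
  if (k < 1L) stop("k must be >= 1")
  if (k > p) stop("k exceeds feature count")
  nms <- colnames(features)
  if (is.null(nms)) nms <- paste0("f", seq_len(p))
  disc <- suppressWarnings(apply(features, 2L, discretize))
  cls <- as.integer(as.factor(labels))
  relevance <- vapply(seq_len(p), function(j)
    mutual_information(disc[, j], cls), numeric(1))
  selected <- integer(0)
  red_sum <- numeric(p)          # sum of MI(x_j, s) over selected s
  score <- rel_s <- red_s <- numeric(k)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), selected)
    red <- if (step == 1L) rep(0, p) else red_sum / length(selected)
    phi <- relevance - red
    pick <- cand[which.max(phi[cand])]
    selected <- c(selected, pick)
    score[step] <- phi[pick]
    rel_s[step] <- relevance[pick]
    red_s[step] <- red[pick]
    if (step < k) {
      rest <- setdiff(seq_len(p), selected)
      for (j in rest)
        red_sum[j] <- red_sum[j] + mutual_information(disc[, j], disc[, pick])
    }
  }
  structure(list(order = nms[selected], index = selected, score = score,
                 relevance = rel_s, redundancy = red_s,
                 discretization = "mu_pm_sigma_3level"),
            class = "mrmr_result")
}

#' @export
print.mrmr_result <- function(x, ...) {
  cat("<mrmr_result>", length(x$order), "features ranked\n")
  n <- min(10L, length(x$order))
  for (i in seq_len(n))
    cat(sprintf("  %2d. %-16s Phi = % .4f (D = %.4f, R = %.4f)\n", i,
                x$order[i], x$score[i], x$relevance[i], x$redundancy[i]))
  if (length(x$order) > n) cat("  ...\n")
  invisible(x)
}
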