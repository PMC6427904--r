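# Dimension sweep: rank the top-f mRMR feature sets (f = 62 - 5n) by
# cross-validated performance and pick the rank-sum winner.

#' The f = 62 - 5n dimension ladder
#'
#' @param n_features Total feature count (default 62).
#' @param step Decrement (default 5).
#' @return Integer vector \{62, 57, ..., 7, 2\} (clipped at >= 1).
#' @export
sweep_f_list <- function(n_features = 62L, step = 5L) {
  f <- n_features - step * (0:((n_features - 1L) %/% step))
  as.integer(f[f >= 1L])
}

#' Rank-sum model selection over a per-f metric table
#'
#' Each metric column is ranked across the f values (higher is better, best
#' = rank 1, ties share the mean rank); ranks are summed per f; the f with
#' the minimal rank sum wins, and rank-sum ties resolve to the smaller
#' feature-set size. NA metric cells (undefined, e.g. LGG enhancing) are
#' dropped column-wise.
#'
#' @param metric_table Numeric matrix/data.frame, rows = f values (rownames
#'   = f), columns = metric cells.
#' @param f_values Integer vector of f per row (default from rownames).
#' @return List: `f_m` (selected dimension), `rank_sum` (named by f),
#'   `n_cells` (metric cells actually ranked).
#' @export
rank_sum_select <- function(metric_table, f_values = NULL) {
  m <- as.matrix(metric_table)
  if (is.null(f_values)) f_values <- as.integer(rownames(m))
  stopifnot(length(f_values) == nrow(m))
  keep <- colSums(is.na(m)) == 0
  m <- m[, keep, drop = FALSE]
  ranks <- apply(m, 2L, function(col) rank(-col, ties.method = "average"))
  ranks <- matrix(ranks, nrow = nrow(m))
  rs <- rowSums(ranks)
  names(rs) <- f_values
  best <- which(rs == min(rs))
  f_m <- min(f_values[best])            # tie-break: smaller feature set
  list(f_m = f_m, rank_sum = rs, n_cells = ncol(m))
}

#' mRMR dimension sweep with cross-validated rank-sum selection
#'
#' One global mRMR ranking is computed on the pooled class-balanced training
#' sample of all subjects; for each f in `f_list` the top-f features feed a
#' k-fold cross-validation, whose mean cohort x region metrics populate the
#' rank-sum table.
#'
#' @param subjects List of [prepare_subject()] results.
#' @param config A [gx_config()] (supplies `f_list` by default).
#' @param f_list Feature-set sizes to sweep.
#' @param k Cross-validation folds.
#' @param metrics Metric columns entering the ranking (default all four).
#' @param seed Master seed.
#' @return A list of class `gx_sweep`: `ranking` (the global `mrmr_result`),
#'   `f_list`, `metric_table`, `rank_sum`, `f_m`, `cv` (per-f gx_cv).
#' @export
dimension_sweep <- function(subjects, config = gx_config(),
                            f_list = config$f_list, k = 5L,
                            metrics = c("dice", "ppv", "sensitivity",
                                        "specificity"),
                            seed = 1L) {
  n_feat <- length(feature_names())
  if (any(f_list > n_feat))
    stop("f exceeds the feature count (", n_feat, ")")
  pooled <- .train_fold_table(subjects, seed = seed)
  ranking <- mrmr_rank(.table_features(pooled), pooled$label)
  cvs <- list()
  rows <- list()
  for (f in f_list) {
    feats <- ranking$order[seq_len(f)]
    cv <- cross_validate(subjects, k = k, config = config, features = feats,
                         seed = seed)
    cvs[[as.character(f)]] <- cv
    tab <- cv$mean
    cells <- unlist(lapply(seq_len(nrow(tab)), function(i)
      stats::setNames(as.numeric(tab[i, metrics]),
                      paste(tab$cohort[i], tab$region[i], metrics, sep = "."))))
    rows[[as.character(f)]] <- cells
  }
  metric_table <- do.call(rbind, rows)
  sel <- rank_sum_select(metric_table, f_values = as.integer(f_list))
  structure(list(ranking = ranking, f_list = as.integer(f_list),
                 metric_table = metric_table, rank_sum = sel$rank_sum,
                 n_cells = sel$n_cells, f_m = sel$f_m, cv = cvs),
            class = "gx_sweep")
}

#' @export
print.gx_sweep <- function(x, ...) {
  cat("<gx_sweep> f values:", paste(x$f_list, collapse = ", "), "\n")
  cat("  ranked metric cells:", x$n_cells, "\n")
  cat("  rank sums:", paste(sprintf("%s=%g", names(x$rank_sum), x$rank_sum),
                            collapse = ", "), "\n")
  cat("  selected f_m =", x$f_m, "\n")
  invisible(x)
}
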