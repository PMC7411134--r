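#' Final evaluation: MC-CV validation curves plus external test metrics
#'
#' Validation curves (median MCC/accuracy with MAD per model size) come
#' from [mc_cv()] on the training set.  Test metrics per model size come
#' from one final model per size trained on the *full* training set:
#' stumps per scale, ranked by training MCC, evaluated on the held-out
#' test set.  Summary fields follow the usual reporting: `mcc_max` (best
#' test MCC over sizes), `mcc_vali_max` (test MCC at the size that
#' maximizes median validation MCC) and `a_vali_max` (test accuracy at
#' that size).
#'
#' @param train,test Construct `data.frame`s with `id`, `sequence`,
#'   `label` (and `strategy_id` if a modifier is used); ids must be
#'   disjoint.
#' @param table A `scale_table`.
#' @param modifier Optional [modification_vector()].
#' @param runs MC-CV runs for the validation curves (default 1000).
#' @param seed Seed for the MC-CV splits.
#' @return Object of class `evaluation_report`: list with `per_size`
#'   (data.frame) and `summary`.
#' @export
evaluate_model <- function(train, test, table, modifier = NULL,
                           runs = 1000L, seed = 1L) {
  stopifnot(is.data.frame(train), is.data.frame(test))
  if (length(intersect(train$id, test$id)) > 0L) {
    stop("train and test sets overlap")
  }
  if (any(is.na(test$label))) stop("test labels missing")
  vali <- mc_cv(train, table, n_runs = runs, seed = seed,
                modifier = modifier, keep_predictions = FALSE)
  fm_tr <- build_feature_matrix(train, table)
  fm_te <- build_feature_matrix(test, table)
  ytr <- as.numeric(train$label)
  yte <- as.numeric(test$label)
  k <- ncol(fm_tr)
  imp <- rank_by_importance(fm_tr, ytr)
  stumps <- lapply(imp$scale, function(nm) {
    train_stump(fm_tr[, nm], ytr, scale_name = nm)
  })
  votes <- vapply(stumps, function(s) stump_vote(s, fm_te[, s$scale_name]),
                  numeric(nrow(fm_te)))
  votes <- matrix(votes, nrow = nrow(fm_te))
  cum <- votes
  if (k > 1L) for (j in 2L:k) cum[, j] <- cum[, j - 1L] + votes[, j]
  p <- sweep(cum, 2L, seq_len(k), "/")
  if (!is.null(modifier)) {
    p <- p + modifier_offsets(modifier, test$strategy_id)
  }
  predpos <- p > 0
  posmask <- yte > 0
  TP <- colSums(predpos & posmask); FP <- colSums(predpos & !posmask)
  FN <- colSums(!predpos & posmask); TN <- colSums(!predpos & !posmask)
  test_mcc <- .mcc(TP, TN, FP, FN)
  test_acc <- (TP + TN) / length(yte)
  per_size <- data.frame(
    model_size = vali$model_sizes,
    median_vali_mcc = vali$median_mcc, mad_vali_mcc = vali$mad_mcc,
    median_vali_accuracy = vali$median_accuracy,
    mad_vali_accuracy = vali$mad_accuracy,
    test_mcc = test_mcc, test_accuracy = test_acc)
  size_sel <- select_model_size(vali)
  summary <- list(
    mcc_max = max(test_mcc),
    size_at_mcc_max = vali$model_sizes[which.max(test_mcc)],
    size_vali_max = size_sel,
    mcc_vali_max = test_mcc[size_sel],
    a_vali_max = test_acc[size_sel])
  structure(list(per_size = per_size, summary = summary,
                 scale_order = imp$scale, modifier = modifier,
                 runs = runs, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat("<evaluation_report> ", nrow(x$per_size), " model sizes, ",
      x$runs, "-fold MC-CV\n", sep = "")
  cat(sprintf("  MCC_max      = %.3f (size %d)\n", s$mcc_max,
              s$size_at_mcc_max))
  cat(sprintf("  MCC_vali,max = %.3f (size %d)\n", s$mcc_vali_max,
              s$size_vali_max))
  cat(sprintf("  A_vali,max   = %.3f\n", s$a_vali_max))
  invisible(x)
}

#' Percent change of a metric relative to its maximum range
#'
#' `100 * (after - before) / metric_range`, rounded to integer percent;
#' the ranges are 1 for accuracy and 2 for MCC.
#'
#' @param before,after Metric values.
#' @param metric_range Maximum range of the metric (> 0).
#' @return Integer-valued percent change.
#' @export
change_metric <- function(before, after, metric_range) {
  stopifnot(metric_range > 0)
  round(100 * (after - before) / metric_range)
}

#' Explained variance fraction of a scale table's first PC
#'
#' Scales are normalized (zero mean, unit variance over the 20
#' residues), assembled into a 20 x k matrix with residues as
#' observations, and decomposed without further centering (the columns
#' are already mean-zero).  High PC1 variance means the scales are
#' strongly mutually correlated; independently synthesized scales should
#' score lower than literature collections.
#'
#' @param table A `scale_table` with >= 2 scales.
#' @return Fraction in (0, 1].
#' @export
pc1_explained_variance <- function(table) {
  stopifnot(inherits(table, "scale_table"))
  if (n_scales(table) < 2L) stop("need >= 2 scales for PCA")
  X <- apply(table$values, 2L, function(v) {
    as.numeric(normalize_scale(aa_scale("x", structure(v,
                                                       names = aa_residues()))))
  })
  d <- svd(X, nu = 0L, nv = 0L)$d
  tot <- sum(d^2)
  if (tot == 0) stop("rank-0 scale table")
  d[1L]^2 / tot
}
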