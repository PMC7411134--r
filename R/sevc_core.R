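#' Train a one-level decision tree (stump) on a single feature
#'
#' The stump threshold minimizes the leaf-size-weighted Gini diversity
#' index over all candidate splits, which are midpoints between
#' consecutive distinct sorted feature values.  Each leaf predicts its
#' majority class with the raw majority fraction as probability (no
#' smoothing).  Deterministic tie rules: equal impurity -> smallest
#' threshold; leaf majority tie -> insoluble (-1).
#'
#' Degenerate inputs (one class only, or a constant feature) yield a
#' stump whose two leaves both carry the overall majority class, with
#' threshold `-Inf`.
#'
#' @param features Numeric feature vector.
#' @param labels Vector in `{-1, +1}` (+1 = soluble).
#' @param scale_name Name recorded on the stump.
#' @return Object of class `decision_stump`.
#' @export
train_stump <- function(features, labels, scale_name = "feature") {
  stopifnot(length(features) == length(labels), length(features) >= 1L,
            all(labels %in% c(-1, 1)))
  st <- .fit_stump(as.numeric(features), as.numeric(labels))
  st$scale_name <- scale_name
  class(st) <- "decision_stump"
  st
}

# Fast core shared by everything; labels numeric -1/+1.
.fit_stump <- function(x, y) {
  n <- length(x)
  npos <- sum(y > 0)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  cand <- which(diff(xs) > 0)
  if (npos == 0L || npos == n || length(cand) == 0L) {
    cls <- if (2L * npos > n) 1 else -1
    prob <- max(npos, n - npos) / n
    return(list(threshold = -Inf, class_low = cls, class_high = cls,
                prob_low = prob, prob_high = prob, degenerate = TRUE))
  }
  posc <- cumsum(ys > 0)
  nL <- cand
  posL <- posc[cand]
  negL <- nL - posL
  nR <- n - nL
  posR <- npos - posL
  negR <- nR - posR
  # n * (weighted Gini impurity); monotone transform of the usual form
  g <- (nL - (posL^2 + negL^2) / nL) + (nR - (posR^2 + negR^2) / nR)
  near <- which(g <= min(g) + 1e-9)
  b <- near[1L]
  if (length(near) > 1L) {
    # resolve exact impurity ties (and 1-ulp float noise) by integer
    # cross-multiplication; ascending scan keeps the smallest threshold
    num <- (nL^2 - posL^2 - negL^2) * nR + (nR^2 - posR^2 - negR^2) * nL
    den <- nL * nR
    for (j in near[-1L]) {
      if (num[j] * den[b] < num[b] * den[j]) b <- j
    }
  }
  i <- cand[b]
  thr <- (xs[i] + xs[i + 1L]) / 2
  leaf <- function(pos, neg) {
    cls <- if (pos > neg) 1 else -1       # tie -> insoluble
    list(cls = cls, prob = max(pos, neg) / (pos + neg))
  }
  lo <- leaf(posL[b], negL[b])
  hi <- leaf(posR[b], negR[b])
  list(threshold = thr, class_low = lo$cls, class_high = hi$cls,
       prob_low = lo$prob, prob_high = hi$prob, degenerate = FALSE)
}

#' @export
print.decision_stump <- function(x, ...) {
  cat("<decision_stump> on '", x$scale_name, "': F <= ",
      format(x$threshold), " -> ", x$class_low, " (p=",
      format(x$prob_low, digits = 3), "), F > -> ", x$class_high,
      " (p=", format(x$prob_high, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Soft vote of a stump for a feature value
#'
#' Sign is the leaf's class, magnitude the leaf's training majority
#' fraction; a feature exactly at the threshold falls in the low leaf.
#'
#' @param st A `decision_stump`.
#' @param feature Numeric vector of feature values.
#' @return Votes in `[-1, 1]`.
#' @export
stump_vote <- function(st, feature) {
  ifelse(feature <= st$threshold,
         st$class_low * st$prob_low,
         st$class_high * st$prob_high)
}

#' Assemble an ensemble model from trained stumps
#'
#' @param stumps List of `decision_stump`s in descending feature
#'   importance (fixed at training time).
#' @param n_included Number of leading stumps the ensemble averages.
#' @param modifier Optional [modification_vector()] of per-strategy
#'   additive offsets on the continuous vote.
#' @return Object of class `ensemble_model`.
#' @export
ensemble_model <- function(stumps, n_included = length(stumps),
                           modifier = NULL) {
  stopifnot(length(stumps) >= 1L, n_included >= 1L,
            n_included <= length(stumps))
  structure(list(stumps = stumps, n_included = as.integer(n_included),
                 modifier = modifier),
            class = "ensemble_model")
}

#' Continuous and discrete ensemble prediction
#'
#' The continuous prediction p of an observation is the mean of the
#' signed-probability votes of the first `n_included` stumps, plus the
#' observation's strategy offset when a modification vector is set.
#' Discretization: p > 0 -> soluble (+1); p <= 0 -> insoluble (-1).
#'
#' @param m An [ensemble_model()].
#' @param fm Feature matrix (rows observations, columns named by scale).
#' @param strategy_ids Optional per-observation strategy labels, needed
#'   when `m$modifier` is set.
#' @return `data.frame` with columns `p` and `class`.
#' @export
ensemble_predict <- function(m, fm, strategy_ids = NULL) {
  stopifnot(inherits(m, "ensemble_model"))
  use <- m$stumps[seq_len(m$n_included)]
  need <- vapply(use, function(s) s$scale_name, character(1L))
  miss <- setdiff(need, colnames(fm))
  if (length(miss) > 0L) {
    stop("feature matrix lacks column(s): ", paste(miss, collapse = ", "))
  }
  votes <- vapply(use, function(s) stump_vote(s, fm[, s$scale_name]),
                  numeric(nrow(fm)))
  votes <- matrix(votes, nrow = nrow(fm))
  p <- rowMeans(votes)
  if (!is.null(m$modifier)) {
    if (is.null(strategy_ids)) {
      stop("modifier set but strategy_ids missing")
    }
    p <- p + modifier_offsets(m$modifier, strategy_ids)
  }
  data.frame(p = p, class = ifelse(p > 0, 1L, -1L),
             row.names = rownames(fm))
}

#' Per-strategy modification vector
#'
#' Additive offsets on the continuous ensemble vote, one per insertion
#' strategy; strategies not listed map to offset 0.
#'
#' @param offsets Named numeric vector (may be empty).
#' @return Object of class `modification_vector`.
#' @export
modification_vector <- function(offsets = numeric(0L)) {
  stopifnot(is.numeric(offsets))
  if (length(offsets) > 0L) stopifnot(!is.null(names(offsets)))
  structure(as.numeric(offsets), names = names(offsets),
            class = "modification_vector")
}

modifier_offsets <- function(modifier, strategy_ids) {
  if (is.null(modifier) || length(modifier) == 0L) {
    return(numeric(length(strategy_ids)))
  }
  off <- unclass(modifier)[strategy_ids]
  off[is.na(off)] <- 0
  as.numeric(off)
}

#' Contingency matrix of a binary prediction
#'
#' @param predicted,actual Vectors in `{-1, +1}`; +1 is the positive
#'   (soluble) class.
#' @return Object of class `contingency`: named integer vector with
#'   entries TP, TN, FP, FN.
#' @export
contingency <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  pp <- predicted > 0
  ap <- actual > 0
  structure(c(TP = sum(pp & ap), TN = sum(!pp & !ap),
              FP = sum(pp & !ap), FN = sum(!pp & ap)),
            class = "contingency")
}

as_contingency <- function(c) {
  v <- unlist(c)[c("TP", "TN", "FP", "FN")]
  if (any(is.na(v)) || any(v < 0)) stop("need TP, TN, FP, FN counts >= 0")
  v
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, defined as 0
#' whenever a denominator factor vanishes (the standard convention; it
#' keeps feature rankings total).
#'
#' @param c A [contingency()] or anything with named TP/TN/FP/FN counts.
#' @return Value in `[-1, 1]`.
#' @export
mcc <- function(c) {
  v <- as_contingency(c)
  if (sum(v) == 0) stop("empty contingency matrix")
  .mcc(v["TP"], v["TN"], v["FP"], v["FN"])
}

.mcc <- function(TP, TN, FP, FN) {
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  # single sqrt of the exact integer product: equal-count MCCs compare
  # bit-identical, keeping stable ties in the importance ranking
  den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  out <- (TP * TN - FP * FN) / den
  out[!is.finite(out)] <- 0
  unname(out)
}

#' Classification accuracy
#'
#' @inheritParams mcc
#' @return `(TP + TN) / (TP + TN + FP + FN)`.
#' @export
accuracy <- function(c) {
  v <- as_contingency(c)
  if (sum(v) == 0) stop("empty contingency matrix")
  unname((v["TP"] + v["TN"]) / sum(v))
}

#' Rank scales by feature importance (training MCC)
#'
#' One stump per scale is trained on the full provided data; scales are
#' sorted by descending MCC of the stump's training-set predictions.
#' Ties keep the original table order (stable sort).
#'
#' @param fm Feature matrix (observations x scales).
#' @param labels Labels in `{-1, +1}`.
#' @return `data.frame` with columns `scale` and `mcc`, ordered.
#' @export
rank_by_importance <- function(fm, labels) {
  stopifnot(nrow(fm) == length(labels))
  y <- as.numeric(labels)
  imp <- vapply(seq_len(ncol(fm)), function(j) {
    st <- .fit_stump(fm[, j], y)
    pred <- ifelse(fm[, j] <= st$threshold, st$class_low, st$class_high)
    mcc(contingency(pred, y))
  }, numeric(1L))
  ord <- order(-imp)
  data.frame(scale = colnames(fm)[ord], mcc = imp[ord],
             stringsAsFactors = FALSE)
}

#' Monte Carlo cross-validation of the soft ensemble vote classifier
#'
#' Each run draws an unstratified uniform 1:1 split of the supplied
#' training set, trains one stump per scale on the run's training half,
#' ranks them by training MCC, and evaluates ensembles of size
#' 1..n_scales on the run's validation half — the identical validation
#' split for every model size within a run.
#'
#' @param constructs `data.frame` with columns `id`, `sequence`, `label`
#'   (+1/-1) and optionally `strategy_id`.
#' @param table A `scale_table`.
#' @param n_runs Number of MC-CV runs.
#' @param seed Integer seed; results are fully reproducible.
#' @param modifier Optional [modification_vector()].
#' @param keep_predictions Retain per-run continuous validation
#'   predictions (needed by the optimizers; costs memory).
#' @return Object of class `mccv_result`.
#' @export
mc_cv <- function(constructs, table, n_runs = 25L, seed = 1L,
                  modifier = NULL, keep_predictions = TRUE) {
  stopifnot(is.data.frame(constructs), "label" %in% names(constructs))
  fm <- build_feature_matrix(constructs, table)
  .mc_cv(fm, as.numeric(constructs$label),
         strategies = constructs$strategy_id,
         n_runs = n_runs, seed = seed, modifier = modifier,
         keep_predictions = keep_predictions)
}

.mc_cv <- function(features, labels, strategies = NULL, n_runs = 25L,
                   seed = 1L, modifier = NULL, keep_predictions = TRUE) {
  n <- nrow(features)
  k <- ncol(features)
  stopifnot(n >= 4L, k >= 1L, n_runs >= 1L)
  sizes <- seq_len(k)
  n_tr <- n %/% 2L
  M <- matrix(NA_real_, n_runs, k)
  A <- matrix(NA_real_, n_runs, k)
  runs <- if (keep_predictions) vector("list", n_runs) else NULL
  n_degenerate <- 0L
  off_all <- if (!is.null(modifier)) modifier_offsets(modifier, strategies)
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      idx <- sample.int(n, n_tr)
      ytr <- labels[idx]
      if (length(unique(ytr)) < 2L) n_degenerate <- n_degenerate + 1L
      va <- setdiff(seq_len(n), idx)
      yva <- labels[va]
      thr <- numeric(k); cl <- numeric(k); ch <- numeric(k)
      pl <- numeric(k); ph <- numeric(k); imp <- numeric(k)
      for (j in seq_len(k)) {
        x <- features[idx, j]
        st <- .fit_stump(x, ytr)
        thr[j] <- st$threshold
        cl[j] <- st$class_low; ch[j] <- st$class_high
        pl[j] <- st$prob_low; ph[j] <- st$prob_high
        pred <- ifelse(x <= st$threshold, st$class_low, st$class_high)
        imp[j] <- .mcc(sum(pred > 0 & ytr > 0), sum(pred < 0 & ytr < 0),
                       sum(pred > 0 & ytr < 0), sum(pred < 0 & ytr > 0))
      }
      ord <- order(-imp)                  # stable: ties keep table order
      votes <- matrix(0, length(va), k)
      for (j in seq_len(k)) {
        jj <- ord[j]
        fva <- features[va, jj]
        votes[, j] <- ifelse(fva <= thr[jj], cl[jj] * pl[jj],
                             ch[jj] * ph[jj])
      }
      cum <- votes
      if (k > 1L) {
        for (j in 2L:k) cum[, j] <- cum[, j - 1L] + votes[, j]
      }
      p <- sweep(cum, 2L, sizes, "/")
      if (!is.null(modifier)) p <- p + off_all[va]
      predpos <- p > 0
      posmask <- yva > 0
      TP <- colSums(predpos & posmask)
      FP <- colSums(predpos & !posmask)
      FN <- colSums(!predpos & posmask)
      TN <- colSums(!predpos & !posmask)
      M[r, ] <- .mcc(TP, TN, FP, FN)
      A[r, ] <- (TP + TN) / length(va)
      if (keep_predictions) {
        runs[[r]] <- list(vali = va, p = p, order = ord)
      }
    }
  })
  structure(list(
    mcc = M, accuracy = A, model_sizes = sizes,
    scale_names = colnames(features),
    median_mcc = apply(M, 2L, median),
    mad_mcc = apply(M, 2L, raw_mad),
    median_accuracy = apply(A, 2L, median),
    mad_accuracy = apply(A, 2L, raw_mad),
    labels = labels,
    strategies = strategies,
    runs = runs,
    n_runs = n_runs, seed = seed,
    n_degenerate_runs = n_degenerate,
    modifier = modifier
  ), class = "mccv_result")
}

# Raw median absolute deviation about the median (no 1.4826 constant).
raw_mad <- function(x) median(abs(x - median(x)))

#' @export
print.mccv_result <- function(x, ...) {
  cat("<mccv_result> ", x$n_runs, " runs, ", length(x$model_sizes),
      " model size(s)\n", sep = "")
  best <- select_model_size(x)
  cat("  best size by median validation MCC: ", best, " (MCC ",
      format(x$median_mcc[best], digits = 3), " +/- MAD ",
      format(x$mad_mcc[best], digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Pick the model size maximizing median validation MCC
#'
#' Ties resolve to the smallest size.
#'
#' @param r An `mccv_result`.
#' @return Integer model size.
#' @export
select_model_size <- function(r) {
  stopifnot(inherits(r, "mccv_result"))
  r$model_sizes[which.max(r$median_mcc)]
}
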