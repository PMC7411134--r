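#' Accumulated validation contingency matrix per insertion strategy
#'
#' TP/TN/FP/FN classifications are summed over every MC-CV run and (by
#' default) every model size, bucketed by the validation observation's
#' insertion strategy.  Systematic over-/under-estimation of a strategy
#' shows up as an FN/FP imbalance here.
#'
#' @param r An `mccv_result` with `keep_predictions = TRUE`.
#' @param strategy_ids Per-observation strategy labels; defaults to the
#'   ones stored on `r`.
#' @param sizes `"all"` (default) accumulates over the whole 1..n model
#'   space, `"best"` only over the size maximizing median validation MCC.
#' @return Integer matrix, strategies x c(TP, TN, FP, FN).
#' @export
accumulate_strategy_contingency <- function(r, strategy_ids = NULL,
                                            sizes = c("all", "best")) {
  stopifnot(inherits(r, "mccv_result"))
  sizes <- match.arg(sizes)
  if (is.null(strategy_ids)) strategy_ids <- r$strategies
  if (is.null(strategy_ids)) stop("strategy annotations missing")
  if (is.null(r$runs)) stop("mccv_result lacks per-observation predictions")
  strat <- sort(unique(strategy_ids))
  out <- matrix(0L, length(strat), 4L,
                dimnames = list(strat, c("TP", "TN", "FP", "FN")))
  cols <- if (sizes == "best") which.max(r$median_mcc) else r$model_sizes
  for (run in r$runs) {
    predpos <- run$p[, cols, drop = FALSE] > 0
    yva <- r$labels[run$vali] > 0
    sva <- strategy_ids[run$vali]
    for (s in strat) {
      m <- sva == s
      if (!any(m)) next
      pp <- predpos[m, , drop = FALSE]
      yp <- yva[m]
      out[s, "TP"] <- out[s, "TP"] + sum(pp & yp)
      out[s, "FP"] <- out[s, "FP"] + sum(pp & !yp)
      out[s, "FN"] <- out[s, "FN"] + sum(!pp & yp)
      out[s, "TN"] <- out[s, "TN"] + sum(!pp & !yp)
    }
  }
  out
}

#' One hill-climbing step of the strategy modification vector
#'
#' The strategy with the largest `|FN - FP|` in the accumulated
#' contingency gets its offset changed by one step: positive when
#' FN > FP (that strategy should be classified more soluble), negative
#' when FN < FP.  Ties resolve to the first strategy in row order; if
#' FN = FP everywhere the vector is returned unchanged.
#'
#' @param cont Strategy contingency matrix from
#'   [accumulate_strategy_contingency()].
#' @param current Current [modification_vector()].
#' @param step Absolute step size (vote units).
#' @return Updated `modification_vector`.
#' @export
update_modifier <- function(cont, current = modification_vector(),
                            step = 0.01) {
  stopifnot(is.matrix(cont), all(c("FN", "FP") %in% colnames(cont)))
  d <- as.numeric(cont[, "FN"]) - as.numeric(cont[, "FP"])
  if (all(d == 0)) return(current)
  i <- which.max(abs(d))                  # first max on ties
  s <- rownames(cont)[i]
  off <- unclass(current)
  if (is.null(names(off))) names(off) <- character(0L)
  cur <- if (s %in% names(off)) off[[s]] else 0
  off[s] <- cur + sign(d[i]) * step
  modification_vector(off)
}

#' Hill-climb per-strategy vote offsets against median validation MCC
#'
#' Iterates: evaluate the current modification vector in a fresh
#' `runs_per_iter`-fold MC-CV; the target is the median over model sizes
#' of the per-size median validation MCC (so the whole 1..n model space
#' counts).  A new best target stores vector and MCC and resets the
#' patience counter; a target within `margin` of the best keeps the
#' current vector; anything worse resets the vector to the best.  Unless
#' reset, the next vector comes from [update_modifier()] on this
#' iteration's accumulated contingency.  Stops after `patience`
#' consecutive iterations without a new best.
#'
#' @param constructs Training constructs (`id`, `sequence`, `label`,
#'   `strategy_id`).
#' @param table A `scale_table`.
#' @param seed Master seed; each iteration draws fresh MC-CV splits from
#'   this stream, so the whole trajectory is reproducible.
#' @param runs_per_iter MC-CV runs per iteration (default 25).
#' @param step Offset step size (default 0.01).
#' @param margin Acceptance margin below the best target (default 0.05).
#' @param patience Consecutive non-improvements before stopping
#'   (default 50).
#' @param max_iter Safety cap on iterations.
#' @param contingency_sizes Passed to
#'   [accumulate_strategy_contingency()].
#' @return List with `best_modifier`, `best_mcc`, `trace` (one row per
#'   iteration), and `iterations`.
#' @export
optimize_strategies <- function(constructs, table, seed = 1L,
                                runs_per_iter = 25L, step = 0.01,
                                margin = 0.05, patience = 50L,
                                max_iter = 1000L,
                                contingency_sizes = "all") {
  stopifnot("strategy_id" %in% names(constructs))
  if (length(unique(constructs$strategy_id)) < 2L) {
    stop("need >= 2 insertion strategies to optimize")
  }
  fm <- build_feature_matrix(constructs, table)
  labels <- as.numeric(constructs$label)
  strat <- constructs$strategy_id
  iter_seeds <- derive_seeds(seed, max_iter)

  current <- modification_vector()
  best <- current
  best_mcc <- -Inf
  no_improve <- 0L
  trace <- vector("list", 0L)
  strat_levels <- sort(unique(strat))
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    res <- .mc_cv(fm, labels, strategies = strat, n_runs = runs_per_iter,
                  seed = iter_seeds[it],
                  modifier = if (length(current) > 0L) current else NULL,
                  keep_predictions = TRUE)
    target <- median(res$median_mcc)
    if (target > best_mcc) {
      best_mcc <- target
      best <- current
      no_improve <- 0L
      status <- "new_best"
    } else if (target >= best_mcc - margin) {
      no_improve <- no_improve + 1L
      status <- "accepted_within_margin"
    } else {
      no_improve <- no_improve + 1L
      status <- "reset"
    }
    snap <- structure(numeric(length(strat_levels)), names = strat_levels)
    snap[names(unclass(current))] <- unclass(current)
    trace[[it]] <- data.frame(iteration = it, target_mcc = target,
                              best_mcc = best_mcc, status = status,
                              no_improve = no_improve,
                              t(snap), check.names = FALSE)
    if (no_improve >= patience) break
    if (status == "reset") {
      current <- best
    } else {
      cont <- accumulate_strategy_contingency(res, strat,
                                              sizes = contingency_sizes)
      current <- update_modifier(cont, current, step = step)
    }
  }
  list(best_modifier = best, best_mcc = best_mcc,
       trace = do.call(rbind, trace), iterations = it)
}
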