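#' Mean continuous MC-CV prediction per construct
#'
#' Runs MC-CV on the supplied constructs (typically the soluble members
#' of one insertion strategy) and, instead of discretizing, averages
#' each construct's continuous prediction p over all runs in which it
#' fell into the validation half.  With the default model size all
#' scales in the table vote.
#'
#' @param constructs Construct `data.frame` (`id`, `sequence`, `label`).
#' @param table A `scale_table`, ordered by feature importance.
#' @param runs MC-CV runs (default 1000).
#' @param seed Seed for the splits.
#' @param model_size Ensemble size whose continuous prediction is
#'   averaged; defaults to all scales in the table.
#' @return Named numeric vector of mean continuous predictions in
#'   `[-1, 1]`, keyed by construct id.
#' @export
mean_continuous_prediction <- function(constructs, table, runs = 1000L,
                                       seed = 1L, model_size = NULL) {
  stopifnot(is.data.frame(constructs))
  if (is.null(model_size)) model_size <- n_scales(table)
  res <- mc_cv(constructs, table, n_runs = runs, seed = seed,
               keep_predictions = TRUE)
  j <- match(model_size, res$model_sizes)
  if (is.na(j)) stop("model size ", model_size, " not available")
  n <- nrow(constructs)
  tot <- numeric(n)
  cnt <- integer(n)
  for (run in res$runs) {
    tot[run$vali] <- tot[run$vali] + run$p[, j]
    cnt[run$vali] <- cnt[run$vali] + 1L
  }
  if (any(cnt == 0L)) {
    stop("construct(s) never in validation: ",
         paste(constructs$id[cnt == 0L], collapse = ", "),
         " (increase runs)")
  }
  structure(tot / cnt, names = constructs$id)
}

#' Ordinary least squares of precipitation concentration on prediction
#'
#' Fits `as_conc ~ prediction` by OLS, reports the ordinary R-squared
#' and 95% confidence bounds of the mean response at each observed
#' prediction.  Linearity is an assumption justified only by the small
#' datasets this is meant for.
#'
#' @param preds Named numeric vector from
#'   [mean_continuous_prediction()].
#' @param records `data.frame` with columns `construct_id` and `as_conc`
#'   (ammonium sulfate molarity, > 0).
#' @return Object of class `precip_fit`: list with `slope` (M per vote
#'   unit), `intercept` (M), `r_squared`, `fitted` (per-construct table
#'   with confidence bounds) and the underlying `lm` fit.
#' @export
fit_precipitation_model <- function(preds, records) {
  stopifnot(is.data.frame(records),
            all(c("construct_id", "as_conc") %in% names(records)))
  if (any(records$as_conc <= 0)) stop("as_conc must be positive")
  idx <- match(records$construct_id, names(preds))
  if (any(is.na(idx))) {
    stop("no prediction for construct(s): ",
         paste(records$construct_id[is.na(idx)], collapse = ", "))
  }
  d <- data.frame(construct_id = records$construct_id,
                  pred = as.numeric(preds[idx]),
                  as_conc = records$as_conc)
  if (nrow(d) < 3L) stop("need >= 3 matched construct/concentration pairs")
  if (sd(d$pred) == 0) stop("zero variance in predictions")
  fit <- lm(as_conc ~ pred, data = d)
  cb <- predict(fit, interval = "confidence", level = 0.95)
  out <- cbind(d, fit = cb[, "fit"], lwr = cb[, "lwr"], upr = cb[, "upr"])
  structure(list(slope = unname(coef(fit)["pred"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r_squared = summary(fit)$r.squared,
                 fitted = out, model = fit),
            class = "precip_fit")
}

#' @export
print.precip_fit <- function(x, ...) {
  cat("<precip_fit> as_conc = ", format(x$intercept, digits = 3), " + ",
      format(x$slope, digits = 3), " * p   (R^2 = ",
      format(x$r_squared, digits = 3), ", n = ", nrow(x$fitted), ")\n",
      sep = "")
  invisible(x)
}
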