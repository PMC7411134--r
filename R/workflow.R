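#' Run an end-to-end experiment pipeline
#'
#' Chains the stages simulate -> crossval -> synth_scales ->
#' optimize_strategy -> evaluate -> regress on synthetic data, writing
#' each stage's artifacts (CSV/JSON) plus a config snapshot into one
#' output directory.  Every stage seeds from the master seed through a
#' fixed counter scheme, so any stage is independently reproducible.
#'
#' @param cfg A [synthetic_config()] describing the dataset.
#' @param stages Ordered subset of
#'   `c("simulate", "crossval", "synth_scales", "optimize_strategy",
#'   "evaluate", "regress")`; dependencies are checked.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed for the algorithm stages.
#' @param n_train Training set size for the stratified split.
#' @param scale_table Optional `scale_table` used by crossval/evaluate;
#'   default: synthesized scales (when the stage ran) or a seeded table
#'   of random scales.
#' @param k_scales Number of scales to synthesize / draw (default 8).
#' @param mc_runs MC-CV runs for crossval and evaluate stages.
#' @param ... Passed to [synthesize_scale_table()] and
#'   [optimize_strategies()] (e.g. `stats_runs`, `eval_runs`,
#'   `patience`, `max_iter`, `runs_per_iter`).
#' @return Invisible list of in-memory stage results; artifacts on disk.
#' @export
run_pipeline <- function(cfg = synthetic_config(),
                         stages = c("simulate", "crossval", "evaluate"),
                         out_dir = tempfile("sevc_run_"), seed = 1L,
                         n_train = NULL, scale_table = NULL,
                         k_scales = 8L, mc_runs = 100L, ...) {
  all_stages <- c("simulate", "crossval", "synth_scales",
                  "optimize_strategy", "evaluate", "regress")
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 8L)
  state <- list()
  dots <- list(...)
  log_line <- function(...) {
    cat(format(Sys.time(), "%H:%M:%S"), ..., "\n",
        file = file.path(out_dir, "pipeline.log"), append = TRUE)
  }
  jsonlite::write_json(
    list(seed = seed, stages = stages, config = unclass(cfg)),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    null = "null")

  need <- function(what, stage) {
    if (is.null(state[[what]])) {
      stop("stage '", stage, "' needs upstream stage producing '", what,
           "' (run 'simulate' first)")
    }
  }

  for (stage in stages) {
    log_line("stage", stage)
    if (stage == "simulate") {
      ds <- generate_dataset(cfg)
      if (is.null(n_train)) {
        n_train <- round(nrow(ds$constructs) * 384 / 568)
      }
      split <- stratified_split(ds$constructs, n_train = n_train,
                                seed = seeds[1L])
      state$dataset <- ds
      state$train <- ds$constructs[ds$constructs$id %in% split$train_ids, ]
      state$test <- ds$constructs[ds$constructs$id %in% split$test_ids, ]
      write.csv(ds$constructs, file.path(out_dir, "constructs.csv"),
                row.names = FALSE)
      write.csv(data.frame(id = c(split$train_ids, split$test_ids),
                           set = rep(c("train", "test"),
                                     c(length(split$train_ids),
                                       length(split$test_ids)))),
                file.path(out_dir, "split.csv"), row.names = FALSE)
      write_fasta(c(backbone = ds$truth$backbone),
                  file.path(out_dir, "backbone.fasta"))
      write_fasta(ds$truth$inserts, file.path(out_dir, "inserts.fasta"))
    } else if (stage == "synth_scales") {
      need("train", stage)
      st <- do.call(synthesize_scale_table,
                    c(list(state$train, k_subsets = k_scales,
                           seed = seeds[2L]),
                      dots[names(dots) %in% c("rate", "stats_runs",
                                              "eval_runs", "margin",
                                              "patience", "max_iter")]))
      state$scales <- st
      write_scale_table(st, file.path(out_dir, "synthesized_scales.csv"))
    } else {
      need("train", stage)
      if (is.null(state$scales)) {
        state$scales <- if (!is.null(scale_table)) scale_table else {
          scale_table(lapply(seq_len(k_scales), function(i) {
            random_scale(seeds[3L] + i, name = paste0("R", i))
          }), provenance = "literature")
        }
      }
      if (stage == "crossval") {
        cv <- mc_cv(state$train, state$scales, n_runs = mc_runs,
                    seed = seeds[4L], modifier = state$modifier,
                    keep_predictions = FALSE)
        state$crossval <- cv
        write.csv(data.frame(model_size = cv$model_sizes,
                             median_mcc = cv$median_mcc,
                             mad_mcc = cv$mad_mcc,
                             median_accuracy = cv$median_accuracy,
                             mad_accuracy = cv$mad_accuracy),
                  file.path(out_dir, "crossval.csv"), row.names = FALSE)
      } else if (stage == "optimize_strategy") {
        opt <- do.call(optimize_strategies,
                       c(list(state$train, state$scales, seed = seeds[5L]),
                         dots[names(dots) %in% c("runs_per_iter", "step",
                                                 "margin", "patience",
                                                 "max_iter")]))
        state$modifier <- if (length(opt$best_modifier) > 0L) {
          opt$best_modifier
        } else NULL
        state$strategy_opt <- opt
        write.csv(opt$trace, file.path(out_dir, "strategy_opt_trace.csv"),
                  row.names = FALSE)
        jsonlite::write_json(as.list(unclass(opt$best_modifier)),
                             file.path(out_dir, "best_modifier.json"),
                             auto_unbox = TRUE, digits = NA)
      } else if (stage == "evaluate") {
        rep <- evaluate_model(state$train, state$test, state$scales,
                              modifier = state$modifier, runs = mc_runs,
                              seed = seeds[6L])
        state$report <- rep
        write.csv(rep$per_size, file.path(out_dir, "evaluation.csv"),
                  row.names = FALSE)
        jsonlite::write_json(
          c(rep$summary,
            list(scale_provenance = state$scales$provenance,
                 modifier = if (is.null(state$modifier)) NULL else
                   as.list(unclass(state$modifier)))),
          file.path(out_dir, "evaluation_summary.json"),
          auto_unbox = TRUE, digits = NA, null = "null")
      } else if (stage == "regress") {
        tr <- state$dataset$truth
        all_c <- state$dataset$constructs
        # regression model is trained on every construct of one strategy
        # (both classes); screening data exist only for soluble ones
        strat1 <- all_c$strategy_id[1L]
        sub <- all_c[all_c$strategy_id == strat1, ]
        sol <- sub[sub$label == 1L, ]
        prec <- generate_precipitation_data(sol, tr, seed = seeds[7L])
        preds <- mean_continuous_prediction(sub, state$scales,
                                            runs = mc_runs,
                                            seed = seeds[8L])
        fitr <- fit_precipitation_model(preds, prec)
        state$regression <- fitr
        write.csv(fitr$fitted, file.path(out_dir, "regression.csv"),
                  row.names = FALSE)
        jsonlite::write_json(list(slope = fitr$slope,
                                  intercept = fitr$intercept,
                                  r_squared = fitr$r_squared),
                             file.path(out_dir, "regression.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  invisible(state)
}

#' Minimal command-line entry point
#'
#' Subcommands: `simulate`, `crossval`, `run`, `scales`.  Arguments are
#' `--key value` pairs; see the package README for examples.  Designed
#' for `Rscript -e 'sevc::sevc_cli()' ...` or the installed `exec/sevc`
#' script.
#'
#' @param args Character vector of CLI arguments (default: from the
#'   command line).
#' @return Exit status, invisibly.
#' @export
sevc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: sevc <command> [--key value ...]",
    "  simulate  --seed S [--out DIR] [--inserts N] [--strategies K]",
    "  crossval  --seed S [--out DIR] [--runs N] [--scales K]",
    "  run       --seed S [--out DIR] [--stages a,b,c]",
    "  scales    validate|normalize|dedupe --csv FILE [--out FILE]",
    sep = "\n")
  if (length(args) == 0L) {
    cat(usage, "\n")
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  opt <- list()
  positional <- character(0L)
  i <- 1L
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      opt[[substring(rest[i], 3L)]] <- rest[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, rest[i])
      i <- i + 1L
    }
  }
  get_int <- function(name, default) {
    if (is.null(opt[[name]])) default else as.integer(opt[[name]])
  }
  out_dir <- if (is.null(opt$out)) file.path(getwd(), "sevc_out") else opt$out
  seed <- get_int("seed", 1L)
  if (cmd == "simulate") {
    cfg <- synthetic_config(n_inserts = get_int("inserts", 71L),
                            n_strategies = get_int("strategies", 8L),
                            seed = seed)
    run_pipeline(cfg, stages = "simulate", out_dir = out_dir, seed = seed)
    cat("wrote", file.path(out_dir, "constructs.csv"), "\n")
  } else if (cmd == "crossval") {
    cfg <- synthetic_config(seed = seed)
    run_pipeline(cfg, stages = c("simulate", "crossval"),
                 out_dir = out_dir, seed = seed,
                 k_scales = get_int("scales", 8L),
                 mc_runs = get_int("runs", 100L))
    cat("wrote", file.path(out_dir, "crossval.csv"), "\n")
  } else if (cmd == "run") {
    stages <- if (is.null(opt$stages)) {
      c("simulate", "crossval", "evaluate")
    } else strsplit(opt$stages, ",")[[1L]]
    cfg <- synthetic_config(seed = seed)
    run_pipeline(cfg, stages = stages, out_dir = out_dir, seed = seed,
                 mc_runs = get_int("runs", 100L))
    cat("pipeline artifacts in", out_dir, "\n")
  } else if (cmd == "scales") {
    sub <- positional[1L]
    if (is.na(sub) || is.null(opt$csv)) {
      cat(usage, "\n")
      return(invisible(1L))
    }
    t <- load_scale_table(opt$csv)
    if (sub == "validate") {
      cat("valid scale table:", n_scales(t), "scale(s)\n")
    } else if (sub == "normalize") {
      m <- apply(t$values, 2L, function(v) {
        as.numeric(normalize_scale(aa_scale("x", structure(v,
          names = aa_residues()))))
      })
      dimnames(m) <- dimnames(t$values)
      norm <- scale_table(m, provenance = t$provenance)
      write_scale_table(norm, if (is.null(opt$out)) opt$csv else opt$out)
      cat("normalized", n_scales(t), "scale(s)\n")
    } else if (sub == "dedupe") {
      dd <- dedupe_reversed(t)
      write_scale_table(dd, if (is.null(opt$out)) opt$csv else opt$out)
      cat("kept", n_scales(dd), "of", n_scales(t), "scale(s)\n")
    } else {
      cat(usage, "\n")
      return(invisible(1L))
    }
  } else {
    cat(usage, "\n")
    return(invisible(1L))
  }
  invisible(0L)
}
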