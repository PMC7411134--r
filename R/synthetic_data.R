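#' Default parameterized insertion strategies
#'
#' Eight strategy recipes placed around a loop-like region at roughly
#' half the backbone (emulating insertion into a surface loop of a
#' 149-residue core protein): distinct combinations of insertion
#' position, deletion count, and glycine/serine linkers.
#'
#' @param n Number of strategies (<= 8).
#' @param backbone_length Backbone length used to place the loop.
#' @return List of [insertion_strategy()] objects labelled `A`, `B`, ...
#' @export
default_strategies <- function(n = 8L, backbone_length = 149L) {
  stopifnot(n >= 1L, n <= 8L)
  center <- max(1L, round(backbone_length * 0.52))
  pos_off <- c(0L, 2L, 0L, 2L, 4L, -1L, 3L, 1L)
  n_del <- c(0L, 0L, 2L, 3L, 1L, 4L, 2L, 1L)
  lb <- c("", "GG", "", "G", "GS", "", "G", "GGS")
  la <- c("", "GG", "", "G", "GS", "", "", "")
  lapply(seq_len(n), function(i) {
    insertion_strategy(LETTERS[i], position = center + pos_off[i],
                       n_deleted = n_del[i], linker_before = lb[i],
                       linker_after = la[i])
  })
}

#' Configuration of the synthetic construct-grid generator
#'
#' States the world the generator emulates: a backbone protein, a grid
#' of insert peptides times insertion strategies, labels driven by a
#' hidden ground-truth hydrophobicity scale plus per-strategy offsets
#' and Gaussian noise, and a quantile threshold fixing class balance.
#'
#' @param n_inserts Number of insert peptides (default 71).
#' @param n_strategies Number of insertion strategies (default 8).
#' @param insert_length_range Insert length range in residues
#'   (default 9--30).
#' @param backbone_length Backbone length (default 149,
#'   core-protein-truncation-like).
#' @param ground_truth_scale Optional `aa_scale`; default: a seeded
#'   random normalized scale.
#' @param strategy_offsets Named numeric per-strategy latent offsets
#'   (insolubility units); default all zero.
#' @param noise_sd Latent noise standard deviation; default
#'   `NULL` = 0.25 x the sd of the noiseless latent.
#' @param label_balance_target Soluble fraction fixed by the label
#'   threshold (default 0.5).
#' @param seed Master seed; all stage seeds derive from it.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_inserts = 71L, n_strategies = 8L,
                             insert_length_range = c(9L, 30L),
                             backbone_length = 149L,
                             ground_truth_scale = NULL,
                             strategy_offsets = NULL,
                             noise_sd = NULL,
                             label_balance_target = 0.5,
                             seed = 2020L) {
  stopifnot(n_inserts >= 1L, n_strategies >= 1L, n_strategies <= 8L,
            length(insert_length_range) == 2L,
            insert_length_range[1L] >= 1L,
            insert_length_range[2L] >= insert_length_range[1L],
            backbone_length >= 10L,
            label_balance_target > 0, label_balance_target < 1)
  if (!is.null(ground_truth_scale)) {
    stopifnot(inherits(ground_truth_scale, "aa_scale"))
  }
  if (!is.null(strategy_offsets)) {
    stopifnot(is.numeric(strategy_offsets), !is.null(names(strategy_offsets)),
              all(is.finite(strategy_offsets)))
  }
  if (!is.null(noise_sd)) stopifnot(noise_sd >= 0)
  structure(list(n_inserts = as.integer(n_inserts),
                 n_strategies = as.integer(n_strategies),
                 insert_length_range = as.integer(insert_length_range),
                 backbone_length = as.integer(backbone_length),
                 ground_truth_scale = ground_truth_scale,
                 strategy_offsets = strategy_offsets,
                 noise_sd = noise_sd,
                 label_balance_target = label_balance_target,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a labelled synthetic construct grid with known ground truth
#'
#' Draws a random backbone and insert peptides (uniform over the
#' canonical alphabet), builds the full insert x strategy grid, computes
#' each construct's latent insolubility as the ground-truth-scale
#' feature of the full chimeric sequence plus its strategy offset plus
#' Gaussian noise, and labels a construct insoluble (-1) iff its latent
#' exceeds the empirical quantile that yields the target class balance.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `constructs` (`data.frame`: id, insert_id,
#'   strategy_id, sequence, label) and `truth` (generating scale,
#'   offsets, latent scores, threshold `tau`, noise sd, backbone,
#'   inserts, strategies).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  seeds <- derive_seeds(cfg$seed, 4L)
  res <- aa_residues()
  backbone <- with_seed(seeds[1L], paste0(
    sample(res, cfg$backbone_length, replace = TRUE), collapse = ""))
  inserts <- with_seed(seeds[2L], {
    lens <- sample(seq(cfg$insert_length_range[1L],
                       cfg$insert_length_range[2L]),
                   cfg$n_inserts, replace = TRUE)
    structure(vapply(lens, function(L) {
      paste0(sample(res, L, replace = TRUE), collapse = "")
    }, character(1L)),
    names = sprintf("I%02d", seq_len(cfg$n_inserts)))
  })
  strategies <- default_strategies(cfg$n_strategies, cfg$backbone_length)
  constructs <- build_construct_grid(backbone, inserts, strategies)
  gt <- cfg$ground_truth_scale
  if (is.null(gt)) gt <- random_scale(seeds[3L], name = "ground_truth")
  counts <- residue_counts(constructs$sequence)
  raw <- as.numeric(counts %*% as.numeric(gt))
  offs <- structure(numeric(cfg$n_strategies),
                    names = vapply(strategies, `[[`, character(1L), "id"))
  if (!is.null(cfg$strategy_offsets)) {
    common <- intersect(names(cfg$strategy_offsets), names(offs))
    offs[common] <- cfg$strategy_offsets[common]
  }
  noise_sd <- cfg$noise_sd
  if (is.null(noise_sd)) noise_sd <- 0.25 * sd(raw)
  latent <- raw + as.numeric(offs[constructs$strategy_id]) +
    with_seed(seeds[4L], rnorm(nrow(constructs), 0, noise_sd))
  tau <- quantile(latent, cfg$label_balance_target, names = FALSE)
  constructs$label <- ifelse(latent <= tau, 1L, -1L)
  names(latent) <- constructs$id
  list(constructs = constructs,
       truth = list(scale = gt, strategy_offsets = offs, latent = latent,
                    tau = tau, noise_sd = noise_sd, sd_raw = sd(raw),
                    backbone = backbone, inserts = inserts,
                    strategies = strategies))
}

#' Stratified train/test split over the insert x strategy grid
#'
#' Splits the full grid once so that both marginals are preserved:
#' every strategy contributes an equal (+/- 1) number of training
#' constructs, and every insert contributes `floor` or `ceil` of its
#' proportional share.  Realized by a randomized max-remaining-capacity
#' assignment over the bipartite insert/strategy grid.
#'
#' @param constructs Full-grid construct `data.frame`.
#' @param n_train Training set size (default 384).
#' @param seed Seed; the split is drawn once and reproducibly.
#' @return List with character vectors `train_ids` and `test_ids`
#'   (disjoint, exhaustive).
#' @export
stratified_split <- function(constructs, n_train = 384L, seed = 1L) {
  stopifnot(is.data.frame(constructs), n_train >= 1L,
            n_train < nrow(constructs))
  ins <- sort(unique(constructs$insert_id))
  str <- sort(unique(constructs$strategy_id))
  tab <- table(constructs$insert_id, constructs$strategy_id)
  if (any(tab != 1L)) {
    stop("infeasible strata: constructs must form a full insert x ",
         "strategy grid (one construct per cell)")
  }
  ni <- length(ins)
  ns <- length(str)
  with_seed(seed, {
    base_q <- n_train %/% ni
    quota <- rep(base_q, ni)
    extra <- n_train - sum(quota)
    if (extra > 0L) quota[sample.int(ni, extra)] <- base_q + 1L
    names(quota) <- ins
    cap <- rep(n_train %/% ns, ns)
    extraS <- n_train - sum(cap)
    if (extraS > 0L) {
      bump <- sample.int(ns, extraS)
      cap[bump] <- cap[bump] + 1L
    }
    names(cap) <- str
    if (any(quota > ns)) stop("infeasible strata: insert quota exceeds ",
                              "number of strategies")
    sel <- matrix(FALSE, ni, ns, dimnames = list(ins, str))
    for (i in order(-quota, runif(ni))) {
      q <- quota[i]
      if (q == 0L) next
      pick <- order(-cap, runif(ns))[seq_len(q)]
      if (any(cap[pick] <= 0L)) stop("infeasible strata")
      cap[pick] <- cap[pick] - 1L
      sel[i, pick] <- TRUE
    }
  })
  key <- paste(constructs$insert_id, constructs$strategy_id, sep = "\r")
  cells <- which(sel, arr.ind = TRUE)
  train_key <- paste(ins[cells[, 1L]], str[cells[, 2L]], sep = "\r")
  in_train <- key %in% train_key
  list(train_ids = constructs$id[in_train],
       test_ids = constructs$id[!in_train])
}

#' Simulate precipitation screening data for soluble constructs
#'
#' Emulates an ammonium sulfate screening of soluble constructs from one
#' insertion strategy: the required molarity grows linearly with the
#' construct's distance from the solubility threshold (more robustly
#' soluble constructs need more salt), plus Gaussian noise, floored at
#' 0.05 M.  Defaults put most concentrations in 0.5--0.7 M with
#' occasional values toward 0.4 and 1 M.
#'
#' @param constructs Soluble-labelled constructs of one strategy.
#' @param truth Ground truth list from [generate_dataset()].
#' @param beta0 Intercept (M), default 0.43.
#' @param beta1 Slope per standardized latent margin (M), default 0.25.
#' @param noise_sd Measurement noise (M), default 0.05.
#' @param seed Seed.
#' @param n Number of constructs to screen (default 10; sampled without
#'   replacement when more are supplied).
#' @return `data.frame` with columns `construct_id` and `as_conc` (M).
#' @export
generate_precipitation_data <- function(constructs, truth, beta0 = 0.43,
                                        beta1 = 0.25, noise_sd = 0.05,
                                        seed = 1L, n = 10L) {
  stopifnot(is.data.frame(constructs))
  if (nrow(constructs) == 0L) stop("empty construct subset")
  if (any(constructs$label != 1L)) {
    stop("precipitation subset must be soluble-labelled (+1)")
  }
  lat <- truth$latent[constructs$id]
  if (any(is.na(lat))) stop("constructs missing from ground truth")
  sd_lat <- sd(truth$latent)
  z <- (truth$tau - lat) / sd_lat          # standardized solubility margin
  with_seed(seed, {
    keep <- if (nrow(constructs) > n) sample.int(nrow(constructs), n) else
      seq_len(nrow(constructs))
    conc <- beta0 + beta1 * z[keep] + rnorm(length(keep), 0, noise_sd)
  })
  data.frame(construct_id = constructs$id[keep],
             as_conc = pmax(0.05, as.numeric(conc)),
             stringsAsFactors = FALSE)
}
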