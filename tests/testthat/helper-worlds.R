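# Shared synthetic worlds, built in code at test time.

# Small grid for fast unit tests: 12 inserts x 4 strategies = 48.
small_world <- function(seed = 42, noise_sd = NULL, strategy_offsets = NULL,
                        n_train = 32L) {
  cfg <- synthetic_config(n_inserts = 12L, n_strategies = 4L,
                          insert_length_range = c(6L, 12L),
                          backbone_length = 60L, noise_sd = noise_sd,
                          strategy_offsets = strategy_offsets, seed = seed)
  ds <- generate_dataset(cfg)
  sp <- stratified_split(ds$constructs, n_train = n_train, seed = seed + 1L)
  list(cfg = cfg, constructs = ds$constructs, truth = ds$truth,
       train = ds$constructs[ds$constructs$id %in% sp$train_ids, ],
       test = ds$constructs[ds$constructs$id %in% sp$test_ids, ])
}

# Full-size grid matching the published dataset geometry (71 x 8, 384/184).
paper_world <- function(seed = 2020, noise_sd = NULL,
                        strategy_offsets = NULL, split_seed = seed + 1L) {
  cfg <- synthetic_config(noise_sd = noise_sd,
                          strategy_offsets = strategy_offsets, seed = seed)
  ds <- generate_dataset(cfg)
  sp <- stratified_split(ds$constructs, n_train = 384L, seed = split_seed)
  list(cfg = cfg, constructs = ds$constructs, truth = ds$truth,
       train = ds$constructs[ds$constructs$id %in% sp$train_ids, ],
       test = ds$constructs[ds$constructs$id %in% sp$test_ids, ])
}

# Partially informative scale table: convex mixtures of the planted
# ground-truth scale with seeded random scales (fixed weights), standing
# in for literature scales of varying relevance.
mixed_scale_table <- function(truth_scale, seed, weights = c(0.8, 0.6, 0.5,
                                                             0.3, 0)) {
  gt <- as.numeric(truth_scale)
  scales <- lapply(seq_along(weights), function(i) {
    v <- weights[i] * gt +
      (1 - weights[i]) * as.numeric(random_scale(1000L * seed + i))
    normalize_scale(toy_scale(v, name = paste0("L", i)))
  })
  scale_table(scales, provenance = "literature")
}

random_scale_table <- function(k, seed) {
  scale_table(lapply(seq_len(k), function(i) {
    random_scale(seed + i, name = paste0("R", i))
  }), provenance = "literature")
}

# Labels shuffled once: independent of sequence and strategy.
null_world <- function(seed = 42, label_seed = 9L, ...) {
  w <- paper_world(seed = seed, ...)
  perm <- sevc:::with_seed(label_seed, sample(nrow(w$constructs)))
  w$constructs$label <- w$constructs$label[perm]
  lab <- structure(w$constructs$label, names = w$constructs$id)
  w$train$label <- as.integer(lab[w$train$id])
  w$test$label <- as.integer(lab[w$test$id])
  w
}
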