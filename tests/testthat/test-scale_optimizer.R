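test_that("compute_group_stats reproduces the worked FN/FP example", {
  s <- toy_scale(replace(replace(numeric(20), match("A", aa_residues()), 1),
                         match("R", aa_residues()), -1))
  gs <- compute_group_stats(s, fn = "AA", fp = "RR")
  expect_equal(unname(gs$a_fn[match("A", aa_residues())]), 2)
  expect_equal(unname(gs$a_fp[match("R", aa_residues())]), 2)
  expect_equal(gs$f_fn, 2)
  expect_equal(gs$f_fp, -2)
  expect_equal(gs$delta_f, 4)
  expect_equal(unname(gs$delta_a[match("A", aa_residues())]), 2)
  expect_equal(unname(gs$delta_a[match("R", aa_residues())]), -2)
  expect_equal(unname(gs$m[match("A", aa_residues())]), 8)
  expect_equal(unname(gs$m[match("R", aa_residues())]), -8)
  expect_equal(sum(gs$m != 0), 2L)

  # identical compositions -> zero modifier
  gs0 <- compute_group_stats(s, fn = c("AR", "RA"), fp = "AR")
  expect_true(all(gs0$delta_a == 0))
  expect_true(all(gs0$m == 0))

  # empty group -> no-update signal
  expect_null(compute_group_stats(s, fn = character(0), fp = "AR"))
  expect_null(compute_group_stats(s, fn = residue_counts(character(0)),
                                  fp = residue_counts("AR")))
})

test_that("group mean feature values equal dot products (oracle)", {
  set.seed(31)
  for (i in 1:20) {
    s <- random_scale(400 + i)
    fn <- replicate(sample(1:5, 1), paste0(
      sample(aa_residues(), sample(4:12, 1), replace = TRUE), collapse = ""))
    fp <- replicate(sample(1:5, 1), paste0(
      sample(aa_residues(), sample(4:12, 1), replace = TRUE), collapse = ""))
    gs <- compute_group_stats(s, fn, fp)
    # oracle: mean of per-sequence features computed independently
    expect_equal(gs$f_fn, mean(vapply(fn, compute_feature, numeric(1),
                                      s = s)), tolerance = 1e-9)
    expect_equal(gs$f_fp, mean(vapply(fp, compute_feature, numeric(1),
                                      s = s)), tolerance = 1e-9)
    expect_equal(gs$delta_f, gs$f_fn - gs$f_fp, tolerance = 1e-12)
  }
})

test_that("modify_scale standardizes the step and renormalizes", {
  s <- random_scale(9)
  m <- rnorm(20)
  expect_identical(modify_scale(s, m, 0), s)            # rate 0: identity
  out <- modify_scale(s, m, 0.05)
  expect_lt(abs(mean(out)), 1e-9)
  expect_lt(abs(var(as.numeric(out)) - 1), 1e-9)
  expect_null(modify_scale(s, rep(3, 20), 0.01))        # constant m

  # the added component has variance r^2 before renormalization
  for (r in c(0.01, 0.05, 0.5)) {
    mbar <- (m - mean(m)) / sd(m)
    expect_equal(var(r * mbar), r^2, tolerance = 1e-12)
  }
})

test_that("optimize_scale improves on separable data, deterministically", {
  w <- small_world(noise_sd = 0, n_train = 40L)
  fit <- optimize_scale(random_scale(55), w$train, rate = 0.02, seed = 8,
                        stats_runs = 5, eval_runs = 10, patience = 10,
                        max_iter = 40)
  expect_gte(fit$best_mcc, fit$initial_mcc)
  expect_true(all(diff(fit$trace$best_mcc) >= 0))
  # accepted scales stay normalized
  expect_lt(abs(mean(fit$best_scale)), 1e-9)
  expect_lt(abs(var(as.numeric(fit$best_scale)) - 1), 1e-9)

  fit2 <- optimize_scale(random_scale(55), w$train, rate = 0.02, seed = 8,
                         stats_runs = 5, eval_runs = 10, patience = 10,
                         max_iter = 40)
  expect_identical(fit$trace, fit2$trace)
  expect_identical(as.numeric(fit$best_scale), as.numeric(fit2$best_scale))

  mono <- w$train
  mono$label <- 1L
  expect_error(optimize_scale(random_scale(1), mono), "single class")
})

test_that("synthesize_scale_table splits subsets as specified", {
  w <- paper_world()
  # 384 observations, k = 8 random subsets of 48
  tab <- synthesize_scale_table(w$train, k_subsets = 8, seed = 10,
                                stats_runs = 3, eval_runs = 5, patience = 2,
                                max_iter = 3)
  expect_equal(ncol(tab$values), 8L)
  expect_equal(tab$provenance, "synthesized")
  runs <- attr(tab, "runs")
  sizes <- vapply(runs, function(r) length(r$subset), integer(1))
  expect_true(all(sizes == 48L))
  expect_equal(length(unique(unlist(lapply(runs, `[[`, "subset")))), 384L)

  # by-strategy subsets are single-strategy, one per strategy
  tab2 <- synthesize_scale_table(w$train, k_subsets = 8,
                                 mode = "by_strategy", seed = 11,
                                 stats_runs = 3, eval_runs = 5,
                                 patience = 2, max_iter = 3)
  runs2 <- attr(tab2, "runs")
  for (r in runs2) {
    expect_equal(length(unique(w$train$strategy_id[r$subset])), 1L)
  }
  expect_error(synthesize_scale_table(w$train, k_subsets = 5,
                                      mode = "by_strategy", seed = 1),
               "by_strategy")
  expect_error(synthesize_scale_table(w$train, k_subsets = 17, seed = 1),
               "too small")

  # k = 1 uses the full training set
  tab1 <- synthesize_scale_table(w$train, k_subsets = 1, seed = 12,
                                 stats_runs = 3, eval_runs = 5, patience = 2,
                                 max_iter = 3)
  expect_equal(length(attr(tab1, "runs")[[1]]$subset), 384L)

  # independently synthesized scales are less collinear than copies
  expect_lt(pc1_explained_variance(tab), 1)
})
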