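test_that("wide-CSV scale tables round-trip and validate", {
  t <- scale_table(list(random_scale(1, "a"), random_scale(2, "b")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_scale_table(t, path)
  back <- load_scale_table(path)
  expect_equal(back$values, t$values, tolerance = 1e-12)
  expect_equal(colnames(back$values), c("a", "b"))

  # residue order in the file must not matter
  df <- utils::read.csv(path, check.names = FALSE)
  df <- df[rev(seq_len(nrow(df))), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_equal(load_scale_table(path)$values, t$values, tolerance = 1e-12)

  # missing residue row named in the error
  df <- df[df$residue != "W", ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(load_scale_table(path), "W")

  # non-numeric cell named by scale and residue
  write_scale_table(t, path)
  df <- utils::read.csv(path, check.names = FALSE)
  df$b[df$residue == "K"] <- "oops"
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  err <- tryCatch(load_scale_table(path), error = conditionMessage)
  expect_match(err, "b")
  expect_match(err, "K")
})

test_that("aa_scale rejects non-canonical and incomplete inputs", {
  vals <- structure(rnorm(20), names = aa_residues())
  expect_s3_class(aa_scale("ok", vals), "aa_scale")
  bad <- vals
  names(bad)[1] <- "X"
  expect_error(aa_scale("s", bad), "X")
  expect_error(aa_scale("s", vals[-3]), names(vals)[3])
  nf <- vals
  nf[5] <- NaN
  expect_error(aa_scale("s", nf), "non-finite")
})

test_that("normalize_scale centers, scales, is idempotent, rejects constants", {
  for (seed in 1:5) {
    s <- random_scale(seed, normalize = FALSE)
    ns <- normalize_scale(s)
    expect_lt(abs(mean(ns)), 1e-9)
    expect_lt(abs(var(as.numeric(ns)) - 1), 1e-9)
    expect_equal(as.numeric(normalize_scale(ns)), as.numeric(ns),
                 tolerance = 1e-12)
  }
  expect_error(normalize_scale(toy_scale(rep(2, 20))), "degenerate")
  # order-independence of residue keys
  vals <- structure(rnorm(20), names = aa_residues())
  shuf <- sample(20)
  expect_equal(as.numeric(normalize_scale(aa_scale("a", vals))),
               as.numeric(normalize_scale(aa_scale("a", vals[shuf]))))
})

test_that("dedupe_reversed drops reversed duplicates only, idempotently", {
  x <- random_scale(3, "x")
  negx <- toy_scale(-as.numeric(x), name = "negx")
  y <- random_scale(4, "y")

  t1 <- scale_table(list(x, negx))
  d1 <- suppressMessages(dedupe_reversed(t1))
  expect_equal(ncol(d1$values), 1L)
  expect_equal(colnames(d1$values), "x")   # non-reversed member kept
  expect_equal(attr(d1, "removed"), "negx")

  t2 <- scale_table(list(x, negx, y))
  d2 <- suppressMessages(dedupe_reversed(t2))
  expect_setequal(colnames(d2$values), c("x", "y"))

  # uncorrelated scales untouched; dedupe is idempotent
  t3 <- scale_table(list(x, y, random_scale(5, "z")))
  d3 <- suppressMessages(dedupe_reversed(t3))
  expect_equal(d3$values, t3$values)
  expect_equal(suppressMessages(dedupe_reversed(d2))$values, d2$values)

  # near-exact negation (rounded) still caught
  rounded <- toy_scale(round(-as.numeric(x), 4), name = "neg_round")
  d4 <- suppressMessages(dedupe_reversed(scale_table(list(x, rounded))))
  expect_equal(colnames(d4$values), "x")
})

test_that("random_scale is seed-deterministic and normalized", {
  expect_identical(as.numeric(random_scale(1)), as.numeric(random_scale(1)))
  expect_false(identical(as.numeric(random_scale(1)),
                         as.numeric(random_scale(2))))
  s <- random_scale(10)
  expect_lt(abs(mean(s)), 1e-9)
  expect_lt(abs(var(as.numeric(s)) - 1), 1e-9)
  # drawing must not disturb the global RNG stream
  set.seed(123)
  a <- rnorm(1)
  set.seed(123)
  invisible(random_scale(77))
  expect_identical(rnorm(1), a)
})

test_that("raw random_scale draws are standard normal (KS, alpha = 0.01)", {
  draws <- vapply(1:1000, function(s) {
    as.numeric(random_scale(s, normalize = FALSE))
  }, numeric(20L))
  # per-residue across seeds, and pooled
  for (i in c(1L, 7L, 20L)) {
    expect_gt(stats::ks.test(draws[i, ], "pnorm")$p.value, 0.01)
  }
  expect_gt(stats::ks.test(as.numeric(draws), "pnorm")$p.value, 0.01)
})

test_that("downstream ranking is invariant to scale sign flips", {
  w <- small_world()
  s <- random_scale(6, "s")
  flipped <- toy_scale(-as.numeric(s), name = "s")
  fm1 <- build_feature_matrix(w$train, scale_table(list(s)))
  fm2 <- build_feature_matrix(w$train, scale_table(list(flipped)))
  r1 <- rank_by_importance(fm1, w$train$label)
  r2 <- rank_by_importance(fm2, w$train$label)
  expect_equal(r1$mcc, r2$mcc, tolerance = 1e-12)
})
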