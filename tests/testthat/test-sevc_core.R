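test_that("train_stump reproduces hand-worked splits", {
  # separable: midpoint threshold, pure leaves
  st <- train_stump(c(0.1, 0.2, 0.8, 0.9), c(-1, -1, 1, 1))
  expect_equal(st$threshold, 0.5)
  expect_equal(stump_vote(st, c(0.0, 1.0)), c(-1, 1))

  # enumerated candidate splits 1.5/2.5/3.5 with weighted Gini
  # 1/3, 1/2, 1/3: tie broken toward the smallest threshold
  st <- train_stump(c(1, 2, 3, 4), c(-1, 1, -1, 1))
  expect_equal(st$threshold, 1.5)
  expect_equal(st$class_low, -1)
  expect_equal(st$prob_low, 1)
  expect_equal(st$class_high, 1)
  expect_equal(st$prob_high, 2 / 3)
  expect_equal(stump_vote(st, 3), 2 / 3)

  # feature exactly at the threshold falls in the low leaf
  expect_equal(stump_vote(st, 1.5), -1)

  # leaf majority tie defaults to insoluble
  st <- train_stump(c(0, 1, 1.5), c(-1, 1, -1))
  expect_equal(st$class_high, -1)

  # degenerate: single class / constant feature
  st1 <- train_stump(c(1, 2, 3), c(1, 1, 1))
  expect_equal(st1$threshold, -Inf)
  expect_equal(st1$class_low, 1)
  expect_equal(st1$prob_low, 1)
  st2 <- train_stump(c(2, 2, 2, 2), c(1, -1, 1, -1))
  expect_equal(st2$class_low, -1)   # tie -> insoluble
  expect_equal(st2$prob_low, 0.5)
})

test_that("train_stump equals exhaustive Gini minimization (oracle, n <= 12)", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    x <- round(runif(n), sample(c(1, 3), 1))  # some repeated values
    y <- sample(c(-1, 1), n, replace = TRUE)
    st <- train_stump(x, y)
    or <- brute_stump(x, y)
    # tie-breaking is exact in both paths, so full agreement is required
    expect_equal(st$threshold, or$threshold)
    expect_equal(st$class_low, or$class_low)
    expect_equal(st$class_high, or$class_high)
    expect_equal(st$prob_low, or$prob_low)
    expect_equal(st$prob_high, or$prob_high)
  }
})

test_that("mcc and accuracy follow the contingency identities", {
  expect_equal(mcc(contingency(rep(c(1, -1), c(5, 5)),
                               rep(c(1, -1), c(5, 5)))), 1)
  c0 <- structure(c(TP = 3, TN = 3, FP = 3, FN = 3), class = "contingency")
  expect_equal(mcc(c0), 0)
  c1 <- structure(c(TP = 4, TN = 3, FP = 1, FN = 2), class = "contingency")
  expect_equal(mcc(c1), 10 / sqrt(600))
  expect_equal(accuracy(c1), 7 / 10)
  expect_equal(accuracy(structure(c(TP = 1, TN = 1, FP = 1, FN = 1),
                                  class = "contingency")), 0.5)
  expect_error(mcc(structure(c(TP = 0, TN = 0, FP = 0, FN = 0),
                             class = "contingency")), "empty")

  # symmetry under simultaneous class swap, and accuracy + error = 1
  set.seed(5)
  for (i in 1:25) {
    v <- sample(0:6, 4, replace = TRUE)
    if (sum(v) == 0) v[1] <- 1
    cm <- structure(c(TP = v[1], TN = v[2], FP = v[3], FN = v[4]),
                    class = "contingency")
    sw <- structure(c(TP = v[2], TN = v[1], FP = v[4], FN = v[3]),
                    class = "contingency")
    expect_equal(mcc(cm), mcc(sw), tolerance = 1e-12)
    err <- (v[3] + v[4]) / sum(v)
    expect_equal(accuracy(cm) + err, 1, tolerance = 1e-12)
  }
})

test_that("ensemble_predict averages votes, applies modifier, discretizes", {
  s1 <- train_stump(c(0, 1), c(-1, 1), scale_name = "a")  # vote +1 at f = 1
  # mixed high leaf (1 pos, 1 neg, tie -> insoluble): vote -0.5 at f = 1
  s2 <- train_stump(c(0, 1, 1), c(1, -1, 1), scale_name = "b")
  expect_equal(stump_vote(s2, 1), -0.5)
  fm <- matrix(1, 1, 2, dimnames = list("x", c("a", "b")))
  m <- ensemble_model(list(s1, s2))
  out <- ensemble_predict(m, fm)
  expect_equal(out$p, (1 - 0.5) / 2)
  expect_equal(out$class, 1L)

  # p = 0 -> insoluble
  s3 <- train_stump(c(0, 1), c(1, -1), scale_name = "b")  # vote -1 at f = 1
  out0 <- ensemble_predict(ensemble_model(list(s1, s3)), fm)
  expect_equal(out0$p, 0)
  expect_equal(out0$class, -1L)

  # additive strategy modifier flips the decision
  mod <- modification_vector(c(H = -0.5))
  mH <- ensemble_model(list(s1, s2), modifier = mod)
  outH <- ensemble_predict(mH, fm, strategy_ids = "H")
  expect_equal(outH$p, 0.25 - 0.5)
  expect_equal(outH$class, -1L)
  outG <- ensemble_predict(mH, fm, strategy_ids = "G")  # unknown -> offset 0
  expect_equal(outG$p, 0.25)

  expect_error(ensemble_predict(m, fm[, 1, drop = FALSE]), "lacks")
})

test_that("rank_by_importance orders by training MCC with stable ties", {
  w <- small_world(noise_sd = 0)
  tab <- scale_table(list(w$truth$scale, random_scale(50, "noise")))
  fm <- build_feature_matrix(w$train, tab)
  r <- rank_by_importance(fm, w$train$label)
  expect_equal(r$scale[1], "ground_truth")
  expect_equal(r$mcc[1], 1)

  # oracle: per-scale brute-force stump MCC, stable sort
  set.seed(77)
  for (i in 1:50) {
    n <- sample(6:14, 1)
    k <- sample(2:4, 1)
    fm2 <- matrix(round(rnorm(n * k), 1), n, k,
                  dimnames = list(NULL, paste0("s", seq_len(k))))
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    got <- rank_by_importance(fm2, y)
    imp <- vapply(seq_len(k), function(j) {
      st <- brute_stump(fm2[, j], y)
      pred <- ifelse(fm2[, j] <= st$threshold, st$class_low, st$class_high)
      brute_mcc(sum(pred == 1 & y == 1), sum(pred == -1 & y == -1),
                sum(pred == 1 & y == -1), sum(pred == -1 & y == 1))
    }, numeric(1))
    ord <- order(-imp)
    expect_equal(got$scale, colnames(fm2)[ord])
    expect_equal(got$mcc, imp[ord], tolerance = 1e-9)
  }
})

test_that("mc_cv halves the training set, is deterministic, finds signal", {
  w <- paper_world(noise_sd = 0)
  tab <- scale_table(list(w$truth$scale, random_scale(3, "r")))
  res <- mc_cv(w$train, tab, n_runs = 10, seed = 4)
  expect_equal(nrow(w$train), 384L)
  for (run in res$runs) expect_length(run$vali, 192L)

  res2 <- mc_cv(w$train, tab, n_runs = 10, seed = 4)
  expect_identical(res$mcc, res2$mcc)
  expect_identical(lapply(res$runs, `[[`, "p"), lapply(res2$runs, `[[`, "p"))

  # separable world with the generating scale available: 1-stump model
  # must validate near-perfectly
  expect_gte(res$median_mcc[1], 0.9)
  expect_equal(select_model_size(res), 1L)
})

test_that("a label-independent scale validates at MCC ~ 0 (null property)", {
  w <- small_world(n_train = 40L)
  lab <- sevc:::with_seed(11, sample(w$train$label))
  tr <- w$train
  tr$label <- lab
  res <- mc_cv(tr, scale_table(list(random_scale(123, "n"))),
               n_runs = 200, seed = 2, keep_predictions = FALSE)
  expect_lt(abs(median(res$mcc[, 1])), 0.1)
})

test_that("duplicating an included scale leaves predictions unchanged", {
  w <- small_world()
  s <- random_scale(21, "s")
  dup <- toy_scale(as.numeric(s), name = "s_copy")
  fm1 <- build_feature_matrix(w$train, scale_table(list(s)))
  fm2 <- build_feature_matrix(w$train, scale_table(list(s, dup)))
  y <- w$train$label
  st1 <- train_stump(fm1[, "s"], y, "s")
  st2 <- train_stump(fm2[, "s_copy"], y, "s_copy")
  p1 <- ensemble_predict(ensemble_model(list(st1)), fm1)$p
  p2 <- ensemble_predict(ensemble_model(list(st1, st2)), fm2)$p
  expect_equal(p2, p1, tolerance = 1e-12)
  expect_true(all(abs(p2) <= 1))
})

test_that("select_model_size takes the argmax with smallest-size ties", {
  mk <- function(med) {
    structure(list(median_mcc = med, model_sizes = seq_along(med)),
              class = "mccv_result")
  }
  expect_equal(select_model_size(mk(c(0.2, 0.6, 0.5))), 2L)
  expect_equal(select_model_size(mk(c(0.6, 0.6))), 1L)
  expect_equal(select_model_size(mk(0.3)), 1L)
})
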