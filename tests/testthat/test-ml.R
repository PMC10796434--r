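test_that("model_spec carries the published defaults and audits overrides", {
  gbt <- model_spec("GBT")
  expect_equal(gbt$params$learning_rate, 0.28)
  expect_equal(gbt$params$n_estimators, 650L)
  expect_equal(gbt$params$min_samples_leaf, 120L)
  expect_equal(gbt$params$max_depth, 5L)
  expect_equal(model_spec("RF")$params$n_estimators, 300L)
  expect_equal(model_spec("RF")$params$min_samples_leaf, 85L)
  expect_equal(model_spec("LR")$params$C, 0.45)
  expect_equal(model_spec("LR")$params$max_iter, 500L)
  expect_equal(model_spec("SVM")$params$C, 0.42)
  expect_equal(model_spec("SVM")$params$kernel, "linear")
  expect_equal(gbt$class_weighting, "balanced")

  lr <- model_spec("LR", overrides = list(C = 1.0))
  expect_equal(lr$params$C, 1.0)
  expect_equal(lr$overrides, list(C = 1.0))
  expect_error(model_spec("LR", overrides = list(trees = 5)), "trees")
})

test_that("confusion_metrics matches the published unseen-set arithmetic", {
  # original-data model: 12 + 64 of 250 correct
  m1 <- confusion_metrics(tp = 12, fn = 2, tn = 64, fp = 172)
  expect_equal(m1$acc, 76 / 250)
  expect_equal(m1$fpr, 172 / 236)
  expect_equal(round(m1$acc, 2), 0.30)
  expect_equal(round(m1$fpr, 2), 0.73)
  # augmented-data model: 11 + 130 of 250 correct
  m2 <- confusion_metrics(tp = 11, fn = 3, tn = 130, fp = 106)
  expect_equal(m2$acc, 141 / 250)
  expect_equal(m2$fpr, 106 / 236)
  expect_equal(round(m2$acc, 2), 0.56)
  expect_equal(round(m2$fpr, 2), 0.45)

  perfect <- confusion_metrics(10, 0, 10, 0)
  expect_equal(perfect$acc, 1); expect_equal(perfect$tpr, 1)
  expect_equal(perfect$ppv, 1); expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1); expect_equal(perfect$fpr, 0)

  # undefined ratios are NA, not 0
  nop <- confusion_metrics(0, 0, 5, 5)
  expect_true(is.na(nop$ppv))
  expect_error(confusion_metrics(0, 0, 0, 0), "all-zero")

  # MCC equals the determinant formula on random tables
  set.seed(801)
  for (i in 1:25) {
    k <- sample(0:30, 4, replace = TRUE)
    if (sum(k) == 0) next
    m <- confusion_metrics(k[1], k[2], k[3], k[4])
    den <- sqrt(prod(c(k[1] + k[2], k[1] + k[4], k[3] + k[2],
                       k[3] + k[4])))
    ref <- if (den == 0) NA_real_
           else (k[1] * k[3] - k[2] * k[4]) / den
    expect_equal(m$mcc, ref, tolerance = 1e-12)
  }
})

test_that("roc_auc equals Mann-Whitney counting and is rank-invariant", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(1, 0), 5)), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")

  set.seed(802)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # with ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    got <- roc_auc(sc, lb)
    expect_equal(got, oracle_auc(sc, lb), tolerance = 1e-12)
    # invariant under strictly increasing transforms
    expect_equal(roc_auc(qlogis((sc + 0.5) / 2), lb), got,
                 tolerance = 1e-12)
  }
})

test_that("probability quartiles match a sorted-order oracle", {
  p <- seq(0.1, 1.0, by = 0.1)
  q <- probability_quartiles(p)
  ref <- unname(quantile(p, c(0.25, 0.5, 0.75)))
  expect_equal(c(q$q1, q$q2, q$q3), ref)
  expect_equal(q$iqr, ref[3] - ref[1])
  expect_equal(q$whisker_low, ref[1] - 1.5 * q$iqr)
  expect_equal(q$whisker_high, ref[3] + 1.5 * q$iqr)
  expect_true(q$q1 <= q$q2 && q$q2 <= q$q3)

  same <- probability_quartiles(rep(0.4, 7))
  expect_equal(same$q1, 0.4); expect_equal(same$q3, 0.4)
  expect_equal(probability_quartiles(numeric(0))$n, 0L)
})

test_that("crossval honors flags, seeds and the metric stream invariant", {
  sim <- small_sim(seed = 81)
  lab <- build_labeled_dataset(sim$synergy)
  dp <- hashed_drug_embedder(sim$library, dimension = 8, seed = 81)
  cp <- hashed_cell_embedder(dimension = 8, seed = 81)
  X <- featurize_dataset(lab, dp, cp)
  asg <- assign_folds(lab, "random_stratified", seed = 81)

  spec <- model_spec("LR", seed = 81)
  r1 <- crossval(lab, X, asg, spec)
  expect_equal(r1$dataset, "original")
  expect_equal(r1$protocol, "random_stratified")
  expect_equal(length(r1$per_fold) + length(r1$skipped_folds), 5L)
  # parameter audit: the report reproduces the effective hyperparameters
  expect_equal(r1$model$params, spec$params)
  # metrics recomputed from the confusion counts agree with the report
  for (pf in r1$per_fold) {
    m <- confusion_metrics(pf$confusion$tp, pf$confusion$fp,
                           pf$confusion$tn, pf$confusion$fn)
    for (nm in c("acc", "tpr", "fpr", "ppv", "mcc", "f1"))
      expect_equal(pf[[nm]], m[[nm]])
  }
  expect_true(all(r1$roc$tpr >= 0 & r1$roc$tpr <= 1))

  # determinism under a fixed seed
  r1b <- crossval(lab, X, asg, model_spec("LR", seed = 81))
  expect_equal(r1, r1b)
  rf <- crossval(lab, X, asg, model_spec("RF", seed = 81))
  rfb <- crossval(lab, X, asg, model_spec("RF", seed = 81))
  expect_equal(rf, rfb)

  # use_augmented = FALSE never touches augmented rows
  aug_raw <- augment_dataset(sim$synergy, sim$library, sim$target_map,
                             0.5, max_records = 200, seed = 81)
  aug <- build_labeled_dataset(aug_raw, origin = "augmented")
  Xa <- featurize_dataset(aug, dp, cp)
  r2 <- crossval(lab, X, asg, spec, augmented = aug,
                 augmented_features = Xa, use_augmented = FALSE)
  for (pf in r2$per_fold) expect_equal(pf$n_train_augmented, 0L)
  r3 <- crossval(lab, X, asg, spec, augmented = aug,
                 augmented_features = Xa, use_augmented = TRUE)
  expect_equal(r3$dataset, "augmented")
  expect_true(any(vapply(r3$per_fold, function(p)
    p$n_train_augmented, numeric(1)) > 0))
})

test_that("probability spectrum reports quartiles per rung and class", {
  sim <- small_sim(seed = 82)
  ladder <- build_threshold_ladder(sim$synergy)
  dp <- hashed_drug_embedder(sim$library, dimension = 8, seed = 82)
  cp <- hashed_cell_embedder(dimension = 8, seed = 82)
  lf <- lapply(ladder, featurize_dataset, dp, cp)
  spec <- model_spec("LR", seed = 82)
  sp <- probability_spectrum(spec, ladder$t20, lf$t20, ladder, lf)
  expect_equal(nrow(sp), 2L * length(ladder))
  ok <- !is.na(sp$q2)
  expect_true(all(sp$q1[ok] <= sp$q2[ok] & sp$q2[ok] <= sp$q3[ok]))
  expect_true(all(sp$q1[ok] >= 0 & sp$q3[ok] <= 1))
  # counts add up to the rung sizes
  for (nm in names(ladder))
    expect_equal(sum(sp$n[sp$dataset == nm]), nrow(ladder[[nm]]))
})
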