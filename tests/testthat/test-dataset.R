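test_that("label_instance honors boundary semantics", {
  expect_equal(as.character(label_instance(25)), "synergistic")
  expect_equal(as.character(label_instance(-25)), "antagonistic")
  expect_true(is.na(label_instance(0)))
  expect_true(is.na(label_instance(19.999)))
  expect_equal(as.character(label_instance(20)), "synergistic")   # inclusive
  expect_equal(as.character(label_instance(-20)), "antagonistic")
  # strict variant used by the t = 0 ladder rung
  expect_true(is.na(label_instance(0, 0, 0, inclusive = FALSE)))
  expect_equal(as.character(label_instance(0.1, 0, 0, inclusive = FALSE)),
               "synergistic")
  expect_error(label_instance(1, pos_threshold = -5, neg_threshold = 5),
               "exceed")
})

test_that("threshold ladder matches brute-force filtering and nests", {
  set.seed(601)
  recs <- synergy_table(data.frame(
    drug_a = sprintf("a%03d", 1:200), drug_b = sprintf("b%03d", 1:200),
    cell_line = "cl", tissue = "t",
    synergy_score = runif(200, -40, 40)))
  ladder <- build_threshold_ladder(recs)
  expect_named(ladder, c("t0", "t5", "t10", "t15", "t20"))
  for (t in c(0, 5, 10, 15, 20)) {
    ds <- ladder[[paste0("t", t)]]
    keep <- if (t == 0) recs$synergy_score > 0 | recs$synergy_score < 0
            else recs$synergy_score >= t | recs$synergy_score <= -t
    expect_equal(nrow(ds), sum(keep))
    s <- dataset_summary(ds)
    expect_equal(s$n_total, s$n_synergistic + s$n_antagonistic)
    expect_equal(s$synergistic_fraction,
                 100 * s$n_synergistic / s$n_total)
  }
  # nesting: each higher rung is a subset of the rung below
  key <- function(ds) paste(ds$drug_a, ds$drug_b, ds$cell_line,
                            ds$synergy_score)
  for (i in 2:5)
    expect_true(all(key(ladder[[i]]) %in% key(ladder[[i - 1]])))
  # a mildly positive score appears only in the t = 0 rung
  one <- synergy_table(data.frame(drug_a = "x", drug_b = "y",
                                  cell_line = "cl", tissue = "t",
                                  synergy_score = 3))
  l2 <- build_threshold_ladder(one)
  expect_equal(vapply(l2, nrow, integer(1)),
               c(t0 = 1L, t5 = 0L, t10 = 0L, t15 = 0L, t20 = 0L))
})

test_that("build_unseen_set equals an all-against-all TC scan", {
  train <- bit_library(list(tr1 = c(1, 2, 3, 4), tr2 = c(9, 10, 11, 12)))
  cand_bits <- list(near = c(1, 2, 3, 5),    # TC 0.6 to tr1 -> excluded
                    far1 = c(13, 14), far2 = c(15, 16))
  cand <- bit_library(cand_bits)
  recs <- synergy_table(data.frame(
    drug_a = c("near", "far1"), drug_b = c("far1", "far2"),
    cell_line = "cl", tissue = "t", synergy_score = c(30, -30)))
  out <- build_unseen_set(recs, cand, train)
  expect_equal(nrow(out), 1L)
  expect_equal(out$drug_a, "far1")

  # identical compound (TC 1.0) always excluded
  cand2 <- bit_library(list(tr1 = c(1, 2, 3, 4), far1 = c(13, 14)))
  recs2 <- synergy_table(data.frame(drug_a = "far1", drug_b = "tr1",
                                    cell_line = "cl", tissue = "t",
                                    synergy_score = 30))
  expect_equal(nrow(build_unseen_set(recs2, cand2, train)), 0L)

  # mixed random set vs brute-force oracle
  set.seed(602)
  tb <- lapply(1:6, function(i) sample(40, 8))
  names(tb) <- sprintf("t%02d", 1:6)
  qb <- lapply(1:30, function(i) sample(40, 8))
  names(qb) <- sprintf("q%02d", 1:30)
  tlib <- bit_library(tb, nbits = 40L)
  qlib <- bit_library(qb, nbits = 40L)
  qids <- names(qb)
  recs3 <- synergy_table(data.frame(
    drug_a = qids[1:15], drug_b = qids[16:30], cell_line = "cl",
    tissue = "t", synergy_score = rep(c(30, -30), length.out = 15)))
  unseen_drug <- vapply(qids, function(q) {
    all(vapply(names(tb), function(t)
      length(intersect(qb[[q]], tb[[t]])) /
        length(union(qb[[q]], tb[[t]])) < 0.4, logical(1)))
  }, logical(1))
  keep <- unseen_drug[recs3$drug_a] & unseen_drug[recs3$drug_b]
  out3 <- build_unseen_set(recs3, qlib, tlib)
  expect_equal(nrow(out3), sum(keep &
    !is.na(label_instance(recs3$synergy_score))))
})

test_that("random-stratified folds preserve class proportions", {
  lab <- factor(rep(c("synergistic", "antagonistic"), c(80, 20)),
                levels = c("synergistic", "antagonistic"))
  inst <- data.frame(drug_a = "a", drug_b = "b",
                     cell_line = sprintf("c%d", 1:100), tissue = "t")
  inst$label <- lab
  asg <- assign_folds(inst, "random_stratified", n_folds = 5, seed = 9)
  expect_equal(sort(unique(asg$fold)), 1:5)
  for (f in 1:5) {
    expect_equal(sum(asg$fold == f & lab == "synergistic"), 16L)
    expect_equal(sum(asg$fold == f & lab == "antagonistic"), 4L)
  }
  # determinism
  asg2 <- assign_folds(inst, "random_stratified", n_folds = 5, seed = 9)
  expect_identical(asg$fold, asg2$fold)
  expect_false(identical(
    assign_folds(inst, "random_stratified", n_folds = 5, seed = 10)$fold,
    asg$fold))
})

test_that("tissue-based folds partition tissues and reject unmapped ones", {
  sim <- small_sim(seed = 61)
  lab <- build_labeled_dataset(sim$synergy)
  grouping <- setNames(seq_along(unique(lab$tissue)), unique(lab$tissue))
  asg <- assign_folds(lab, "tissue_based", tissue_grouping = grouping)
  for (f in unique(asg$fold)) {
    val_t <- unique(lab$tissue[asg$fold == f])
    tr_t <- unique(lab$tissue[asg$fold != f])
    expect_length(intersect(val_t, tr_t), 0L)
  }
  expect_error(assign_folds(lab, "tissue_based",
                            tissue_grouping = grouping[-1]),
               names(grouping)[1])
})

test_that("augmented data attaches to training only, ratio-matched", {
  sim <- small_sim(seed = 62)
  lab <- build_labeled_dataset(sim$synergy)
  asg <- assign_folds(lab, "random_stratified", seed = 5)
  aug_raw <- augment_dataset(sim$synergy, sim$library, sim$target_map,
                             0.5, seed = 5)
  aug <- build_labeled_dataset(aug_raw, origin = "augmented")
  folds <- attach_augmented_to_training(lab, asg, aug, seed = 5)
  okey <- instance_key_test(lab$drug_a, lab$drug_b, lab$cell_line)
  for (f in seq_along(folds)) {
    fd <- folds[[f]]
    # validation contains only original instances
    expect_true(all(fd$validation$origin == "original"))
    # leakage guard: no augmented instance from a validation-fold parent
    if (!is.null(fd$train_augmented) && nrow(fd$train_augmented)) {
      pf <- asg$fold[match(
        instance_key_test(fd$train_augmented$parent_a,
                          fd$train_augmented$parent_b,
                          fd$train_augmented$cell_line), okey)]
      expect_true(all(pf != f, na.rm = TRUE))
      # per-fold class ratio within tolerance of the training originals
      p_ref <- mean(fd$train_original$label == "synergistic")
      p_aug <- mean(fd$train_augmented$label == "synergistic")
      expect_lt(abs(p_aug - p_ref), 0.01)
    }
  }
  # no augmented data -> plain CV
  plain <- attach_augmented_to_training(lab, asg, NULL)
  for (fd in plain) expect_null(fd$train_augmented)
})
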