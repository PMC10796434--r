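# Classifier harness: the four model families with their published default
# hyperparameters, both cross-validation protocols, confusion metrics, ROC
# machinery and the prediction-probability spectrum.
#
# Model fitting is delegated to scikit-learn through a subprocess bridge
# (inst/python/sklearn_bridge.py): the hyperparameter vocabulary of the
# defaults below (C, min_samples_leaf, max_features="sqrt", ...) is
# scikit-learn's, and fits are deterministic under a fixed random_state.
# All metrics, fold logic and leakage guards live in R.

MODEL_DEFAULTS <- list(
  LR = list(penalty = "l2", tol = 1e-4, C = 0.45, max_iter = 500L),
  SVM = list(C = 0.42, kernel = "linear", tol = 1e-3, probability = TRUE),
  RF = list(n_estimators = 300L, min_samples_leaf = 85L,
            max_features = "sqrt"),
  GBT = list(n_estimators = 650L, min_samples_leaf = 120L,
             max_features = "sqrt", learning_rate = 0.28, max_depth = 5L)
)

#' Specify a classifier
#'
#' Families and defaults: LR (L2 penalty, tol 1e-4, inverse regularization
#' strength C = 0.45, 500 iterations), SVM (C = 0.42, linear kernel, tol
#' 1e-3, calibrated probability outputs), RF (300 trees, min 85 samples per
#' leaf, sqrt features per split), GBT (650 stages, min 120 samples per
#' leaf, sqrt features, learning rate 0.28, depth 5).  Class weighting is
#' "balanced" by default for the imbalanced synergy data.  Any override is
#' recorded and echoed in every downstream report (parameter audit).
#'
#' @param family one of `"LR"`, `"SVM"`, `"RF"`, `"GBT"`.
#' @param overrides named list of hyperparameter overrides; unknown names
#'   are an error.
#' @param class_weighting `"balanced"` or `"none"`.
#' @param seed integer seed forwarded to the backend (`random_state`).
#' @return a `model_spec`.
#' @export
model_spec <- function(family = c("LR", "SVM", "RF", "GBT"),
                       overrides = list(),
                       class_weighting = c("balanced", "none"),
                       seed = 0L) {
  family <- match.arg(family)
  class_weighting <- match.arg(class_weighting)
  params <- MODEL_DEFAULTS[[family]]
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", family, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  params[names(overrides)] <- overrides
  structure(list(family = family, params = params,
                 overrides = overrides,
                 class_weighting = class_weighting,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s (class_weighting=%s, seed=%d)>\n",
              x$family, x$class_weighting, x$seed))
  for (nm in names(x$params)) {
    over <- if (nm %in% names(x$overrides)) "  [override]" else ""
    cat(sprintf("  %s = %s%s\n", nm, format(x$params[[nm]]), over))
  }
  invisible(x)
}

# ---- metrics ---------------------------------------------------------------

#' Classification metrics from a confusion matrix
#'
#' ACC, TPR (recall), FPR, PPV (precision), MCC and F1 from the standard
#' confusion definitions; ratios with a zero denominator are reported as
#' `NA` (undefined), never coerced to 0.  The positive class is
#' "synergistic" throughout the package.
#'
#' @param tp,fp,tn,fn confusion counts (all >= 0, not all zero).
#' @return list of metrics plus the `confusion` counts.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  if (sum(counts) == 0) stop("all-zero confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  ppv <- ratio(tp, tp + fp)
  tpr <- ratio(tp, tp + fn)
  f1 <- if (is.na(ppv) || is.na(tpr) || ppv + tpr == 0) NA_real_
        else 2 * ppv * tpr / (ppv + tpr)
  list(acc = (tp + tn) / sum(counts),
       tpr = tpr,
       fpr = ratio(fp, fp + tn),
       ppv = ppv,
       mcc = if (mcc_den == 0) NA_real_
             else (as.double(tp) * tn - as.double(fp) * fn) / mcc_den,
       f1 = f1,
       confusion = as.list(counts))
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with midranks for ties.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels logical/0-1 vector, TRUE/1 = positive class; both classes
#'   must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0 || nn == 0)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)  # midranks
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

# TPR values of the empirical ROC at fixed FPR grid points (step-function,
# right-continuous), used for vertical fold averaging.
roc_at_fpr <- function(scores, labels, fpr_grid) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  # collapse tied scores to one operating point
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, tp[last] / sum(lab))
  fpr <- c(0, fp[last] / sum(!lab))
  vapply(fpr_grid, function(g) max(tpr[fpr <= g]), numeric(1))
}

# ---- scikit-learn bridge ---------------------------------------------------

# Run a batch of fit/predict jobs through one python process.
# X: numeric feature matrix covering every referenced row.
# jobs: list of list(id, train = integer rows, test = integer rows,
#                    y = 0/1 labels aligned with train, seed).
# Returns: named list id -> numeric vector of positive-class probabilities
# aligned with the job's test rows.
sklearn_fit_predict <- function(spec, X, jobs) {
  stopifnot(inherits(spec, "model_spec"))
  td <- tempfile("dacsaug_skl_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  xfile <- file.path(td, "X.csv")
  utils::write.table(X, xfile, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  payload <- list(
    family = spec$family,
    params = spec$params,
    class_weight = if (spec$class_weighting == "balanced") "balanced"
                   else NULL,
    jobs = lapply(jobs, function(j) list(
      id = j$id, seed = j$seed %||% spec$seed,
      train = as.integer(j$train) - 1L,   # 0-based for numpy
      test = as.integer(j$test) - 1L,
      y = as.integer(j$y))))
  jfile <- file.path(td, "jobs.json")
  jsonlite::write_json(payload, jfile, auto_unbox = TRUE, digits = NA,
                       null = "null")
  ofile <- file.path(td, "probs.csv")
  res <- system2(dacsaug_python(),
                 c(bridge_script("sklearn_bridge.py"), xfile, jfile, ofile),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(ofile))
    stop("scikit-learn bridge failed:\n", paste(res, collapse = "\n"),
         call. = FALSE)
  out <- utils::read.csv(ofile, stringsAsFactors = FALSE,
                         colClasses = c("character", "integer", "numeric"))
  split_probs <- split(out, out$job_id)
  res <- lapply(jobs, function(j) {
    block <- split_probs[[j$id]]
    block$prob[match(as.integer(j$test) - 1L, block$row)]
  })
  stats::setNames(res, vapply(jobs, `[[`, "", "id"))
}

# ---- cross-validation ------------------------------------------------------

#' Cross-validate a classifier over a fold assignment
#'
#' Runs the per-fold train/validate loop with the augmented-data-in-
#' training-only rule: validation always contains only original instances,
#' and augmented instances derived from a validation-fold parent never
#' enter that fold's training set.  Per-fold seeds are `seed + fold` (a
#' declared counter scheme, so folds are independently reproducible).
#' Folds whose validation set contains a single class are skipped with a
#' warning and recorded.
#'
#' @param instances `labeled_instances` (original data).
#' @param features numeric matrix aligned with `instances`.
#' @param assignment a [assign_folds()] result.
#' @param spec a [model_spec()].
#' @param augmented labeled augmented instances (or NULL).
#' @param augmented_features matrix aligned with `augmented`.
#' @param use_augmented attach augmented data to training sets?
#' @param ratio_tolerance see [attach_augmented_to_training()].
#' @param decision_threshold probability at or above which an instance is
#'   called positive (default 0.5).
#' @param fpr_grid grid for vertical ROC averaging.
#' @return a `metrics_report`: per-fold metrics, means over folds
#'   (undefined metrics excluded with a recorded count), the mean ROC
#'   curve, the effective hyperparameters, protocol and dataset tags.
#' @export
crossval <- function(instances, features, assignment, spec,
                     augmented = NULL, augmented_features = NULL,
                     use_augmented = FALSE, ratio_tolerance = 0.005,
                     decision_threshold = 0.5,
                     fpr_grid = seq(0, 1, by = 0.01)) {
  stopifnot(nrow(features) == nrow(instances))
  if (use_augmented && (is.null(augmented) || is.null(augmented_features)))
    stop("use_augmented = TRUE needs augmented instances and features",
         call. = FALSE)
  aug <- if (use_augmented) augmented else NULL
  folds <- attach_augmented_to_training(instances, assignment, aug,
                                        ratio_tolerance,
                                        seed = spec$seed)
  n_orig <- nrow(instances)
  X <- if (use_augmented) rbind(features, augmented_features) else features
  aug_row <- function(df) n_orig + as.integer(rownames(df))
  if (use_augmented) rownames(augmented) <- seq_len(nrow(augmented))

  jobs <- list(); fold_meta <- list()
  for (f in seq_along(folds)) {
    fd <- folds[[f]]
    val_ix <- which(assignment$fold == f)
    if (length(unique(instances$label[val_ix])) < 2L) {
      warning("fold ", f, " skipped: single-class validation set",
              call. = FALSE)
      fold_meta[[f]] <- list(skipped = TRUE)
      next
    }
    train_ix <- which(assignment$fold != f)
    y <- as.integer(instances$label[train_ix] == "synergistic")
    if (use_augmented && !is.null(fd$train_augmented) &&
        nrow(fd$train_augmented)) {
      arows <- n_orig + match(
        instance_key(fd$train_augmented$drug_a, fd$train_augmented$drug_b,
                     fd$train_augmented$cell_line),
        instance_key(augmented$drug_a, augmented$drug_b,
                     augmented$cell_line))
      train_ix <- c(train_ix, arows)
      y <- c(y, as.integer(fd$train_augmented$label == "synergistic"))
    }
    jobs[[length(jobs) + 1L]] <- list(id = as.character(f),
                                      train = train_ix, test = val_ix,
                                      y = y, seed = spec$seed + f)
    fold_meta[[f]] <- list(skipped = FALSE, n_train = length(train_ix),
                           n_train_augmented = length(train_ix) -
                             sum(assignment$fold != f),
                           n_validation = length(val_ix))
  }
  if (!length(jobs))
    stop("no usable folds (all validation sets single-class)",
         call. = FALSE)
  probs <- sklearn_fit_predict(spec, X, jobs)

  per_fold <- list()
  roc_mat <- NULL
  for (j in jobs) {
    f <- as.integer(j$id)
    p <- probs[[j$id]]
    truth <- instances$label[j$test] == "synergistic"
    pred <- p >= decision_threshold
    m <- confusion_metrics(tp = sum(pred & truth),
                           fp = sum(pred & !truth),
                           tn = sum(!pred & !truth),
                           fn = sum(!pred & truth))
    m$auc <- roc_auc(p, truth)
    m$fold <- f
    m$n_train <- fold_meta[[f]]$n_train
    m$n_train_augmented <- fold_meta[[f]]$n_train_augmented
    per_fold[[length(per_fold) + 1L]] <- m
    roc_mat <- rbind(roc_mat, roc_at_fpr(p, truth, fpr_grid))
  }
  metric_names <- c("acc", "tpr", "fpr", "ppv", "auc", "mcc", "f1")
  vals <- sapply(metric_names, function(nm)
    vapply(per_fold, function(m) m[[nm]], numeric(1)))
  vals <- matrix(vals, nrow = length(per_fold),
                 dimnames = list(NULL, metric_names))
  mean_metrics <- colMeans(vals, na.rm = TRUE)
  n_undefined <- colSums(is.na(vals))
  structure(list(
    protocol = assignment$scheme,
    dataset = if (use_augmented) "augmented" else "original",
    model = list(family = spec$family, params = spec$params,
                 overrides = spec$overrides,
                 class_weighting = spec$class_weighting, seed = spec$seed,
                 decision_threshold = decision_threshold,
                 probability_note = if (spec$family == "SVM")
                   "SVM probabilities from internal Platt calibration"
                 else NULL),
    per_fold = per_fold,
    mean = as.list(mean_metrics),
    n_undefined = as.list(n_undefined),
    skipped_folds = which(vapply(fold_meta, function(x)
      isTRUE(x$skipped), logical(1))),
    roc = data.frame(fpr = fpr_grid, tpr = colMeans(roc_mat))),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report %s | %s | %s>\n", x$model$family,
              x$protocol, x$dataset))
  m <- x$mean
  cat(sprintf(
    "  mean over %d fold(s): ACC %.3f TPR %.3f FPR %.3f PPV %.3f AUC %.3f MCC %.3f F1 %.3f\n",
    length(x$per_fold), m$acc, m$tpr, m$fpr, m$ppv, m$auc, m$mcc, m$f1))
  if (length(x$skipped_folds))
    cat("  skipped folds:", paste(x$skipped_folds, collapse = ", "), "\n")
  invisible(x)
}

# ---- probability spectrum --------------------------------------------------

#' Quartiles of a probability sample (box-plot statistics)
#'
#' @param p numeric vector of probabilities in \[0, 1\].
#' @return list with `q1`, `q2`, `q3`, `iqr` and the whisker bounds
#'   Q1 - 1.5 IQR / Q3 + 1.5 IQR.
#' @export
probability_quartiles <- function(p) {
  if (!length(p)) return(list(q1 = NA_real_, q2 = NA_real_, q3 = NA_real_,
                              iqr = NA_real_, whisker_low = NA_real_,
                              whisker_high = NA_real_, n = 0L))
  q <- unname(stats::quantile(p, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  list(q1 = q[1], q2 = q[2], q3 = q[3], iqr = iqr,
       whisker_low = q[1] - 1.5 * iqr, whisker_high = q[3] + 1.5 * iqr,
       n = length(p))
}

#' Prediction-probability spectrum across the ambiguity ladder
#'
#' Trains one classifier on the reliable (t = 20) dataset and reports, for
#' each ladder dataset and each class, the quartiles of the predicted
#' positive-class probability.  As labels get more ambiguous (t -> 0) a
#' well-behaved model's confidence degrades, visible as wider interquartile
#' ranges.
#'
#' @param spec a [model_spec()] (the reference analysis uses GBT).
#' @param train_instances,train_features the t = 20 training data.
#' @param ladder named list of `labeled_instances` (see
#'   [build_threshold_ladder()]).
#' @param ladder_features named list of matrices aligned with `ladder`.
#' @return data.frame: one row per (ladder dataset, class) with quartile
#'   columns; empty datasets yield `NA` rows.
#' @export
probability_spectrum <- function(spec, train_instances, train_features,
                                 ladder, ladder_features) {
  stopifnot(identical(names(ladder), names(ladder_features)))
  X <- train_features
  offsets <- list(); test_rows <- integer(0)
  for (nm in names(ladder)) {
    lf <- ladder_features[[nm]]
    offsets[[nm]] <- nrow(X) + seq_len(nrow(lf))
    X <- rbind(X, lf)
  }
  y <- as.integer(train_instances$label == "synergistic")
  jobs <- list(list(id = "spectrum", train = seq_len(nrow(train_features)),
                    test = unlist(offsets, use.names = FALSE), y = y,
                    seed = spec$seed))
  p_all <- sklearn_fit_predict(spec, X, jobs)[["spectrum"]]
  pos <- 0L
  rows <- list()
  for (nm in names(ladder)) {
    k <- length(offsets[[nm]])
    p <- p_all[pos + seq_len(k)]; pos <- pos + k
    for (cls in c("synergistic", "antagonistic")) {
      q <- probability_quartiles(p[ladder[[nm]]$label == cls])
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = nm, class = cls, q1 = q$q1, q2 = q$q2, q3 = q$q3,
        iqr = q$iqr, whisker_low = q$whisker_low,
        whisker_high = q$whisker_high, n = q$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
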