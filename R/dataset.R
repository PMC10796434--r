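# Classification dataset construction: +/-20 labeling, the ambiguity ladder,
# the chemically-unseen external set, fold assignment for random-stratified
# and tissue-held-out cross-validation, and the augmented-data-in-training-
# only attachment rule.

#' Label a synergy score
#'
#' Scores at or above `pos_threshold` are synergistic, at or below
#' `neg_threshold` antagonistic, strictly between the two excluded (`NA`).
#' With `inclusive = FALSE` the comparisons are strict (used for the
#' threshold-0 ladder rung: score > 0 / score < 0).
#'
#' @param synergy_score numeric vector of synergy scores.
#' @param pos_threshold,neg_threshold class thresholds (defaults +/-20).
#' @param inclusive boundary semantics (default inclusive).
#' @return factor with levels `synergistic`, `antagonistic`; `NA` = excluded.
#' @export
label_instance <- function(synergy_score, pos_threshold = 20,
                           neg_threshold = -20, inclusive = TRUE) {
  if (pos_threshold < neg_threshold ||
      (pos_threshold == neg_threshold && inclusive))
    stop("pos_threshold must exceed neg_threshold", call. = FALSE)
  syn <- if (inclusive) synergy_score >= pos_threshold
         else synergy_score > pos_threshold
  ant <- if (inclusive) synergy_score <= neg_threshold
         else synergy_score < neg_threshold
  out <- rep(NA_character_, length(synergy_score))
  out[syn] <- "synergistic"
  out[ant] <- "antagonistic"
  factor(out, levels = c("synergistic", "antagonistic"))
}

#' Build a labeled dataset from synergy records
#'
#' @param records a `synergy_table` (or augmented records).
#' @param pos_threshold,neg_threshold,inclusive see [label_instance()].
#' @param origin `"original"` or `"augmented"`.
#' @return `labeled_instances` data.frame: record columns + `label` +
#'   `origin`, excluded (ambiguous) rows dropped.
#' @export
build_labeled_dataset <- function(records, pos_threshold = 20,
                                  neg_threshold = -20, inclusive = TRUE,
                                  origin = "original") {
  lab <- label_instance(records$synergy_score, pos_threshold, neg_threshold,
                        inclusive)
  out <- as.data.frame(records)[!is.na(lab), , drop = FALSE]
  out$label <- lab[!is.na(lab)]
  out$origin <- rep(origin, nrow(out))
  rownames(out) <- NULL
  structure(out, thresholds = c(positive = pos_threshold,
                                negative = neg_threshold),
            class = c("labeled_instances", "data.frame"))
}

#' Summarize a labeled dataset
#' @param instances a `labeled_instances` data.frame.
#' @return list with `n_total`, `n_synergistic`, `n_antagonistic`,
#'   `synergistic_fraction` (percent) and the thresholds used.
#' @export
dataset_summary <- function(instances) {
  n_syn <- sum(instances$label == "synergistic")
  n_ant <- sum(instances$label == "antagonistic")
  list(n_total = n_syn + n_ant, n_synergistic = n_syn,
       n_antagonistic = n_ant,
       synergistic_fraction = 100 * n_syn / (n_syn + n_ant),
       thresholds = attr(instances, "thresholds"))
}

#' Build the ambiguity-threshold ladder of datasets
#'
#' One labeled dataset per threshold t with classes at (+t, -t); the t = 0
#' rung uses strict inequalities (score > 0 / score < 0), all other rungs
#' are boundary-inclusive.
#'
#' @param records a `synergy_table`.
#' @param thresholds ascending non-negative thresholds
#'   (default `c(0, 5, 10, 15, 20)`).
#' @return named list of `labeled_instances` (names `"t0"`, `"t5"`, ...).
#' @export
build_threshold_ladder <- function(records,
                                   thresholds = c(0, 5, 10, 15, 20)) {
  if (any(thresholds < 0) || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be non-negative and ascending", call. = FALSE)
  out <- lapply(thresholds, function(t) {
    if (t == 0)
      build_labeled_dataset(records, 0, 0, inclusive = FALSE)
    else
      build_labeled_dataset(records, t, -t, inclusive = TRUE)
  })
  stats::setNames(out, paste0("t", thresholds))
}

#' Build a chemically-unseen evaluation set
#'
#' Keeps only candidate records in which BOTH drugs have Tanimoto
#' coefficient strictly below `tc_max` to EVERY training compound, then
#' labels them.
#'
#' @param candidates `synergy_table` of candidate external records.
#' @param candidate_library `drug_library` covering the candidate drugs.
#' @param training_library `drug_library` of the training compounds.
#' @param tc_max exclusion threshold (default 0.4: a candidate with
#'   TC >= 0.4 to any training compound is removed).
#' @param pos_threshold,neg_threshold label thresholds (defaults +/-20).
#' @return `labeled_instances` of surviving records.
#' @export
build_unseen_set <- function(candidates, candidate_library,
                             training_library, tc_max = 0.4,
                             pos_threshold = 20, neg_threshold = -20) {
  drugs <- unique(c(candidates$drug_a, candidates$drug_b))
  unseen <- vapply(drugs, function(d) {
    fp <- lib_fingerprint(candidate_library, d)
    all(vapply(training_library$fingerprint,
               function(tfp) tanimoto(fp, tfp) < tc_max, logical(1)))
  }, logical(1))
  names(unseen) <- drugs
  keep <- unseen[candidates$drug_a] & unseen[candidates$drug_b]
  build_labeled_dataset(candidates[keep, , drop = FALSE],
                        pos_threshold, neg_threshold)
}

#' Assign cross-validation folds
#'
#' `random_stratified`: seeded per-class shuffle followed by round-robin
#' assignment, so per-fold class proportions match the global proportions
#' within one instance.  `tissue_based`: fold = the group of the instance's
#' tissue under the supplied `tissue_grouping` map, so no tissue ever spans
#' two folds.
#'
#' @param instances `labeled_instances` (needs `label`; `tissue` for the
#'   tissue scheme).
#' @param scheme `"random_stratified"` or `"tissue_based"`.
#' @param n_folds fold count (default 5).
#' @param tissue_grouping named integer vector tissue -> fold id (required
#'   and must cover every observed tissue for the tissue scheme).
#' @param seed integer seed (random scheme).
#' @return a `fold_assignment` list: `scheme`, `n_folds`, `fold` (integer
#'   vector aligned with `instances`), `tissue_groups` (tissue scheme).
#' @export
assign_folds <- function(instances,
                         scheme = c("random_stratified", "tissue_based"),
                         n_folds = 5L, tissue_grouping = NULL, seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(instances)
  fold <- integer(n)
  tissue_groups <- NULL
  if (scheme == "random_stratified") {
    local_seed(seed, {
      for (ix in split(seq_len(n), instances$label)) {
        if (!length(ix)) next
        fold[sample(ix)] <- rep_len(seq_len(n_folds), length(ix))
      }
    })
  } else {
    if (is.null(tissue_grouping))
      stop("tissue_based scheme needs a tissue_grouping map", call. = FALSE)
    unmapped <- setdiff(unique(instances$tissue), names(tissue_grouping))
    if (length(unmapped))
      stop("tissue(s) without fold group: ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    fold <- as.integer(tissue_grouping[instances$tissue])
    n_folds <- max(tissue_grouping)
    tissue_groups <- split(names(tissue_grouping),
                           as.integer(tissue_grouping))
  }
  structure(list(scheme = scheme, n_folds = as.integer(n_folds),
                 fold = fold, tissue_groups = tissue_groups, seed = seed),
            class = "fold_assignment")
}

instance_key <- function(drug_a, drug_b, cell_line) {
  swap <- drug_a > drug_b
  a <- ifelse(swap, drug_b, drug_a); b <- ifelse(swap, drug_a, drug_b)
  paste(a, b, cell_line, sep = "\r")
}

# Fold of each augmented record = fold of its parent original instance
# (first match on canonical parent pair + cell line); NA when no parent is
# present in the assignment.
augmented_parent_fold <- function(instances, assignment, augmented) {
  okey <- instance_key(instances$drug_a, instances$drug_b,
                       instances$cell_line)
  pkey <- instance_key(augmented$parent_a, augmented$parent_b,
                       augmented$cell_line)
  assignment$fold[match(pkey, okey)]
}

#' Per-fold training sets with augmented data attached
#'
#' For each fold, training = original instances of the other folds plus
#' augmented instances derived from parents in those folds; augmented
#' instances whose parent sits in the held-out fold are excluded (leakage
#' guard), and validation sets contain only original instances.  The
#' attached augmented subset is subsampled so its synergistic:antagonistic
#' ratio matches the fold's original-training ratio within
#' `ratio_tolerance`.
#'
#' @param instances `labeled_instances` (original data).
#' @param assignment a [assign_folds()] result for `instances`.
#' @param augmented labeled augmented instances (needs `label`, `parent_a`,
#'   `parent_b`, `cell_line`), or NULL for plain CV.
#' @param ratio_tolerance class-fraction tolerance (default 0.005).
#' @param seed seed for the ratio-matching subsample.
#' @return list of `n_folds` elements, each
#'   `list(train_original, train_augmented, validation)`.
#' @export
attach_augmented_to_training <- function(instances, assignment,
                                         augmented = NULL,
                                         ratio_tolerance = 0.005,
                                         seed = 1L) {
  parent_fold <- if (!is.null(augmented) && nrow(augmented))
    augmented_parent_fold(instances, assignment, augmented) else integer(0)
  lapply(seq_len(assignment$n_folds), function(f) {
    tr <- assignment$fold != f
    train_orig <- instances[tr, , drop = FALSE]
    validation <- instances[!tr, , drop = FALSE]
    train_aug <- NULL
    if (!is.null(augmented) && nrow(augmented)) {
      ok <- !is.na(parent_fold) & parent_fold != f
      pool <- augmented[ok, , drop = FALSE]
      train_aug <- match_class_ratio(pool, train_orig$label,
                                     ratio_tolerance,
                                     seed = seed + f)
    }
    list(train_original = train_orig, train_augmented = train_aug,
         validation = validation)
  })
}

# Subsample `pool` (labeled) so that its class fraction matches that of
# `ref_labels` within `tol`; keeps as many rows as possible.
match_class_ratio <- function(pool, ref_labels, tol = 0.005, seed = 1L) {
  if (is.null(pool) || !nrow(pool)) return(pool)
  p <- mean(ref_labels == "synergistic")
  syn_ix <- which(pool$label == "synergistic")
  ant_ix <- which(pool$label == "antagonistic")
  ns <- length(syn_ix); na_ <- length(ant_ix)
  if (p <= 0 || p >= 1) {
    keep <- if (p >= 1) syn_ix else ant_ix
    return(pool[keep, , drop = FALSE])
  }
  # largest (k_syn, k_ant) with k_syn/(k_syn+k_ant) ~= p
  k_ant <- min(na_, floor(ns * (1 - p) / p))
  k_syn <- min(ns, round(k_ant * p / (1 - p)))
  if (k_syn + k_ant == 0L) return(pool[integer(0), , drop = FALSE])
  got <- k_syn / (k_syn + k_ant)
  if (abs(got - p) > tol)
    warning(sprintf(
      "augmented class fraction %.4f misses target %.4f (tolerance %g)",
      got, p, tol), call. = FALSE)
  keep <- local_seed(seed, c(
    if (k_syn > 0) sample(syn_ix, k_syn) else integer(0),
    if (k_ant > 0) sample(ant_ix, k_ant) else integer(0)))
  out <- pool[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
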