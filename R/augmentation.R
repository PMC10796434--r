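# Threshold selection and the substitution engine.
#
# Augmentation replaces exactly one drug of a synergy record with a library
# molecule whose DACS to the replaced drug clears a cutoff; the synergy
# score (hence the class) is transferred from the parent record.  The
# cutoff is picked where the fidelity curve (fraction of drug pairs with
# positive tau-b above the threshold) crosses the max-normalized coverage
# curve (number of available substitutes above the threshold).

#' Build fidelity and coverage curves over a DACS threshold grid
#'
#' @param pair_scores data.frame with `dacs` and `tau_b` columns (drug-pair
#'   similarity vs pharmacological agreement).
#' @param candidate_dacs numeric vector of DACS values of all
#'   (query drug, candidate substitute) pairs under consideration; coverage
#'   at threshold t is `sum(candidate_dacs >= t)`.
#' @param grid ascending threshold grid (default 0 to 1.41 step 0.01).
#' @return a `threshold_curves` data.frame with columns `grid`, `fidelity`,
#'   `coverage`, `coverage_norm`.
#' @export
build_threshold_curves <- function(pair_scores, candidate_dacs,
                                   grid = seq(0, 1.41, by = 0.01)) {
  if (is.null(nrow(pair_scores)) || nrow(pair_scores) == 0L)
    stop("empty pair_scores", call. = FALSE)
  if (!length(grid) || is.unsorted(grid, strictly = TRUE))
    stop("grid must be non-empty and strictly ascending", call. = FALSE)
  fidelity <- vapply(grid, function(t)
    fraction_positive_tau(pair_scores, t), numeric(1))
  coverage <- vapply(grid, function(t)
    sum(candidate_dacs >= t), numeric(1))
  cmax <- max(coverage)
  out <- data.frame(grid = grid, fidelity = fidelity, coverage = coverage,
                    coverage_norm = if (cmax > 0) coverage / cmax
                                    else coverage)
  structure(out, class = c("threshold_curves", "data.frame"))
}

#' Select the DACS augmentation cutoff from threshold curves
#'
#' The crossing abscissa of the (non-decreasing) fidelity curve and the
#' (non-increasing) max-normalized coverage curve, linearly interpolated
#' between adjacent grid points; an exact grid-point crossing returns that
#' point.  Grid points where fidelity is undefined (no qualifying pair) are
#' discarded before validation.
#'
#' @param curves a `threshold_curves` object.
#' @param tol slack allowed when validating curve monotonicity.
#' @param smooth apply isotonic (non-decreasing) regression to the
#'   empirical fidelity curve before validating?  Default FALSE: raw
#'   empirical fidelity curves on noisy data are not guaranteed monotone
#'   and are rejected as such.
#' @return the selected threshold (scalar).
#' @export
select_dacs_threshold <- function(curves, tol = 1e-9, smooth = FALSE) {
  ok <- !is.na(curves$fidelity)
  g <- curves$grid[ok]; f <- curves$fidelity[ok]; c_ <- curves$coverage_norm[ok]
  if (smooth) f <- stats::isoreg(g, f)$yf
  if (length(g) < 2L)
    stop("fewer than two grid points with defined fidelity", call. = FALSE)
  if (any(diff(f) < -tol))
    stop("fidelity curve is not non-decreasing over the grid", call. = FALSE)
  if (any(diff(c_) > tol))
    stop("normalized coverage curve is not non-increasing over the grid",
         call. = FALSE)
  h <- f - c_
  exact <- which(abs(h) <= tol)
  if (length(exact)) return(g[exact[1]])
  cross <- which(h[-1] > 0 & h[-length(h)] < 0)
  if (!length(cross)) {
    stop("fidelity and coverage curves never cross on the grid; ",
         "extend the grid", call. = FALSE)
  }
  i <- cross[1]
  g[i] + (g[i + 1] - g[i]) * (0 - h[i]) / (h[i + 1] - h[i])
}

#' Candidate substitutes for one drug
#'
#' All library molecules (excluding the query itself) whose DACS to the
#' query reaches `cutoff`, sorted by descending DACS with ties broken by
#' drug id.
#'
#' @param drug_id query drug id; must be present in `query_library` (or in
#'   `library` if `query_library` is NULL).
#' @param library candidate `drug_library` searched for substitutes.
#' @param target_map optional `target_map` used for the MCC component
#'   (absent target data contributes 0).
#' @param cutoff DACS cutoff in \[0, sqrt(2)\].
#' @param query_library optional separate library holding the query drug's
#'   fingerprint (defaults to `library`).
#' @return data.frame with `drug_id`, `dacs`.
#' @export
candidate_substitutes <- function(drug_id, library, target_map = NULL,
                                  cutoff, query_library = NULL) {
  if (cutoff < 0 || cutoff > sqrt(2) + 1e-12)
    stop("cutoff must lie in [0, sqrt(2)]", call. = FALSE)
  query_library <- query_library %||% library
  fp_q <- lib_fingerprint(query_library, drug_id)
  tq <- if (is.null(target_map)) character(0) else
    targets_of(target_map, drug_id)
  cand <- library$drug_id[library$drug_id != drug_id]
  if (!length(cand))
    return(data.frame(drug_id = character(0), dacs = numeric(0)))
  sc <- vapply(cand, function(cd) {
    tc <- tanimoto(fp_q, lib_fingerprint(library, cd))
    mcc <- if (is.null(target_map)) 0 else
      target_mcc(tq, targets_of(target_map, cd), target_map)
    dacs(tc, mcc)
  }, numeric(1))
  keep <- sc >= cutoff
  out <- data.frame(drug_id = cand[keep], dacs = unname(sc[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$dacs, out$drug_id), , drop = FALSE]
}

#' Augment a single synergy record by single-drug substitution
#'
#' One augmented record per candidate per slot: substitutes for `drug_a`
#' keep `drug_b` fixed and vice versa.  A candidate equal to the untouched
#' partner is dropped (no self-pairs); results are deduplicated on
#' (canonical pair, cell line).  Synergy score, cell line and tissue are
#' copied from the parent, so the class label is transferred.
#'
#' @param record one-row `synergy_table` (or equivalent list/row).
#' @param candidates_a,candidates_b data.frames from
#'   [candidate_substitutes()] for `drug_a` and `drug_b` (already
#'   cutoff-filtered).
#' @return data.frame of augmented records (see [write_augmented_table()]
#'   for the column contract).
#' @export
augment_pair <- function(record, candidates_a, candidates_b) {
  one_slot <- function(cands, slot) {
    if (is.null(cands) || !nrow(cands)) return(NULL)
    fixed <- if (slot == "first") record$drug_b else record$drug_a
    keep <- cands$drug_id != fixed
    if (!any(keep)) return(NULL)
    cands <- cands[keep, , drop = FALSE]
    new_a <- if (slot == "first") cands$drug_id else
      rep(record$drug_a, nrow(cands))
    new_b <- if (slot == "first") rep(record$drug_b, nrow(cands)) else
      cands$drug_id
    data.frame(drug_a = new_a, drug_b = new_b,
               cell_line = record$cell_line, tissue = record$tissue,
               synergy_score = record$synergy_score,
               parent_a = record$drug_a, parent_b = record$drug_b,
               substituted_slot = slot, substitute_id = cands$drug_id,
               dacs_to_parent = cands$dacs, stringsAsFactors = FALSE)
  }
  out <- rbind(one_slot(candidates_a, "first"),
               one_slot(candidates_b, "second"))
  if (is.null(out))
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      cell_line = character(0), tissue = character(0),
                      synergy_score = numeric(0), parent_a = character(0),
                      parent_b = character(0),
                      substituted_slot = character(0),
                      substitute_id = character(0),
                      dacs_to_parent = numeric(0),
                      stringsAsFactors = FALSE))
  out <- canonicalize_pairs(out)
  key <- paste(out$drug_a, out$drug_b, out$cell_line, sep = "\r")
  # within a single parent the score is constant; keep the best-DACS copy
  out <- out[order(-out$dacs_to_parent, out$parent_a, out$parent_b), ,
             drop = FALSE]
  out <- out[!duplicated(paste(out$drug_a, out$drug_b, out$cell_line,
                               sep = "\r")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Augment a whole synergy dataset
#'
#' Union of [augment_pair()] over all records, globally deduplicated on
#' (canonical pair, cell line): collisions are resolved in favour of the
#' record with the highest DACS to its substitute, ties by lexicographic
#' parent order.  Augmented keys that coincide with an original record are
#' dropped.  When `max_records` caps the output, classes (labelled at
#' `pos_threshold`/`neg_threshold`) are subsampled proportionally so the
#' synergistic:antagonistic ratio matches the full augmented pool within
#' `ratio_tolerance`; sampling is deterministic under `seed`.
#'
#' @param records a `synergy_table`.
#' @param library candidate `drug_library` (must also cover the original
#'   drugs, or pass `query_library`).
#' @param target_map optional `target_map`.
#' @param cutoff DACS cutoff (see [select_dacs_threshold()]).
#' @param max_records optional size cap (default unlimited).
#' @param ratio_tolerance allowed class-fraction deviation when capping
#'   (default 0.005).
#' @param pos_threshold,neg_threshold score thresholds defining the classes
#'   used for proportional capping (defaults +/-20).
#' @param seed integer seed for the capped subsample.
#' @param query_library optional library holding the original drugs'
#'   fingerprints.
#' @return data.frame of augmented records; attribute `seed` records the
#'   subsampling seed.
#' @export
augment_dataset <- function(records, library, target_map = NULL, cutoff,
                            max_records = Inf, ratio_tolerance = 0.005,
                            pos_threshold = 20, neg_threshold = -20,
                            seed = 1L, query_library = NULL) {
  query_library <- query_library %||% library
  drugs <- unique(c(records$drug_a, records$drug_b))
  cands <- lapply(stats::setNames(drugs, drugs), function(d)
    candidate_substitutes(d, library, target_map, cutoff,
                          query_library = query_library))
  pieces <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, , drop = FALSE]
    augment_pair(r, cands[[r$drug_a]], cands[[r$drug_b]])
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || !nrow(out)) {
    warning("no augmented instances at cutoff ", cutoff, call. = FALSE)
    return(augment_pair(records[0, ], NULL, NULL))
  }
  # global dedup: best DACS wins, tie -> lexicographic parent order
  out <- out[order(-out$dacs_to_parent, out$parent_a, out$parent_b), ,
             drop = FALSE]
  out <- out[!duplicated(paste(out$drug_a, out$drug_b, out$cell_line,
                               sep = "\r")), , drop = FALSE]
  orig_key <- paste(records$drug_a, records$drug_b, records$cell_line,
                    sep = "\r")
  out <- out[!(paste(out$drug_a, out$drug_b, out$cell_line, sep = "\r")
               %in% orig_key), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > max_records) {
    lab <- label_instance(out$synergy_score, pos_threshold, neg_threshold)
    strata <- ifelse(is.na(lab), "ambiguous", as.character(lab))
    groups <- split(seq_len(nrow(out)), strata)
    frac <- max_records / nrow(out)
    # largest-remainder apportionment: per-stratum quota floor(n * frac),
    # leftovers to the largest fractional remainders
    exact <- vapply(groups, length, integer(1)) * frac
    quota <- floor(exact)
    left <- as.integer(round(max_records - sum(quota)))
    if (left > 0) {
      bump <- order(exact - quota, decreasing = TRUE)[seq_len(left)]
      quota[bump] <- quota[bump] + 1L
    }
    take <- local_seed(seed, {
      unlist(Map(function(ix, k) if (k == 0L) integer(0)
                 else sample(ix, min(k, length(ix))),
                 groups, quota), use.names = FALSE)
    })
    kept <- sort(take)
    new_frac <- mean(strata[kept] == "synergistic")
    old_frac <- mean(strata == "synergistic")
    # tolerance cannot beat the sampling granularity of the cap
    slack <- max(ratio_tolerance, 1 / length(kept))
    if (abs(new_frac - old_frac) > slack)
      warning(sprintf(
        "capped class fraction %.4f deviates from source %.4f by more than %g",
        new_frac, old_frac, slack), call. = FALSE)
    out <- out[kept, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "seed") <- seed
  out
}
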