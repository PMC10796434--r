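# Pairwise drug similarity: chemistry (Tanimoto over fingerprint bits),
# mechanism of action (Matthews correlation of target-set membership over a
# fixed protein universe), pharmacology (Kendall tau-b over shared
# monotherapy pIC50 profiles), and their combination, the drug
# action/chemical similarity (DACS) score
#
#   DACS = sqrt(TC^2 + max(MCC, 0)^2)
#
# so DACS lives in [0, sqrt(2)] and a negative mechanism correlation never
# reduces a chemical match.

#' Concordance bookkeeping for Kendall tau-b
#'
#' Counts over all C(m,2) index pairs of two equal-length vectors:
#' concordant (`n_c`), discordant (`n_d`), tied only in the first list
#' (`n_1`), tied only in the second (`n_2`), and tied in both (`n_12`,
#' excluded from `n_1`/`n_2`).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `n_c`, `n_d`, `n_1`, `n_2`, `n_12`.
#' @export
concordance_counts <- function(x, y) {
  stopifnot(length(x) == length(y))
  m <- length(x)
  if (m < 2L) return(list(n_c = 0L, n_d = 0L, n_1 = 0L, n_2 = 0L, n_12 = 0L))
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  tx <- dx[up] == 0; ty <- dy[up] == 0
  list(n_c = sum(s > 0), n_d = sum(s < 0),
       n_1 = sum(tx & !ty), n_2 = sum(!tx & ty), n_12 = sum(tx & ty))
}

#' Kendall tau-b between two monotherapy profiles
#'
#' Computed over the intersection of cell lines only, with the tie-corrected
#' denominator \eqn{\sqrt{(n_c+n_d+n_1)(n_c+n_d+n_2)}}.  By contract the
#' coefficient is 0 when fewer than two cell lines are shared, or when the
#' denominator vanishes (all values tied in either profile): unusable data
#' means "no association".
#'
#' @param profile_a,profile_b named numeric vectors (cell line -> pIC50).
#' @return list with `tau_b` and `n_common`.
#' @export
kendall_tau_b <- function(profile_a, profile_b) {
  common <- intersect(names(profile_a), names(profile_b))
  n <- length(common)
  if (n < 2L) return(list(tau_b = 0, n_common = n))
  x <- as.numeric(profile_a[common]); y <- as.numeric(profile_b[common])
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("pIC50 values must be finite", call. = FALSE)
  cc <- concordance_counts(x, y)
  den <- sqrt((cc$n_c + cc$n_d + cc$n_1) * (cc$n_c + cc$n_d + cc$n_2))
  tau <- if (den == 0) 0 else (cc$n_c - cc$n_d) / den
  list(tau_b = tau, n_common = n)
}

#' Mechanism-of-action similarity: target-set Matthews correlation
#'
#' With T = proteins targeted by both drugs, N = by neither, A = only by the
#' first, B = only by the second (T + N + A + B = universe size):
#' \deqn{MCC = (TN - AB) / \sqrt{(T+A)(T+B)(N+A)(N+B)}}
#' Zero is returned when any denominator factor vanishes (e.g. an empty
#' target set).
#'
#' @param targets_a,targets_b character vectors of protein ids.
#' @param universe protein universe: a count, a character roster, or a
#'   `target_map` (whose universe is used).
#' @return MCC in \[-1, 1\].
#' @export
target_mcc <- function(targets_a, targets_b, universe) {
  if (inherits(universe, "target_map"))
    universe <- universe$universe %||% universe$universe_size
  targets_a <- unique(as.character(targets_a))
  targets_b <- unique(as.character(targets_b))
  if (is.character(universe)) {
    out <- setdiff(c(targets_a, targets_b), universe)
    if (length(out))
      stop("protein(s) not in universe: ",
           paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
    n_univ <- length(unique(universe))
  } else {
    assert_scalar_number(universe, "universe")
    n_univ <- as.integer(universe)
  }
  T_ <- length(intersect(targets_a, targets_b))
  A_ <- length(setdiff(targets_a, targets_b))
  B_ <- length(setdiff(targets_b, targets_a))
  N_ <- n_univ - T_ - A_ - B_
  if (N_ < 0)
    stop("target sets exceed the declared universe size", call. = FALSE)
  den <- sqrt(as.double(T_ + A_)) * sqrt(as.double(T_ + B_)) *
    sqrt(as.double(N_ + A_)) * sqrt(as.double(N_ + B_))
  if (den == 0) return(0)
  # guard the quotient against floating-point drift past +/-1
  min(1, max(-1, (as.double(T_) * N_ - as.double(A_) * B_) / den))
}

#' Tanimoto coefficient between two fingerprints
#'
#' |intersection| / |union| over set bits; 0 when both fingerprints are
#' all-zero (by contract).  Fingerprints must have equal bit length.
#'
#' @param fp_a,fp_b [new_fingerprint()] objects.
#' @return TC in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (!identical(fp_nbits(fp_a), fp_nbits(fp_b)))
    stop("fingerprint length mismatch (", fp_nbits(fp_a), " vs ",
         fp_nbits(fp_b), ")", call. = FALSE)
  a <- unclass(fp_a); b <- unclass(fp_b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Drug action/chemical similarity (DACS)
#'
#' \deqn{DACS = \sqrt{TC^2 + \max(MCC, 0)^2}}
#' The rare negative MCC is clamped to 0 so a dissimilar mechanism never
#' penalizes a chemical match.
#'
#' @param tc Tanimoto coefficient(s) in \[0, 1\].
#' @param mcc target MCC value(s) in \[-1, 1\].
#' @return DACS in \[0, sqrt(2)\]; vectorized.
#' @export
dacs <- function(tc, mcc) {
  if (any(!is.finite(tc)) || any(tc < 0 | tc > 1))
    stop("tc must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(mcc)) || any(mcc < -1 | mcc > 1))
    stop("mcc must lie in [-1, 1]", call. = FALSE)
  sqrt(tc^2 + pmax(mcc, 0)^2)
}

#' All-pairs similarity table for a drug library
#'
#' One row per unordered drug pair (self-pairs never scored) with `tc`,
#' `mcc`, `tau_b`, `n_common_cells` and `dacs`.  Missing target or response
#' data degrade gracefully: MCC defaults to 0 (no mechanism evidence) and
#' tau_b to 0 (fewer than two shared cell lines).
#'
#' @param library a `drug_library`.
#' @param target_map optional `target_map`.
#' @param responses optional `response_matrix`.
#' @return data.frame of pair scores.
#' @export
drug_pair_similarity <- function(library, target_map = NULL,
                                 responses = NULL) {
  ids <- library$drug_id
  if (length(ids) < 2L)
    stop("need at least two drugs to score pairs", call. = FALSE)
  profiles <- NULL
  if (!is.null(responses))
    profiles <- lapply(stats::setNames(ids, ids),
                       function(d) response_profile(responses, d))
  idx <- utils::combn(length(ids), 2)
  n <- ncol(idx)
  tc <- mcc <- tau <- numeric(n); ncc <- integer(n)
  for (k in seq_len(n)) {
    i <- idx[1, k]; j <- idx[2, k]
    tc[k] <- tanimoto(library$fingerprint[[i]], library$fingerprint[[j]])
    mcc[k] <- if (is.null(target_map)) 0 else
      target_mcc(targets_of(target_map, ids[i]),
                 targets_of(target_map, ids[j]), target_map)
    if (!is.null(profiles)) {
      kt <- kendall_tau_b(profiles[[ids[i]]], profiles[[ids[j]]])
      tau[k] <- kt$tau_b; ncc[k] <- kt$n_common
    }
  }
  data.frame(drug_a = ids[idx[1, ]], drug_b = ids[idx[2, ]],
             tc = tc, mcc = mcc, tau_b = tau, n_common_cells = ncc,
             dacs = dacs(tc, mcc), stringsAsFactors = FALSE)
}

#' Fraction of drug pairs with positive Kendall tau-b above a similarity
#' threshold
#'
#' Among pairs with `similarity >= threshold` (inclusive), the fraction with
#' `tau_b > 0` (strictly; tau_b = 0 counts as not positive).  `NA` when no
#' pair qualifies.
#'
#' @param pair_scores data.frame with a similarity column and `tau_b`.
#' @param threshold similarity threshold.
#' @param sim_col similarity column name (default `"dacs"`).
#' @return fraction in \[0, 1\], or `NA_real_` for an empty selection.
#' @export
fraction_positive_tau <- function(pair_scores, threshold,
                                  sim_col = "dacs") {
  sim <- pair_scores[[sim_col]]
  if (is.null(sim)) stop("no column '", sim_col, "' in pair_scores",
                         call. = FALSE)
  if (any(!is.finite(sim)) || any(!is.finite(pair_scores$tau_b)))
    stop("similarities and tau values must be finite", call. = FALSE)
  sel <- sim >= threshold
  if (!any(sel)) return(NA_real_)
  mean(pair_scores$tau_b[sel] > 0)
}

#' Binned fraction of positive tau-b over the (TC, MCC) plane
#'
#' Grid of per-cell fractions of `tau_b > 0` among pairs falling in each
#' (tc, mcc) bin; empty cells are `NA`.  TC bins partition \[0, 1\] and MCC
#' bins partition \[-1, 1\], right-closed at the top edge.
#'
#' @param pair_scores data.frame with `tc`, `mcc`, `tau_b`.
#' @param tc_bins,mcc_bins bin counts (>= 1).
#' @return matrix (`tc_bins` rows x `mcc_bins` cols) with break attributes.
#' @export
similarity_heatmap <- function(pair_scores, tc_bins = 10L, mcc_bins = 10L) {
  stopifnot(tc_bins >= 1L, mcc_bins >= 1L)
  tc_breaks <- seq(0, 1, length.out = tc_bins + 1L)
  mcc_breaks <- seq(-1, 1, length.out = mcc_bins + 1L)
  ti <- findInterval(pair_scores$tc, tc_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  mi <- findInterval(pair_scores$mcc, mcc_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  grid <- matrix(NA_real_, nrow = tc_bins, ncol = mcc_bins)
  pos <- pair_scores$tau_b > 0
  for (cell in split(seq_along(ti), paste(ti, mi))) {
    grid[ti[cell[1]], mi[cell[1]]] <- mean(pos[cell])
  }
  attr(grid, "tc_breaks") <- tc_breaks
  attr(grid, "mcc_breaks") <- mcc_breaks
  grid
}
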