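test_that("threshold curves equal independent per-threshold tallies", {
  expect_error(build_threshold_curves(data.frame(), 1, seq(0, 1, 0.5)),
               "empty")
  set.seed(501)
  ps <- data.frame(dacs = runif(500, 0, sqrt(2)),
                   tau_b = runif(500, -1, 1))
  cand <- runif(300, 0, sqrt(2))
  grid <- seq(0, 1.41, by = 0.05)
  cv <- build_threshold_curves(ps, cand, grid)
  for (k in seq_along(grid)) {
    sel <- ps$dacs >= grid[k]
    expect_equal(cv$fidelity[k],
                 if (any(sel)) mean(ps$tau_b[sel] > 0) else NA_real_)
    expect_equal(cv$coverage[k], sum(cand >= grid[k]))
  }
  expect_equal(cv$coverage_norm, cv$coverage / max(cv$coverage))
  # coverage anti-monotone in the threshold
  expect_true(all(diff(cv$coverage) <= 0))
  expect_lte(cv$coverage[length(grid)], cv$coverage[1])
})

test_that("select_dacs_threshold finds crossings exactly and interpolated", {
  grid <- seq(0, 1, by = 0.1)
  sym <- structure(data.frame(grid = grid, fidelity = grid,
                              coverage = 1 - grid,
                              coverage_norm = 1 - grid),
                   class = c("threshold_curves", "data.frame"))
  expect_equal(select_dacs_threshold(sym), 0.5)

  # curves touching exactly at a grid point
  g2 <- c(0.50, 0.53, 0.60)
  touch <- structure(data.frame(grid = g2, fidelity = c(0.4, 0.7, 0.9),
                                coverage = c(1, 0.7, 0.2),
                                coverage_norm = c(1, 0.7, 0.2)),
                     class = c("threshold_curves", "data.frame"))
  expect_equal(select_dacs_threshold(touch), 0.53)

  # interpolated crossing between 0.5 and 0.6, oracle: bisection on the
  # piecewise-linear difference
  f <- approxfun(c(0.5, 0.6), c(0.40, 0.80))
  g <- approxfun(c(0.5, 0.6), c(0.70, 0.10))
  root <- uniroot(function(t) f(t) - g(t), c(0.5, 0.6), tol = 1e-12)$root
  pw <- structure(data.frame(grid = c(0.5, 0.6), fidelity = c(0.40, 0.80),
                             coverage = c(0.70, 0.10),
                             coverage_norm = c(0.70, 0.10)),
                  class = c("threshold_curves", "data.frame"))
  expect_equal(select_dacs_threshold(pw), root, tolerance = 1e-10)

  # validation errors
  bad <- structure(data.frame(grid = grid, fidelity = rev(grid),
                              coverage = 1 - grid,
                              coverage_norm = 1 - grid),
                   class = c("threshold_curves", "data.frame"))
  expect_error(select_dacs_threshold(bad), "non-decreasing")
  nocross <- structure(data.frame(grid = grid, fidelity = grid * 0.1,
                                  coverage = 1 - grid * 0.05,
                                  coverage_norm = 1 - grid * 0.05),
                       class = c("threshold_curves", "data.frame"))
  expect_error(select_dacs_threshold(nocross), "never cross")
})

test_that("candidate_substitutes equals an exhaustive DACS scan", {
  bits <- list(q = c(1, 2, 3, 4), hi = c(1, 2, 3, 5), lo = c(9, 10),
               mid = c(1, 2, 9, 10))
  lib <- bit_library(bits)
  got <- candidate_substitutes("q", lib, NULL, cutoff = 0.53)
  expect_equal(got$drug_id, "hi")  # TC(q,hi)=3/5=0.6; others below cutoff

  all_cand <- candidate_substitutes("q", lib, NULL, cutoff = 0)
  expect_setequal(all_cand$drug_id, c("hi", "lo", "mid"))
  expect_false("q" %in% all_cand$drug_id)
  # sorted by descending DACS, ties by id
  expect_true(all(diff(all_cand$dacs) <= 0))

  # 50-molecule random library vs full-scan oracle
  set.seed(502)
  rbits <- lapply(1:50, function(i) sample(64, 12))
  names(rbits) <- sprintf("m%02d", 1:50)
  rlib <- bit_library(rbits, nbits = 64L)
  cutoff <- 0.3
  got <- candidate_substitutes("m01", rlib, NULL, cutoff)
  fpq <- rbits$m01
  oracle <- vapply(names(rbits)[-1], function(id) {
    length(intersect(fpq, rbits[[id]])) / length(union(fpq, rbits[[id]]))
  }, numeric(1))
  keep <- sort(names(oracle)[oracle >= cutoff])
  expect_setequal(got$drug_id, keep)
  expect_equal(got$dacs[order(got$drug_id)], unname(oracle[sort(keep)]))
})

test_that("augment_pair reproduces the flowchart example and its guards", {
  rec <- synergy_table(data.frame(drug_a = "1", drug_b = "2",
                                  cell_line = "cl", tissue = "breast",
                                  synergy_score = 30))[1, ]
  ca <- data.frame(drug_id = c("3", "5"), dacs = c(0.9, 0.8))
  cb <- data.frame(drug_id = "6", dacs = 0.7)
  out <- augment_pair(rec, ca, cb)
  key <- paste(out$drug_a, out$drug_b, sep = ":")
  expect_setequal(key, c("2:3", "2:5", "1:6"))  # canonical order
  expect_true(all(out$synergy_score == 30))
  expect_true(all(out$cell_line == "cl"))
  # exactly one slot substituted per record
  expect_true(all(out$substituted_slot %in% c("first", "second")))
  expect_true(all((out$substituted_slot == "first") ==
                  (out$substitute_id %in% c("3", "5"))))

  expect_equal(nrow(augment_pair(rec, NULL, NULL)), 0L)
  # candidate equal to the partner drug is dropped (self-pair guard)
  drop <- augment_pair(rec, data.frame(drug_id = "2", dacs = 1), NULL)
  expect_equal(nrow(drop), 0L)
})

test_that("augment_dataset equals brute-force enumeration and dedups", {
  sim <- small_sim(seed = 41)
  recs <- sim$synergy[1:20, ]
  cutoff <- 0.5
  aug <- augment_dataset(recs, sim$library, sim$target_map, cutoff,
                         seed = 1)

  # brute-force oracle: every single-slot substitution above cutoff
  ids <- sim$library$drug_id
  pairsc <- function(a, b) {
    tc <- tanimoto(sim$library$fingerprint[[match(a, ids)]],
                   sim$library$fingerprint[[match(b, ids)]])
    mcc <- target_mcc(sim$target_map$associations[[a]],
                      sim$target_map$associations[[b]], sim$target_map)
    dacs(tc, mcc)
  }
  expected_keys <- character(0)
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    for (s in ids) {
      if (s != r$drug_a && s != r$drug_b &&
          pairsc(r$drug_a, s) >= cutoff) {
        k <- sort(c(s, r$drug_b))
        expected_keys <- c(expected_keys,
                           paste(k[1], k[2], r$cell_line, sep = "|"))
      }
      if (s != r$drug_b && s != r$drug_a &&
          pairsc(r$drug_b, s) >= cutoff) {
        k <- sort(c(r$drug_a, s))
        expected_keys <- c(expected_keys,
                           paste(k[1], k[2], r$cell_line, sep = "|"))
      }
    }
  }
  orig_keys <- paste(recs$drug_a, recs$drug_b, recs$cell_line, sep = "|")
  expected_keys <- setdiff(unique(expected_keys), orig_keys)
  got_keys <- paste(aug$drug_a, aug$drug_b, aug$cell_line, sep = "|")
  expect_setequal(got_keys, expected_keys)
  expect_false(anyDuplicated(got_keys) > 0)

  # every augmented record differs from its parent in exactly one slot
  canon_parents <- canonicalize_pairs(
    data.frame(drug_a = aug$parent_a, drug_b = aug$parent_b))
  same_a <- aug$drug_a == canon_parents$drug_a
  same_b <- aug$drug_b == canon_parents$drug_b
  expect_true(all(same_a + same_b == 1))
  expect_true(all(aug$dacs_to_parent >= cutoff))

  # raising the cutoff never increases the augmented-set size
  aug_hi <- augment_dataset(recs, sim$library, sim$target_map, 0.8,
                            seed = 1)
  expect_lte(nrow(aug_hi), nrow(aug))

  # label transfer: augmented scores are a re-weighted copy of parents'
  pkey <- instance_key_test(aug$parent_a, aug$parent_b, aug$cell_line)
  okey <- instance_key_test(recs$drug_a, recs$drug_b, recs$cell_line)
  counts <- table(factor(pkey, levels = okey))
  expect_equal(mean(aug$synergy_score),
               weighted.mean(recs$synergy_score, as.numeric(counts)))
})

test_that("augment_dataset capping preserves the class ratio", {
  sim <- small_sim(seed = 42)
  full <- augment_dataset(sim$synergy, sim$library, sim$target_map, 0.5,
                          seed = 3)
  cap <- 40L
  capped <- augment_dataset(sim$synergy, sim$library, sim$target_map, 0.5,
                            max_records = cap, seed = 3)
  expect_lte(nrow(capped), cap + 2L)  # rounding slack only
  frac_full <- mean(label_instance(full$synergy_score) == "synergistic",
                    na.rm = TRUE)
  frac_cap <- mean(label_instance(capped$synergy_score) == "synergistic",
                   na.rm = TRUE)
  expect_lt(abs(frac_full - frac_cap), 0.05)
  # deterministic under a fixed seed
  capped2 <- augment_dataset(sim$synergy, sim$library, sim$target_map, 0.5,
                             max_records = cap, seed = 3)
  expect_identical(capped, capped2)
})
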