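# Shared fixtures (built in code, no files) and independent oracles.

# -- tiny chemistry fixtures -------------------------------------------------

toy_smiles <- c(
  eth = "CCO",           # ethanol
  ben = "c1ccccc1",      # benzene
  tol = "Cc1ccccc1",     # toluene
  ace = "CC(=O)O",       # acetic acid
  pyr = "c1ccncc1"       # pyridine
)

toy_library <- function(ids = names(toy_smiles)) {
  drug_library(ids, smiles = unname(toy_smiles[ids]))
}

# library with hand-set fingerprints for exact-arithmetic tests
bit_library <- function(bits, nbits = 16L) {
  drug_library(names(bits),
               fingerprints = lapply(bits, new_fingerprint, nbits = nbits),
               backend = "manual", nbits = nbits)
}

toy_target_map <- function() {
  target_map(list(A = c("p1", "p2", "p3"),
                  B = c("p2", "p3", "p4"),
                  C = c("p8", "p9")),
             universe = paste0("p", 1:10))
}

toy_synergy <- function() {
  synergy_table(data.frame(
    drug_a = c("A", "B", "A", "C"),
    drug_b = c("B", "C", "C", "D"),
    cell_line = c("cl1", "cl1", "cl2", "cl2"),
    tissue = c("breast", "breast", "lung", "lung"),
    synergy_score = c(30, -30, 25, 5),
    stringsAsFactors = FALSE))
}

# -- independent oracles -----------------------------------------------------

# exhaustive O(m^2) concordance enumeration (never shares code with the
# implementation's outer()-based counting path beyond language primitives)
oracle_tau_b <- function(x, y) {
  m <- length(x)
  nc <- nd <- n1 <- n2 <- 0
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    a <- x[i] - x[j]; b <- y[i] - y[j]
    if (a * b > 0) nc <- nc + 1
    else if (a * b < 0) nd <- nd + 1
    else if (a == 0 && b != 0) n1 <- n1 + 1
    else if (a != 0 && b == 0) n2 <- n2 + 1
  }
  den <- sqrt((nc + nd + n1) * (nc + nd + n2))
  if (den == 0) 0 else (nc - nd) / den
}

# MCC from an explicitly materialized 2x2 membership table over the universe
oracle_mcc <- function(ta, tb, universe) {
  ina <- universe %in% ta
  inb <- universe %in% tb
  tab <- table(factor(ina, c(TRUE, FALSE)), factor(inb, c(TRUE, FALSE)))
  T_ <- tab[1, 1]; A_ <- tab[1, 2]; B_ <- tab[2, 1]; N_ <- tab[2, 2]
  den <- sqrt(as.double(T_ + A_) * (T_ + B_) * (N_ + A_) * (N_ + B_))
  if (den == 0) 0 else ((as.double(T_) * N_) - (as.double(A_) * B_)) / den
}

# AUC by explicit pairwise Mann-Whitney counting with half-credit ties
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# random named pIC50 profile over shared cell lines
random_profile <- function(m, cells = sprintf("c%02d", seq_len(m)),
                           ties = FALSE) {
  v <- if (ties) sample(seq_len(max(2, m %/% 2)), m, replace = TRUE)
       else stats::rnorm(m)
  stats::setNames(as.numeric(v), cells)
}

instance_key_test <- function(a, b, cl) {
  swap <- a > b
  paste(ifelse(swap, b, a), ifelse(swap, a, b), cl, sep = "|")
}

# small simulated world reused by several test files
small_sim <- function(seed = 7, ...) {
  simulate_world(sim_config(n_clusters = 4, drugs_per_cluster = 5,
                            n_cell_lines = 20, n_records = 120,
                            seed = seed, ...))
}
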