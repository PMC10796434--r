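# Planted-cluster synthetic world.
#
# Drugs fall into substitutability clusters: cluster mates share a template
# fingerprint (per-drug bit relocation at rate 1 - bit_overlap), a cluster
# target set (per-drug protein swaps at rate 1 - target_overlap), and a
# latent per-cell-line potency profile (per-drug Gaussian pIC50 noise).
# Synergy classes are assigned at the cluster-pair level, so every pair
# drawn from the same cluster pair shares a class -- the generative premise
# that makes label transfer by substitution valid by construction.

#' Simulation configuration
#'
#' @param n_clusters number of substitutability clusters (default 8).
#' @param drugs_per_cluster drugs per cluster (default 6).
#' @param n_proteins protein universe size (default 200).
#' @param n_cell_lines cell line count (default 30).
#' @param n_tissues tissue count, assigned round-robin (default 5, matching
#'   the five tissue folds used for real data).
#' @param within_cluster_bit_overlap expected fraction of a cluster's
#'   template bits kept per drug (default 0.9).
#' @param within_cluster_target_overlap same for target proteins
#'   (default 0.9).
#' @param response_noise_sd per-drug pIC50 noise, pIC50 units (default 0.3;
#'   cluster potency profiles have unit spread, so noise sits well below
#'   signal).
#' @param synergy_effect absolute class effect on the synergy scale
#'   (default 30, comfortably outside the +/-20 ambiguity band).
#' @param synergy_noise_sd synergy score noise (default 8).
#' @param class_balance fraction of cluster pairs labelled synergistic
#'   (default 0.767, the class balance of the reference dataset).
#' @param n_records synergy records to emit (default 600).
#' @param fp_nbits fingerprint length (default 1024).
#' @param fp_set_bits template set-bit count (default 64).
#' @param targets_per_cluster proteins per cluster target set (default 12).
#' @param seed integer seed; the whole world is a deterministic function of
#'   the configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_clusters = 8L, drugs_per_cluster = 6L,
                       n_proteins = 200L, n_cell_lines = 30L,
                       n_tissues = 5L,
                       within_cluster_bit_overlap = 0.9,
                       within_cluster_target_overlap = 0.9,
                       response_noise_sd = 0.3,
                       synergy_effect = 30, synergy_noise_sd = 8,
                       class_balance = 0.767, n_records = 600L,
                       fp_nbits = 1024L, fp_set_bits = 64L,
                       targets_per_cluster = 12L, seed = 1L) {
  cfg <- list(n_clusters = as.integer(n_clusters),
              drugs_per_cluster = as.integer(drugs_per_cluster),
              n_proteins = as.integer(n_proteins),
              n_cell_lines = as.integer(n_cell_lines),
              n_tissues = as.integer(n_tissues),
              within_cluster_bit_overlap = within_cluster_bit_overlap,
              within_cluster_target_overlap = within_cluster_target_overlap,
              response_noise_sd = response_noise_sd,
              synergy_effect = synergy_effect,
              synergy_noise_sd = synergy_noise_sd,
              class_balance = class_balance,
              n_records = as.integer(n_records),
              fp_nbits = as.integer(fp_nbits),
              fp_set_bits = as.integer(fp_set_bits),
              targets_per_cluster = as.integer(targets_per_cluster),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_clusters >= 1, drugs_per_cluster >= 1, n_proteins >= 1,
              n_cell_lines >= 1, n_tissues >= 1,
              within_cluster_bit_overlap >= 0,
              within_cluster_bit_overlap <= 1,
              within_cluster_target_overlap >= 0,
              within_cluster_target_overlap <= 1,
              class_balance > 0, class_balance < 1)
    if (fp_set_bits > fp_nbits)
      stop("fp_set_bits exceeds fingerprint length", call. = FALSE)
    if (targets_per_cluster > n_proteins)
      stop("targets_per_cluster exceeds the protein universe", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic drug-synergy world
#'
#' Emits every input table the pipeline consumes -- drug library (with
#' fingerprints), target map, monotherapy response matrix, synergy table,
#' tissue map -- together with the planted ground truth (cluster
#' assignments and cluster-pair classes).  Fully deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a `dacs_simulation` list: `library`, `target_map`, `responses`,
#'   `synergy`, `tissue_map`, `truth`, `config`.
#' @export
simulate_world <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, simulate_world_impl(config))
}

simulate_world_impl <- function(cfg) {
  n_drugs <- cfg$n_clusters * cfg$drugs_per_cluster
  drug_id <- sprintf("D%03d", seq_len(n_drugs))
  cluster_of <- stats::setNames(rep(seq_len(cfg$n_clusters),
                                    each = cfg$drugs_per_cluster), drug_id)
  proteins <- sprintf("P%04d", seq_len(cfg$n_proteins))
  cells <- sprintf("CL%02d", seq_len(cfg$n_cell_lines))
  tissues <- sprintf("tissue_%d", seq_len(cfg$n_tissues))
  tissue_map <- stats::setNames(rep_len(tissues, cfg$n_cell_lines), cells)

  # cluster templates
  fp_templates <- lapply(seq_len(cfg$n_clusters), function(k)
    sample(cfg$fp_nbits, cfg$fp_set_bits))
  tgt_templates <- lapply(seq_len(cfg$n_clusters), function(k)
    sample(proteins, cfg$targets_per_cluster))
  potency <- lapply(seq_len(cfg$n_clusters), function(k)
    stats::setNames(stats::rnorm(cfg$n_cell_lines, mean = 6, sd = 1), cells))

  fingerprints <- vector("list", n_drugs)
  assoc <- vector("list", n_drugs)
  resp <- vector("list", n_drugs)
  for (i in seq_len(n_drugs)) {
    k <- cluster_of[[i]]
    tmpl <- fp_templates[[k]]
    move <- stats::runif(length(tmpl)) > cfg$within_cluster_bit_overlap
    bits <- tmpl
    if (any(move))
      bits[move] <- sample(setdiff(seq_len(cfg$fp_nbits), tmpl), sum(move))
    fingerprints[[i]] <- new_fingerprint(bits, nbits = cfg$fp_nbits)

    tt <- tgt_templates[[k]]
    swap <- stats::runif(length(tt)) > cfg$within_cluster_target_overlap
    tg <- tt
    if (any(swap))
      tg[swap] <- sample(setdiff(proteins, tt), sum(swap))
    assoc[[i]] <- unique(tg)

    resp[[i]] <- data.frame(
      drug_id = drug_id[i], cell_line = cells,
      pIC50 = potency[[k]] + stats::rnorm(cfg$n_cell_lines,
                                          sd = cfg$response_noise_sd),
      stringsAsFactors = FALSE)
  }
  library <- drug_library(drug_id, fingerprints = fingerprints,
                          backend = "simulated", nbits = cfg$fp_nbits)
  tmap <- target_map(stats::setNames(assoc, drug_id), universe = proteins)
  responses <- response_matrix(do.call(rbind, resp), tissue_map)

  # cluster-pair classes: exact quota of synergistic cluster pairs
  cp <- utils::combn(cfg$n_clusters, 2)
  n_cp <- ncol(cp)
  n_syn_cp <- max(1L, min(n_cp - 1L, round(cfg$class_balance * n_cp)))
  cp_class <- rep("antagonistic", n_cp)
  cp_class[sample(n_cp, n_syn_cp)] <- "synergistic"

  # records spread round-robin over cluster pairs; drugs and cells uniform
  rec_cp <- rep_len(sample(n_cp), cfg$n_records)
  rows <- lapply(seq_len(cfg$n_records), function(r) {
    kpair <- cp[, rec_cp[r]]
    da <- sample(drug_id[cluster_of == kpair[1]], 1)
    db <- sample(drug_id[cluster_of == kpair[2]], 1)
    cl <- sample(cells, 1)
    cls <- cp_class[rec_cp[r]]
    score <- (if (cls == "synergistic") 1 else -1) * cfg$synergy_effect +
      stats::rnorm(1, sd = cfg$synergy_noise_sd)
    data.frame(drug_a = da, drug_b = db, cell_line = cl,
               tissue = tissue_map[[cl]], synergy_score = score,
               stringsAsFactors = FALSE)
  })
  syn <- do.call(rbind, rows)
  # drop accidental duplicate (pair, cell line) draws: one record per key
  syn <- canonicalize_pairs(syn)
  syn <- syn[!duplicated(paste(syn$drug_a, syn$drug_b, syn$cell_line,
                               sep = "\r")), , drop = FALSE]
  synergy <- synergy_table(syn)

  pair_class <- stats::setNames(
    cp_class, paste(cp[1, ], cp[2, ], sep = ":"))
  structure(list(library = library, target_map = tmap,
                 responses = responses, synergy = synergy,
                 tissue_map = tissue_map,
                 truth = list(cluster_of = cluster_of,
                              cluster_pair_class = pair_class,
                              config = cfg),
                 config = cfg),
            class = "dacs_simulation")
}

#' Substitution recovery against the planted truth
#'
#' Runs [candidate_substitutes()] for every drug and scores retrieval
#' against the planted clusters: precision = fraction of retrieved
#' substitutes in the query's cluster, recall = fraction of cluster mates
#' retrieved.  Precision is `NA` (undefined) when nothing is retrieved.
#'
#' @param sim a [simulate_world()] result.
#' @param cutoff DACS cutoff passed to the retrieval.
#' @return list with `precision`, `recall`, `n_retrieved`, `per_drug`.
#' @export
recovery_check <- function(sim, cutoff) {
  ids <- sim$library$drug_id
  cl <- sim$truth$cluster_of
  tp <- fp_ <- fn <- 0L
  per_drug <- lapply(stats::setNames(nm = ids), function(d) {
    got <- candidate_substitutes(d, sim$library, sim$target_map, cutoff)
    mates <- ids[cl == cl[[d]] & ids != d]
    hit <- sum(got$drug_id %in% mates)
    tp <<- tp + hit
    fp_ <<- fp_ + (nrow(got) - hit)
    fn <<- fn + (length(mates) - hit)
    list(retrieved = got$drug_id, n_hit = hit, n_mates = length(mates))
  })
  list(precision = if (tp + fp_ == 0) NA_real_ else tp / (tp + fp_),
       recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
       n_retrieved = tp + fp_, per_drug = per_drug)
}
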