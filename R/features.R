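# Instance featurization: pluggable embedding providers.
#
# Real-data pipelines plug in pretrained drug embeddings (e.g. Mol2vec-like
# 300-d vectors) and expression-derived cell embeddings loaded from CSV;
# the package ships deterministic fallback providers (a random projection
# of fingerprint bits for drugs, a seeded per-id vector for cells) so the
# full pipeline runs without external models.  The instance representation
# concatenates drug_a | drug_b | cell embeddings in canonical pair order.

#' Construct an embedding provider
#'
#' @param name provider identifier.
#' @param dimension output dimension (the real-data convention is 300 per
#'   block, giving 900-d instances).
#' @param embed function(entity_id) -> numeric vector of length `dimension`.
#' @return an `embedding_provider`.
#' @export
embedding_provider <- function(name, dimension, embed) {
  stopifnot(is.function(embed), dimension >= 1)
  structure(list(name = name, dimension = as.integer(dimension),
                 embed = embed), class = "embedding_provider")
}

provider_embed <- function(provider, id) {
  v <- provider$embed(id)
  if (length(v) != provider$dimension || !all(is.finite(v)))
    stop("provider '", provider$name, "' returned an invalid vector for ",
         id, call. = FALSE)
  as.numeric(v)
}

#' Deterministic fallback drug embedder (fingerprint random projection)
#'
#' Projects a drug's fingerprint bit vector through a fixed seeded Gaussian
#' matrix, so drugs with similar fingerprints (high Tanimoto) receive
#' similar embeddings and identical fingerprints map to identical vectors.
#'
#' @param library `drug_library` supplying fingerprints.
#' @param dimension embedding dimension (default 300).
#' @param seed projection seed (default 42).
#' @return an `embedding_provider`.
#' @export
hashed_drug_embedder <- function(library, dimension = 300L, seed = 42L) {
  nbits <- attr(library, "nbits")
  proj <- local_seed(seed,
    matrix(stats::rnorm(nbits * dimension), nrow = nbits) / sqrt(dimension))
  fps <- stats::setNames(library$fingerprint, library$drug_id)
  embedding_provider(
    name = sprintf("hashed_fp_projection(d=%d,seed=%d)", dimension, seed),
    dimension = dimension,
    embed = function(id) {
      fp <- fps[[id]]
      if (is.null(fp)) stop("unknown drug: ", id, call. = FALSE)
      bits <- unclass(fp)
      if (!length(bits)) return(numeric(dimension))
      colSums(proj[bits, , drop = FALSE])
    })
}

#' Deterministic fallback cell-line embedder (seeded per-id vector)
#'
#' Each cell id receives a fixed pseudo-random Gaussian vector derived from
#' a hash of (seed, id); stable across runs and sessions.
#'
#' @param dimension embedding dimension (default 300).
#' @param seed base seed (default 42).
#' @return an `embedding_provider`.
#' @export
hashed_cell_embedder <- function(dimension = 300L, seed = 42L) {
  embedding_provider(
    name = sprintf("hashed_cell(d=%d,seed=%d)", dimension, seed),
    dimension = dimension,
    embed = function(id) {
      s <- (str_hash(as.character(id)) + as.double(seed) * 7919) %%
        2147483647
      local_seed(s, stats::rnorm(dimension))
    })
}

#' Load an embedding provider from CSV
#'
#' Format: first column the entity id, then `dimension` numeric columns.
#'
#' @param path CSV file path.
#' @param name provider name (default the file name).
#' @return an `embedding_provider`.
#' @export
load_embedding_csv <- function(path, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  embedding_provider(name, ncol(mat), function(id) {
    if (!id %in% ids) stop("unknown entity: ", id, call. = FALSE)
    mat[id, ]
  })
}

#' Featurize one instance
#'
#' Concatenates the two drug embeddings in canonical (lexicographic) pair
#' order followed by the cell-line embedding, so the vector is invariant to
#' the orientation of the pair in the input file.
#'
#' @param drug_a,drug_b drug ids.
#' @param cell_line cell line id.
#' @param drug_provider,cell_provider `embedding_provider`s.
#' @return numeric vector of length `2 * drug dim + cell dim`.
#' @export
featurize_instance <- function(drug_a, drug_b, cell_line, drug_provider,
                               cell_provider) {
  if (drug_a > drug_b) { tmp <- drug_a; drug_a <- drug_b; drug_b <- tmp }
  c(provider_embed(drug_provider, drug_a),
    provider_embed(drug_provider, drug_b),
    provider_embed(cell_provider, cell_line))
}

#' Featurize a dataset of instances
#'
#' @param instances data.frame with `drug_a`, `drug_b`, `cell_line`.
#' @param drug_provider,cell_provider `embedding_provider`s.
#' @return numeric matrix, one row per instance.
#' @export
featurize_dataset <- function(instances, drug_provider, cell_provider) {
  d <- 2L * drug_provider$dimension + cell_provider$dimension
  out <- matrix(0, nrow = nrow(instances), ncol = d)
  # memoize per-entity embeddings: instance counts far exceed entity counts
  dcache <- new.env(parent = emptyenv())
  ccache <- new.env(parent = emptyenv())
  getd <- function(id) {
    v <- dcache[[id]]
    if (is.null(v)) { v <- provider_embed(drug_provider, id); dcache[[id]] <- v }
    v
  }
  getc <- function(id) {
    v <- ccache[[id]]
    if (is.null(v)) { v <- provider_embed(cell_provider, id); ccache[[id]] <- v }
    v
  }
  for (i in seq_len(nrow(instances))) {
    a <- instances$drug_a[i]; b <- instances$drug_b[i]
    if (a > b) { tmp <- a; a <- b; b <- tmp }
    out[i, ] <- c(getd(a), getd(b), getc(instances$cell_line[i]))
  }
  out
}
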