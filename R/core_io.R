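# Domain containers and table I/O.
#
# All tabular formats are plain CSV (comma, UTF-8, header required); the
# chemical-protein links reader speaks the STITCH-links TSV dialect
# (chemical, protein, combined_score).

#' Construct a drug library
#'
#' @param drug_id character vector of unique drug identifiers.
#' @param smiles optional character vector of SMILES (NA allowed per drug).
#' @param fingerprints optional list of [new_fingerprint()] objects; computed
#'   from SMILES with `backend` when absent.
#' @param backend name of the fingerprint backend (see `fp_backends`).
#' @param nbits fingerprint length used when computing from SMILES.
#' @return a `drug_library` data.frame with a `fingerprint` list column and
#'   attributes `fp_backend`, `nbits`.
#' @export
drug_library <- function(drug_id, smiles = NULL, fingerprints = NULL,
                         backend = "rpath1024", nbits = 1024L) {
  drug_id <- as.character(drug_id)
  dup <- unique(drug_id[duplicated(drug_id)])
  if (length(dup))
    stop("duplicate drug_id in library: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(smiles)) smiles <- rep(NA_character_, length(drug_id))
  if (is.null(fingerprints)) {
    fun <- fp_backends[[backend]]
    if (is.null(fun)) stop("unknown fingerprint backend: ", backend,
                           call. = FALSE)
    fingerprints <- vector("list", length(drug_id))
    for (i in seq_along(drug_id)) {
      if (is.na(smiles[i]))
        stop("drug ", drug_id[i], " has neither SMILES nor fingerprint",
             call. = FALSE)
      fingerprints[[i]] <- tryCatch(fun(smiles[i], nbits = nbits),
        error = function(e) stop(sprintf("row %d (drug %s): %s",
                                         i, drug_id[i], conditionMessage(e)),
                                 call. = FALSE))
    }
  }
  stopifnot(length(fingerprints) == length(drug_id))
  out <- data.frame(drug_id = drug_id, smiles = smiles,
                    stringsAsFactors = FALSE)
  out$fingerprint <- fingerprints
  structure(out, fp_backend = backend, nbits = as.integer(nbits),
            class = c("drug_library", "data.frame"))
}

lib_fingerprint <- function(library, drug_id) {
  i <- match(drug_id, library$drug_id)
  if (is.na(i)) stop("drug not in library: ", drug_id, call. = FALSE)
  library$fingerprint[[i]]
}

#' Read a drug library CSV
#'
#' Two dialects: `smiles_csv` (columns `drug_id`, `smiles`; fingerprints are
#' computed) and `fingerprint_csv` (columns `drug_id`, `fingerprint` with
#' semicolon-separated set-bit indices, optional `smiles`).
#'
#' @param path CSV file path.
#' @param dialect `"smiles_csv"` or `"fingerprint_csv"`.
#' @param backend,nbits see [drug_library()].
#' @return a `drug_library`.
#' @export
read_drug_library <- function(path, dialect = c("smiles_csv",
                                                "fingerprint_csv"),
                              backend = "rpath1024", nbits = 1024L) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"drug_id" %in% names(df))
    stop("drug library needs a drug_id column", call. = FALSE)
  if (dialect == "smiles_csv") {
    if (!"smiles" %in% names(df))
      stop("smiles_csv dialect needs a smiles column", call. = FALSE)
    drug_library(df$drug_id, smiles = df$smiles, backend = backend,
                 nbits = nbits)
  } else {
    if (!"fingerprint" %in% names(df))
      stop("fingerprint_csv dialect needs a fingerprint column",
           call. = FALSE)
    fps <- fingerprint_from_string(df$fingerprint, nbits = nbits)
    drug_library(df$drug_id,
                 smiles = if ("smiles" %in% names(df)) df$smiles else NULL,
                 fingerprints = fps, backend = backend, nbits = nbits)
  }
}

#' Write a drug library CSV (fingerprint dialect)
#' @param library a `drug_library`.
#' @param path output path.
#' @export
write_drug_library <- function(library, path) {
  df <- data.frame(
    drug_id = library$drug_id,
    smiles = library$smiles,
    fingerprint = vapply(library$fingerprint, fingerprint_to_string,
                         character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- target map ------------------------------------------------------------

#' Construct a drug -> protein-target map
#'
#' @param associations named list: drug_id -> character vector of protein ids.
#' @param universe either a count (reference interactome size; the headline
#'   interactome used for real data has 19,968 proteins) or a character
#'   roster of protein ids.
#' @return a `target_map` list with `associations`, `universe_size` and,
#'   when a roster was given, `universe`.
#' @export
target_map <- function(associations, universe) {
  associations <- lapply(associations, function(x) unique(as.character(x)))
  all_prot <- unique(unlist(associations, use.names = FALSE))
  if (is.character(universe)) {
    missing <- setdiff(all_prot, universe)
    if (length(missing))
      stop("protein(s) outside the declared universe: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    size <- length(unique(universe))
    roster <- unique(universe)
  } else {
    assert_scalar_number(universe, "universe")
    size <- as.integer(universe)
    roster <- NULL
    if (size < length(all_prot))
      stop("universe_size (", size, ") smaller than the union of target sets (",
           length(all_prot), ")", call. = FALSE)
  }
  structure(list(associations = associations, universe_size = size,
                 universe = roster), class = "target_map")
}

targets_of <- function(map, drug_id) {
  map$associations[[drug_id]] %||% character(0)
}

#' Read chemical-protein links (STITCH-links TSV dialect)
#'
#' Tab-separated with header columns `chemical`, `protein`,
#' `combined_score`.  Rows with score below `score_min` are filtered out;
#' malformed rows are skipped and counted in a message (never silently).
#'
#' @param path TSV file path.
#' @param score_min minimum combined score kept (default 0 = keep all; the
#'   cutoff is deliberately a configuration value, see the vignette).
#' @param universe optional protein roster; defaults to the file's protein
#'   union.
#' @return a `target_map`.
#' @export
read_target_links <- function(path, score_min = 0, universe = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chemical", "protein", "combined_score")
  if (!all(need %in% names(df)))
    stop("links file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  score <- suppressWarnings(as.numeric(df$combined_score))
  bad <- is.na(score) | !nzchar(df$chemical) | !nzchar(df$protein) |
    is.na(df$chemical) | is.na(df$protein)
  if (any(bad))
    message(sum(bad), " malformed link row(s) skipped")
  df <- df[!bad, , drop = FALSE]; score <- score[!bad]
  keep <- score >= score_min
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) {
    warning("no chemical-protein links kept at score_min = ", score_min,
            call. = FALSE)
    return(target_map(structure(list(), names = character(0)),
                      universe = universe %||% 0))
  }
  assoc <- split(df$protein, df$chemical)
  target_map(assoc, universe = universe %||% unique(df$protein))
}

#' Write chemical-protein links in the STITCH-links TSV dialect
#' @param map a `target_map`.
#' @param path output path.
#' @param score score written for every link (default 900).
#' @export
write_target_links <- function(map, path, score = 900) {
  chem <- rep(names(map$associations),
              vapply(map$associations, length, integer(1)))
  prot <- unlist(map$associations, use.names = FALSE)
  df <- data.frame(chemical = chem, protein = prot, combined_score = score,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- response matrix -------------------------------------------------------

#' Construct a monotherapy response matrix
#'
#' @param entries data.frame with columns `drug_id`, `cell_line`, `pIC50`.
#' @param cell_line_tissue named character vector: cell_line -> tissue label.
#' @return a `response_matrix`.
#' @export
response_matrix <- function(entries, cell_line_tissue) {
  stopifnot(all(c("drug_id", "cell_line", "pIC50") %in% names(entries)))
  key <- paste(entries$drug_id, entries$cell_line, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (drug, cell line) response entries", call. = FALSE)
  if (!all(is.finite(entries$pIC50)))
    stop("pIC50 values must be finite", call. = FALSE)
  missing <- setdiff(unique(entries$cell_line), names(cell_line_tissue))
  if (length(missing))
    stop("cell line(s) without tissue label: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  structure(list(entries = entries[, c("drug_id", "cell_line", "pIC50")],
                 cell_line_tissue = cell_line_tissue),
            class = "response_matrix")
}

#' Extract a drug's monotherapy profile (cell line -> pIC50)
#' @param responses a `response_matrix`.
#' @param drug_id drug identifier.
#' @return named numeric vector.
#' @export
response_profile <- function(responses, drug_id) {
  e <- responses$entries[responses$entries$drug_id == drug_id, , drop = FALSE]
  stats::setNames(e$pIC50, e$cell_line)
}

#' Read a monotherapy response CSV (drug_id, cell_line, pIC50, tissue)
#' @param path CSV file path.
#' @return a `response_matrix`.
#' @export
read_response_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug_id", "cell_line", "pIC50", "tissue")
  if (!all(need %in% names(df)))
    stop("response table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tis <- tapply(df$tissue, df$cell_line, function(x) x[[1]])
  response_matrix(df, stats::setNames(as.character(tis), names(tis)))
}

#' Write a monotherapy response CSV
#' @param responses a `response_matrix`.
#' @param path output path.
#' @export
write_response_table <- function(responses, path) {
  df <- responses$entries
  df$tissue <- unname(responses$cell_line_tissue[df$cell_line])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# ---- synergy records -------------------------------------------------------

#' Canonicalize drug pairs (lexicographic order)
#'
#' The synergy relation is symmetric, so (a, b) and (b, a) denote one
#' record; the stored orientation is `drug_a < drug_b`.
#'
#' @param df data.frame with `drug_a`, `drug_b` columns.
#' @return the data.frame with pairs reordered in place.
#' @export
canonicalize_pairs <- function(df) {
  swap <- df$drug_a > df$drug_b
  if (any(swap)) {
    tmp <- df$drug_a[swap]
    df$drug_a[swap] <- df$drug_b[swap]
    df$drug_b[swap] <- tmp
  }
  df
}

#' Construct a synergy table
#'
#' @param df data.frame with columns `drug_a`, `drug_b`, `cell_line`,
#'   `tissue`, `synergy_score`.
#' @return a canonicalized `synergy_table` data.frame.
#' @export
synergy_table <- function(df) {
  need <- c("drug_a", "drug_b", "cell_line", "tissue", "synergy_score")
  if (!all(need %in% names(df)))
    stop("synergy table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$synergy_score <- suppressWarnings(as.numeric(df$synergy_score))
  bad_num <- which(is.na(df$synergy_score))
  if (length(bad_num))
    stop("non-numeric synergy score in row(s): ",
         paste(utils::head(bad_num, 5), collapse = ", "), call. = FALSE)
  self <- which(df$drug_a == df$drug_b)
  if (length(self))
    stop("self-pair (drug_a == drug_b) in row(s): ",
         paste(utils::head(self, 5), collapse = ", "), call. = FALSE)
  df <- canonicalize_pairs(df[, need, drop = FALSE])
  rownames(df) <- NULL
  structure(df, class = c("synergy_table", "data.frame"))
}

#' Read a synergy CSV (drug_a, drug_b, cell_line, tissue, synergy_score)
#' @param path CSV file path.
#' @return a `synergy_table`.
#' @export
read_synergy_table <- function(path) {
  synergy_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a synergy CSV
#' @param records a `synergy_table`.
#' @param path output path.
#' @export
write_synergy_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

AUGMENTED_COLS <- c("drug_a", "drug_b", "cell_line", "tissue",
                    "synergy_score", "parent_a", "parent_b",
                    "substituted_slot", "substitute_id", "dacs_to_parent")

#' Write an augmented-records CSV
#'
#' Fixed column order; byte-stable for identical input and sort order.
#'
#' @param records data.frame of augmented records (see [augment_dataset()]).
#' @param path output path.
#' @export
write_augmented_table <- function(records, path) {
  if (!nrow(records)) {
    records <- as.data.frame(stats::setNames(
      replicate(length(AUGMENTED_COLS), character(0), simplify = FALSE),
      AUGMENTED_COLS))
  }
  utils::write.csv(records[, AUGMENTED_COLS, drop = FALSE], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read an augmented-records CSV
#' @param path CSV file path.
#' @return data.frame of augmented records.
#' @export
read_augmented_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(synergy_score = "numeric",
                                       dacs_to_parent = "numeric"))
  if (!all(AUGMENTED_COLS %in% names(df)))
    stop("augmented table needs columns: ",
         paste(AUGMENTED_COLS, collapse = ", "), call. = FALSE)
  df[, AUGMENTED_COLS, drop = FALSE]
}
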