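# Molecular fingerprints: fixed-length bit sets over linear atom paths.
#
# The default backend ("rpath1024") enumerates linear substructure paths of up
# to 7 atoms from a minimal SMILES graph and hashes each canonical path string
# into a 1024-bit vector.  This follows the path-fingerprint (FP2-style)
# convention but is not bit-identical to any external toolkit; the producing
# backend is recorded on every drug library so mixed-provenance comparisons
# can be refused.

#' Construct a fingerprint
#'
#' A fingerprint is stored sparsely as the sorted vector of set bit positions
#' (1-based) with the total bit length as an attribute.
#'
#' @param bits integer vector of set bit positions (1-based).
#' @param nbits total fingerprint length (default 1024).
#' @return an object of class `fingerprint`.
#' @export
new_fingerprint <- function(bits, nbits = 1024L) {
  nbits <- as.integer(nbits)
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 1L || max(bits) > nbits))
    stop("fingerprint bit positions must lie in [1, nbits]", call. = FALSE)
  structure(bits, nbits = nbits, class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d/%d bits set>\n", length(x), attr(x, "nbits")))
  invisible(x)
}

fp_nbits <- function(fp) attr(fp, "nbits")

# ---- SMILES parsing --------------------------------------------------------

ORGANIC_TWO <- c("Cl", "Br")
ORGANIC_ONE <- c("B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' Minimal parser sufficient for path fingerprints: element identity,
#' aromaticity, connectivity and bond orders.  Stereo marks (`/ \ @`),
#' isotopes, charges and explicit hydrogens inside brackets are accepted and
#' ignored.  Unparseable input raises an error.
#'
#' @param smiles a single SMILES string.
#' @return a list with `element` (character), `aromatic` (logical) and
#'   `bonds` (data.frame with columns `a`, `b`, `type`).
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("SMILES must be a single non-empty string", call. = FALSE)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)

  element <- character(0); aromatic <- logical(0)
  b_a <- integer(0); b_b <- integer(0); b_t <- character(0)
  prev <- NA_integer_
  pending <- ""            # explicit bond symbol awaiting the next atom
  stack <- integer(0)      # branch stack of previous-atom indices
  ring <- list()           # ring-closure label -> c(atom, bond symbol)

  add_bond <- function(i, j, sym) {
    type <- if (nzchar(sym)) {
      switch(sym, "-" = "1", "/" = "1", "\\" = "1",
             "=" = "2", "#" = "3", ":" = "ar",
             stop("unsupported bond symbol: ", sym, call. = FALSE))
    } else if (aromatic[i] && aromatic[j]) "ar" else "1"
    b_a <<- c(b_a, i); b_b <<- c(b_b, j); b_t <<- c(b_t, type)
  }
  add_atom <- function(el, arom) {
    element <<- c(element, el); aromatic <<- c(aromatic, arom)
    idx <- length(element)
    if (!is.na(prev)) add_bond(prev, idx, pending)
    pending <<- ""
    prev <<- idx
    idx
  }
  close_ring <- function(label) {
    if (is.null(ring[[label]])) {
      if (is.na(prev)) stop("ring closure before any atom in '", smiles, "'",
                            call. = FALSE)
      ring[[label]] <<- list(atom = prev, bond = pending)
      pending <<- ""
    } else {
      opened <- ring[[label]]
      sym <- if (nzchar(pending)) pending else opened$bond
      add_bond(opened$atom, prev, sym)
      ring[[label]] <<- NULL
      pending <<- ""
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% ORGANIC_TWO) {
      add_atom(two, FALSE); i <- i + 2L
    } else if (ch %in% ORGANIC_ONE) {
      add_atom(ch, FALSE); i <- i + 1L
    } else if (ch %in% AROMATIC_ORGANIC) {
      add_atom(toupper(ch), TRUE); i <- i + 1L
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated bracket atom in '", smiles, "'",
                      call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec("^[0-9]*([A-Z][a-z]?|[a-z])", body))[[1]]
      if (length(m) < 2L || !nzchar(m[2]))
        stop("cannot read bracket atom '[", body, "]' in '", smiles, "'",
             call. = FALSE)
      el <- m[2]
      arom <- el == tolower(el)
      add_atom(if (arom) paste0(toupper(substr(el, 1, 1)),
                                substring(el, 2)) else el, arom)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch without preceding atom in '", smiles, "'",
                            call. = FALSE)
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in '", smiles, "'",
                               call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %% ring label in '", smiles, "'",
                           call. = FALSE)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else {
      stop("unsupported SMILES character '", ch, "' in '", smiles, "'",
           call. = FALSE)
    }
  }
  if (length(stack)) stop("unbalanced '(' in '", smiles, "'", call. = FALSE)
  open_rings <- names(ring)[!vapply(ring, is.null, logical(1))]
  if (length(open_rings))
    stop("unclosed ring bond(s) in '", smiles, "'", call. = FALSE)
  if (!length(element)) stop("no atoms parsed from '", smiles, "'",
                             call. = FALSE)
  list(element = element, aromatic = aromatic,
       bonds = data.frame(a = b_a, b = b_b, type = b_t,
                          stringsAsFactors = FALSE))
}

# Enumerate canonical linear-path strings up to `max_len` atoms.
mol_paths <- function(mol, max_len = 7L) {
  n <- length(mol$element)
  lab <- ifelse(mol$aromatic, tolower(mol$element), mol$element)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a[k]; b <- mol$bonds$b[k]; t <- mol$bonds$type[k]
    adj[[a]] <- rbind(adj[[a]], c(b, t))
    adj[[b]] <- rbind(adj[[b]], c(a, t))
  }
  out <- new.env(parent = emptyenv())
  emit <- function(atoms, bonds) {
    fwd <- paste(c(rbind(lab[atoms], c(bonds, ""))), collapse = "")
    rev_ <- paste(c(rbind(lab[rev(atoms)], c(rev(bonds), ""))), collapse = "")
    key <- if (fwd <= rev_) fwd else rev_
    assign(key, TRUE, envir = out)
  }
  walk <- function(atoms, bonds) {
    emit(atoms, bonds)
    if (length(atoms) == max_len) return()
    here <- atoms[length(atoms)]
    nb <- adj[[here]]
    if (is.null(nb)) return()
    for (k in seq_len(nrow(nb))) {
      nxt <- as.integer(nb[k, 1])
      if (nxt %in% atoms) next
      walk(c(atoms, nxt), c(bonds, nb[k, 2]))
    }
  }
  for (a in seq_len(n)) walk(a, character(0))
  ls(out)
}

#' Compute a path fingerprint from SMILES
#'
#' @param smiles a single SMILES string.
#' @param nbits fingerprint length (default 1024).
#' @param max_len maximum path length in atoms (default 7).
#' @return a [new_fingerprint()] object.
#' @export
fingerprint_from_smiles <- function(smiles, nbits = 1024L, max_len = 7L) {
  paths <- mol_paths(parse_smiles(smiles), max_len = max_len)
  bits <- vapply(paths, function(p) (str_hash(p) %% nbits) + 1L, numeric(1))
  new_fingerprint(bits, nbits = nbits)
}

# Named backend registry; outputs record which backend produced them.
fp_backends <- list(
  rpath1024 = function(smiles, nbits = 1024L)
    fingerprint_from_smiles(smiles, nbits = nbits)
)

#' Parse a serialized fingerprint ("5;17;902" bit-index form)
#' @param s character vector of serialized fingerprints.
#' @param nbits fingerprint length.
#' @return list of `fingerprint` objects.
#' @export
fingerprint_from_string <- function(s, nbits = 1024L) {
  lapply(strsplit(s, ";", fixed = TRUE), function(v) {
    v <- v[nzchar(v)]
    new_fingerprint(as.integer(v), nbits = nbits)
  })
}

#' @rdname fingerprint_from_string
#' @param fp a `fingerprint` object.
#' @export
fingerprint_to_string <- function(fp) paste(unclass(fp), collapse = ";")
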