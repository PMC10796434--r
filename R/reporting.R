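# Machine-readable summary artifacts: physicochemical sanity summaries of
# drug sets and synergy score distributions (original vs augmented
# overlays).  Pure functions of their inputs.

#' Physicochemical property summary of a drug set
#'
#' Per-molecule logP (octanol-water partition), hydrogen-bond donors and
#' acceptors, and QED (quantitative estimate of drug-likeness) via the
#' RDKit descriptor backend, then mean and SD per property.  Molecules the
#' backend cannot process are excluded and reported.  The backend name and
#' version are stamped into the summary because descriptor implementations
#' differ slightly across toolkits.
#'
#' @param library a `drug_library` with SMILES.
#' @return a `property_summary`: `per_molecule` data.frame, `summary`
#'   data.frame (property, mean, sd, n), `backend`, `failed` drug ids.
#' @export
property_summary <- function(library) {
  smiles <- library$smiles
  if (all(is.na(smiles)))
    stop("property_summary needs SMILES", call. = FALSE)
  usable <- !is.na(smiles)
  td <- tempfile("dacsaug_desc_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  infile <- file.path(td, "in.csv")
  utils::write.csv(data.frame(drug_id = library$drug_id[usable],
                              smiles = smiles[usable]),
                   infile, row.names = FALSE, quote = TRUE)
  outfile <- file.path(td, "out.csv")
  res <- system2(dacsaug_python(),
                 c(bridge_script("descriptors.py"), infile, outfile),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(outfile))
    stop("descriptor backend failed:\n", paste(res, collapse = "\n"),
         call. = FALSE)
  per <- utils::read.csv(outfile, stringsAsFactors = FALSE)
  failed <- per$drug_id[per$status != "ok"]
  if (length(failed))
    message(length(failed), " molecule(s) excluded by the descriptor ",
            "backend: ", paste(utils::head(failed, 5), collapse = ", "))
  ok <- per[per$status == "ok", , drop = FALSE]
  props <- c("logp", "hbd", "hba", "qed")
  summ <- data.frame(
    property = props,
    mean = vapply(props, function(p) mean(ok[[p]]), numeric(1)),
    sd = vapply(props, function(p) stats::sd(ok[[p]]), numeric(1)),
    n = nrow(ok), row.names = NULL, stringsAsFactors = FALSE)
  summ$sd[is.na(summ$sd)] <- 0  # single-molecule sets have SD 0
  structure(list(per_molecule = ok[, c("drug_id", props)],
                 summary = summ,
                 backend = per$backend[1],
                 failed = failed),
            class = "property_summary")
}

#' @export
print.property_summary <- function(x, ...) {
  cat("<property_summary backend:", x$backend, ">\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-5s %5.2f +/- %.2f (n=%d)\n", s$property[i], s$mean[i],
                s$sd[i], s$n[i]))
  invisible(x)
}

#' Synergy score distribution
#'
#' Histogram of synergy scores plus mean and SD; when a comparison set is
#' given the same bins are reused so the two histograms overlay.
#'
#' @param records a `synergy_table` or augmented records.
#' @param bins bin count (default 50).
#' @param compare optional second record set binned on the same breaks.
#' @return list with `breaks`, `counts`, `mean`, `sd` and, when `compare`
#'   is given, `compare_counts`, `compare_mean`, `compare_sd`.
#' @export
score_distribution <- function(records, bins = 50L, compare = NULL) {
  stopifnot(bins >= 1L)
  x <- records$synergy_score
  rng <- range(c(x, compare$synergy_score))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  out <- list(breaks = breaks, counts = h$counts, mean = mean(x),
              sd = stats::sd(x))
  if (!is.null(compare)) {
    h2 <- graphics::hist(compare$synergy_score, breaks = breaks,
                         plot = FALSE)
    out$compare_counts <- h2$counts
    out$compare_mean <- mean(compare$synergy_score)
    out$compare_sd <- stats::sd(compare$synergy_score)
  }
  out
}
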