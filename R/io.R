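#' Read an expression matrix
#'
#' Tab-separated text with gene ids in the header row and sample ids in
#' the first column (the layout written by [write_expression()]).
#'
#' @param path file path.
#' @return numeric matrix (samples x genes) with dimnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  sample_ids <- as.character(tab[[1]])
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  gene_ids <- colnames(tab)[-1]
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  M <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(M) <- "double")
  if (any(!is.finite(M))) {
    bad <- which(!is.finite(M), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric expression value at sample '%s', gene '%s'",
                 sample_ids[bad[1]], gene_ids[bad[2]]))
  }
  dimnames(M) <- list(sample_ids, gene_ids)
  M
}

#' Write an expression matrix
#'
#' @param X numeric matrix (samples x genes) with dimnames.
#' @param path output path.
#' @export
write_expression <- function(X, path) {
  df <- data.frame(sample = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a survival table aligned to an expression matrix
#'
#' Three tab-separated columns: sample id, observed time, event indicator
#' (0/1). Rows are re-ordered to the given sample order; missing or
#' unmatched samples are an error.
#'
#' @param path file path.
#' @param sample_ids the expression sample order to align to; if NULL the
#'   file order is kept.
#' @return list with `time`, `event`, `sample_ids`.
#' @export
read_survival <- function(path, sample_ids = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("survival table needs 3 columns")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in survival table")
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, ids)
    if (any(is.na(idx)))
      stop("samples missing from survival table: ",
           paste(utils::head(sample_ids[is.na(idx)], 3), collapse = ", "))
    tab <- tab[idx, ]
    ids <- sample_ids
  }
  time <- as.numeric(tab[[2]])
  event <- as.numeric(tab[[3]])
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  list(time = time, event = event, sample_ids = ids)
}

#' Write a survival table
#'
#' @param time,event survival outcomes.
#' @param sample_ids sample identifiers.
#' @param path output path.
#' @export
write_survival <- function(time, event, sample_ids, path) {
  utils::write.table(
    data.frame(sample = sample_ids, time = time, event = event),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One pathway per line: name, description, then member genes, all
#' tab-separated. Lines with fewer than three fields and duplicate
#' pathway names are errors.
#'
#' @param path file path.
#' @return named list of character vectors (pathway -> gene members).
#' @export
read_pathways <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  nm <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate pathway names")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write the simulation ground truth as JSON
#'
#' Stores the true coefficients, the relevant gene ids and an echo of the
#' configuration; the adjacency travels separately via [write_network()].
#'
#' @param truth a `sim_truth`.
#' @param config the matching [sim_config()].
#' @param path output path.
#' @export
write_truth <- function(truth, config, path) {
  obj <- list(
    beta_true = as.list(stats::setNames(truth$beta_true, truth$gene_ids)),
    relevant_genes = truth$gene_ids[truth$relevant_set],
    baseline = as.list(truth$baseline),
    config = unclass(config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Export a Kaplan-Meier curve as a points table
#'
#' @param km a `km_curve`.
#' @param path output path (TSV with columns time, survival, at_risk,
#'   n_events).
#' @export
write_km_curve <- function(km, path) {
  utils::write.table(
    data.frame(time = km$event_times, survival = km$survival,
               at_risk = km$at_risk, n_events = km$n_events),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
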