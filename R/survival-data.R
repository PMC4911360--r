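#' Construct a survival dataset
#'
#' Bundles an expression matrix with right-censored survival outcomes, the
#' unit consumed by every fitter and by the risk-stratification procedure.
#' Rows are subjects (patients), columns are genes. The observed time is
#' \eqn{t_i = \min(T_i, C_i)} and the event indicator \eqn{\delta_i} is 1
#' when the failure was observed, 0 when the subject was censored first.
#'
#' @param X numeric matrix, n subjects by p genes. All entries finite.
#' @param time positive observed times, length n.
#' @param event event indicators in \{0, 1\}, length n.
#' @param gene_ids unique gene identifiers; defaults to `colnames(X)` or
#'   `g1..gp`.
#' @param sample_ids unique sample identifiers; defaults to `rownames(X)` or
#'   `s1..sn`.
#' @return An object of class `survival_dataset` with elements `X`, `time`,
#'   `event`, `gene_ids`, `sample_ids`.
#' @export
survival_dataset <- function(X, time, event, gene_ids = NULL,
                             sample_ids = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != n || length(event) != n)
    stop("time/event length must equal nrow(X)")
  if (any(!is.finite(X)))
    stop("expression matrix contains non-finite entries")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and strictly positive")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 or 1")
  if (is.null(gene_ids)) gene_ids <- colnames(X)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(X)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != p || anyDuplicated(gene_ids))
    stop("gene_ids must be unique and match ncol(X)")
  if (length(sample_ids) != n || anyDuplicated(sample_ids))
    stop("sample_ids must be unique and match nrow(X)")
  colnames(X) <- gene_ids
  rownames(X) <- sample_ids
  structure(
    list(X = X, time = time, event = event,
         gene_ids = gene_ids, sample_ids = sample_ids),
    class = "survival_dataset")
}

#' @export
print.survival_dataset <- function(x, ...) {
  cat(sprintf("survival_dataset: %d subjects x %d genes, %d events (%.1f%% censored)\n",
              nrow(x$X), ncol(x$X), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' Subset a survival dataset by subjects
#'
#' @param data a `survival_dataset`.
#' @param idx integer or logical subject index.
#' @return a `survival_dataset` restricted to the selected subjects.
#' @export
subset_subjects <- function(data, idx) {
  survival_dataset(data$X[idx, , drop = FALSE],
                   data$time[idx], data$event[idx],
                   gene_ids = data$gene_ids,
                   sample_ids = data$sample_ids[idx])
}

# Column standardization used by the fitters: centre and scale to unit
# (population, 1/n) variance. Constant columns get scale 1 so they map to 0.
standardize_columns <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  scl <- sqrt(colSums(Xc^2) / n)
  scl[scl < 1e-12] <- 1
  list(X = sweep(Xc, 2, scl, "/"), center = ctr, scale = scl)
}
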