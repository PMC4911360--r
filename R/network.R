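#' Construct a gene network
#'
#' A weighted undirected graph over genes, stored as a sparse symmetric
#' weight matrix with zero diagonal and edge weights in [0, 1]. This is the
#' source of every Laplacian penalty in the package.
#'
#' @param W square numeric matrix (dense or `Matrix` sparse), symmetric,
#'   zero diagonal, entries in [0, 1].
#' @param gene_ids character vector of unique gene ids; defaults to the
#'   matrix dimnames or `g1..gp`.
#' @return An object of class `gene_network`: list with `gene_ids` and the
#'   sparse weight matrix `W`.
#' @export
gene_network <- function(W, gene_ids = NULL) {
  W <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  p <- nrow(W)
  if (ncol(W) != p) stop("W must be square")
  if (!Matrix::isSymmetric(W, tol = 1e-12)) stop("W must be symmetric")
  if (any(Matrix::diag(W) != 0)) stop("W must have a zero diagonal")
  x <- W@x
  if (length(x) && (any(x < 0) || any(x > 1)))
    stop("edge weights must lie in [0, 1]")
  if (is.null(gene_ids)) gene_ids <- rownames(W)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != p || anyDuplicated(gene_ids))
    stop("gene_ids must be unique and match dim(W)")
  dimnames(W) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, W = W), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  ne <- length(x$W@x[x$W@x != 0]) / 2
  cat(sprintf("gene_network: %d genes, %d edges\n", length(x$gene_ids), ne))
  invisible(x)
}

#' Symmetric degree normalization of the weight matrix
#'
#' Returns \eqn{W_n = D^{-1/2} W D^{-1/2}} with \eqn{D} the diagonal of row
#' sums (degrees). Rows and columns of isolated genes (degree 0) are zero.
#' \eqn{I - W_n} restricted to non-isolated genes is the symmetric
#' normalized graph Laplacian, positive semidefinite with spectrum in
#' [0, 2].
#'
#' @param net a [gene_network()].
#' @return sparse symmetric matrix `W_n`.
#' @export
normalize_weights <- function(net) {
  W <- net$W
  d <- Matrix::rowSums(W)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Matrix::Diagonal(x = inv_sqrt) %*% W %*% Matrix::Diagonal(x = inv_sqrt)
}

# Net-Cox smoothness operator: diag(1{d_i > 0}) - W_n. Isolated genes get a
# zero row/column (they are only penalized through the ridge term), so the
# quadratic form equals the edge sum
#   sum_{(i,j) in E} w_ij (b_i/sqrt(d_i) - b_j/sqrt(d_j))^2.
netcox_laplacian <- function(net) {
  d <- Matrix::rowSums(net$W)
  Matrix::Diagonal(x = as.numeric(d > 0)) - normalize_weights(net)
}

#' Signed normalized Laplacian for the adaptive-Laplacian L1 model
#'
#' Builds the normalized Laplacian L (1 on the diagonal where the degree is
#' non-zero, \eqn{-w_{ij}/\sqrt{d_i d_j}} on edges, 0 elsewhere) and applies
#' the sign flip \eqn{\tilde L = S' L S} with
#' \eqn{S = diag(s_1, \dots, s_p)}, where the signs come from a preliminary
#' coefficient estimate. \eqn{\tilde L} is positive semidefinite: congruence
#' by a diagonal sign matrix preserves the PSD property.
#'
#' @param net a [gene_network()].
#' @param signs vector in \{-1, +1\}, length p.
#' @return sparse symmetric matrix \eqn{\tilde L}.
#' @export
adalnet_laplacian <- function(net, signs) {
  p <- length(net$gene_ids)
  signs <- as.numeric(signs)
  if (length(signs) != p) stop("signs must have one entry per gene")
  if (!all(signs %in% c(-1, 1))) stop("signs must be -1 or +1")
  d <- Matrix::rowSums(net$W)
  L <- Matrix::Diagonal(x = as.numeric(d > 0)) - normalize_weights(net)
  S <- Matrix::Diagonal(x = signs)
  methods::as(S %*% L %*% S, "CsparseMatrix")
}

#' Binarize network weights at a threshold
#'
#' Sets each weight to 1 if strictly above `tau`, else 0 (ties at exactly
#' `tau` drop the edge). Used to adapt continuous functional-linkage weights
#' to models that expect a 0/1 adjacency.
#'
#' @param net a [gene_network()].
#' @param tau threshold in [0, 1]; default 0.5.
#' @return a [gene_network()] with binary weights.
#' @export
threshold_weights <- function(net, tau = 0.5) {
  if (tau < 0 || tau > 1) stop("tau must lie in [0, 1]")
  W <- net$W
  W@x <- as.numeric(W@x > tau)
  gene_network(Matrix::drop0(W), gene_ids = net$gene_ids)
}

#' Read a gene network from file
#'
#' Accepts either a 3-column edge list (`gene_i`, `gene_j`, `weight`,
#' tab-separated with a header) or a square weight matrix with a header row
#' of gene ids and gene ids in the first column. Duplicate edges (in either
#' orientation) are rejected.
#'
#' @param path file path.
#' @param format `"auto"` (edge list when the file has exactly 3 columns),
#'   `"edges"`, or `"matrix"`.
#' @param gene_ids optional gene universe for the edge-list form; defaults
#'   to the sorted set of genes appearing in the file.
#' @return a [gene_network()].
#' @export
read_network <- function(path, format = c("auto", "edges", "matrix"),
                         gene_ids = NULL) {
  format <- match.arg(format)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (format == "auto")
    format <- if (ncol(tab) == 3) "edges" else "matrix"
  if (format == "matrix") {
    ids <- as.character(tab[[1]])
    M <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(M) <- "double"
    if (!identical(colnames(M), ids))
      stop("matrix-form network: header gene ids must match the first column")
    return(gene_network(M, gene_ids = ids))
  }
  gi <- as.character(tab[[1]]); gj <- as.character(tab[[2]])
  w <- as.numeric(tab[[3]])
  if (any(!is.finite(w))) stop("non-numeric edge weight")
  key <- paste(pmin(gi, gj), pmax(gi, gj))
  if (anyDuplicated(key)) stop("duplicate edges in network file")
  if (any(gi == gj)) stop("self-loops are not allowed")
  if (is.null(gene_ids)) gene_ids <- sort(unique(c(gi, gj)))
  if (!all(c(gi, gj) %in% gene_ids)) stop("edge gene absent from gene_ids")
  p <- length(gene_ids)
  i <- match(gi, gene_ids); j <- match(gj, gene_ids)
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(p, p))
  gene_network(W, gene_ids = gene_ids)
}

#' Write a gene network as an edge list
#'
#' @param net a [gene_network()].
#' @param path output file path (tab-separated, header
#'   `gene_i gene_j weight`).
#' @export
write_network <- function(net, path) {
  T3 <- methods::as(Matrix::triu(net$W), "TsparseMatrix")
  keep <- T3@x != 0
  df <- data.frame(gene_i = net$gene_ids[T3@i[keep] + 1L],
                   gene_j = net$gene_ids[T3@j[keep] + 1L],
                   weight = T3@x[keep])
  df <- df[order(df$gene_i, df$gene_j), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
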