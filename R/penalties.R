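#' Ridge plus network-smoothness penalty (Net-Cox form)
#'
#' \deqn{P_{\lambda,\alpha}(\beta) =
#'   \lambda [\alpha \|\beta\|_2^2 + (1-\alpha) \beta'(I - W_n)\beta],}
#' where \eqn{W_n} is the symmetrically normalized weight matrix from
#' [normalize_weights()] and the identity is restricted to non-isolated
#' genes so that isolated genes feel only the ridge term. The smoothness
#' term charges connected gene pairs for differences between their
#' degree-scaled coefficients.
#'
#' @param beta coefficient vector.
#' @param net a [gene_network()].
#' @param lambda non-negative overall penalty weight.
#' @param alpha ridge/network trade-off in (0, 1].
#' @return penalty value (scalar, non-negative).
#' @export
netcox_penalty <- function(beta, net, lambda, alpha) {
  check_lambda_alpha(lambda, alpha)
  beta <- as.numeric(beta)
  if (length(beta) != length(net$gene_ids)) stop("dimension mismatch")
  Ln <- netcox_laplacian(net)
  quad <- as.numeric(Matrix::crossprod(beta, Ln %*% beta))
  lambda * (alpha * sum(beta^2) + (1 - alpha) * quad)
}

#' Adaptive signed-Laplacian L1 penalty (AdaLnet form)
#'
#' \deqn{P_{\lambda,\alpha}(\beta) =
#'   \lambda [\alpha \|\beta\|_1 + (1-\alpha)\, \beta' \tilde L \beta]}
#' with \eqn{\tilde L} the signed normalized Laplacian from
#' [adalnet_laplacian()]. The L1 term induces sparsity; the quadratic term
#' smooths degree-scaled, sign-aligned coefficients of neighbouring genes.
#'
#' @param beta coefficient vector.
#' @param Ltilde signed normalized Laplacian (p x p, PSD).
#' @param lambda non-negative penalty weight.
#' @param alpha L1/Laplacian trade-off in (0, 1].
#' @return penalty value (scalar, non-negative).
#' @export
adalnet_penalty <- function(beta, Ltilde, lambda, alpha) {
  check_lambda_alpha(lambda, alpha)
  beta <- as.numeric(beta)
  if (length(beta) != nrow(Ltilde)) stop("dimension mismatch")
  quad <- as.numeric(Matrix::crossprod(beta, Ltilde %*% beta))
  lambda * (alpha * sum(abs(beta)) + (1 - alpha) * quad)
}

#' Weighted elastic-net penalty
#'
#' \deqn{P_{\lambda,\alpha}(\beta) = \lambda [\alpha \sum_j w_j |\beta_j|
#'   + \tfrac{1}{2}(1-\alpha)\|\beta\|_2^2].}
#' A feature weight \eqn{w_j = 0} exempts gene j from L1 shrinkage, so it is
#' always retained in the model. No network information enters.
#'
#' @param beta coefficient vector.
#' @param feature_weights non-negative per-gene L1 weights (default all 1).
#' @param lambda non-negative penalty weight.
#' @param alpha elastic-net trade-off in (0, 1].
#' @return penalty value (scalar, non-negative).
#' @export
elasticnet_penalty <- function(beta, feature_weights = NULL, lambda, alpha) {
  check_lambda_alpha(lambda, alpha)
  beta <- as.numeric(beta)
  if (is.null(feature_weights)) feature_weights <- rep(1, length(beta))
  if (length(feature_weights) != length(beta)) stop("dimension mismatch")
  if (any(feature_weights < 0)) stop("feature weights must be non-negative")
  lambda * (alpha * sum(feature_weights * abs(beta)) +
              0.5 * (1 - alpha) * sum(beta^2))
}

#' Edge-sum form of a normalized Laplacian quadratic penalty
#'
#' Diagnostic companion to the matrix forms: evaluates
#' \deqn{\sum_{(i,j) \in E} w_{ij}
#'   (s_i \beta_i/\sqrt{d_i} - s_j \beta_j/\sqrt{d_j})^2}
#' over unordered edges. With all signs +1 this equals the Net-Cox
#' quadratic term \eqn{\beta'(I - W_n)\beta}; with signs from a preliminary
#' fit it equals \eqn{\beta'\tilde L\beta}.
#'
#' @param beta coefficient vector.
#' @param net a [gene_network()].
#' @param signs optional sign vector in \{-1, +1\} (default all +1).
#' @return the edge-sum value.
#' @export
laplacian_edge_sum <- function(beta, net, signs = NULL) {
  p <- length(net$gene_ids)
  beta <- as.numeric(beta)
  if (length(beta) != p) stop("dimension mismatch")
  if (is.null(signs)) signs <- rep(1, p)
  d <- Matrix::rowSums(net$W)
  z <- ifelse(d > 0, signs * beta / sqrt(d), 0)
  T3 <- methods::as(Matrix::triu(net$W), "TsparseMatrix")
  keep <- T3@x != 0
  i <- T3@i[keep] + 1L; j <- T3@j[keep] + 1L; w <- T3@x[keep]
  sum(w * (z[i] - z[j])^2)
}

check_lambda_alpha <- function(lambda, alpha) {
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  invisible(TRUE)
}
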