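#' Solver settings
#'
#' @param max_iter maximum outer iterations (Newton steps or IRLS rounds).
#' @param tol convergence tolerance on the relative change of the penalized
#'   objective (and on its gradient norm for the smooth fitter).
#' @param inner_max_iter maximum coordinate-descent sweeps per quadratic
#'   subproblem.
#' @return a `solver_settings` list.
#' @export
solver_settings <- function(max_iter = 200, tol = 1e-7,
                            inner_max_iter = 1000) {
  stopifnot(tol > 0, max_iter >= 1, inner_max_iter >= 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol,
                 inner_max_iter = as.integer(inner_max_iter)),
            class = "solver_settings")
}

new_cox_fit <- function(beta, objective, n_iter, converged, method,
                        lambda, alpha, gene_ids, center, scale) {
  names(beta) <- gene_ids
  structure(list(beta = beta, objective = objective, n_iter = n_iter,
                 converged = converged, method = method, lambda = lambda,
                 alpha = alpha, gene_ids = gene_ids,
                 center = center, scale = scale),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit [%s]: lambda=%g alpha=%g, %d/%d nonzero, obj=%.6g, %s\n",
              x$method, x$lambda, x$alpha, sum(x$beta != 0),
              length(x$beta), x$objective,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Prognostic index from a fitted model
#'
#' Applies the fit's training standardization (centres/scales) to new
#' expression data and returns the linear predictor.
#'
#' @param fit a `cox_fit`.
#' @param X expression matrix on the original (unstandardized) scale, with
#'   the same gene columns used at fit time.
#' @return numeric vector of prognostic indices.
#' @export
predict_pi <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(fit$beta)) stop("dimension mismatch")
  Xs <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
  prognostic_index(Xs, fit$beta)
}

# Prepare the (optionally standardized) design used by all fitters.
fitter_design <- function(data, standardize) {
  if (standardize) {
    s <- standardize_columns(data$X)
    list(X = s$X, center = s$center, scale = s$scale)
  } else {
    p <- ncol(data$X)
    list(X = data$X, center = rep(0, p), scale = rep(1, p))
  }
}

#' Fit the ridge + network-smoothness Cox model (Net-Cox)
#'
#' Maximizes the scaled penalized log-partial likelihood
#' \deqn{\frac{1}{n} pl(\beta) - \lambda[\alpha\|\beta\|_2^2 +
#'   (1-\alpha)\beta'(I - W_n)\beta]}
#' by damped Newton iteration with step-halving. The Newton system is
#' solved through the Woodbury identity: the likelihood curvature has rank
#' at most n, so each step costs one sparse Cholesky solve in the penalty
#' matrix plus an n x n dense solve, which keeps p = 1100 problems fast.
#'
#' @param data a [survival_dataset()].
#' @param net a [gene_network()] over the same genes.
#' @param lambda positive penalty weight (note the 1/n likelihood scaling).
#' @param alpha ridge/network trade-off in (0, 1].
#' @param settings a [solver_settings()].
#' @param standardize centre/scale columns before fitting (default TRUE);
#'   coefficients are reported on the standardized scale.
#' @param beta0 optional warm start (standardized scale).
#' @return a `cox_fit`.
#' @export
fit_netcox <- function(data, net, lambda, alpha,
                       settings = solver_settings(), standardize = TRUE,
                       beta0 = NULL) {
  check_lambda_alpha(lambda, alpha)
  if (lambda <= 0) stop("lambda must be > 0 for the smooth fitter")
  if (length(net$gene_ids) != ncol(data$X))
    stop("network/expression dimension mismatch")
  core <- netcox_core(data, net, alpha, standardize)
  netcox_solve(core, lambda, alpha, settings, beta0, data$gene_ids)
}

# Per-(dataset, alpha) state shared across the whole lambda grid: the
# standardized design, the event-time bookkeeping, the sparse Cholesky of
# the penalty matrix M, M^{-1}X' and the n x n kernel H = X M^{-1} X'.
netcox_core <- function(data, net, alpha, standardize) {
  des <- fitter_design(data, standardize)
  M <- netcox_penalty_matrix(net, alpha)
  chM <- Matrix::Cholesky(M, LDL = FALSE)
  MiXt <- as.matrix(Matrix::solve(chM, t(des$X)))
  list(des = des, rs = cox_risk_setup(data$time, data$event),
       M = M, chM = chM, MiXt = MiXt, H = des$X %*% MiXt,
       time = data$time, event = data$event)
}

# Damped Newton on (1/n) pl(beta) - lambda * beta' M beta. The Newton
# system (2 lambda M + X'AX/n) d = grad is solved by the push-through
# Woodbury identity
#   (Q + X'AX/n)^{-1} = Q^{-1} - Q^{-1}X'(I + (A/n) G)^{-1}(A/n) X Q^{-1},
# G = X Q^{-1} X' = H / (2 lambda), so each step costs one n x n solve
# and no p x p factorization beyond the cached sparse Cholesky of M.
netcox_solve <- function(core, lambda, alpha, settings, beta0, gene_ids) {
  des <- core$des; rs <- core$rs; M <- core$M
  n <- nrow(des$X); p <- ncol(des$X)
  beta <- if (is.null(beta0)) numeric(p) else as.numeric(beta0)
  if (length(beta) != p) stop("beta0 length mismatch")
  obj <- function(b, eta) {
    cox_rs_stats(rs, eta, need = "pl")$pl / n -
      lambda * as.numeric(Matrix::crossprod(b, M %*% b))
  }
  eta <- drop(des$X %*% beta)
  f <- obj(beta, eta)
  if (!is.finite(f)) {            # degenerate warm start: restart at 0
    beta <- numeric(p); eta <- numeric(n); f <- obj(beta, eta)
  }
  converged <- FALSE
  it <- 0
  while (it < settings$max_iter) {
    it <- it + 1
    st <- cox_rs_stats(rs, eta, need = "hess")
    grad <- drop(crossprod(des$X, st$g)) / n -
      2 * lambda * as.numeric(M %*% beta)
    if (any(!is.finite(grad))) break   # numerically degenerate; flag fit
    if (sqrt(sum(grad^2)) <= settings$tol * (1 + sqrt(sum(beta^2)))) {
      converged <- TRUE
      break
    }
    Abar <- cox_A_matrix(st) / n
    g1 <- as.numeric(Matrix::solve(core$chM, grad)) / (2 * lambda)
    t1 <- drop(des$X %*% g1)
    W <- diag(n) + Abar %*% core$H / (2 * lambda)
    y <- tryCatch(solve(W, Abar %*% t1), error = function(e) NULL)
    if (is.null(y)) break              # singular system; flag fit
    dir <- g1 - drop(core$MiXt %*% y) / (2 * lambda)
    if (any(!is.finite(dir))) break
    step <- 1
    improved <- FALSE
    for (h in 0:30) {
      cand <- beta + step * dir
      eta_c <- drop(des$X %*% cand)
      f_c <- obj(cand, eta_c)
      if (is.finite(f_c) && f_c >= f - 1e-12 * (abs(f) + 1)) {
        improved <- f_c > f
        rel <- abs(f_c - f) / (abs(f) + 1e-10)
        beta <- cand; eta <- eta_c; f <- f_c
        if (rel < settings$tol) converged <- TRUE
        break
      }
      step <- step / 2
    }
    if (converged || !improved) break
  }
  new_cox_fit(beta, f, it, converged, "netcox", lambda, alpha,
              gene_ids, des$center, des$scale)
}

# alpha * I + (1 - alpha) * (diag(1{d>0}) - W_n): positive definite for
# alpha > 0, sparse; factored once per (net, alpha).
netcox_penalty_matrix <- function(net, alpha) {
  p <- length(net$gene_ids)
  M <- alpha * Matrix::Diagonal(p) + (1 - alpha) * netcox_laplacian(net)
  Matrix::forceSymmetric(methods::as(M, "CsparseMatrix"))
}
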