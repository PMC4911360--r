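# IRLS + coordinate-descent machinery shared by the two L1 fitters.
#
# The smooth part (1/n) pl(beta) is majorized at the current beta by a
# weighted least-squares model with the true diagonal curvature as subject
# weights and working response z_i = eta_i + g_i / w_i; the penalized
# subproblem is solved exactly by cyclic coordinate descent with
# soft-thresholding (compiled, see src/cd_cox.cpp). A step-halving guard
# keeps the true penalized objective non-decreasing across outer rounds.
# Outer convergence is declared either on the relative objective change
# (settings$tol) or when refreshing the quadratic approximation no longer
# moves any coefficient beyond settings$tol in weighted-squared units —
# the same stationarity rule glmnet's `thresh` implements.

# K: sparse symmetric PSD quadratic-penalty matrix (or NULL);
# v: per-gene L1 weights. Objective maximized:
#   (1/n) pl(X b) - lambda * (alpha * sum(v |b|) + (1 - alpha) * b'Kb)
fit_l1_quad <- function(data, Xs, K, lambda, alpha, v, settings,
                        beta0 = NULL) {
  n <- nrow(Xs); p <- ncol(Xs)
  if (is.null(beta0)) beta0 <- numeric(p)
  Kc <- if (is.null(K)) {
    list(p = integer(0), i = integer(0), x = numeric(0))
  } else {
    Kg <- methods::as(methods::as(K, "generalMatrix"), "CsparseMatrix")
    list(p = Kg@p, i = Kg@i, x = Kg@x)
  }
  rs <- if (is.null(attr(data, "risk_setup")))
    cox_risk_setup(data$time, data$event) else attr(data, "risk_setup")
  quad <- function(b) {
    if (is.null(K)) 0 else as.numeric(Matrix::crossprod(b, K %*% b))
  }
  objective <- function(b, eta) {
    cox_rs_stats(rs, eta, need = "pl")$pl / n -
      lambda * (alpha * sum(v * abs(b)) + (1 - alpha) * quad(b))
  }
  beta <- beta0
  eta <- drop(Xs %*% beta)
  f <- objective(beta, eta)
  converged <- FALSE
  it <- 0
  while (it < settings$max_iter) {
    it <- it + 1
    st <- cox_rs_stats(rs, eta, need = "grad")
    w <- pmax(st$adiag, 1e-8)
    z <- eta + st$g / w
    sol <- cd_wls_l1(Xs, w, z, beta,
                     lambda * alpha, v, lambda * (1 - alpha),
                     Kc$p, Kc$i, Kc$x,
                     tol = settings$tol * 1e-2,
                     max_sweeps = settings$inner_max_iter)
    bnew <- sol$beta
    if (all(bnew == beta) || sol$maxmove < settings$tol) {
      if (sol$maxmove > 0) {
        eta <- drop(Xs %*% bnew)
        f <- objective(bnew, eta)
        beta <- bnew
      }
      converged <- TRUE
      break
    }
    step <- 1
    accepted <- FALSE
    for (h in 0:30) {
      cand <- beta + step * (bnew - beta)
      eta_c <- drop(Xs %*% cand)
      f_c <- objective(cand, eta_c)
      if (is.finite(f_c) && f_c >= f - 1e-12 * (abs(f) + 1)) {
        rel <- abs(f_c - f) / (abs(f) + 1e-10)
        # only a full IRLS step preserves exact zeros; treat a converged
        # half-step as converged only if the solution did not move
        if (rel < settings$tol && step == 1) converged <- TRUE
        beta <- cand; eta <- eta_c; f <- f_c
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (converged || !accepted) break
  }
  list(beta = beta, objective = f, n_iter = it, converged = converged)
}

#' Fit the adaptive signed-Laplacian L1 Cox model (AdaLnet)
#'
#' Two-stage fit of
#' \deqn{\frac{1}{n} pl(\beta) - \lambda[\alpha\|\beta\|_1 +
#'   (1-\alpha)\beta'\tilde L\beta].}
#' Stage 1 maximizes the same objective with the unsigned normalized
#' Laplacian (all signs +1) to obtain the preliminary estimate
#' \eqn{\tilde\beta}; stage 2 builds \eqn{\tilde L = S'LS} from
#' \eqn{sign(\tilde\beta)} (zeros count as +1) and refits. Each stage is
#' solved by iteratively reweighted quadratic approximation with cyclic
#' coordinate descent and soft-thresholding, so returned coefficients are
#' exactly zero outside the active set.
#'
#' @inheritParams fit_netcox
#' @return a `cox_fit` with an extra element `signs` (the stage-1 signs).
#' @export
fit_adalnet <- function(data, net, lambda, alpha,
                        settings = solver_settings(), standardize = TRUE) {
  check_lambda_alpha(lambda, alpha)
  p <- ncol(data$X)
  if (length(net$gene_ids) != p) stop("network/expression dimension mismatch")
  des <- fitter_design(data, standardize)
  v <- rep(1, p)
  L <- adalnet_laplacian(net, rep(1, p))
  s1 <- fit_l1_quad(data, des$X, L, lambda, alpha, v, settings)
  signs <- ifelse(s1$beta < 0, -1, 1)
  Lt <- adalnet_laplacian(net, signs)
  s2 <- fit_l1_quad(data, des$X, Lt, lambda, alpha, v, settings,
                    beta0 = s1$beta)
  fit <- new_cox_fit(s2$beta, s2$objective, s1$n_iter + s2$n_iter,
                     s1$converged && s2$converged, "adalnet",
                     lambda, alpha, data$gene_ids, des$center, des$scale)
  fit$signs <- signs
  fit
}

#' Fit the weighted elastic-net Cox model
#'
#' Maximizes
#' \deqn{\frac{1}{n} pl(\beta) - \lambda[\alpha\sum_j w_j|\beta_j| +
#'   \tfrac{1}{2}(1-\alpha)\|\beta\|_2^2]}
#' by the same majorize-then-coordinate-descent scheme as [fit_adalnet()].
#' Setting a feature weight to zero exempts that gene from L1 shrinkage.
#'
#' @inheritParams fit_netcox
#' @param feature_weights non-negative per-gene L1 weights (default 1).
#' @return a `cox_fit`.
#' @export
fit_elasticnet_cox <- function(data, feature_weights = NULL, lambda, alpha,
                               settings = solver_settings(),
                               standardize = TRUE) {
  check_lambda_alpha(lambda, alpha)
  p <- ncol(data$X)
  if (is.null(feature_weights)) feature_weights <- rep(1, p)
  if (length(feature_weights) != p) stop("feature_weights length mismatch")
  if (any(feature_weights < 0)) stop("feature weights must be non-negative")
  des <- fitter_design(data, standardize)
  K <- 0.5 * Matrix::Diagonal(p)
  s <- fit_l1_quad(data, des$X, K, lambda, alpha, feature_weights, settings)
  new_cox_fit(s$beta, s$objective, s$n_iter, s$converged, "elasticnet",
              lambda, alpha, data$gene_ids, des$center, des$scale)
}

#' Penalty-weight sequence for the L1 fitters
#'
#' For the L1-penalized methods, computes \eqn{\lambda_{max}}, the smallest
#' penalty at which the all-zero solution satisfies the KKT conditions:
#' \eqn{\lambda_{max} = \max_j |\nabla_j \frac{1}{n} pl(0)| / (\alpha v_j)},
#' then returns a log-spaced decreasing sequence down to
#' `lambda_max * min_ratio`. For the ridge-type network fitter the fixed
#' grid \eqn{\{10^{-5}, 10^{-4}, 10^{-3}, 10^{-2}, 10^{-1}, 1\}} is
#' returned instead; those values are stated in unscaled-likelihood units,
#' so they are divided by n to match this package's 1/n-scaled objective.
#'
#' @param data a [survival_dataset()].
#' @param method `"netcox"`, `"adalnet"` or `"elasticnet"`.
#' @param n_lambda number of path points (default 30).
#' @param min_ratio ratio of smallest to largest lambda (default 0.01).
#' @param alpha the L1 trade-off used in the KKT bound (default 0.5).
#' @param feature_weights per-gene L1 weights (elastic net only).
#' @param standardize match the fitter's standardization (default TRUE).
#' @return decreasing positive numeric vector.
#' @export
lambda_path <- function(data, method = c("adalnet", "elasticnet", "netcox"),
                        n_lambda = 30, min_ratio = 1e-2, alpha = 0.5,
                        feature_weights = NULL, standardize = TRUE) {
  method <- match.arg(method)
  if (method == "netcox") return(10^(0:-5) / nrow(data$X))
  stopifnot(n_lambda >= 2, min_ratio > 0, min_ratio < 1)
  check_lambda_alpha(1, alpha)
  des <- fitter_design(data, standardize)
  n <- nrow(des$X)
  st <- cox_eta_stats(data$time, data$event, numeric(n), need = "grad")
  g0 <- abs(drop(crossprod(des$X, st$g))) / n
  if (all(g0 < 1e-14)) stop("degenerate data: zero score at beta = 0")
  v <- if (is.null(feature_weights)) rep(1, ncol(des$X)) else feature_weights
  ratio <- ifelse(v > 0, g0 / (alpha * v), 0)  # unpenalized genes put no
  lmax <- max(ratio)                           # constraint on lambda_max
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

# Dispatch a single fit by method name; used by cross-validation, the
# stratification procedure and the study driver.
fit_cox_penalized <- function(data, method, lambda, alpha, net = NULL,
                              feature_weights = NULL,
                              settings = solver_settings(),
                              standardize = TRUE) {
  switch(method,
    netcox = fit_netcox(data, net, lambda, alpha, settings, standardize),
    adalnet = fit_adalnet(data, net, lambda, alpha, settings, standardize),
    elasticnet = fit_elasticnet_cox(data, feature_weights, lambda, alpha,
                                    settings, standardize),
    stop("unknown method: ", method))
}
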