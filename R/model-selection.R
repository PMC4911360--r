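#' Random fold assignment
#'
#' Partitions `n` subjects into `K` folds whose sizes differ by at most
#' one; deterministic given the seed. Optionally stratifies by the event
#' indicator so each fold receives a near-proportional share of events
#' (off by default).
#'
#' @param n number of subjects.
#' @param K number of folds, `2 <= K <= n`.
#' @param seed integer seed.
#' @param event optional 0/1 vector of length n; when given, folds are
#'   drawn separately within events and censored subjects.
#' @return integer vector of fold labels in `1..K`, length n.
#' @export
assign_folds <- function(n, K, seed = 1L, event = NULL) {
  if (K < 2 || K > n) stop("K must lie in [2, n]")
  set.seed(seed)
  if (is.null(event)) return(sample(rep(seq_len(K), length.out = n)))
  if (length(event) != n) stop("event must have length n")
  folds <- integer(n)
  for (lev in unique(event)) {
    idx <- which(event == lev)
    folds[idx] <- sample(rep(seq_len(K), length.out = length(idx)))
  }
  folds
}

#' Cross-validated partial likelihood (CVPL)
#'
#' The van Houwelingen criterion: for each fold k the model is fitted on
#' the complement and
#' \deqn{CVPL(\lambda,\alpha) = -\frac{1}{n}\sum_{k=1}^K
#'   \{\ell(\hat\beta^{(-k)}) - \ell^{(-k)}(\hat\beta^{(-k)})\},}
#' where \eqn{\ell} is the (unscaled) log-partial likelihood on the full
#' sample and \eqn{\ell^{(-k)}} on the training fold alone. Lower is
#' better.
#'
#' @param data a [survival_dataset()].
#' @param folds fold labels from [assign_folds()].
#' @param method `"netcox"`, `"adalnet"` or `"elasticnet"`.
#' @param lambda,alpha penalty parameters to evaluate.
#' @param net a [gene_network()] (network methods).
#' @param feature_weights elastic-net L1 weights.
#' @param settings a [solver_settings()].
#' @param standardize centre/scale within each training fold.
#' @return the CVPL value (scalar).
#' @export
cvpl <- function(data, folds, method, lambda, alpha, net = NULL,
                 feature_weights = NULL, settings = solver_settings(),
                 standardize = TRUE) {
  n <- nrow(data$X)
  if (length(folds) != n) stop("folds must label every subject")
  total <- 0
  for (k in sort(unique(folds))) {
    train <- subset_subjects(data, folds != k)
    fit <- fit_cox_penalized(train, method, lambda, alpha, net = net,
                             feature_weights = feature_weights,
                             settings = settings, standardize = standardize)
    total <- total + cvpl_fold_term(fit, data, train)
  }
  -total / n
}

# l(full) - l(train) at the training-fold estimate, both unscaled; the
# linear predictor applies the training standardization to all subjects.
cvpl_fold_term <- function(fit, data, train) {
  eta_full <- predict_pi(fit, data$X)
  eta_train <- predict_pi(fit, train$X)
  l_full <- cox_eta_stats(data$time, data$event, eta_full, need = "pl")$pl
  l_train <- cox_eta_stats(train$time, train$event, eta_train,
                           need = "pl")$pl
  l_full - l_train
}

# Fit a decreasing lambda sequence with warm starts; returns standardized
# coefficients as a p x length(lambdas) matrix plus the standardization.
fit_path <- function(data, method, lambdas, alpha, net = NULL,
                     feature_weights = NULL, settings = solver_settings(),
                     standardize = TRUE) {
  des <- fitter_design(data, standardize)
  attr(data, "risk_setup") <- cox_risk_setup(data$time, data$event)
  p <- ncol(des$X)
  L <- length(lambdas)
  betas <- matrix(0, p, L)
  conv <- logical(L)
  objective <- numeric(L)
  if (method == "netcox") {
    core <- netcox_core(data, net, alpha, standardize)
    b <- NULL
    for (l in seq_len(L)) {
      fit <- netcox_solve(core, lambdas[l], alpha, settings, b,
                          data$gene_ids)
      b <- betas[, l] <- fit$beta
      conv[l] <- fit$converged; objective[l] <- fit$objective
    }
  } else if (method == "adalnet") {
    v <- rep(1, p)
    Lmat <- adalnet_laplacian(net, rep(1, p))
    b1 <- b2 <- NULL
    for (l in seq_len(L)) {
      s1 <- fit_l1_quad(data, des$X, Lmat, lambdas[l], alpha, v, settings,
                        beta0 = b1)
      b1 <- s1$beta
      signs <- ifelse(b1 < 0, -1, 1)
      Lt <- adalnet_laplacian(net, signs)
      s2 <- fit_l1_quad(data, des$X, Lt, lambdas[l], alpha, v, settings,
                        beta0 = if (is.null(b2)) b1 else b2)
      b2 <- betas[, l] <- s2$beta
      conv[l] <- s1$converged && s2$converged
      objective[l] <- s2$objective
    }
  } else if (method == "elasticnet") {
    v <- if (is.null(feature_weights)) rep(1, p) else feature_weights
    K <- 0.5 * Matrix::Diagonal(p)
    b <- NULL
    for (l in seq_len(L)) {
      s <- fit_l1_quad(data, des$X, K, lambdas[l], alpha, v, settings,
                       beta0 = b)
      b <- betas[, l] <- s$beta
      conv[l] <- s$converged; objective[l] <- s$objective
    }
  } else stop("unknown method: ", method)
  list(betas = betas, center = des$center, scale = des$scale,
       converged = conv, objective = objective)
}

path_eta <- function(path, X) {
  Xs <- sweep(sweep(X, 2, path$center, "-"), 2, path$scale, "/")
  Xs %*% path$betas
}

#' Tune penalty parameters by K-fold cross-validated partial likelihood
#'
#' Evaluates [cvpl()] over a full (alpha, lambda) grid and returns the
#' minimizer. For the ridge-type network fitter the lambda grid defaults to
#' the fixed set \eqn{\{10^{-5}, \dots, 1\}}; for the L1 fitters a
#' decreasing path is generated per alpha by [lambda_path()] on the full
#' data. Fold-wise fits are warm-started along each path. Ties are broken
#' toward larger lambda, then larger alpha (the smoother/sparser model).
#'
#' @inheritParams cvpl
#' @param alpha_grid alpha values to search.
#' @param lambda_grid optional explicit lambda values (shared across
#'   alphas); default chosen per method.
#' @param K number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @param n_lambda,min_ratio path controls for the L1 methods.
#' @param stratify_folds draw folds stratified by the event indicator
#'   (default FALSE).
#' @param refit also fit the full data at the optimum (element `fit`).
#' @return a `cv_result`: `grid` (data.frame alpha/lambda), `cvpl`, `best`
#'   (list with `lambda`, `alpha`), `fold_assignment`, and optionally
#'   `fit`.
#' @export
select_tuning <- function(data, method, alpha_grid, lambda_grid = NULL,
                          K = 5, seed = 1L, net = NULL,
                          feature_weights = NULL,
                          settings = solver_settings(),
                          standardize = TRUE, n_lambda = 30,
                          min_ratio = 1e-2, stratify_folds = FALSE,
                          refit = TRUE) {
  if (length(alpha_grid) == 0) stop("empty alpha grid")
  n <- nrow(data$X)
  folds <- assign_folds(n, K, seed,
                        event = if (stratify_folds) data$event else NULL)
  grids <- lapply(alpha_grid, function(a) {
    lam <- if (!is.null(lambda_grid)) sort(lambda_grid, decreasing = TRUE)
           else if (method == "netcox") lambda_path(data, "netcox")
           else lambda_path(data, method, n_lambda = n_lambda,
                            min_ratio = min_ratio, alpha = a,
                            feature_weights = feature_weights,
                            standardize = standardize)
    if (length(lam) == 0) stop("empty lambda grid")
    lam
  })
  rows <- do.call(rbind, lapply(seq_along(alpha_grid), function(ai)
    data.frame(alpha = alpha_grid[ai], lambda = grids[[ai]])))
  terms <- numeric(nrow(rows))
  for (k in seq_len(K)) {
    train <- subset_subjects(data, folds != k)
    off <- 0
    for (ai in seq_along(alpha_grid)) {
      lam <- grids[[ai]]
      pth <- fit_path(train, method, lam, alpha_grid[ai], net = net,
                      feature_weights = feature_weights,
                      settings = settings, standardize = standardize)
      eta_full <- path_eta(pth, data$X)
      eta_train <- path_eta(pth, train$X)
      for (l in seq_along(lam)) {
        lf <- cox_eta_stats(data$time, data$event, eta_full[, l],
                            need = "pl")$pl
        lt <- cox_eta_stats(train$time, train$event, eta_train[, l],
                            need = "pl")$pl
        terms[off + l] <- terms[off + l] + (lf - lt)
      }
      off <- off + length(lam)
    }
  }
  cv <- -terms / n
  cv[!is.finite(cv)] <- Inf          # degenerate corner fits never win
  # minimize; ties toward larger lambda then larger alpha
  best_idx <- order(cv, -rows$lambda, -rows$alpha)[1]
  best <- list(lambda = rows$lambda[best_idx], alpha = rows$alpha[best_idx])
  out <- structure(list(grid = rows, cvpl = cv, best = best,
                        fold_assignment = folds), class = "cv_result")
  if (refit)
    out$fit <- fit_cox_penalized(data, method, best$lambda, best$alpha,
                                 net = net,
                                 feature_weights = feature_weights,
                                 settings = settings,
                                 standardize = standardize)
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d grid points, best lambda=%g alpha=%g (CVPL=%.4f)\n",
              nrow(x$grid), x$best$lambda, x$best$alpha, min(x$cvpl)))
  invisible(x)
}
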