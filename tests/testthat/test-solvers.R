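# independent ridge-Cox Newton (dense, small p) used as a reduction oracle
ridge_cox_oracle <- function(data, lambda, standardize = TRUE) {
  Xs <- if (standardize) {
    n <- nrow(data$X)
    sc <- scale(data$X, TRUE, FALSE)
    sweep(sc, 2, sqrt(colSums(sc^2) / n), "/")
  } else data$X
  n <- nrow(Xs); p <- ncol(Xs)
  beta <- rep(0, p)
  for (it in 1:100) {
    gh <- pl_gradient_hessian(beta, survival_dataset(Xs, data$time,
                                                     data$event))
    grad <- gh$gradient / n - 2 * lambda * beta
    Hp <- gh$hessian / n - 2 * lambda * diag(p)
    step <- solve(-Hp, grad)
    beta <- beta + step
    if (sqrt(sum(grad^2)) < 1e-10) break
  }
  unname(beta)
}

test_that("huge penalties shrink the smooth fit to zero", {
  d <- toy_surv_data(30, 4, seed = 51, beta = c(1, -1, 0, 0))
  net <- toy_network(4, density = 0.5, seed = 51)
  f <- fit_netcox(d, net, lambda = 1e6, alpha = 0.5)
  expect_lt(max(abs(f$beta)), 1e-3)
})

test_that("smooth fitter matches a generic optimizer on small instances", {
  d <- toy_surv_data(40, 5, seed = 52, beta = c(0.8, -0.6, 0, 0, 0.4))
  net <- toy_network(5, density = 0.5, seed = 52)
  lambda <- 0.05; alpha <- 0.4
  f <- fit_netcox(d, net, lambda, alpha)
  n <- nrow(d$X)
  des <- netcoxkm:::fitter_design(d, TRUE)
  objective <- function(b)
    brute_logpl(b, des$X, d$time, d$event) / n -
      netcox_penalty(b, net, lambda, alpha)
  orc <- oracle_maximize(objective, 5)
  expect_equal(f$objective, orc$value, tolerance = 1e-4)
  expect_true(f$converged)
})

test_that("alpha = 1 reduces the smooth fitter to ridge Cox", {
  d <- toy_surv_data(35, 4, seed = 53, beta = c(1, 0, -0.5, 0))
  net <- toy_network(4, density = 0.4, seed = 53)
  f <- fit_netcox(d, net, lambda = 0.1, alpha = 1)
  expect_equal(unname(f$beta), ridge_cox_oracle(d, 0.1), tolerance = 1e-5)
})

test_that("adaptive-Laplacian fit with empty network equals a lasso fit", {
  d <- toy_surv_data(50, 6, seed = 54, beta = c(1.2, -1, 0, 0, 0, 0))
  empty <- gene_network(matrix(0, 6, 6))
  lambda <- 0.08
  f <- fit_adalnet(d, empty, lambda, alpha = 1,
                   settings = solver_settings(tol = 1e-9))
  # same objective solved by the elastic-net coordinate descent with no
  # ridge term (alpha = 1)
  g <- fit_elasticnet_cox(d, lambda = lambda, alpha = 1,
                          settings = solver_settings(tol = 1e-9))
  expect_equal(unname(f$beta), unname(g$beta), tolerance = 1e-4)
  skip_if_not_installed("glmnet")
  # independent implementation: glmnet Cox with the same 1/n objective
  y <- survival::Surv(d$time, d$event)
  gl <- glmnet::glmnet(d$X, y, family = "cox", alpha = 1,
                       lambda = lambda, standardize = TRUE,
                       thresh = 1e-14)
  bg <- as.numeric(gl$beta)
  # glmnet reports coefficients on the original scale; move ours back
  ours <- unname(f$beta) / unname(f$scale)
  expect_equal(ours, bg, tolerance = 1e-3)
})

test_that("weighted elastic-net fit matches glmnet", {
  skip_if_not_installed("glmnet")
  d <- toy_surv_data(60, 8, seed = 55,
                     beta = c(1, -0.8, 0.6, 0, 0, 0, 0, 0))
  for (alpha in c(0.5, 1)) {
    lambda <- 0.06
    f <- fit_elasticnet_cox(d, lambda = lambda, alpha = alpha)
    y <- survival::Surv(d$time, d$event)
    gl <- glmnet::glmnet(d$X, y, family = "cox", alpha = alpha,
                         lambda = lambda, standardize = TRUE,
                         thresh = 1e-14)
    ours <- unname(f$beta) / unname(f$scale)
    expect_equal(ours, as.numeric(gl$beta), tolerance = 1e-3)
  }
})

test_that("zero feature weights exempt genes from L1 shrinkage", {
  d <- toy_surv_data(40, 4, seed = 56, beta = c(1, -1, 0, 0))
  w0 <- rep(0, 4)
  f <- fit_elasticnet_cox(d, feature_weights = w0, lambda = 0.05,
                          alpha = 1)
  # alpha = 1 and all weights zero: no penalty at all on this instance;
  # every coordinate is active
  expect_true(all(f$beta != 0))
  n <- nrow(d$X)
  des <- netcoxkm:::fitter_design(d, TRUE)
  objective <- function(b) brute_logpl(b, des$X, d$time, d$event) / n
  orc <- oracle_maximize(objective, 4)
  expect_equal(f$objective, orc$value, tolerance = 1e-3)
})

test_that("the lambda path boundary gives an exactly zero solution", {
  d <- toy_surv_data(45, 6, seed = 57, beta = c(1, -1, 0.5, 0, 0, 0))
  net <- toy_network(6, density = 0.4, seed = 57)
  for (method in c("adalnet", "elasticnet")) {
    lp <- lambda_path(d, method, n_lambda = 10, alpha = 0.7)
    expect_true(all(diff(lp) < 0))
    # log-spacing
    expect_equal(diff(log(lp)), rep(diff(log(lp))[1], 9), tolerance = 1e-9)
    fit_at <- function(lam) {
      if (method == "adalnet") fit_adalnet(d, net, lam, 0.7)
      else fit_elasticnet_cox(d, lambda = lam, alpha = 0.7)
    }
    expect_equal(sum(fit_at(lp[1])$beta != 0), 0)
    expect_equal(sum(fit_at(lp[1] * 1.01)$beta != 0), 0)
    expect_gte(sum(fit_at(lp[1] * 0.5)$beta != 0), 1)
  }
  # smooth fitter uses the fixed grid in unscaled units over n
  expect_equal(lambda_path(d, "netcox"), 10^(0:-5) / nrow(d$X))
})

test_that("KKT conditions hold at the L1 solutions", {
  d <- toy_surv_data(50, 6, seed = 58, beta = c(1.5, -1, 0, 0, 0, 0))
  net <- toy_network(6, density = 0.4, seed = 58)
  lambda <- 0.05; alpha <- 0.6
  tol <- 1e-4
  des <- netcoxkm:::fitter_design(d, TRUE)
  n <- nrow(des$X)
  check_kkt <- function(beta, K) {
    eta <- drop(des$X %*% beta)
    st <- netcoxkm:::cox_eta_stats(d$time, d$event, eta, need = "grad")
    g <- drop(crossprod(des$X, st$g)) / n -
      2 * lambda * (1 - alpha) * as.numeric(K %*% beta)
    thr <- lambda * alpha
    for (j in seq_along(beta)) {
      if (beta[j] == 0) expect_lte(abs(g[j]), thr + tol)
      else expect_lt(abs(g[j] - thr * sign(beta[j])), tol)
    }
  }
  fa <- fit_adalnet(d, net, lambda, alpha,
                    settings = solver_settings(tol = 1e-9))
  check_kkt(unname(fa$beta), adalnet_laplacian(net, fa$signs))
  fe <- fit_elasticnet_cox(d, lambda = lambda, alpha = alpha,
                           settings = solver_settings(tol = 1e-9))
  check_kkt(unname(fe$beta), 0.5 * Matrix::Diagonal(6))
})

test_that("all three fitters match the generic optimizer (p <= 8)", {
  d <- toy_surv_data(45, 6, seed = 59, beta = c(1, -1, 0.5, 0, 0, 0))
  net <- toy_network(6, density = 0.5, seed = 59)
  des <- netcoxkm:::fitter_design(d, TRUE)
  n <- nrow(d$X)
  lambda <- 0.05; alpha <- 0.5
  pl_n <- function(b) brute_logpl(b, des$X, d$time, d$event) / n

  f1 <- fit_netcox(d, net, lambda, alpha)
  o1 <- oracle_maximize(function(b)
    pl_n(b) - netcox_penalty(b, net, lambda, alpha), 6)
  expect_equal(f1$objective, o1$value, tolerance = 1e-4)

  f2 <- fit_adalnet(d, net, lambda, alpha)
  Lt <- adalnet_laplacian(net, f2$signs)
  o2 <- oracle_maximize(function(b)
    pl_n(b) - adalnet_penalty(b, Lt, lambda, alpha), 6)
  expect_equal(f2$objective, o2$value, tolerance = 1e-4)

  f3 <- fit_elasticnet_cox(d, lambda = lambda, alpha = alpha)
  o3 <- oracle_maximize(function(b)
    pl_n(b) - elasticnet_penalty(b, rep(1, 6), lambda, alpha), 6)
  expect_equal(f3$objective, o3$value, tolerance = 1e-4)
})

test_that("warm-started path solutions vary continuously", {
  d <- toy_surv_data(50, 6, seed = 60, beta = c(1, -1, 0.5, 0, 0, 0))
  lp <- lambda_path(d, "elasticnet", n_lambda = 15, alpha = 1)
  pth <- netcoxkm:::fit_path(d, "elasticnet", lp, 1)
  jumps <- vapply(2:15, function(l)
    sqrt(sum((pth$betas[, l] - pth$betas[, l - 1])^2)), numeric(1))
  expect_lt(max(jumps), 1.0)
  expect_true(all(pth$converged))
})
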