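# connected components of a 0/1 adjacency via union-find (test-side oracle)
n_components <- function(A) {
  p <- nrow(A)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  T3 <- methods::as(methods::as(A, "generalMatrix"), "TsparseMatrix")
  for (k in seq_along(T3@x)) {
    if (T3@x[k] != 0) {
      ri <- find(T3@i[k] + 1L); rj <- find(T3@j[k] + 1L)
      if (ri != rj) parent[ri] <- rj
    }
  }
  length(unique(vapply(seq_len(p), find, integer(1))))
}

test_that("configuration is validated", {
  expect_error(sim_config(1, n_relevant_networks = 101), "exceed")
  expect_error(sim_config(2, n_relevant_networks = 4), "8 relevant")
  expect_error(sim_config(1, censor_low = 5, censor_high = 2), "censor_low")
  expect_error(sim_config(1, correlation = 1.2), "correlation")
})

test_that("disjoint-network truth has the documented structure", {
  cfg <- sim_config(1, seed = 3)
  tr <- build_truth(cfg)
  p <- length(tr$beta_true)
  expect_equal(p, 1100)
  expect_equal(length(tr$relevant_set), 88)
  deg <- Matrix::rowSums(tr$adjacency)
  expect_true(all(deg[tr$tf_flags] == 10))
  expect_true(all(deg[!tr$tf_flags] == 1))
  expect_equal(n_components(tr$adjacency), 100)
  expect_true(Matrix::isSymmetric(tr$adjacency))
  expect_true(all(Matrix::diag(tr$adjacency) == 0))
  expect_true(all(tr$adjacency@x %in% c(0, 1)))
  # coefficient sign blocks: first 44 positive in (0.1, 1),
  # last 44 negative in (-1.5, -0.1); zero outside the relevant set
  b <- tr$beta_true[tr$relevant_set]
  expect_true(all(b[1:44] > 0.1 & b[1:44] < 1))
  expect_true(all(b[45:88] > -1.5 & b[45:88] < -0.1))
  expect_true(all(tr$beta_true[-tr$relevant_set] == 0))
})

test_that("smallest instance builds a single-edge network", {
  cfg <- sim_config(1, n_networks = 1, genes_per_network = 2,
                    n_relevant_networks = 1, seed = 1)
  tr <- build_truth(cfg)
  expect_equal(as.matrix(tr$adjacency), matrix(c(0, 1, 1, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(tr$beta_true != 0), 2)
})

test_that("overlapped truth adds a complete bipartite block", {
  cfg <- sim_config(2, seed = 4)
  tr <- build_truth(cfg)
  n_edges <- sum(tr$adjacency != 0) / 2
  expect_equal(n_edges, 100 * 10 + 44 * 44)
  inner <- which(tr$network_assignment %in% 3:6)
  outer <- which(tr$network_assignment %in% c(1, 2, 7, 8))
  expect_true(all(as.matrix(tr$adjacency[inner, outer]) == 1))
  # coefficient blocks: 22 in (0.1, 0.5), 44 in (-0.1, 0.1), 22 in (-1, -0.5)
  b <- tr$beta_true[tr$relevant_set]
  expect_true(all(b[1:22] > 0.1 & b[1:22] < 0.5))
  expect_true(all(abs(b[23:66]) < 0.1))
  expect_true(all(b[67:88] > -1 & b[67:88] < -0.5))
})

test_that("TF-regulated correlation structure is as constructed", {
  cfg <- sim_config(1, n_networks = 2, n_relevant_networks = 2,
                    n_samples = 100000, seed = 6)
  tr <- build_truth(cfg)
  X <- sample_expression(tr, cfg)
  # first regulated gene is activated (+0.7), last repressed (-0.7)
  expect_equal(cor(X[, 1], X[, 2]), 0.7, tolerance = 0.01)
  expect_equal(cor(X[, 1], X[, 11]), -0.7, tolerance = 0.01)
  # columns are marginally standard normal
  expect_equal(mean(X[, 5]), 0, tolerance = 0.02)
  expect_equal(var(X[, 5]), 1, tolerance = 0.02)
})

test_that("marginal law: columns pass a KS test against N(0,1)", {
  cfg <- sim_config(1, n_networks = 2, n_relevant_networks = 2,
                    n_samples = 10000, seed = 16)
  tr <- build_truth(cfg)
  X <- sample_expression(tr, cfg)
  pv <- apply(X, 2, function(x) stats::ks.test(x, "pnorm")$p.value)
  # Bonferroni over the 22 columns at alpha = 0.01
  expect_true(min(pv) > 0.01 / length(pv))
})

test_that("overlapped-scenario expression carries AR(1) covariance", {
  cfg <- sim_config(2, n_networks = 8, n_samples = 100000, seed = 8)
  tr <- build_truth(cfg)
  X <- sample_expression(tr, cfg)
  expect_equal(cor(X[, 3], X[, 4]), 0.5, tolerance = 0.01)
  expect_equal(cor(X[, 3], X[, 5]), 0.25, tolerance = 0.015)
})

test_that("survival generation follows the Weibull Cox model", {
  # null coefficients: closed-form Weibull median 2 * log(2)^(1/5)
  cfg <- sim_config(1, n_networks = 2, n_relevant_networks = 2,
                    n_samples = 100000, seed = 12)
  tr <- build_truth(cfg)
  tr$beta_true[] <- 0
  X <- sample_expression(tr, cfg)
  sv <- sample_survival(X, tr, cfg)
  expect_equal(median(sv$failure_time), 2 * log(2)^(1 / 5),
               tolerance = 0.01)
  expect_true(all(sv$time > 0))
  expect_true(all(sv$event %in% c(0, 1)))
  # proportional hazards: doubling the hazard exp(eta) halves the median
  # cumulative baseline hazard H0(T) = (T/b)^a
  tr2 <- tr
  tr2$beta_true[1] <- log(2)   # eta = log(2) * X1
  X1 <- matrix(1, 50000, ncol(X))  # X1 column = 1 doubles the hazard
  X0 <- matrix(0, 50000, ncol(X))
  s1 <- sample_survival(X1, tr2, cfg)
  s0 <- sample_survival(X0, tr2, cfg)
  H0 <- function(t) (t / 2)^5
  expect_equal(median(H0(s1$failure_time)) / median(H0(s0$failure_time)),
               0.5, tolerance = 0.05)
  # censoring times independent of expression
  cfg3 <- sim_config(1, n_networks = 2, n_relevant_networks = 2,
                     n_samples = 20000, seed = 13)
  tr3 <- build_truth(cfg3)
  X3 <- sample_expression(tr3, cfg3)
  sv3 <- sample_survival(X3, tr3, cfg3)
  expect_lt(max(abs(cor(sv3$censor_time, X3[, 1:5]))), 0.03)
})

test_that("per-network noise summary behaves on known inputs", {
  cfg <- sim_config(1, n_networks = 2, n_relevant_networks = 2,
                    n_samples = 500, seed = 14)
  tr <- build_truth(cfg)
  # constant columns: zero noise
  Xc <- matrix(5, 500, 22)
  expect_equal(quantify_noise(Xc, tr), c(0, 0))
  # simulated columns: unit variance by construction
  X <- sample_expression(tr, cfg)
  expect_equal(quantify_noise(X, tr), c(1, 1), tolerance = 0.15)
})

test_that("identical seeds give bit-identical datasets", {
  cfg <- sim_config(1, n_networks = 3, n_relevant_networks = 2,
                    n_samples = 40, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$data$X, b$data$X)
  expect_identical(a$data$time, b$data$time)
  expect_identical(a$truth$beta_true, b$truth$beta_true)
  cfg2 <- cfg; cfg2$seed <- 100L
  c2 <- simulate_dataset(cfg2)
  expect_false(identical(a$data$X, c2$data$X))
})
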