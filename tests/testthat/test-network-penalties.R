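test_that("gene_network validates symmetry, diagonal and weight range", {
  W <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_s3_class(gene_network(W), "gene_network")
  expect_error(gene_network(matrix(c(0, 0.5, 0.2, 0), 2, 2)), "symmetric")
  expect_error(gene_network(matrix(c(1, 0, 0, 0), 2, 2)), "diagonal")
  expect_error(gene_network(matrix(c(0, 2, 2, 0), 2, 2)), "0, 1")
})

test_that("normalized weights have the expected structure and spectrum", {
  # empty graph: all zero
  net0 <- gene_network(matrix(0, 3, 3))
  expect_equal(as.matrix(normalize_weights(net0)), matrix(0, 3, 3),
               ignore_attr = TRUE)
  # two nodes, one unit edge: degrees 1, off-diagonals 1
  net2 <- gene_network(matrix(c(0, 1, 1, 0), 2, 2))
  Wn <- as.matrix(normalize_weights(net2))
  expect_equal(Wn, matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
  # spectrum of I - W_n on random graphs lies in [0, 2]
  for (s in 1:5) {
    net <- toy_network(7, density = 0.4, seed = s)
    Ln <- diag(as.numeric(Matrix::rowSums(net$W) > 0)) -
      as.matrix(normalize_weights(net))
    ev <- eigen(Ln, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-10 & ev <= 2 + 1e-10))
  }
})

test_that("signed Laplacian flips edge signs and stays PSD", {
  net2 <- gene_network(matrix(c(0, 1, 1, 0), 2, 2))
  L <- as.matrix(adalnet_laplacian(net2, c(1, 1)))
  expect_equal(L, matrix(c(1, -1, -1, 1), 2, 2), ignore_attr = TRUE)
  Lpm <- as.matrix(adalnet_laplacian(net2, c(1, -1)))
  expect_equal(Lpm, matrix(c(1, 1, 1, 1), 2, 2), ignore_attr = TRUE)
  set.seed(4)
  for (s in 1:5) {
    net <- toy_network(6, density = 0.5, seed = 40 + s)
    signs <- sample(c(-1, 1), 6, replace = TRUE)
    ev <- eigen(as.matrix(adalnet_laplacian(net, signs)),
                symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1e-8))
  }
  # isolated gene keeps a zero row
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  L3 <- as.matrix(adalnet_laplacian(gene_network(W), rep(1, 3)))
  expect_equal(L3[3, ], rep(0, 3), ignore_attr = TRUE)
})

test_that("ridge + smoothness penalty evaluates correctly", {
  net2 <- gene_network(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(netcox_penalty(c(0, 0), net2, 1, 0.5), 0)
  b <- c(0.3, -0.8)
  expect_equal(netcox_penalty(b, net2, 2, 1), 2 * sum(b^2))
  # explicit 2x2 algebra: quad part of (1, -1) is 4
  expect_equal(netcox_penalty(c(1, -1), net2, 1, 0.5),
               0.5 * 2 + 0.5 * 4)
  expect_error(netcox_penalty(b, net2, -1, 0.5), "lambda")
})

test_that("L1 + signed-Laplacian penalty evaluates correctly", {
  net2 <- gene_network(matrix(c(0, 1, 1, 0), 2, 2))
  Lt <- adalnet_laplacian(net2, c(1, 1))
  expect_equal(adalnet_penalty(c(0, 0), Lt, 3, 0.5), 0)
  b <- c(1, -2)
  expect_equal(adalnet_penalty(b, Lt, 2, 1), 2 * sum(abs(b)))
})

test_that("quadratic Laplacian terms equal their edge-sum form", {
  # independent edge-sum implementation, unordered edges
  edge_sum <- function(beta, W, signs) {
    d <- unname(rowSums(W))
    z <- ifelse(d > 0, signs * beta / sqrt(d), 0)
    s <- 0
    p <- nrow(W)
    for (i in seq_len(p - 1)) for (j in (i + 1):p)
      if (W[i, j] > 0) s <- s + W[i, j] * (z[i] - z[j])^2
    as.numeric(s)
  }
  set.seed(9)
  for (s in 1:6) {
    p <- sample(3:8, 1)
    net <- toy_network(p, density = 0.5, seed = 90 + s)
    W <- as.matrix(net$W)
    beta <- rnorm(p)
    signs <- sample(c(-1, 1), p, replace = TRUE)
    # Net-Cox quadratic part (all signs +1): isolate it from the ridge term
    quad_net <- (netcox_penalty(beta, net, 1, 0.5) - 0.5 * sum(beta^2)) / 0.5
    expect_equal(quad_net, edge_sum(beta, W, rep(1, p)), tolerance = 1e-10)
    # signed-Laplacian quadratic part
    Lt <- adalnet_laplacian(net, signs)
    quad_ada <- (adalnet_penalty(beta, Lt, 1, 0.5) -
                   0.5 * sum(abs(beta))) / 0.5
    expect_equal(quad_ada, edge_sum(beta, W, signs), tolerance = 1e-10)
    # and the package's own edge-sum diagnostic agrees
    expect_equal(laplacian_edge_sum(beta, net, signs),
                 edge_sum(beta, W, signs), tolerance = 1e-10)
  }
})

test_that("weighted elastic-net penalty evaluates correctly", {
  expect_equal(elasticnet_penalty(c(0, 0), c(1, 1), 1, 0.5), 0)
  # zero feature weights with alpha = 1: no shrinkage at all
  expect_equal(elasticnet_penalty(c(3, -7), c(0, 0), 5, 1), 0)
  expect_equal(elasticnet_penalty(c(1, -2), c(1, 1), 2, 0.5),
               2 * (0.5 * 3 + 0.25 * 5))
  expect_error(elasticnet_penalty(c(1, 1), c(-1, 1), 1, 0.5), "non-negative")
})

test_that("penalties are non-negative, vanish at zero and scale with lambda", {
  set.seed(15)
  net <- toy_network(5, density = 0.5, seed = 15)
  Lt <- adalnet_laplacian(net, rep(1, 5))
  for (s in 1:5) {
    b <- rnorm(5)
    for (a in c(0.3, 1)) {
      p1 <- netcox_penalty(b, net, 1, a)
      p2 <- adalnet_penalty(b, Lt, 1, a)
      p3 <- elasticnet_penalty(b, rep(1, 5), 1, a)
      expect_true(all(c(p1, p2, p3) >= 0))
      expect_equal(netcox_penalty(b, net, 2.5, a), 2.5 * p1)
      expect_equal(adalnet_penalty(b, Lt, 2.5, a), 2.5 * p2)
      expect_equal(elasticnet_penalty(b, rep(1, 5), 2.5, a), 2.5 * p3)
    }
  }
})

test_that("weight thresholding binarizes strictly above tau", {
  W <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(sum(threshold_weights(gene_network(W), 0.5)$W), 0)
  W2 <- matrix(0, 3, 3)
  W2[1, 2] <- W2[2, 1] <- 0.2
  W2[1, 3] <- W2[3, 1] <- 0.7
  tw <- as.matrix(threshold_weights(gene_network(W2), 0.5)$W)
  expect_equal(tw[1, 2], 0)
  expect_equal(tw[1, 3], 1)
  # ties at exactly tau drop the edge
  W3 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(sum(threshold_weights(gene_network(W3), 0.5)$W), 0)
  # tau = 0 keeps every positive edge
  expect_equal(as.matrix(threshold_weights(gene_network(W2), 0)$W) > 0,
               W2 > 0, ignore_attr = TRUE)
})

test_that("network files round-trip and duplicates are rejected", {
  net <- toy_network(6, density = 0.5, seed = 77)
  f <- tempfile(fileext = ".tsv")
  write_network(net, f)
  net2 <- read_network(f, gene_ids = net$gene_ids)
  expect_equal(as.matrix(net2$W), as.matrix(net$W), tolerance = 1e-12)
  # duplicate edge (either orientation) rejected
  writeLines(c("gene_i\tgene_j\tweight", "a\tb\t0.5", "b\ta\t0.4"), f)
  expect_error(read_network(f), "duplicate")
  # square-matrix form with header and id column
  writeLines(c("id\tga\tgb\tgc\tgd",
               "ga\t0\t0.5\t0\t0", "gb\t0.5\t0\t0\t0.25",
               "gc\t0\t0\t0\t0", "gd\t0\t0.25\t0\t0"), f)
  nm <- read_network(f, format = "matrix")
  expect_equal(nm$gene_ids, c("ga", "gb", "gc", "gd"))
  expect_equal(as.numeric(nm$W["gb", "gd"]), 0.25)
})
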