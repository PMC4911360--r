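#' Configuration for the regulatory-network survival simulator
#'
#' Describes the study conditions of the two simulation scenarios: a
#' collection of TF-centred regulatory networks (one transcription factor
#' regulating `genes_per_network - 1` genes each), survival times from a
#' Cox model with a Weibull baseline hazard, and uniform independent
#' censoring. Scenario `"not_overlapped"` keeps all networks disjoint with
#' TF-gene correlation `+/- correlation`; scenario `"overlapped"` connects
#' the middle four of the eight relevant networks to the outer four and
#' draws expression from a multivariate normal with AR(1) covariance
#' `ar_decay^|i-j|` over the gene index.
#'
#' @param scenario `"not_overlapped"` (1) or `"overlapped"` (2); integers 1
#'   and 2 are accepted.
#' @param n_networks number of regulatory networks (default 100).
#' @param genes_per_network genes per network incl. the TF (default 11).
#' @param n_samples subjects per dataset (default 200).
#' @param n_relevant_networks networks carrying non-zero coefficients
#'   (default 8; scenario 2 requires exactly 8).
#' @param censor_low,censor_high censoring-time uniform range (default 2, 15).
#' @param weibull_shape,weibull_scale baseline-hazard Weibull parameters
#'   (default 5, 2).
#' @param correlation TF-regulated gene correlation magnitude, in (-1, 1)
#'   (default 0.7; scenario 1 only).
#' @param ar_decay AR(1) decay of the scenario-2 covariance, in (0, 1)
#'   (default 0.5).
#' @param ar_scope `"all"` applies the AR(1) covariance across the full
#'   gene vector ordered by network (TF first); `"relevant_only"` applies
#'   it to the genes of the eight relevant networks and generates the
#'   remaining networks as in scenario 1.
#' @param seed integer seed; every draw in the simulator derives from it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(scenario = c("not_overlapped", "overlapped"),
                       n_networks = 100, genes_per_network = 11,
                       n_samples = 200, n_relevant_networks = 8,
                       censor_low = 2, censor_high = 15,
                       weibull_shape = 5, weibull_scale = 2,
                       correlation = 0.7, ar_decay = 0.5,
                       ar_scope = c("all", "relevant_only"),
                       seed = 1L) {
  if (is.numeric(scenario))
    scenario <- c("not_overlapped", "overlapped")[scenario]
  scenario <- match.arg(scenario)
  ar_scope <- match.arg(ar_scope)
  stopifnot(n_networks >= 1, genes_per_network >= 2, n_samples >= 1,
            n_relevant_networks >= 1)
  if (n_relevant_networks > n_networks)
    stop("n_relevant_networks cannot exceed n_networks")
  if (scenario == "overlapped" && n_relevant_networks != 8)
    stop("the overlapped scenario is defined only for 8 relevant networks")
  if (!(censor_low < censor_high)) stop("censor_low must be < censor_high")
  stopifnot(weibull_shape > 0, weibull_scale > 0)
  if (abs(correlation) >= 1) stop("correlation must lie in (-1, 1)")
  if (ar_decay <= 0 || ar_decay >= 1) stop("ar_decay must lie in (0, 1)")
  structure(list(
    scenario = scenario, n_networks = as.integer(n_networks),
    genes_per_network = as.integer(genes_per_network),
    n_samples = as.integer(n_samples),
    n_relevant_networks = as.integer(n_relevant_networks),
    censor_low = censor_low, censor_high = censor_high,
    weibull_shape = weibull_shape, weibull_scale = weibull_scale,
    correlation = correlation, ar_decay = ar_decay, ar_scope = ar_scope,
    seed = as.integer(seed)), class = "sim_config")
}

#' Build the simulation ground truth
#'
#' Draws the network adjacency, the true coefficient vector and the
#' relevant-gene set for a [sim_config()]. Genes are ordered by network,
#' TF first. In scenario 1 the 100 networks are disjoint (each TF has
#' degree `genes_per_network - 1`, each regulated gene degree 1); the first
#' half of the relevant networks carries coefficients drawn from U(0.1, 1)
#' and the second half from U(-1.5, -0.1). In scenario 2 the genes of
#' networks P3-P6 are additionally connected to every gene of P1, P2, P7,
#' P8 (complete bipartite, weight 1) and the coefficient blocks are
#' U(0.1, 0.5) for P1-P2, U(-0.1, 0.1) for the 44 shared genes of P3-P6,
#' and U(-1, -0.5) for P7-P8.
#'
#' @param config a [sim_config()].
#' @return a `sim_truth` list: `adjacency` (sparse 0/1, symmetric, zero
#'   diagonal), `beta_true`, `relevant_set` (gene indices),
#'   `network_assignment`, `tf_flags`, `baseline` (shape, scale),
#'   `gene_ids`.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$genes_per_network
  G <- config$n_networks
  p <- m * G
  network_assignment <- rep(seq_len(G), each = m)
  tf_flags <- rep(c(TRUE, rep(FALSE, m - 1)), G)
  gene_ids <- paste0("n", network_assignment, "_",
                     ifelse(tf_flags, "tf", paste0("g", rep(seq_len(m) - 1, G))))
  # within-network star edges: TF (first gene) to each regulated gene
  tf_idx <- (seq_len(G) - 1) * m + 1
  ei <- rep(tf_idx, each = m - 1)
  ej <- ei + rep(seq_len(m - 1), times = G)
  if (config$scenario == "overlapped") {
    inner <- which(network_assignment %in% 3:6)   # P3-P6
    outer <- which(network_assignment %in% c(1, 2, 7, 8))
    ei <- c(ei, rep(inner, each = length(outer)))
    ej <- c(ej, rep(outer, times = length(inner)))
  }
  adjacency <- Matrix::sparseMatrix(i = c(ei, ej), j = c(ej, ei),
                                    x = 1, dims = c(p, p), use.last.ij = TRUE)
  s_nets <- config$n_relevant_networks
  relevant_set <- which(network_assignment <= s_nets)
  s <- length(relevant_set)
  beta_true <- numeric(p)
  if (config$scenario == "not_overlapped") {
    n_pos <- ceiling(s_nets / 2) * m
    beta_true[relevant_set] <- c(stats::runif(n_pos, 0.1, 1),
                                 stats::runif(s - n_pos, -1.5, -0.1))
  } else {
    beta_true[relevant_set] <- c(stats::runif(2 * m, 0.1, 0.5),
                                 stats::runif(4 * m, -0.1, 0.1),
                                 stats::runif(2 * m, -1, -0.5))
  }
  structure(list(
    adjacency = adjacency, beta_true = beta_true,
    relevant_set = relevant_set, network_assignment = network_assignment,
    tf_flags = tf_flags,
    baseline = c(shape = config$weibull_shape, scale = config$weibull_scale),
    gene_ids = gene_ids), class = "sim_truth")
}

#' Sample expression data for a simulated truth
#'
#' Scenario 1: each TF column is i.i.d. standard normal and each regulated
#' gene is conditionally normal given its TF with mean `rho * TF` and
#' variance `1 - rho^2` (so every column is marginally standard normal);
#' within each network the first half of the regulated genes is activated
#' (`+rho`) and the second half repressed (`-rho`). Scenario 2: the gene
#' vector carries AR(1) covariance `ar_decay^|i-j|` in gene order (see
#' `ar_scope` in [sim_config()]).
#'
#' @param truth a `sim_truth` from [build_truth()].
#' @param config the matching [sim_config()].
#' @return numeric matrix, `n_samples` x p, columns named by gene id.
#' @export
sample_expression <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_samples
  m <- config$genes_per_network
  G <- config$n_networks
  p <- m * G
  X <- matrix(0, n, p)
  scen1_block <- function(net_index) {
    tf <- stats::rnorm(n)
    nreg <- m - 1
    n_act <- ceiling(nreg / 2)
    rho <- config$correlation *
      c(rep(1, n_act), rep(-1, nreg - n_act))
    reg <- vapply(rho, function(r)
      r * tf + sqrt(1 - r^2) * stats::rnorm(n), numeric(n))
    cbind(tf, reg, deparse.level = 0)
  }
  ar1_block <- function(ncols) {
    a <- config$ar_decay
    Z <- matrix(stats::rnorm(n * ncols), n, ncols)
    for (j in seq_len(ncols)[-1])
      Z[, j] <- a * Z[, j - 1] + sqrt(1 - a^2) * Z[, j]
    Z
  }
  if (config$scenario == "not_overlapped") {
    for (g in seq_len(G))
      X[, ((g - 1) * m + 1):(g * m)] <- scen1_block(g)
  } else if (config$ar_scope == "all") {
    X <- ar1_block(p)
  } else {
    nrel <- config$n_relevant_networks * m
    X[, seq_len(nrel)] <- ar1_block(nrel)
    if (G > config$n_relevant_networks)
      for (g in seq(config$n_relevant_networks + 1, G))
        X[, ((g - 1) * m + 1):(g * m)] <- scen1_block(g)
  }
  colnames(X) <- truth$gene_ids
  rownames(X) <- paste0("s", seq_len(n))
  X
}

#' Sample survival outcomes from the Cox model
#'
#' Latent failure times come from inverting the Weibull cumulative baseline
#' hazard \eqn{H_0(t) = (t/b)^a}: with \eqn{\eta_i = X_i'\beta} and
#' \eqn{U_i \sim U(0,1)},
#' \eqn{T_i = b\,(-\log U_i \cdot e^{-\eta_i})^{1/a}}. Censoring times are
#' uniform on (`censor_low`, `censor_high`), independent of expression. The
#' observed data are \eqn{t_i = \min(T_i, C_i)} and
#' \eqn{\delta_i = 1\{T_i \le C_i\}}.
#'
#' @param X expression matrix with p columns.
#' @param truth a `sim_truth`.
#' @param config the matching [sim_config()].
#' @return list with `time`, `event`, and the latent `failure_time` and
#'   `censor_time` (kept for diagnostics).
#' @export
sample_survival <- function(X, truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  if (ncol(X) != length(truth$beta_true))
    stop("X has the wrong number of genes")
  set.seed(config$seed + 2L)
  n <- nrow(X)
  eta <- drop(X %*% truth$beta_true)
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor; check input scaling")
  a <- config$weibull_shape
  b <- config$weibull_scale
  U <- stats::runif(n)
  failure <- b * (-log(U) * exp(-eta))^(1 / a)
  censor <- stats::runif(n, config$censor_low, config$censor_high)
  list(time = pmin(failure, censor),
       event = as.numeric(failure <= censor),
       failure_time = failure, censor_time = censor)
}

#' Per-network noise summary
#'
#' For each regulatory network, the mean of (i) the sample variance of the
#' TF column and (ii) the average sample variance of its regulated columns.
#' Both scenarios construct unit-variance margins, so values near 1 are
#' expected at large n.
#'
#' @param X expression matrix.
#' @param truth a `sim_truth`.
#' @return numeric vector, one value per network.
#' @export
quantify_noise <- function(X, truth) {
  vapply(sort(unique(truth$network_assignment)), function(g) {
    cols <- which(truth$network_assignment == g)
    tf <- cols[truth$tf_flags[cols]]
    reg <- setdiff(cols, tf)
    v <- apply(X[, cols, drop = FALSE], 2, stats::var)
    mean(c(v[match(tf, cols)], mean(v[match(reg, cols)])))
  }, numeric(1))
}

#' Generate one complete simulated dataset
#'
#' Convenience wrapper running [build_truth()], [sample_expression()] and
#' [sample_survival()] for a configuration, returning everything the other
#' modules need. Identical seeds give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `data` (a [survival_dataset()]), `net`
#'   (a [gene_network()] over the true adjacency), `truth`, and `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- build_truth(config)
  X <- sample_expression(truth, config)
  surv <- sample_survival(X, truth, config)
  data <- survival_dataset(X, surv$time, surv$event,
                           gene_ids = truth$gene_ids)
  net <- gene_network(truth$adjacency, gene_ids = truth$gene_ids)
  list(data = data, net = net, truth = truth, config = config)
}
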