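# Independent oracles used across the suite. These deliberately avoid the
# package's internal computation paths: the partial likelihood is a direct
# double loop over subjects, the log-rank statistic is assembled from the
# event-time 2x2 tables, and small optimizations go through stats::optim.

# Direct evaluation of the Breslow log-partial likelihood.
brute_logpl <- function(beta, X, time, event) {
  eta <- as.numeric(X %*% beta)
  total <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      total <- total + eta[i] - log(sum(exp(eta[risk])))
    }
  }
  total
}

# Two-sample log-rank chi-square from observed-minus-expected event counts
# summed over distinct event times (hypergeometric variance).
brute_logrank_chi2 <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ets <- sort(unique(time[event == 1]))
  O_minus_E <- 0
  V <- 0
  for (t0 in ets) {
    at_risk <- time >= t0
    n_all <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d_all <- sum(event == 1 & time == t0)
    d1 <- sum(event == 1 & time == t0 & g == 1)
    e1 <- d_all * n1 / n_all
    O_minus_E <- O_minus_E + d1 - e1
    if (n_all > 1)
      V <- V + d_all * (n1 / n_all) * (1 - n1 / n_all) *
        (n_all - d_all) / (n_all - 1)
  }
  (O_minus_E)^2 / V
}

# Hand product-limit estimator on distinct event times.
brute_km <- function(time, event) {
  ets <- sort(unique(time[event == 1]))
  surv <- numeric(length(ets))
  s <- 1
  for (k in seq_along(ets)) {
    n_risk <- sum(time >= ets[k])
    d <- sum(event == 1 & time == ets[k])
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  list(event_times = ets, survival = surv)
}

# Generic numerical maximizer of a penalized Cox objective (small p only).
oracle_maximize <- function(objective, p, starts = 3, seed = 42) {
  set.seed(seed)
  best <- NULL
  for (s in seq_len(starts)) {
    b0 <- if (s == 1) rep(0, p) else stats::rnorm(p, sd = 0.3)
    opt <- stats::optim(b0, function(b) -objective(b), method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  list(beta = best$par, value = -best$value)
}

# Small dataset generator with a controllable signal, used when the full
# simulator would be overkill.
toy_surv_data <- function(n, p, seed, beta = NULL, censor = 0.3) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  if (is.null(beta)) beta <- rep(0, p)
  eta <- as.numeric(X %*% beta)
  Tlat <- stats::rexp(n, rate = exp(eta))
  C <- stats::quantile(Tlat, 1 - censor) * stats::runif(n, 0.5, 1.5)
  survival_dataset(X, pmin(Tlat, C) + 1e-9, as.numeric(Tlat <= C))
}

toy_network <- function(p, density = 0.3, seed = 1) {
  set.seed(seed)
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (stats::runif(1) < density) {
      w <- stats::runif(1)
      W[i, j] <- W[j, i] <- w
    }
  }
  gene_network(W)
}
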