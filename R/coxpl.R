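#' Cox log-partial likelihood
#'
#' Evaluates Cox's log-partial likelihood
#' \deqn{pl(\beta) = \sum_i \delta_i \{ X_i'\beta -
#'   \log \sum_{j \in R(t_i)} \exp(X_j'\beta) \},}
#' with risk set \eqn{R(t_i) = \{j : t_j \ge t_i\}} (subjects still at risk
#' just before \eqn{t_i}) and the Breslow convention for tied event times.
#' The inner sum is stabilized by max-subtraction before exponentiation.
#'
#' @param beta coefficient vector, length `ncol(data$X)`.
#' @param data a [survival_dataset()].
#' @return the (unscaled) log-partial likelihood, a scalar.
#' @export
log_partial_likelihood <- function(beta, data) {
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$X))
    stop("length(beta) must equal the number of genes")
  eta <- drop(data$X %*% beta)
  cox_eta_stats(data$time, data$event, eta, need = "pl")$pl
}

#' Gradient and Hessian of the Cox log-partial likelihood
#'
#' Exact analytic first and second derivatives of
#' [log_partial_likelihood()] with respect to `beta`. The Hessian is
#' negative semidefinite (the log-partial likelihood is concave). Intended
#' for moderate p; the fitters use specialised low-rank representations
#' internally instead of forming the dense p x p Hessian.
#'
#' @inheritParams log_partial_likelihood
#' @return list with elements `gradient` (length p) and `hessian` (p x p).
#' @export
pl_gradient_hessian <- function(beta, data) {
  beta <- as.numeric(beta)
  if (length(beta) != ncol(data$X))
    stop("length(beta) must equal the number of genes")
  eta <- drop(data$X %*% beta)
  st <- cox_eta_stats(data$time, data$event, eta, need = "hess")
  grad <- drop(crossprod(data$X, st$g))
  A <- cox_A_matrix(st)
  hess <- -crossprod(data$X, A %*% data$X)
  list(gradient = grad, hessian = (hess + t(hess)) / 2)
}

#' Prognostic index
#'
#' The linear predictor \eqn{PI_i = x_i'\hat\beta} for each subject; higher
#' values mean higher predicted hazard.
#'
#' @param X expression matrix (subjects x genes).
#' @param beta fitted coefficient vector.
#' @return numeric vector of length `nrow(X)`.
#' @export
prognostic_index <- function(X, beta) {
  X <- as.matrix(X)
  beta <- as.numeric(beta)
  if (ncol(X) != length(beta)) stop("ncol(X) must equal length(beta)")
  drop(X %*% beta)
}

# One-time event-time bookkeeping for a (time, event) pair: distinct event
# times, tie multiplicities, the descending-time order used for risk-set
# cumulative sums, and per-subject indices. Every eta evaluation reuses it.
cox_risk_setup <- function(time, event) {
  n <- length(time)
  et <- sort(unique(time[event == 1]))
  K <- length(et)
  if (K == 0)
    return(list(n = n, K = 0, event = event))
  d <- as.numeric(table(factor(time[event == 1], levels = et)))
  list(n = n, K = K, event = event, time = time, et = et, d = d,
       ord = order(time, decreasing = TRUE),
       nk = n - findInterval(et, sort(time), left.open = TRUE),
       idx = findInterval(time, et),   # number of event times <= t_j
       is_event = event == 1)
}

# Internal workhorse: given the risk structure and eta return the Breslow
# partial-likelihood value plus the pieces needed for derivatives:
#   g  : per-subject score, grad pl = X'g
#   mu : per-subject expected event count
#   adiag and the low-rank correction so that -hess pl = X' A X with
#   A = diag(mu) - Pi diag(d) Pi',  Pi[,k] = r * 1{t >= t_k} / S_k.
# Everything is computed on the exp(eta - max(eta)) scale; ratios d/S are
# shift-invariant so only the pl value needs the shift added back.
cox_rs_stats <- function(rs, eta, need = c("pl", "grad", "hess")) {
  need <- match.arg(need)
  n <- rs$n
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor (eta); check input scaling")
  if (rs$K == 0) {
    return(list(pl = 0, g = numeric(n), mu = numeric(n),
                adiag = numeric(n), Pi = matrix(0, n, 0), d = numeric(0)))
  }
  m <- max(eta)
  r <- exp(eta - m)
  cr <- cumsum(r[rs$ord])
  S <- cr[rs$nk]
  pl <- sum(eta[rs$is_event]) - sum(rs$d * (log(S) + m))
  if (need == "pl") return(list(pl = pl))
  # h_j = sum_{k: et_k <= t_j} d_k / S_k ; h2_j same with S_k^2
  cds  <- cumsum(rs$d / S)
  cds2 <- cumsum(rs$d / S^2)
  h  <- c(0, cds)[rs$idx + 1]
  h2 <- c(0, cds2)[rs$idx + 1]
  g  <- rs$event - r * h
  mu <- r * h
  adiag <- pmax(mu - r^2 * h2, 0)        # diagonal of the curvature matrix A
  if (need == "grad") return(list(pl = pl, g = g, mu = mu, adiag = adiag))
  Pi <- matrix(0, n, rs$K)
  for (k in seq_len(rs$K)) {
    at_risk <- rs$time >= rs$et[k]
    Pi[at_risk, k] <- r[at_risk] / S[k]
  }
  list(pl = pl, g = g, mu = mu, adiag = adiag, Pi = Pi, d = rs$d)
}

cox_eta_stats <- function(time, event, eta, need = c("pl", "grad", "hess")) {
  cox_rs_stats(cox_risk_setup(time, event), eta, need)
}

# Dense n x n curvature matrix A with -hess pl = X' A X.
cox_A_matrix <- function(st) {
  n <- length(st$mu)
  A <- -st$Pi %*% (st$d * t(st$Pi))
  diag(A) <- diag(A) + st$mu
  A
}
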