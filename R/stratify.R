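#' Adaptive prognostic-index cutoff
#'
#' Scans a grid of quantiles of the training prognostic indices (default
#' 30\% to 70\% in steps of 5\%), splits the training patients at each
#' quantile (strictly above = high risk), and returns the quantile whose
#' two-group log-rank test attains the smallest p-value (ties broken
#' toward the smallest quantile). Quantiles producing an empty group are
#' skipped; if every quantile is degenerate an error is raised.
#'
#' @param pi_train training prognostic indices.
#' @param time_train,event_train training survival outcomes.
#' @param q_grid quantile grid inside (0, 1).
#' @return list with `threshold` (PI scale), `q_star`, and `p_star`.
#' @export
adaptive_cutoff <- function(pi_train, time_train, event_train,
                            q_grid = seq(0.30, 0.70, by = 0.05)) {
  if (any(q_grid <= 0 | q_grid >= 1)) stop("q_grid must lie inside (0, 1)")
  q_grid <- sort(q_grid)
  best <- NULL
  for (q in q_grid) {
    thr <- stats::quantile(pi_train, q, names = FALSE)
    high <- pi_train > thr
    if (!any(high) || all(high)) next
    lr <- logrank_test(time_train, event_train,
                       ifelse(high, "high", "low"))
    if (is.null(best) || lr$p < best$p_star - 1e-15)
      best <- list(threshold = thr, q_star = q, p_star = lr$p)
  }
  if (is.null(best))
    stop("all candidate cutoffs give a degenerate split")
  best
}

#' Cross-validated Kaplan-Meier risk stratification
#'
#' The k-fold re-sampling procedure for survival prediction: the data are
#' partitioned into K folds; for each fold the model is tuned by inner
#' K-fold CVPL and fitted on the training part, a gene set \eqn{G_k} is
#' selected, each held-out patient receives a prognostic index
#' \eqn{PI = x'\hat\beta^{T_k}}, and is labelled high or low risk relative
#' to an adaptive cutoff chosen on the training part
#' ([adaptive_cutoff()]; patients exactly at the threshold go to the
#' low-risk group). All patients, each labelled exactly once, are pooled
#' and the pooled two-group log-rank statistic \eqn{\chi^2_0} is computed
#' along with the pooled Kaplan-Meier curves.
#'
#' @param data a [survival_dataset()].
#' @param method `"netcox"`, `"adalnet"` or `"elasticnet"`.
#' @param K outer folds (default 5).
#' @param inner_K folds for the inner CVPL tuning (default 5).
#' @param seed seed controlling the outer partition and inner tuning.
#' @param selection_rule how \eqn{G_k} is chosen: `"nonzero"` (default for
#'   the sparse fitters) or `"top"` (top `top_k` genes by absolute
#'   coefficient, default for the ridge-type fitter).
#' @param top_k number of genes per fold under the `"top"` rule
#'   (default 50).
#' @param alpha_grid,lambda_grid tuning grids, as in [select_tuning()].
#' @param net a [gene_network()] (network methods).
#' @param feature_weights elastic-net L1 weights.
#' @param settings a [solver_settings()].
#' @param standardize centre/scale within each training fold.
#' @param q_grid cutoff quantile grid, see [adaptive_cutoff()].
#' @param n_lambda,min_ratio path controls for the L1 methods.
#' @param frozen_tuning optional list of K `(lambda, alpha)` pairs; when
#'   given, the inner CVPL tuning is skipped and fold k is fitted at the
#'   k-th pair (used by the fast permutation mode).
#' @return a `stratification_result`: `pi`, `group` (high/low), `cutoffs`,
#'   `per_fold_genes`, `union_genes`, `chi2_observed`, `p_asymptotic`,
#'   `perm_pvalue` (NA until [permutation_pvalue()]), `km_high`, `km_low`,
#'   `fold_assignment`, `per_fold` (tuning echo and convergence flags).
#' @export
cross_validated_km <- function(data, method, K = 5, inner_K = 5, seed = 1L,
                               selection_rule = NULL, top_k = 50,
                               alpha_grid = c(0.1, 0.5, 1),
                               lambda_grid = NULL, net = NULL,
                               feature_weights = NULL,
                               settings = solver_settings(),
                               standardize = TRUE,
                               q_grid = seq(0.30, 0.70, by = 0.05),
                               n_lambda = 30, min_ratio = 1e-2,
                               frozen_tuning = NULL) {
  n <- nrow(data$X)
  if (n < 2 * K) stop("need at least 2K subjects")
  if (is.null(selection_rule))
    selection_rule <- if (method == "netcox") "top" else "nonzero"
  folds <- assign_folds(n, K, seed)
  pi_all <- numeric(n)
  group <- character(n)
  cutoffs <- numeric(K)
  per_fold_genes <- vector("list", K)
  per_fold <- vector("list", K)
  for (k in seq_len(K)) {
    test_idx <- which(folds == k)
    train <- subset_subjects(data, folds != k)
    if (sum(train$event) < 2) stop("fold ", k, ": fewer than 2 events")
    fit <- if (is.null(frozen_tuning)) {
      cv <- select_tuning(train, method, alpha_grid = alpha_grid,
                          lambda_grid = lambda_grid, K = inner_K,
                          seed = seed + k, net = net,
                          feature_weights = feature_weights,
                          settings = settings, standardize = standardize,
                          n_lambda = n_lambda, min_ratio = min_ratio)
      cv$fit
    } else {
      fit_cox_penalized(train, method, frozen_tuning[[k]]$lambda,
                        frozen_tuning[[k]]$alpha, net = net,
                        feature_weights = feature_weights,
                        settings = settings, standardize = standardize)
    }
    per_fold_genes[[k]] <- if (selection_rule == "top")
      consensus_rank(fit, top_k) else names(fit$beta)[fit$beta != 0]
    pi_train <- predict_pi(fit, train$X)
    # an uninformative fold model (constant training PI, e.g. beta = 0 in
    # a sparse fit) admits no cutoff: its whole test fold goes to low risk
    cut <- tryCatch(
      adaptive_cutoff(pi_train, train$time, train$event, q_grid),
      error = function(e) list(threshold = Inf, q_star = NA_real_,
                               p_star = NA_real_))
    cutoffs[k] <- cut$threshold
    pi_test <- predict_pi(fit, data$X[test_idx, , drop = FALSE])
    pi_all[test_idx] <- pi_test
    group[test_idx] <- ifelse(pi_test > cut$threshold, "high", "low")
    per_fold[[k]] <- list(lambda = fit$lambda, alpha = fit$alpha,
                          converged = fit$converged, q_star = cut$q_star)
  }
  # with every fold uninformative all patients may share one label; the
  # stratification then carries no evidence and the statistic is 0
  lr <- if (length(unique(group)) == 2) {
    logrank_test(data$time, data$event, group)
  } else {
    list(chi2 = 0, p = 1)
  }
  structure(list(
    pi = pi_all, group = group, cutoffs = cutoffs,
    per_fold_genes = per_fold_genes,
    union_genes = sort(unique(unlist(per_fold_genes))),
    chi2_observed = lr$chi2, p_asymptotic = lr$p, perm_pvalue = NA_real_,
    km_high = if (any(group == "high"))
      kaplan_meier(data$time[group == "high"],
                   data$event[group == "high"]) else NULL,
    km_low = if (any(group == "low"))
      kaplan_meier(data$time[group == "low"],
                   data$event[group == "low"]) else NULL,
    fold_assignment = folds, per_fold = per_fold),
    class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("stratification_result: %d high / %d low, chi2=%.3f%s\n",
              sum(x$group == "high"), sum(x$group == "low"),
              x$chi2_observed,
              if (!is.na(x$perm_pvalue))
                sprintf(", permutation p=%.4g", x$perm_pvalue) else ""))
  invisible(x)
}

#' Permutation p-value for the cross-validated log-rank statistic
#'
#' For each of M permutations the (time, event) pairs are jointly permuted
#' against the expression rows — the null of no expression-survival
#' association, preserving the marginal survival distribution — and the
#' full cross-validation procedure (same fold partition, same inner
#' tuning) is re-run to obtain a permuted statistic \eqn{\chi^2_m}. The
#' p-value is \eqn{\hat p = M^{-1} \#\{m : \chi^2_m \ge \chi^2_0\}}.
#' Permutation runs that fail are excluded with a warning; more than 10\%
#' failures aborts.
#'
#' @inheritParams cross_validated_km
#' @param M number of permutations (default 500).
#' @param observed optionally, the `stratification_result` for the
#'   unpermuted data (recomputed if omitted).
#' @param fast freeze the observed run's per-fold `(lambda, alpha)`
#'   instead of re-tuning inside every permutation (default FALSE: the
#'   full procedure, inner tuning included, is re-run).
#' @param refold draw a fresh fold partition per permutation (default
#'   FALSE: the observed partition is reused so only the permutation
#'   effect varies).
#' @param ... further arguments passed to [cross_validated_km()].
#' @return the `stratification_result` for the observed data with
#'   `perm_pvalue` filled in and an extra element `chi2_perm`.
#' @export
permutation_pvalue <- function(data, method, K = 5, M = 500, seed = 1L,
                               observed = NULL, fast = FALSE,
                               refold = FALSE, ...) {
  if (M < 1) stop("M must be >= 1")
  if (is.null(observed))
    observed <- cross_validated_km(data, method, K = K, seed = seed, ...)
  frozen <- if (fast) {
    lapply(observed$per_fold, function(pf)
      list(lambda = pf$lambda, alpha = pf$alpha))
  } else NULL
  set.seed(seed + 10000L)
  perms <- replicate(M, sample(nrow(data$X)), simplify = FALSE)
  chi2_perm <- rep(NA_real_, M)
  for (m in seq_len(M)) {
    prm <- perms[[m]]
    dperm <- survival_dataset(data$X, data$time[prm], data$event[prm],
                              gene_ids = data$gene_ids,
                              sample_ids = data$sample_ids)
    res <- tryCatch(
      cross_validated_km(dperm, method, K = K,
                         seed = if (refold) seed + m else seed,
                         frozen_tuning = frozen, ...),
      error = function(e) NULL)
    if (!is.null(res)) chi2_perm[m] <- res$chi2_observed
  }
  failed <- sum(is.na(chi2_perm))
  if (failed > 0.1 * M)
    stop(failed, " of ", M, " permutation runs failed")
  if (failed > 0)
    warning(failed, " permutation runs failed and were excluded")
  ok <- chi2_perm[!is.na(chi2_perm)]
  observed$perm_pvalue <- mean(ok >= observed$chi2_observed)
  observed$chi2_perm <- chi2_perm
  observed
}
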