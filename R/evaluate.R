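#' Confusion counts and selection metrics against the simulation truth
#'
#' Compares a selected gene set with the relevant set of a `sim_truth` and
#' returns the confusion counts together with sensitivity (TPR),
#' specificity (TNR) and the Matthews correlation coefficient.
#'
#' @param selected character vector of selected gene ids (subset of the
#'   gene universe).
#' @param truth a `sim_truth` from [build_truth()].
#' @return a `selection_metrics` list: `tp`, `fp`, `tn`, `fn`, `tpr`,
#'   `tnr`, `mcc`, `n_selected`.
#' @export
confusion_counts <- function(selected, truth) {
  universe <- truth$gene_ids
  selected <- unique(as.character(selected))
  if (!all(selected %in% universe))
    stop("unknown gene id(s): ",
         paste(utils::head(setdiff(selected, universe), 3), collapse = ", "))
  relevant <- universe[truth$relevant_set]
  tp <- sum(selected %in% relevant)
  fp <- length(selected) - tp
  fn <- length(relevant) - tp
  tn <- length(universe) - tp - fp - fn
  m <- tpr_tnr_mcc(list(tp = tp, fp = fp, tn = tn, fn = fn))
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 tpr = m$tpr, tnr = m$tnr, mcc = m$mcc,
                 n_selected = tp + fp),
            class = "selection_metrics")
}

#' @export
print.selection_metrics <- function(x, ...) {
  cat(sprintf(
    "selection_metrics: %d selected | TP %d FP %d TN %d FN %d | sens %.3f spec %.3f MCC %.3f\n",
    x$n_selected, x$tp, x$fp, x$tn, x$fn, x$tpr, x$tnr, x$mcc))
  invisible(x)
}

#' Sensitivity, specificity and Matthews correlation from counts
#'
#' \deqn{TPR = TP/(TP+FN), \quad TNR = TN/(TN+FP),}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' Any zero factor in the MCC denominator yields MCC = 0 (the usual
#' convention, needed when a method selects nothing).
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn`.
#' @return list with `tpr`, `tnr`, `mcc`.
#' @export
tpr_tnr_mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  list(tpr = tpr, tnr = tnr, mcc = mcc)
}

#' Consensus gene ranking by absolute coefficient
#'
#' For a ridge-type fit, genes are ranked in descending order of the
#' absolute regression coefficient and the top k are selected (ties broken
#' by column order). Given several fits (e.g. one per fold), the union of
#' the per-fit top-k sets is returned.
#'
#' @param fit_or_fits a `cox_fit` or a list of them.
#' @param k number of genes per fit, `1 <= k <= p`.
#' @return character vector of selected gene ids.
#' @export
consensus_rank <- function(fit_or_fits, k) {
  if (k <= 0) stop("k must be positive")
  top_one <- function(fit) {
    if (k > length(fit$beta)) stop("k exceeds the number of genes")
    ord <- order(-abs(fit$beta), seq_along(fit$beta))
    names(fit$beta)[ord[seq_len(k)]]
  }
  if (inherits(fit_or_fits, "cox_fit")) return(top_one(fit_or_fits))
  sort(unique(unlist(lapply(fit_or_fits, top_one))))
}

#' Split replication results by model size
#'
#' Re-aggregates per-replication selection metrics into two subgroups
#' split at a method-specific model-size threshold: at most 100 selected
#' genes for the adaptive-Laplacian L1 model, at most 10 for the elastic
#' net. Methods without a defined threshold return the single general
#' group.
#'
#' @param rows data.frame of per-replication metrics with columns
#'   `sensitivity`, `specificity`, `n_selected`, `fp`, `mcc`.
#' @param method method name.
#' @return data.frame of aggregated subgroup rows (see
#'   [run_simulation_study()] for the column layout).
#' @export
group_replications <- function(rows, method) {
  thr <- switch(method, adalnet = 100, elasticnet = 10, NULL)
  agg <- function(sub, label) aggregate_metric_rows(sub, method, label)
  if (is.null(thr)) return(agg(rows, "general"))
  out <- agg(rows, "general")
  lo <- rows[rows$n_selected <= thr, , drop = FALSE]
  hi <- rows[rows$n_selected > thr, , drop = FALSE]
  if (nrow(lo) > 0) out <- rbind(out, agg(lo, sprintf("n_le_%d", thr)))
  if (nrow(hi) > 0) out <- rbind(out, agg(hi, sprintf("n_gt_%d", thr)))
  out
}

aggregate_metric_rows <- function(rows, method, label) {
  if (nrow(rows) == 0) return(NULL)
  cols <- c("sensitivity", "specificity", "n_selected", "fp", "mcc")
  means <- vapply(cols, function(cn) mean(rows[[cn]]), numeric(1))
  sds <- vapply(cols, function(cn) stats::sd(rows[[cn]]), numeric(1))
  sds[is.na(sds)] <- 0
  df <- data.frame(method = method, subgroup = label,
                   n_replications = nrow(rows))
  for (cn in cols) {
    df[[paste0(cn, "_mean")]] <- means[[cn]]
    df[[paste0(cn, "_sd")]] <- sds[[cn]]
  }
  df
}

#' Drop pathway-isolated genes
#'
#' Keeps a gene only if at least one other gene of the set shares a
#' pathway with it.
#'
#' @param genes character vector of gene ids.
#' @param pathways named list of character vectors (pathway -> members),
#'   e.g. from [read_pathways()].
#' @return the non-isolated subset of `genes`.
#' @export
not_isolated_filter <- function(genes, pathways) {
  genes <- unique(as.character(genes))
  keep <- vapply(genes, function(g) {
    in_pw <- vapply(pathways, function(pw) g %in% pw, logical(1))
    any(vapply(pathways[in_pw], function(pw)
      length(intersect(pw, setdiff(genes, g))) > 0, logical(1)))
  }, logical(1))
  genes[keep]
}

#' Run the simulation benchmarking study
#'
#' For each replication: generate a dataset from the configuration, tune
#' (lambda, alpha) by K-fold CVPL on the full dataset, fit, select genes
#' (the non-zero set for the sparse fitters; fixed-size consensus rankings
#' for the ridge-type fitter), and score the selection against the ground
#' truth. Aggregates means and standard deviations across replications,
#' including the model-size subgroup split of [group_replications()].
#'
#' @param config a [sim_config()]; its seed field is overridden per
#'   replication from `seed`.
#' @param methods subset of `c("netcox", "adalnet", "elasticnet")`.
#' @param n_replications number of replications (>= 2).
#' @param seed master seed; replication r uses `seed + 101 * (r - 1)`.
#' @param alpha_grid tuning grid for alpha.
#' @param consensus_k consensus ranking sizes for the ridge-type fitter
#'   (default 44, 88, 176).
#' @param K folds for the CVPL tuning (default 5).
#' @param n_lambda,min_ratio path controls for the L1 methods.
#' @param settings a [solver_settings()].
#' @return a `study_result`: `summary` (aggregated rows), `replications`
#'   (per-replication metrics), `failures` (count).
#' @export
run_simulation_study <- function(config, methods = c("netcox", "adalnet",
                                                     "elasticnet"),
                                 n_replications = 10, seed = 1L,
                                 alpha_grid = c(0.1, 0.5, 1),
                                 consensus_k = c(44, 88, 176), K = 5,
                                 n_lambda = 30, min_ratio = 1e-2,
                                 settings = solver_settings()) {
  if (n_replications < 2) stop("need at least 2 replications")
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- list()
  n_fail <- 0
  for (r in seq_len(n_replications)) {
    cfg <- config
    cfg$seed <- as.integer(seed + 101 * (r - 1))
    sim <- simulate_dataset(cfg)
    for (method in methods) {
      res <- tryCatch({
        cv <- select_tuning(sim$data, method, alpha_grid = alpha_grid,
                            K = K, seed = cfg$seed, net = sim$net,
                            settings = settings, n_lambda = n_lambda,
                            min_ratio = min_ratio)
        fit <- cv$fit
        if (method == "netcox") {
          do.call(rbind, lapply(consensus_k, function(k) {
            m <- confusion_counts(consensus_rank(fit, k), sim$truth)
            metric_row(method, sprintf("top_%d", k), r, cv, m)
          }))
        } else {
          sel <- names(fit$beta)[fit$beta != 0]
          m <- confusion_counts(sel, sim$truth)
          metric_row(method, "general", r, cv, m)
        }
      }, error = function(e) {
        message("replication ", r, " (", method, ") failed: ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) n_fail <- n_fail + 1 else reps[[length(reps) + 1]] <- res
    }
  }
  if (n_fail > 0.1 * n_replications * length(methods))
    stop("more than 10% of replication fits failed (", n_fail, ")")
  repdf <- do.call(rbind, reps)
  summaries <- list()
  for (method in methods) {
    sub <- repdf[repdf$method == method, , drop = FALSE]
    if (method == "netcox") {
      for (lab in unique(sub$selection)) {
        rows <- sub[sub$selection == lab, , drop = FALSE]
        summaries[[length(summaries) + 1]] <-
          aggregate_metric_rows(rows, method, lab)
      }
    } else {
      summaries[[length(summaries) + 1]] <- group_replications(sub, method)
    }
  }
  summary <- do.call(rbind, summaries)
  summary$scenario <- config$scenario
  structure(list(summary = summary, replications = repdf,
                 failures = n_fail, scenario = config$scenario),
            class = "study_result")
}

metric_row <- function(method, selection, r, cv, m) {
  data.frame(method = method, selection = selection, replication = r,
             lambda = cv$best$lambda, alpha = cv$best$alpha,
             sensitivity = m$tpr, specificity = m$tnr,
             n_selected = m$n_selected, fp = m$fp, mcc = m$mcc)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result (%s): %d replication rows, %d failures\n",
              x$scenario, nrow(x$replications), x$failures))
  print(x$summary, digits = 3)
  invisible(x)
}
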