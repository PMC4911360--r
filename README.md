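# netcoxkm

Network-regularized Cox regression for high-dimensional gene-expression
survival data, with cross-validated Kaplan–Meier risk stratification and
a regulatory-network simulation benchmark.

## Who this is for

Analysts relating gene-expression profiles to patient survival when the
number of genes far exceeds the number of patients and prior knowledge —
regulatory networks, pathway membership, functional-linkage weights — is
available as a gene–gene graph. Penalized Cox models that ignore that
graph select unstable, hard-to-interpret signatures; the models here
fold the graph into the penalty.

## The models

With observed data $(t_i, \delta_i, X_i)$ and risk set
$R(t) = \{j : t_j \ge t\}$, all three fitters maximize the penalized
log-partial likelihood

$$\frac{1}{n}\sum_i \delta_i \Big\{X_i'\beta -
\log\!\!\sum_{j\in R(t_i)}\!\! e^{X_j'\beta}\Big\} \;-\;
P_{\lambda,\alpha}(\beta)$$

with one of three penalties built on a weighted gene graph
$G = (V, E, W)$:

| fitter | penalty | selection |
|---|---|---|
| `fit_netcox` | $\lambda[\alpha\|\beta\|_2^2 + (1-\alpha)\beta'(I-W_n)\beta]$, $W_n = D^{-1/2}WD^{-1/2}$ | consensus ranking (top-k by abs. coefficient) |
| `fit_adalnet` | $\lambda[\alpha\|\beta\|_1 + (1-\alpha)\beta'\tilde L\beta]$, $\tilde L = S'LS$ signed normalized Laplacian | exact non-zeros |
| `fit_elasticnet_cox` | $\lambda[\alpha\sum_j w_j\|\beta_j\| + \tfrac12(1-\alpha)\|\beta\|_2^2]$ | exact non-zeros |

$(\lambda, \alpha)$ are tuned by 5-fold cross-validated partial
likelihood (CVPL, `select_tuning`). `cross_validated_km` implements
k-fold cross-validated Kaplan–Meier risk stratification: per fold the
model is tuned and fitted on the training part, held-out patients are
scored by their prognostic index $x'\hat\beta$ and split at an
adaptively chosen training quantile (30–70%), and the pooled two-group
log-rank statistic is referred to a permutation distribution
(`permutation_pvalue`) that re-runs the entire procedure on
survival-permuted data. `simulate_dataset` generates the two
TF-regulatory-network benchmark scenarios (disjoint and overlapped
networks, Weibull baseline hazard, uniform censoring) with full ground
truth, and `run_simulation_study` scores selection accuracy
(sensitivity, specificity, MCC) against it.

## Worked example

A reduced disjoint-network benchmark: 10 regulatory networks (110
genes), two of them (22 genes) carrying true effects, 120 patients.

```r
library(netcoxkm)

cfg <- sim_config("not_overlapped", n_networks = 10, n_samples = 120,
                  n_relevant_networks = 2, seed = 42)
sim <- simulate_dataset(cfg)
sim$data
#> survival_dataset: 120 subjects x 110 genes, 116 events (3.3% censored)

# tune the ridge + network-smoothness model by 5-fold CVPL
cv <- select_tuning(sim$data, "netcox", alpha_grid = c(0.1, 0.5, 1),
                    seed = 42, net = sim$net)
cv
#> cv_result: 18 grid points, best lambda=0.00833333 alpha=1 (CVPL=11.3283)

# consensus ranking: keep the 22 genes with the largest |coefficient|
confusion_counts(consensus_rank(cv$fit, 22), sim$truth)
#> selection_metrics: 22 selected | TP 12 FP 10 TN 78 FN 10 | sens 0.545 spec 0.886 MCC 0.432

# cross-validated Kaplan-Meier stratification with permutation p-value
res <- cross_validated_km(sim$data, "netcox", K = 5, seed = 42,
                          net = sim$net, alpha_grid = c(0.1, 0.5, 1),
                          top_k = 10)
perm <- permutation_pvalue(sim$data, "netcox", K = 5, M = 50, seed = 42,
                           observed = res, net = sim$net,
                           alpha_grid = c(0.1, 0.5, 1), top_k = 10)
perm
#> stratification_result: 82 high / 38 low, chi2=39.977, permutation p=0
```

Reading the output: CVPL picked the pure-ridge corner ($\alpha = 1$) for
this small instance; the 22-gene consensus ranking recovered 12 of the
22 truly relevant genes (MCC 0.43); and the cross-validated
stratification separates the pooled high- and low-risk groups with a
log-rank chi-square of 40.0, which none of 50 survival-permuted
re-runs of the full procedure matched (permutation p = 0, i.e.
p < 1/50).

A command-line surface wraps the same functions
(`inst/cli/netcoxkm simulate|fit|cv|stratify|evaluate|run-study`); see
`?cli_dispatch`.

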