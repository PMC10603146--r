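# survsel

Variable selection for right-censored survival data with many, highly
collinear covariates — the regime of biomarker discovery in clinical
trials, where a handful of weak protective effects hide inside blocks of
strongly correlated assay features and the ordinary Cox model is
unidentifiable.

The package implements, side by side and under a shared benchmarking
harness:

| Family | Methods | Selection rule |
|---|---|---|
| Penalized Cox | lasso, elastic net, ridge, adaptive lasso (10-fold CV grid search) | non-zero coefficients |
| Spike-and-slab Cox (EM posterior mode) | SSVS (Gaussian mixture), sslasso (double-exponential mixture), gsslasso (group-structured) | CI rule, BIC thresholding, greedy modified BIC |
| Random survival forest | log-rank splitting, bootstrap aggregation | minimal depth vs. closed-form null threshold, or top-k |

All methods share one core: the Breslow partial log-likelihood
`pl(β) = Σ_i δ_i [β'x_i − log Σ_{i'∈R(t_i)} exp(β'x_i')]`, its score and
observed information, computed in compiled code. Penalized fits minimise
`−pl(β) + λ Σ_j w_j |β_j|` (+ an L2 term for the elastic net); the
spike-and-slab models place two-component priors
`(1−γ_j)·spike + γ_j·slab` on each coefficient and are fitted by EM to
the posterior mode, with mode-curvature standard errors feeding the
CI selection rule. The BIC rules rank candidates by `|β̂|` and minimise
`BIC_j = −2(l(β̂_(1:j)) − l(0)) + j·log(n)` over refitted Cox models.

A simulation module generates the benchmark's data-generating world:
blocks of standard-normal covariates with within-block AR(1) correlation
`ρ^|i−j|` (ρ = 0.9, block size 50), q ∈ {5, 10} negative true
coefficients drawn from a LOW ([−0.4, −0.1]) or HIGH ([−1.0, −0.5])
range, exponential event times with a 4-year baseline median, and
exponential censoring calibrated by bisection to a 50% censoring rate.
The harness scores every method × rule combination by TPR, TNR, FPR
(`TNR + FPR = 1` by construction).

## Worked example

```r
library(survsel)

# one replicate of benchmark design 2 (q = 5 strong protective effects)
des <- simulation_design(2)
des$censor_rate_c <- calibrate_censoring(des, seed = 12)
rep <- generate_replicate(des, seed = 501)
d <- rep$data
foldid <- make_folds(d$event, 10, seed = 501)   # shared CV folds

fit <- fit_gsslasso_cox(d, foldid = foldid)     # group spike-and-slab
sel <- ci_rule(fit$beta, fit$se, alpha = 0.10)  # 90% CI rule
operating_characteristics(sel, rep$truth$support, d$p)
```

Output from this exact run:

```
#> gss: 1.188s, chosen s0 = 0.03
#> $tpr  [1] 1
#> $tnr  [1] 1
#> $fpr  [1] 0
#> $n_selected [1] 5
```

i.e. the 90% CI rule applied to the group spike-and-slab posterior mode
recovers all 5 true biomarkers on this replicate with no false positives
(a HIGH-signal design; LOW-signal designs are substantially harder).

The full study is one call:

```r
bench <- run_benchmark(as.list(1:4),
                       methods = c("lasso", "elastic_net",
                                   "adaptive_lasso", "rsf"),
                       reps = 100, seed_base = 1)
bench             # mean TPR/TNR/FPR per design x method x rule
render_tables(bench, "results/")
```

There is also a command-line front end (`inst/cli/survsel`):

```sh
survsel simulate --config design.yaml --out data/
survsel fit --method lasso --data data/replicate_001.csv \
        --folds 10 --seed 1 --out fit.json
survsel select --rule mbic --fit fit.json \
        --data data/replicate_001.csv --out selection.json
```

Every run writes a `manifest.json` sufficient to re-execute it
byte-for-byte.

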