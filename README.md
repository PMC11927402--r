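# cateselect

Model selection for causal inference with **outcome models**
(g-computation): given a family of candidate predictors
`f(x, a)` of an outcome `y` under a binary treatment `a`, which one
should be trusted to estimate treatment effects?

Contrasting a predictor's arms induces an estimate of the conditional
average treatment effect (CATE), `τ̂_f(x) = f(x, 1) − f(x, 0)`. The model
with the best factual prediction error is **not** in general the model
with the best CATE: the classical mean squared error ignores how the
error splits across treated and control regions. The ideal criterion —
the **τ-risk** (PEHE), `E[(τ(X) − τ̂_f(X))²]` — needs the true effect and
is only computable in simulation. `cateselect` implements the family of
feasible causal risks that proxy it from observable data via two
nuisance functions, the propensity score `e(x) = P(A=1|x)` and the
conditional mean outcome `m(x) = E[Y|x]`:

| risk | formula (sample mean over the test set) |
|---|---|
| μ-risk | `(y − f(x; a))²` |
| μ-risk_IPW | `(a/e + (1−a)/(1−e)) · (y − f(x; a))²` |
| τ-risk_IPW | `(y(a/e − (1−a)/(1−e)) − τ̂_f(x))²` |
| U-risk | `((y − m)/(a − e) − τ̂_f(x))²` |
| **R-risk** | `((y − m) − (a − e) τ̂_f(x))²` |

each in a *semi-oracle* version (true nuisances, simulation only) and a
*feasible* version (stacked ridge + gradient-boosting nuisance
estimators, hyperparameters by nested cross-validation). The R-risk —
the squared residual of the Robinson decomposition
`y = m(x) + (a − e(x)) τ(x) + ε` — is the recommended default: its
population value is the τ-risk reweighted by `e(x)(1 − e(x))` plus a
candidate-independent noise term, and it involves no division by the
propensity.

The package provides:

* `select_cate()` — the fitting function: train/test split, candidate
  and nuisance fitting on the train side, full risk table on the test
  side, argmin selection; returns a classed object with
  `print`/`summary`/`predict` (CATE) /`coef` (ATE) /`plot` methods;
* `sample_caussim()` — a ground-truth simulator built on random radial
  basis function expansions with a controllable treated/control overlap
  knob, exposing all oracle quantities (`mu0`, `mu1`, `e`, `m`, `tau`);
* `build_caussim_family()` / `build_gbt_family()` — the 120-member
  ridge-on-RBF meta-learner family (TLearner/SftLearner × 6 penalties ×
  10 random featurizations) and the 18-member gradient-boosted SLearner
  grid;
* `run_benchmark()` — the evaluation harness: Kendall and relative
  Kendall agreement of every risk with the oracle τ-risk, excess τ-risk
  of each risk's selection, overlap (normalized total variation) and
  effect-ratio stratification.

For whom: applied statisticians and methods researchers in
biostatistics/epidemiology who use flexible outcome models (meta-learners,
boosting) for treatment-effect estimation and need a principled,
data-driven way to choose among them — or to benchmark selection metrics
themselves.

## Worked example

```r
library(cateselect)
data <- sample_caussim(caussim_config(n_samples = 1000,
                                      overlap_strength = 1, seed = 7))
sel <- select_cate(data, family = build_caussim_family(),
                   risk = "r_risk", seed = 7)
print(sel)
#> Causal model selection (train/test risk minimization)
#>   120 candidates, n = 1000 (train fraction 0.90, shared nuisance set)
#>   selection risk: r_risk (feasible)
#>   selected: TLearner_b08_lam1e-03
#>   oracle check: excess tau-risk 0.00% over the best candidate
```

The feasible R-risk — computed from *estimated* nuisances on the 100
held-out rows — picked the candidate whose oracle PEHE is the best of
all 120 (excess 0.00%). `summary(sel)` prints the top of the risk table
and the rank agreement with the oracle:

```r
summary(sel)
#>           candidate_id  mu_risk tau_risk_oracle ... r_risk_feas
#>  TLearner_b08_lam1e-03 0.004684        0.004096 ...    0.006182
#>  ...
#> Kendall agreement of r_risk_feas with the oracle tau-risk: 0.827
```

The selected model's g-computation ATE is close to the truth:

```r
coef(sel, newdata = data)
#>       ate
#> -0.702931
mean(data$tau)   # oracle
#> [1] -0.7076636
```

`predict(sel, newdata)` returns the selected model's CATE at new points,
and `plot(sel)` shows every candidate's selection risk against its
oracle τ-risk.

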