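# icomproc

Information-complexity model selection for ROC curves.

Diagnostic and classification studies routinely summarize a score's
discriminating ability by its ROC curve, but choosing *which* ROC curve
model to trust — which pair of score distributions for the two classes, or
which classifier among several — is usually left to the AUC alone.
`icomproc` implements an information-criterion alternative for
biostatisticians and ML practitioners: candidate ROC models are scored with
**AIC-ROC** and the information-complexity criterion **ICOMP-ROC**, both
built from the correlation structure of the curve's (FPR, TPR) points, so
that model fit and model complexity are weighed together.

## The model

A Bi-distributional (Universal) ROC model assumes parametric families for
the negative-class and positive-class score distributions, `F0` and `F1`,
fitted by maximum likelihood; the curve is

    R(p) = 1 - F1(F0^-1(1 - p)),   p in [0, 1]

and AUC = ∫ R(p) dp, evaluated by adaptive Gauss–Kronrod quadrature. Seven
families are supported (Normal, Exponential, Weibull, Gamma, minimum
extreme value, generalized extreme value, generalized Pareto), enumerated
into sixteen candidate pairs. With `R = [[1, r], [r, 1]]` the correlation
matrix of a candidate's ROC point set and `n = n1 + n2` the total sample
size,

    AIC-ROC   = n (log 2π + log|R| + 1) + 2 rank(R)
    ICOMP-ROC = n (log 2π + log|R| + 1) + 2 C1(F^-1)

where `C1(F) = (s/2) log(tr(F)/s) - (1/2) log det(F)` is the maximal
entropic complexity of the inverse Fisher information matrix of the
standardized bivariate normal, assembled block-diagonally from `R` and the
duplication-matrix transform `(2/n) D2+ (R ⊗ R) D2+'` (rank `s = 5`).
Both criteria are minimized. The package also provides the Monte Carlo
harness that measures how often each criterion recovers a known generating
pair, confusion-matrix metrics with criterion scoring for five stock
classifiers under stratified cross-validation, genetic-algorithm feature
selection, and synthetic-data generators. See the methods vignette
(`vignettes/icomp-roc-methods.Rmd`) for assumptions, numerical choices and
known limitations.

## Worked example

Fit the true families to a simulated two-class score sample and score the
candidate:

```r
library(icomproc)

d <- simulate_scores(dist_spec("Weibull", alpha = 1, beta = 2),   # positive
                     dist_spec("Gamma",  alpha = 2, beta = 2),    # negative
                     seed = 7)                                    # 300 / 200

neg <- d$score[d$label == 0]
pos <- d$score[d$label == 1]
pair <- biroc_pair(fit_dist(pos, "Weibull"), fit_dist(neg, "Gamma"))
pair
#> <biroc_pair> Weibull-Gamma
#>   positive (F1): <dist_spec> Weibull(alpha = 1.12916, beta = 2.13196)
#>   negative (F0): <dist_spec> Gamma(alpha = 2.03584, beta = 2.15782)

score_candidate(pair, n = nrow(d), pooled = d$score)
#>       candidate    auc aic_roc icomp_roc    c1      r   n excluded
#> 1 Weibull-Gamma 0.6933   299.9     317.6 10.84 0.9456 500    FALSE
```

The fitted shapes and scales sit near the generating values, the
quadrature AUC (0.693) matches the empirical AUC of the same sample
(`roc_auc(roc_empirical(d, score, label))` gives 0.695), and the report
carries both criteria with the point-set correlation `r` they were built
from. `run_monte_carlo(mc_scenario_preset("nn"))` repeats this over all
sixteen candidates and tabulates each criterion's selections;
`autoplot()` methods draw curves, frequency tables and GA traces.

A thin command-line front end over the same functions is installed at
`inst/cli/icomproc.R` (`fit-pair`, `simulate`, `make-data`,
`score-classifiers`, `ga-select`, `ga-intersect`).

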