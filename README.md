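# irtfuse

Latent trait measurement that fuses a Likert questionnaire with
free-text evidence. `irtfuse` is aimed at psychometricians and applied
researchers who have, for the same subjects, (a) an ordered polytomous
response matrix, (b) per-subject documents (essay answers, social-media
posts), and (c) binary criterion labels (high/low trait), and who want
to know whether the text improves on the questionnaire — and by how
much.

## The model

**Questionnaire route.** Samejima's graded response model: item *i* with
*K* ordered categories has discrimination *a*ᵢ and ordered boundary
difficulties *b*ᵢ₁ ≤ … ≤ *b*ᵢ,ₖ₋₁; the cumulative curves are

&nbsp;&nbsp;&nbsp;&nbsp;P\*ᵢₓ(θ) = 1 / (1 + exp(−D·aᵢ·(θ − bᵢₓ))),&nbsp;&nbsp;D = 1.702,

and category probabilities are adjacent differences Pᵢₓ = P\*ᵢₓ −
P\*ᵢ,ₓ₊₁. Item parameters are estimated either by Metropolis–Hastings
Robbins–Monro stochastic approximation (`method = "mhrm"`) or by a
deterministic Bock–Aitkin quadrature EM (`method = "em"`, the reference
implementation); traits θ are scored by MAP on a bounded grid.

**Text route.** Row-normalised TF-IDF with the smoothed idf
ln(N/(nₜ+0.01)), univariate F-test feature selection (p ≤ 0.1), a
calibrated linear SVM, and the per-subject log likelihood ratio
y = ln(S₁/S₂) of the two class probabilities.

**Fusion.** On training folds, θ is regressed on y, so each subject gets
a personal prior θ|y ~ N(b₀ + b₁y, σ²); traits are re-scored by MAP
under that prior and a Gaussian naive Bayes classifier is trained on the
fused features [y, θ]. All routes share one stratified 5-fold
assignment and are compared by the six confusion-matrix indicators
(accuracy, sensitivity, specificity, PPV, NPV, F1), averaged over
validation folds.

Because real cohorts of this design are rarely shareable, the package
ships a first-class synthetic generator (`simulate_study()`) producing
traits, GRM responses, median-split labels from a noisy trait-linked
score, and token-level text whose informative terms carry a tunable
class/trait signal λ.

## Worked example

```r
library(irtfuse)

sim <- simulate_study(sim_config(n = 200, m = 6, K = 5, vocab_size = 80,
                                 seed = 42))
fit <- grm(sim$responses, method = "em")
round(coef(fit), 2)
#>           a    b1    b2    b3   b4
#> item_1 1.27 -1.36  0.00  0.80 1.11
#> item_2 1.71 -0.91 -0.42 -0.08 1.65
#> item_3 0.66 -0.47 -0.29 -0.08 1.53
#> item_4 0.68 -1.00 -0.63  0.51 0.91
#> item_5 1.48 -1.94 -0.71  0.70 2.10
#> item_6 1.08 -1.04 -0.13  0.23 1.20
```

Each row is one item: its discrimination (how sharply responses separate
subjects along the trait) and the trait levels at which a subject is
50/50 to cross each category boundary.

```r
st <- run_study(sim$responses, sim$labels, sim$corpora,
                config = study_config(seed = 42))
st
#> Three-method latent trait study (200 subjects, 5-fold stratified CV, seed 42)
#>
#>            model   ACC  SEN  SPE   PPV   NPV    F1
#>              irt 0.780 0.80 0.76 0.770 0.793 0.784
#>       text_essay 0.845 0.86 0.83 0.847 0.855 0.850
#>      fused_essay 0.855 0.84 0.87 0.869 0.843 0.854
#>   text_microblog 0.875 0.91 0.84 0.858 0.905 0.881
#>  fused_microblog 0.845 0.86 0.83 0.840 0.859 0.848
#>    text_combined 0.885 0.91 0.86 0.870 0.911 0.887
#>   fused_combined 0.865 0.88 0.85 0.857 0.876 0.868
```

The seven rows are the questionnaire-only model, three text models
(essay, micro-blog, concatenation) and three fused models. Here the
questionnaire-only classifier reaches 0.78 accuracy while every
text-informed model sits in the mid-0.8s; at n = 200 single replicates
are noisy, so the package's formal claims average over replicates (see
below). `write_report(st, dir)` serialises the table, item parameters,
trait estimates, per-subject predictions and a JSON manifest, and a
rerun with the same seed reproduces them byte for byte.

A thin CLI wraps the same functions:

```sh
exec/irtfuse simulate --n 901 --seed 1 --out data/
exec/irtfuse run-all --responses data/responses.csv --labels data/labels.csv \
  --corpus-essay data/corpus_essay.jsonl --corpus-microblog data/corpus_microblog.jsonl \
  --seed 1 --out results/
```

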