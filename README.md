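# clearf

Supervised feature scoring for continuous omics data (bulk and single-cell
expression matrices, and any samples-by-features table with class labels)
via **class-wise low-dimensional embedding and reconstruction error**.

## The idea

Information-theoretic feature selection scores a feature by its mutual
information with the class label, $I(X;Y) = H(X) - H(X\mid Y)$, but
estimating entropies forces continuous expression values through
discretisation and is slow at genome scale.  `clearf` replaces both
entropy terms with reconstruction errors of low-dimensional embeddings:
fit a $k$-component embedding (PCA or kernel PCA) once to the pooled data
and once to each class separately — always with the same $k$ — and score
each feature $j$ by

```
score_j = err_all(j) - sum_c err_c(j)
```

where `err(j)` is the feature's aggregated squared reconstruction
residual.  The pooled term plays the role of $H(X)$ (complex data
compress badly), the class-wise sum that of $H(X\mid Y)$.  Features whose
variation is hard to compress pooled but easy to compress within each
class — i.e. features that differ *between* classes — score high.  The
score is continuous end to end, needs only $C+1$ embedding fits, and
ranks features for downstream classifiers or biomarker shortlists.

The package implements the scorer (linear PCA, RBF and cubic-polynomial
kernel PCA backends with a deterministic ridge pre-image), the
component-size search anchored on the smallest class
(candidates $1, C_{\min}/4, C_{\min}/2, 3C_{\min}/4, C_{\min}$), a
stratified 10-fold cross-validated SVM benchmark over feature counts
5–50, and the simulation generators used to validate the method:
the entropy/reconstruction-error correspondence, a separated-vs-
overlapping two-class demonstration, and informative-feature recovery.

## Worked example

Two two-feature, 500-sample scenarios: classes far apart with opposing
within-class trends, versus classes drawn from one distribution.

```r
library(clearf)

cfg   <- score_config(embedding_spec("pca", 1), aggregation = "sum",
                      standardize = FALSE)
d_sep <- generate_two_class_2d("separated",   500, seed = 101)
d_ovl <- generate_two_class_2d("overlapping", 500, seed = 102)

clearf_scores(d_sep, cfg)
#> clearf_scores: 2 features (aggregation = sum)
#>  feature    score rank
#>       X1 146.2642    1
#>       X2 145.8026    2

clearf_scores(d_ovl, cfg)
#> clearf_scores: 2 features (aggregation = sum)
#>  feature     score rank
#>       X1 0.3856832    1
#>       X2 0.2437696    2
```

When the classes separate, each class is individually near
one-dimensional, so the class-wise embeddings reconstruct almost
perfectly while the pooled embedding cannot — both features score in the
hundreds.  When the classes coincide, pooled and class-wise fits are
equally good and the scores collapse toward zero (here a ~400-fold drop).
Ranking features by this score and keeping the top $f$ is the whole
selection step; `cross_validate()` measures held-out SVM accuracy over a
grid of $f$ with scoring confined to each fold's training part.

The entropy surrogate itself can be checked directly:

```r
simulate_entropy_correlation(500, 100, k = 1, reps = 1000, seed = 1)
#> entropy_sim_result: 1000 reps, R^2 = 0.9036
```

A command-line interface over the same functions ships at
`inst/cli/clearf.R` (subcommands `score`, `benchmark`,
`simulate-entropy`, `simulate-twoclass`).

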