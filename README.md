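# mdbnc

Identifying informative genes across expression datasets of increasing
biological complexity with Bayesian network classifiers.

## What this package is for

Given several expression datasets covering the same biological process
— one clean and controlled, the others noisier and biologically more
complex (the motivating case is myogenic differentiation: in-vitro
time courses vs heterogeneous experiments) — `mdbnc` asks which genes
remain *predictable* across all of them.  The premise is that a model
trained on the simple dataset captures interactions that are genuinely
part of the process, and that genes it keeps predicting well on
independent complex data are the informative ones, even where the
complex data's own differential-expression statistics are drowned in
noise.

The machinery:

* **Conditional linear-Gaussian Bayesian network classifiers** over a
  binary class node (differentiation status) and continuous gene
  nodes, in three structural complexity classes: selective naive Bayes
  (SNB, class-to-gene edges only), one-parent (1PB, at most one gene
  parent per gene), and unrestricted (NPB).
* **Structure learning by simulated annealing** with the Bayesian
  Information Criterion, `BIC = logL − (k/2)·log n`, over
  add/remove/swap edge operators, plus an exhaustive-search oracle for
  small instances.
* **Multi-dataset evaluation**: k-fold cross-validation on the simple
  dataset; every fold model is also scored on each independent dataset
  in full.  Per gene g the score is the mean squared prediction error
  `SSE(g) = (1/n) Σ_s (x̂_g(s) − x_g(s))²` and its across-fold
  variance; genes are ranked by both.
* **Ranking statistics**: position p-values against spiked-in
  uninformative genes (`p = (1 + #nulls ranked above) / (n_null + 1)`),
  Kolmogorov–Smirnov separation of informative vs uninformative ranks,
  and rank improvement/deterioration of gene groups between a
  dataset's own t-test ranking and the model-based ranking.
* **A synthetic regulatory-network generator** (Hill-kinetics
  steady-state simulator on a scale-free topology, 1330 genes / 2724
  interactions at source scale) producing three datasets of increasing
  noise from one subnetwork, with full ground truth — so every claim
  the pipeline makes can be checked against planted truth.

## Worked example

Simulate the three-tier series, run the full experiment with the
one-parent classifier, and look at the design's key read-outs:

```r
library(mdbnc)

bench <- tier_benchmark(seed = 11)

bench$order
#>   name n_significant replicate_cor index
#> 1  low            30     0.9475342     1
#> 2  mid             0     0.7176101     2
#> 3 high            0     0.6495554     3

bench$summary[, c("train", "constraint", "cv_error", "test_error")]
#>   train constraint  cv_error test_error
#> 1   low        1PB 0.5258426  0.5779552
#> 2   mid        1PB 0.6352723  0.6545916
#> 3  high        1PB 0.7732574  0.8097419

bench$shift_groups
#>                  group   n mean_shift         ks_p
#> 1      top_informative 100      25.37 3.641266e-10
#> 2        uninformative  50     -50.74 3.641266e-10
#> 3 condition_responsive  46     -12.70 1.331786e-03
```

Reading the output: the tiers order from simplest (most differentially
expressed genes at BH < 0.05, highest replicate correlation) to most
complex — in the noisy tiers the t-test finds *nothing* at all.
Cross-validation *and* independent-test error are lowest for models
trained on the cleanest tier and rise with training-tier noise.  And
when the clean tier's models re-rank genes in the noisiest dataset,
the 100 informative panel genes move up by ~25 rank places on average
while the 50 spiked-in uninformative genes drop by ~51: the model
separates signal from noise where the noisy dataset's own t-test
cannot.  (Group compositions — here, how many planted responsive genes
end up inside the panel — vary from seed to seed; the acceptance
checks assert the majority behaviour over several seeds.)

Lower-level entry points do each stage separately:
`read_expression_matrix()` / `standardize()` / `select_gene_panel()` /
`make_folds()` (data handling), `anneal()` / `exhaustive_search()` /
`bic_score()` (structure learning), `multidata_eval()` (the
cross-validated multi-dataset scoring), `position_p_values()` /
`ks_separation()` / `rank_shift()` (ranking statistics), and
`generate_source_topology()` / `make_dataset_series()` (the
generator).  A thin command-line front end lives in `inst/cli/mdbnc`
(subcommands `simulate` and `run` over a YAML config).  See
`vignettes/methods.Rmd` for the model, the search, the generator's
assumptions, and the package's design decisions.

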