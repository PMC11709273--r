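# omixfuse

Cancer molecular subtype diagnosis from **incomplete multi-omics data**.

Clinical cohorts rarely provide complete DNA methylation, miRNA and mRNA
profiles for every patient, and in-house cohorts are often too small to
train a reliable classifier. `omixfuse` implements an integrative model
that addresses both constraints:

* **Low-rank multimodal fusion.** Per-omics feedforward extractors embed
  each block; the bias-augmented embeddings $\tilde h^m = [h^m; 1]$ are
  fused as
  $z = \sum_{r=1}^{R} \bigwedge_m (w^m_r)^\top \tilde h^m + b$ — the
  factored contraction of a rank-$R$ decomposed $(M{+}1)$-order tensor,
  never materialized.
* **Missing-omics imputation.** Complete samples are augmented into two
  omics-masked views; an NT-Xent contrastive loss
  $\ell(u',u'') = -\log \frac{\exp(\cos(u',u'')/\tau)}
  {\sum_{u \neq u'} \exp(\cos(u',u)/\tau)}$ enforces cross-view agreement,
  and omics-specific generators $g^m$ reconstruct masked blocks from the
  fused representation (masking-and-reconstruction), gated by the
  availability mask $\Lambda$ for genuinely incomplete samples.
* **Class-weighted diagnosis.** Missing blocks are imputed, encoded and
  classified with weights $w_y = N^{tr}/(N^s N_y)$; the three losses are
  routed to disjoint sub-networks (contrastive → encoder+projector,
  generation → encoder+generators, diagnosis → encoder+head).
* **Meta-learning transfer.** N-way K-shot episodes from external cohorts
  drive a first-order bi-level optimization; a category-level contrastive
  loss over kernel-density estimates of per-subtype representation
  distributions (affinity $F = -\mathrm{JSD}$) aligns subtypes across
  cohorts and updates only the encoder.
* **Interpretation.** Permutation feature importance (10-repeat averaged
  diagnosis-loss increase, optionally per subtype) and an integrated
  prognostic risk score
  $\mathrm{ICS} = e^{\,\mathrm{CIN} + (1-\mathrm{MSI}) + 2\,\mathrm{GS} +
  (1-\mathrm{EBV})}$ over sigmoid subtype scores.

A synthetic multi-omics generator with known subtype structure, block-wise
missingness and controllable cross-cohort shift makes every component
testable without any data download. All trainable components run on a
small, fully tested reverse-mode autodiff engine over base-R matrices —
no external deep-learning runtime is required.

The methods vignette (`vignettes/methods.Rmd`) documents the model,
parameter defaults, experiment designs and limitations.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "omixfuse", load_package = "installed")'
```

## Worked example

Train on a synthetic three-omics cohort with 25% simulated block
missingness, evaluate, and inspect the model:

```r
library(omixfuse)

spec <- synthetic_spec(n_samples = 200, dims = c(50, 50, 50),
                       n_subtypes = 4, separation = 3, noise_sd = 0.3,
                       rng_seed = 7)
ds <- generate_multiomics_dataset(spec)$dataset |>
  simulate_missingness(rate = 0.25, rng_seed = 7)

cfg <- learner_config(d_e = 16, d_h = 16, rank = 4, hidden = 32,
                      proj_hidden = 16, proj_dim = 8, epochs = 40)
run <- run_supervised(ds, load_run_config(overrides = c(as.list(cfg))),
                      seed = 7)
run$metrics
#> # A tibble: 1 × 5
#>    seed accuracy auroc precision f1_weighted
#>   <dbl>    <dbl> <dbl>     <dbl>       <dbl>
#> 1     7        1     1         1           1

glance(run$learner)
#> # A tibble: 1 × 9
#>   n_omics n_features n_classes   d_h  rank n_parameters epochs final_loss
#>     <int>      <int>     <int> <dbl> <dbl>        <dbl>  <int>      <dbl>
#> 1       3        150         4    16     4        13554     40       2.96
#> # ℹ 1 more variable: final_diagnosis_loss <dbl>
```

Accuracy 1 on the held-out 20% means every test patient's subtype was
recovered despite a quarter of the cohort missing one omics block — the
synthetic cohort is deliberately well separated; `separation` and
`noise_sd` control how hard the problem is. `autoplot(run$learner)` draws
the per-epoch loss components; `tidy(run$learner)` returns them as a long
tibble.

Imputation quality against a column-mean baseline, importance and risk
scores:

```r
lrn <- run$learner
imp <- permutation_importance(lrn, ds, repeats = 10, rng_seed = 1)
top_features(imp, n = 5)         # top features per omics
autoplot(imp)

preds <- predict_subtypes(lrn, ds)
# with gastric-style labels CIN/MSI/GS/EBV the sigmoid scores feed the
# integrated risk score:
# integrated_subtype_score(preds)
```

Few-shot transfer from an external cohort to a small target cohort:

```r
pair <- generate_domain_shifted_pair(synthetic_spec(
  n_samples = 200, dims = c(50, 50, 50), separation = 1.5,
  noise_sd = 0.4, shift = 1, rng_seed = 3))
res <- run_transfer(pair$external, pair$target,
                    config = load_run_config(overrides = list(
                      d_e = 8, d_h = 8, rank = 2, hidden = 24,
                      proj_hidden = 8, proj_dim = 4, n_outer = 10,
                      n_sub = 2, kde_grid = 48, inner_rate = 0.02,
                      outer_rate = 0.005, finetune_epochs = 30)),
                    seed = 3)
res$report
#> # A tibble: 2 × 6
#>   model   accuracy auroc precision f1_weighted accuracy_gain
#>   <chr>      <dbl> <dbl>     <dbl>       <dbl>         <dbl>
#> 1 meta       0.731 0.933     0.744       0.707         0.175
#> 2 scratch    0.556 0.861     0.639       0.483         0.175
```

(Early in meta-training the density estimator may warn about
near-constant representation dimensions and floor their bandwidths; the
warnings are benign.)

The `meta` row is the model meta-trained on the external cohort and
fine-tuned on a 4-way 10-shot target subset (40 labeled samples); the
`scratch` row trains the same architecture on those 40 samples alone.
`accuracy_gain` is the meta-over-scratch difference on the held-out
target samples.

A thin command-line front-end over the same functions lives at
`inst/cli/omixfuse.R` (`synth`, `preprocess`, `simulate-missing`,
`train`, `transfer`, `impute`, `importance`, `ics`).

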