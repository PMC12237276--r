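# farka

Field-Agnostic Riemannian-Kernel Alignment: cross-subject motor-imagery
EEG classification without target labels.

## What it does

A motor-imagery brain–computer interface classifies short multichannel EEG
epochs by their spatial covariance: imagined movement suppresses band
power in class-specific channels (event-related desynchronization), and
that contrast lives in the covariance matrix of each epoch. Covariances
are symmetric positive definite (SPD) matrices, and the affine-invariant
Riemannian metric δ(M₁, M₂) = ‖log(M₁^{-1/2} M₂ M₁^{-1/2})‖_F is the
natural geometry because it is invariant to the invertible linear mixing
each subject's head imposes on the underlying sources.

Classifiers rarely survive a change of subject, since each subject is a
differently mixed *field* of epochs. `farka` stacks two label-free
adaptations:

1. **Centroid alignment** — whiten every subject's covariances by their
   own Riemannian (Karcher) mean, so each field's centroid becomes the
   identity. Aligned covariances are mapped to Euclidean tangent-space
   features whose norms equal Riemannian distances.
2. **Kernel-spectrum adaptation** — eigendecompose a kernel on the
   unlabelled target field, express the labelled source field in that
   eigenbasis by Nyström extrapolation, and re-learn the source spectrum
   with a small quadratic program constrained to a power-law decay
   (σᵢ ≥ μ σᵢ₊₁ ≥ 0). The adapted union kernel feeds a precomputed-kernel
   SVM trained on source labels only.

The package also ships a synthetic multi-subject EEG generator with
ERD-style class covariances and per-subject invertible mixing, degradation
operators (attenuation, calibrated AWGN, zero-phase FIR band-pass), and
M2S (all-but-one-to-one) / S2S (pairwise) evaluation harnesses that return
tidy tibbles with `tidy()`, `glance()`, and `autoplot()` methods.

See `vignettes/field-agnostic-kernel-alignment.Rmd` for the method in
detail, including numerical choices and known limitations (centroid
alignment removes a congruence shift only up to an orthogonal rotation —
the kernel step handles the rest).

## Worked example

```r
library(farka)

# three synthetic subjects differing only by invertible channel mixing
pop  <- make_population(population_spec(n_subjects = 3, seed = 42))
plan <- plan_tasks(c("s1", "s2", "s3"), mode = "m2s")
ev   <- run_plan(pop, plan)
ev
#> <farka_eval> 3 tasks (m2s), mean accuracy 1.0000
#> # A tibble: 3 × 6
#>   task_id       mode  target_id n_source n_target accuracy
#>   <chr>         <chr> <chr>        <int>    <int>    <dbl>
#> 1 m2s:s2+s3->s1 m2s   s1             160       80        1
#> 2 m2s:s1+s3->s2 m2s   s2             160       80        1
#> 3 m2s:s1+s2->s3 m2s   s3             160       80        1

glance(ev)
#> # A tibble: 1 × 8
#>   n_tasks mode  mean_accuracy n_failed    mu   eta kernel alignment
#>     <int> <chr>         <dbl>    <int> <dbl> <dbl> <chr>  <chr>
#> 1       3 m2s               1        0   1.5    10 rbf    riemannian
```

At the default mixing strength the task is easy; alignment earns its keep
when mixing is severe:

```r
pop <- make_population(population_spec(n_subjects = 3,
                                       subject_mixing_strength = 0.85,
                                       seed = 42))
run_plan(pop, plan)$mean_accuracy                                    # 0.9292
run_plan(pop, plan, farka_params(alignment_space = "none"))$mean_accuracy
#> 0.8292
```

Lower-level building blocks are exported too: `estimate_covariances()`,
`align_subject()`, `tangent_map()`, `kka()`, `farka_fit()`/`predict()`,
`sweep_farka()`, and `mean_spd()`/`riemannian_distance()` for SPD
geometry. A thin CLI lives at `inst/scripts/farka.R`
(`simulate` / `run` / `degrade` over epoch directories written by
`write_epoch_dir()`).

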