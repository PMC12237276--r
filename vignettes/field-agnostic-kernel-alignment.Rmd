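---
title: "Field-agnostic Riemannian-kernel alignment for cross-subject EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-agnostic Riemannian-kernel alignment for cross-subject EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(farka)
```

## The problem

A motor-imagery brain–computer interface classifies short multichannel EEG
*epochs* into imagined-movement classes. The discriminative signal lives in
the spatial covariance of each epoch: event-related desynchronization
suppresses band power in class-specific channels. Covariance matrices are
symmetric positive definite (SPD), and the affine-invariant Riemannian
metric

$$\delta(M_1, M_2) = \lVert \log(M_1^{-1/2} M_2 M_1^{-1/2}) \rVert_F$$

is the natural geometry: it is invariant under any congruence
$M \mapsto A M A^\top$ with invertible $A$, which is exactly how a change
of electrode mixing acts on covariances.

Classifiers trained on one subject transfer poorly to another because each
subject imposes their own (approximately linear, invertible) mixing of the
underlying sources. This package treats each subject as a *field* — a set
of epochs with covariances — and combines two adaptations:

1. **Centroid alignment.** Each subject's covariance set is whitened by its
   own Riemannian (Karcher) mean $N$: $Q_i = N^{-1/2} M_i N^{-1/2}$. After
   alignment every subject's centroid is the identity, so first-order
   differences in mixing are removed. (This is a partial correction, see
   *Limitations*.)
2. **Kernel-spectrum adaptation (KKA).** After mapping aligned covariances
   to tangent-space features, a kernel on the unlabelled *target* field is
   eigendecomposed, the *source* field is expressed in the target's
   eigenbasis by Nyström extrapolation, and a replacement spectrum for the
   source kernel is learned by a small quadratic program constrained to a
   power-law decay. The resulting union kernel over source and target rows
   feeds a precomputed-kernel SVM trained on source labels only.

## Pipeline in code

```{r}
pop <- make_population(population_spec(
  n_subjects = 3, n_epochs_per_class = 20, ch = 6, n_samples = 256,
  erd_channels = list(c(1L, 2L), c(3L, 4L)), seed = 7
))

covs  <- estimate_covariances(pop[[1]])      # epochs -> trace-normalized SPD
covs  <- align_subject(covs)                  # whiten by the Karcher mean
feats <- tangent_map(covs)                    # log-map at the identity
head(as_tibble(feats))[, 1:5]
```

The tangent map vectorizes $\log Q_i$ with off-diagonal entries weighted by
$\sqrt 2$, so the Euclidean norm of a feature equals its Riemannian
distance from the identity. Classification between two subjects is one
call:

```{r}
model <- farka_fit(source = feats,
                   target = tangent_map(align_subject(
                     estimate_covariances(pop[[2]]))),
                   params = farka_params(mu = 1.5, eta = 10))
glance(model)
```

`predict(model)` labels the target epochs; no target labels are ever used
during fitting. The evaluation harness wraps this over all transfer tasks:

```{r}
plan <- plan_tasks(c("s1", "s2", "s3"), "m2s")
ev <- run_plan(pop, plan)
tidy(ev)
```

`sweep_farka()` runs the same plan over a hyperparameter grid and returns
a tibble (one row per grid point) with the full reports in a list column;
`autoplot()` methods visualize evaluations, sweeps, and kernel spectra.

## The kernel adaptation in detail

Let $K_t$ be the target Gram matrix and
$K_t = \Phi_t \Delta_t \Phi_t^\top$ its truncated eigendecomposition
(`target_eigensystem()`; eigenvalues below `floor_ratio` times the largest
are dropped and each eigenvector's sign is fixed by its first nonzero
component). The source rows are expressed in this basis by Nyström
extrapolation,

$$\tilde\Phi_s = K_{st} \Phi_t \Delta_t^{-1},$$

deliberately *not* re-orthonormalized (`nystrom_extrapolate()`). The
adapted source spectrum $\sigma$ minimizes
$\lVert \tilde\Phi_s \operatorname{diag}(\sigma) \tilde\Phi_s^\top - K_s \rVert_F^2$,
a quadratic program in $\sigma$ with Gram matrix
$G_{ij} = (\tilde a_i^\top \tilde a_j)^2$, subject to the damped-decay cone

$$\sigma_1 \ge \mu\,\sigma_2 \ge \mu^2\,\sigma_3 \ge \dots \ge 0,
\qquad \mu \ge 1.$$

Larger $\mu$ forces faster spectral decay, trading fidelity to $K_s$ for
smoothness in the target's basis; $\mu = 1.5$ is the default. The union
kernel $\tilde K = \Phi \operatorname{diag}(\sigma^\*) \Phi^\top$ with
$\Phi = [\tilde\Phi_s; \Phi_t]$ is PSD by construction, and its
source–target off-diagonal block is what lets a source-trained SVM score
target rows.

## Numerical choices

* **Karcher mean**: fixed-point iteration
  $N \leftarrow N^{1/2} \exp\!\big(\tfrac1n \sum_i \log(N^{-1/2} M_i
  N^{-1/2})\big) N^{1/2}$, arithmetic-mean start, tolerance $10^{-8}$, at
  most 50 iterations, with a warning on non-convergence.
* **Distances** use the generalized eigenvalues of $(M_1, M_2)$ rather
  than forming $M_1^{-1/2}$ explicitly.
* **QP solving**: `quadprog::solve.QP` after diagonal equilibration of
  $G$. The Nyström columns scale like $1/\delta_t$, so $G$ can span many
  orders of magnitude and `quadprog` occasionally reports an infeasible
  system on perfectly feasible inputs; the solver then falls back to an
  exact reparameterization $\sigma = M t$, $t \ge 0$ ($M$ upper-triangular
  in powers of $\mu$, which maps the cone onto the nonnegative orthant)
  solved as a non-negative least-squares problem. Both paths agree to
  machine precision where both succeed.
* **SVM**: `kernlab::ksvm` on the explicitly PSD-clipped precomputed
  kernel; dual coefficients are extracted so decision values can be
  formed on the union kernel's cross block.

## Limitations

Centroid alignment does **not** make two fields related by a congruence
$M \mapsto A M A^\top$ identical: if one field's covariances are
$\{M_i\}$ with Karcher mean $N$ and the other's are $\{A M_i A^\top\}$,
the aligned sets differ by conjugation with the *orthogonal* matrix
$B = N_c^{-1/2} A N^{1/2}$ (with $N_c$ the congruent field's mean). The
residual rotation is norm- and distance-preserving — distances to the
identity and the whole intra-field geometry coincide — which is exactly
why the subsequent kernel-spectrum step still has work to do: it matches
fields through their kernel spectra, which are invariant to this residual
rotation when features enter through inner products.

The synthetic generator covers the regime the method is designed for —
per-subject invertible mixing over shared class covariance templates —
and the degradation operators (attenuation, additive white Gaussian
noise, zero-phase FIR band-pass) probe robustness. Real EEG adds
nonstationarity and non-linear effects outside this model; the problem
sizes used throughout (tens of channels, tens of epochs per class) are
the package's own choice of a desk-scale test bed.
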