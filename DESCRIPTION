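Package: farka
Title: Field-Agnostic Riemannian-Kernel Alignment for Cross-Subject EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cross-subject motor-imagery EEG classification via Riemannian
    geometry and spectral kernel adaptation. Per-subject covariance sets are
    aligned so their Riemannian (or log-Euclidean, or Euclidean) centroid
    becomes the identity, mapped to Euclidean tangent-space features, and a
    field-agnostic kernel between a labelled source field and an unlabelled
    target field is learned by Nystrom extrapolation of the target kernel's
    eigen-system followed by a power-law-constrained quadratic program on the
    spectrum. Classification uses a precomputed-kernel support vector
    machine. Includes a synthetic multi-subject EEG generator with
    event-related-desynchronization covariance structure, signal degradation
    operators (attenuation, additive white Gaussian noise, FIR band-pass),
    and multi-source-to-single (M2S) / single-source-to-single (S2S)
    evaluation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    pracma,
    quadprog,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
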