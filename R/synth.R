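# run `expr` under a given seed without disturbing the caller's RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specify a synthetic multi-subject EEG population
#'
#' The generator emulates the statistical structure that the FARKA pipeline
#' consumes: two motor-imagery classes differ only through event-related
#' desynchronization (ERD), modelled as variance suppression in a
#' class-specific channel group; subjects differ only through an invertible
#' spatial mixing `A_c = I + (strength/sqrt(ch)) G` (`G` standard normal,
#' resampled while its condition number exceeds `1e6`) plus an optional
#' isotropic noise floor. Epochs are zero-mean Gaussian, so all class and
#' subject information lives in the covariances — exactly the regime the
#' method assumes.
#'
#' @param n_subjects Number of subjects (default 5).
#' @param n_epochs_per_class Epochs per class per subject (default 40).
#' @param ch Number of channels (default 8).
#' @param n_samples Samples per epoch (default 512).
#' @param erd_channels List of two disjoint integer channel sets, one per
#'   class, whose variance is suppressed for that class.
#' @param erd_depth Variance multiplier in `(0, 1]` applied to the ERD
#'   channels; `1` makes the classes identical (null case), smaller values
#'   are more separable. Default 0.5.
#' @param subject_mixing_strength Scale of the per-subject mixing
#'   perturbation (default 0.3); `0` removes all inter-subject shift.
#' @param subject_noise Variance of isotropic noise added to each subject's
#'   class covariance (default 0).
#' @param sample_rate Nominal sampling rate in Hz (default 250).
#' @param seed Integer RNG seed; the population is a deterministic function
#'   of the spec.
#' @return An object of class `population_spec`.
#' @examples
#' population_spec(seed = 1)
#' @export
population_spec <- function(n_subjects = 5, n_epochs_per_class = 40, ch = 8,
                            n_samples = 512,
                            erd_channels = list(c(1L, 2L), c(3L, 4L)),
                            erd_depth = 0.5, subject_mixing_strength = 0.3,
                            subject_noise = 0, sample_rate = 250,
                            seed = 1L) {
  stopifnot(n_subjects >= 1, n_epochs_per_class >= 1, ch >= 2, n_samples >= 1,
            is.list(erd_channels), length(erd_channels) == 2L,
            erd_depth > 0, erd_depth <= 1,
            subject_mixing_strength >= 0, subject_noise >= 0)
  if (length(intersect(erd_channels[[1]], erd_channels[[2]])) > 0L) {
    stop("the two ERD channel sets must be disjoint", call. = FALSE)
  }
  if (max(unlist(erd_channels)) > ch || min(unlist(erd_channels)) < 1) {
    stop("ERD channel indices must lie in 1..ch", call. = FALSE)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_epochs_per_class = as.integer(n_epochs_per_class),
         ch = as.integer(ch), n_samples = as.integer(n_samples),
         erd_channels = lapply(erd_channels, as.integer),
         erd_depth = erd_depth,
         subject_mixing_strength = subject_mixing_strength,
         subject_noise = subject_noise, sample_rate = sample_rate,
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "<population_spec> %d subjects x %d epochs/class, %d ch x %d samples, erd_depth = %g, mixing = %g, noise = %g, seed = %d\n",
    x$n_subjects, x$n_epochs_per_class, x$ch, x$n_samples, x$erd_depth,
    x$subject_mixing_strength, x$subject_noise, x$seed))
  invisible(x)
}

# invertible per-subject mixing, resampled while badly conditioned
.draw_mixing <- function(ch, strength, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    A <- diag(ch) + (strength / sqrt(ch)) * matrix(stats::rnorm(ch * ch), ch)
    if (kappa(A, exact = TRUE) < 1e6) return(A)
  }
  stop("could not draw a well-conditioned mixing matrix", call. = FALSE)
}

#' Generate a synthetic multi-subject population
#'
#' For class `k`, the base covariance is the identity with the variance of
#' that class's ERD channels multiplied by `erd_depth`; subject `c` observes
#' `A_c Sigma_k A_c' + subject_noise * I` and draws zero-mean Gaussian
#' epochs from it. Labels are balanced and interleaved (1, 2, 1, 2, ...).
#'
#' @param spec A [population_spec()].
#' @return A list of [epoch_set()] objects, one per subject, with subject
#'   ids `"s1" .. "sN"`. Deterministic given `spec` (including its seed),
#'   and leaves the caller's RNG state untouched.
#' @examples
#' pop <- make_population(population_spec(n_subjects = 2,
#'   n_epochs_per_class = 3, ch = 4, n_samples = 64, seed = 7))
#' pop[[1]]
#' @export
make_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  .with_seed(spec$seed, {
    ch <- spec$ch
    base_cov <- lapply(1:2, function(k) {
      S <- diag(ch)
      idx <- spec$erd_channels[[k]]
      S[cbind(idx, idx)] <- spec$erd_depth
      S
    })
    lapply(seq_len(spec$n_subjects), function(c_idx) {
      A <- if (spec$subject_mixing_strength > 0) {
        .draw_mixing(ch, spec$subject_mixing_strength)
      } else diag(ch)
      chol_k <- lapply(base_cov, function(S) {
        Sc <- A %*% S %*% t(A) + spec$subject_noise * diag(ch)
        chol(.symmetrize(Sc)) # upper triangular, Sc = t(R) %*% R
      })
      labels <- rep(c(1L, 2L), spec$n_epochs_per_class)
      epochs <- lapply(labels, function(k) {
        Z <- matrix(stats::rnorm(ch * spec$n_samples), ch)
        t(chol_k[[k]]) %*% Z
      })
      epoch_set(paste0("s", c_idx), epochs, labels, spec$sample_rate)
    })
  })
}

#' Attenuate epoch amplitudes by a global factor
#'
#' Every sample is multiplied by `af`, emulating globally weakened signals
#' (e.g. faint motor imagery). Covariances scale by `af^2`; because
#' centroid alignment removes any global scale, the aligned FARKA pipeline
#' is provably unaffected by this operator in exact arithmetic.
#'
#' @param e An [epoch_set()].
#' @param af Attenuation factor in `(0, 1]`.
#' @return An [epoch_set()] with scaled epochs; labels unchanged.
#' @export
attenuate <- function(e, af) {
  stopifnot(inherits(e, "epoch_set"), is.numeric(af), af > 0, af <= 1)
  e$epochs <- lapply(e$epochs, function(X) af * X)
  e
}

#' Add white Gaussian noise at a target signal-to-noise ratio
#'
#' Signal power is the mean squared amplitude over all epochs, channels and
#' samples; noise is i.i.d. Gaussian with variance
#' `P_signal / 10^(snr_db / 10)`, so that `10 log10(P_signal / P_noise)`
#' equals `snr_db` in expectation (within 0.1 dB realized once the set has
#' at least ~1e4 samples).
#'
#' @param e A non-empty [epoch_set()].
#' @param snr_db Target SNR in decibels (finite).
#' @param seed Optional seed for the noise draw; when given, the caller's
#'   RNG stream is left untouched.
#' @return An [epoch_set()] with noisy epochs.
#' @export
add_awgn <- function(e, snr_db, seed = NULL) {
  stopifnot(inherits(e, "epoch_set"), is.finite(snr_db))
  p_signal <- mean(unlist(lapply(e$epochs, function(X) X^2)))
  sd_noise <- sqrt(p_signal / 10^(snr_db / 10))
  draw <- function() {
    e$epochs <- lapply(e$epochs, function(X) {
      X + matrix(stats::rnorm(length(X), sd = sd_noise), nrow(X))
    })
    e
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

#' Zero-phase FIR band-pass filtering of an epoch set
#'
#' A Hamming-window linear-phase FIR band-pass of the given order is applied
#' forward and backward (zero-phase) to every channel of every epoch; the
#' default 8–30 Hz band covers the mu and beta rhythms that carry motor
#' imagery.
#'
#' @param e An [epoch_set()].
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo < hi < sample_rate / 2`.
#' @param order FIR order (default 50).
#' @return An [epoch_set()] of identical shape.
#' @export
bandpass_epochs <- function(e, lo_hz = 8, hi_hz = 30, order = 50) {
  stopifnot(inherits(e, "epoch_set"))
  nyq <- e$sample_rate / 2
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < nyq)) {
    stop(sprintf("band edges must satisfy 0 < lo < hi < %g Hz", nyq),
         call. = FALSE)
  }
  b <- signal::fir1(order, c(lo_hz, hi_hz) / nyq, type = "pass")
  e$epochs <- lapply(e$epochs, function(X) {
    t(apply(X, 1, function(row) signal::filtfilt(b, row)))
  })
  e
}
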