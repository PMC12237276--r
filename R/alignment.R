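#' Labelled epoch set for one subject
#'
#' The raw per-subject input: a list of epochs, each a `ch x T` numeric
#' matrix (channels by time samples, arbitrary amplitude units), with one
#' integer class label per epoch.
#'
#' @param subject_id A length-1 identifier.
#' @param epochs A non-empty list of `ch x T` numeric matrices, all with the
#'   same dimensions.
#' @param labels Integer class labels, one per epoch (two-class problems use
#'   labels `1` and `2` by convention, but any two integers work downstream).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `epoch_set`.
#' @examples
#' e <- epoch_set("s1", list(matrix(rnorm(20), 2), matrix(rnorm(20), 2)),
#'                labels = c(1, 2), sample_rate = 250)
#' e
#' @export
epoch_set <- function(subject_id, epochs, labels, sample_rate) {
  stopifnot(length(subject_id) == 1L)
  if (!is.list(epochs) || length(epochs) == 0L) {
    stop("`epochs` must be a non-empty list of channel x time matrices",
         call. = FALSE)
  }
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all epochs must share the same channel and sample counts",
         call. = FALSE)
  }
  if (dims[2, 1] < 1L) stop("epochs must have at least one sample", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != length(epochs)) {
    stop("`labels` must have one entry per epoch", call. = FALSE)
  }
  stopifnot(is.numeric(sample_rate), sample_rate > 0)
  structure(
    list(subject_id = as.character(subject_id), epochs = epochs,
         labels = labels, sample_rate = sample_rate),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs[[1]])
  cat(sprintf("<epoch_set> subject %s: %d epochs of %d ch x %d samples @ %g Hz; classes: %s\n",
              x$subject_id, length(x$epochs), d[1], d[2], x$sample_rate,
              paste(sprintf("%d (n=%d)", sort(unique(x$labels)),
                            tabulate(factor(x$labels))[order(unique(x$labels))]),
                    collapse = ", ")))
  invisible(x)
}

#' Per-subject set of SPD covariance matrices
#'
#' @param subject_id Identifier.
#' @param matrices List of `ch x ch` SPD matrices.
#' @param labels Integer labels, one per matrix.
#' @param aligned Whether the set has been centroid-aligned to the identity.
#' @param alignment_space The [mean_spec()] used for alignment, or `NULL`.
#' @return An object of class `spd_set`.
#' @export
spd_set <- function(subject_id, matrices, labels, aligned = FALSE,
                    alignment_space = NULL) {
  stopifnot(is.list(matrices), length(matrices) == length(labels))
  structure(
    list(subject_id = as.character(subject_id), matrices = matrices,
         labels = as.integer(labels), aligned = isTRUE(aligned),
         alignment_space = alignment_space),
    class = "spd_set"
  )
}

#' @export
print.spd_set <- function(x, ...) {
  cat(sprintf("<spd_set> subject %s: %d matrices of %d x %d, %s\n",
              x$subject_id, length(x$matrices), nrow(x$matrices[[1]]),
              ncol(x$matrices[[1]]),
              if (x$aligned) sprintf("aligned (%s)", x$alignment_space$space)
              else "unaligned"))
  invisible(x)
}

#' Estimate per-epoch spatial covariance matrices
#'
#' Computes `M_i = X_i X_i' / T` (or the unnormalized `X_i X_i'`), then
#' applies optional trace-preserving shrinkage toward a scaled identity:
#' `M_i <- (1 - shrinkage) M_i + shrinkage * (tr(M_i)/ch) I`. Every output
#' must pass the SPD check; a rank-deficient epoch (fewer samples than
#' channels) with zero shrinkage is an error, not a silent repair.
#'
#' @param e An [epoch_set()].
#' @param normalize Divide by the number of samples `T` (default `TRUE`).
#'   Downstream centroid alignment cancels any global scale, so this choice
#'   only affects conditioning.
#' @param shrinkage Shrinkage weight in `[0, 1)`.
#' @return An unaligned [spd_set()] with the labels passed through.
#' @examples
#' e <- epoch_set("s1", list(matrix(rnorm(1000), 2)), 1L, 250)
#' s <- estimate_covariances(e)
#' s$matrices[[1]]
#' @export
estimate_covariances <- function(e, normalize = TRUE, shrinkage = 0) {
  stopifnot(inherits(e, "epoch_set"),
            is.numeric(shrinkage), shrinkage >= 0, shrinkage < 1)
  ch <- nrow(e$epochs[[1]])
  Tn <- ncol(e$epochs[[1]])
  if (Tn < ch && shrinkage == 0) {
    stop(sprintf(
      "epochs have %d samples for %d channels: covariances are rank-deficient; use shrinkage > 0",
      Tn, ch), call. = FALSE)
  }
  mats <- lapply(e$epochs, function(X) {
    M <- tcrossprod(X)
    if (normalize) M <- M / Tn
    if (shrinkage > 0) {
      M <- (1 - shrinkage) * M + shrinkage * (sum(diag(M)) / ch) * diag(ch)
    }
    M <- .symmetrize(M)
    .assert_spd_values(.sym_eig(M)$values, "covariance estimate")
    M
  })
  spd_set(e$subject_id, mats, e$labels, aligned = FALSE)
}

#' Align a subject's covariance set to the identity
#'
#' Computes the centroid `N` of all of the subject's covariance matrices in
#' the requested space (unsupervised: labels are ignored) and whitens every
#' matrix by its inverse square root, `Q_i = N^{-1/2} M_i N^{-1/2}`. After
#' Riemannian alignment the recomputed Riemannian mean of the set is the
#' identity, so subjects become directly comparable in a common tangent
#' space.
#'
#' @param s An unaligned [spd_set()].
#' @param spec A [mean_spec()] choosing the centroid space.
#' @return An aligned [spd_set()]; labels pass through untouched. Centroid
#'   non-convergence warns but still returns the whitened set.
#' @export
align_subject <- function(s, spec = mean_spec("riemannian")) {
  stopifnot(inherits(s, "spd_set"), inherits(spec, "mean_spec"))
  if (s$aligned) stop("`s` is already aligned", call. = FALSE)
  N <- mean_spd(s$matrices, spec)
  W <- sym_power(N, -0.5)
  mats <- lapply(s$matrices, function(M) .symmetrize(W %*% M %*% W))
  out <- spd_set(s$subject_id, mats, s$labels, aligned = TRUE,
                 alignment_space = spec)
  out$centroid <- N
  out
}
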