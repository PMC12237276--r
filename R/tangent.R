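#' Upper-triangular vectorization of a symmetric matrix
#'
#' Row-major upper triangle including the diagonal. Under the default
#' `sqrt2_offdiag` weighting the off-diagonal entries are multiplied by
#' `sqrt(2)` so that the Euclidean norm of the vector equals the Frobenius
#' norm of the matrix — the convention that makes tangent-vector norms agree
#' with Riemannian distances.
#'
#' @param S A symmetric numeric matrix (asymmetry beyond `1e-8` is an error).
#' @param weighting `"sqrt2_offdiag"` or `"unweighted"`.
#' @return A numeric vector of length `ch (ch + 1) / 2`.
#' @examples
#' upper_vectorize(diag(2))                        # c(1, 0, 1)
#' upper_vectorize(matrix(c(0, 1, 1, 0), 2))       # c(0, sqrt(2), 0)
#' @export
upper_vectorize <- function(S, weighting = c("sqrt2_offdiag", "unweighted")) {
  weighting <- match.arg(weighting)
  .assert_square(S, "S")
  if (max(abs(S - t(S))) > 1e-8) {
    stop("`S` must be symmetric (tolerance 1e-8)", call. = FALSE)
  }
  ch <- nrow(S)
  if (weighting == "sqrt2_offdiag") {
    W <- matrix(sqrt(2), ch, ch)
    diag(W) <- 1
    S <- S * W
  }
  # row-major upper triangle incl. diagonal
  t(S)[lower.tri(S, diag = TRUE)]
}

#' Tangent-space features for one subject
#'
#' @param subject_id Identifier.
#' @param vectors An `n x d` numeric matrix, one row per epoch.
#' @param labels Integer labels.
#' @param reference The SPD matrix used as the tangent point.
#' @param weighting Vectorization weighting used.
#' @return An object of class `tangent_features`.
#' @export
tangent_features <- function(subject_id, vectors, labels, reference,
                             weighting = "sqrt2_offdiag") {
  stopifnot(is.matrix(vectors), nrow(vectors) == length(labels))
  structure(
    list(subject_id = as.character(subject_id), vectors = vectors,
         labels = as.integer(labels), reference = reference,
         weighting = weighting),
    class = "tangent_features"
  )
}

#' @export
print.tangent_features <- function(x, ...) {
  cat(sprintf("<tangent_features> subject %s: %d epochs x %d features (%s)\n",
              x$subject_id, nrow(x$vectors), ncol(x$vectors), x$weighting))
  invisible(x)
}

#' Convert tangent features to a tibble
#'
#' One row per epoch: `subject_id`, `label`, then feature columns `f1..fd`.
#'
#' @param x A `tangent_features` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.tangent_features <- function(x, ...) {
  d <- ncol(x$vectors)
  V <- x$vectors
  colnames(V) <- paste0("f", seq_len(d))
  tibble::as_tibble(V) |>
    dplyr::mutate(subject_id = x$subject_id, label = x$labels,
                  .before = 1L)
}

#' Map an aligned SPD set to the Riemannian tangent space
#'
#' Each matrix `Q_i` becomes
#' `upper_vectorize(sym_log(Q_ref %*% Q_i %*% Q_ref))` with
#' `Q_ref = reference^{-1/2}`. The default reference is the identity: after
#' centroid alignment every subject's Riemannian mean is the identity, so the
#' identity is the one tangent point at which subjects' features are directly
#' comparable. `"set_mean"` uses the Riemannian mean of the set itself.
#'
#' @param s An [spd_set()] (a warning is raised if it is not aligned).
#' @param reference `"identity"`, `"set_mean"`, or an SPD matrix.
#' @param weighting Passed to [upper_vectorize()].
#' @return A [tangent_features()] object; feature dimension `ch(ch+1)/2`.
#' @examples
#' e <- epoch_set("s1", replicate(4, matrix(rnorm(200), 4), simplify = FALSE),
#'                rep(1:2, 2), 250)
#' f <- estimate_covariances(e) |> align_subject() |> tangent_map()
#' dim(f$vectors) # 4 x 10
#' @export
tangent_map <- function(s, reference = "identity",
                        weighting = c("sqrt2_offdiag", "unweighted")) {
  stopifnot(inherits(s, "spd_set"))
  weighting <- match.arg(weighting)
  if (!s$aligned) {
    warning("tangent_map() called on an unaligned spd_set; features of different subjects will not be comparable",
            call. = FALSE)
  }
  ch <- nrow(s$matrices[[1]])
  if (is.character(reference)) {
    reference <- match.arg(reference, c("identity", "set_mean"))
    ref_mat <- if (reference == "identity") diag(ch)
               else mean_spd(s$matrices, mean_spec("riemannian"))
  } else {
    .spd_eig(reference, "reference")
    ref_mat <- reference
  }
  identity_ref <- is.character(reference) && reference == "identity"
  Q_ref <- if (identity_ref) diag(ch) else sym_power(ref_mat, -0.5)
  vecs <- t(vapply(s$matrices, function(Q) {
    S <- if (identity_ref) sym_log(Q) else sym_log(Q_ref %*% Q %*% Q_ref)
    upper_vectorize(S, weighting)
  }, numeric(ch * (ch + 1) / 2)))
  tangent_features(s$subject_id, vecs, s$labels, ref_mat, weighting)
}
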