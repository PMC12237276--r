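#' Symmetric positive-definite matrix primitives
#'
#' Covariance matrices of multichannel EEG live on the manifold of symmetric
#' positive-definite (SPD) matrices. These primitives — matrix logarithm,
#' fractional powers, the affine-invariant Riemannian distance, and three
#' notions of mean — are the numerical substrate for per-subject alignment
#' and tangent-space feature extraction.
#'
#' All eigendecompositions symmetrize their input as `(M + t(M)) / 2` first
#' to suppress asymmetric floating-point residue. Positivity is enforced
#' relative to the largest eigenvalue: an input whose smallest eigenvalue is
#' at or below `1e-10 * max(eigenvalue)` is rejected, never silently
#' repaired — regularization is the caller's job (see the `shrinkage`
#' argument of [estimate_covariances()]).
#'
#' @name spd-core
NULL

# relative floor under which an eigenvalue counts as a positivity violation
.eps_spd_ratio <- 1e-10

.symmetrize <- function(M) (M + t(M)) / 2

# eigendecomposition of the symmetrized input; the workhorse of this file
.sym_eig <- function(M) {
  eigen(.symmetrize(M), symmetric = TRUE)
}

.assert_square <- function(M, arg = "M") {
  if (!is.matrix(M) || nrow(M) != ncol(M) || !is.numeric(M)) {
    stop(sprintf("`%s` must be a square numeric matrix", arg), call. = FALSE)
  }
  invisible(M)
}

# error (never repair) when an eigenvalue sits at or below the relative floor
.assert_spd_values <- function(values, arg = "M") {
  floor_val <- .eps_spd_ratio * max(values, 0)
  bad <- which(values <= floor_val)
  if (length(bad) > 0L) {
    stop(sprintf(
      "`%s` is not symmetric positive-definite: eigenvalue %d is %.6g (floor %.6g)",
      arg, bad[length(bad)], values[bad[length(bad)]], floor_val
    ), call. = FALSE)
  }
  invisible(values)
}

#' Test a matrix for symmetric positive-definiteness
#'
#' @param M A square numeric matrix.
#' @param arg Name used in the error message.
#' @return Invisibly, the eigendecomposition (as from [base::eigen()]) of the
#'   symmetrized matrix; errors if any eigenvalue is at or below
#'   `1e-10 * largest eigenvalue`.
#' @keywords internal
.spd_eig <- function(M, arg = "M") {
  .assert_square(M, arg)
  e <- .sym_eig(M)
  .assert_spd_values(e$values, arg)
  e
}

#' Check whether a matrix is SPD
#'
#' @param M A square numeric matrix.
#' @return `TRUE` if `M` (after symmetrization) has all eigenvalues above the
#'   relative positivity floor, else `FALSE`.
#' @examples
#' is_spd(diag(2))
#' is_spd(matrix(c(1, 2, 2, 1), 2)) # indefinite
#' @export
is_spd <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || !is.numeric(M)) return(FALSE)
  v <- .sym_eig(M)$values
  all(v > .eps_spd_ratio * max(v, 0))
}

#' Matrix logarithm of an SPD matrix
#'
#' `sym_log(M)` is `U diag(log lambda) U'` from the eigendecomposition of the
#' symmetrized `M`; `sym_exp(S)` is its inverse, defined for any symmetric
#' matrix and always returning an SPD matrix.
#'
#' @param M An SPD matrix.
#' @param S A symmetric matrix.
#' @return A symmetric matrix (`sym_log`) or SPD matrix (`sym_exp`).
#' @examples
#' sym_log(diag(c(exp(1), exp(2)))) # diag(1, 2)
#' sym_exp(sym_log(diag(2) + 0.5))
#' @export
sym_log <- function(M) {
  e <- .spd_eig(M, "M")
  .symmetrize(e$vectors %*% (log(e$values) * t(e$vectors)))
}

#' @rdname sym_log
#' @export
sym_exp <- function(S) {
  .assert_square(S, "S")
  e <- .sym_eig(S)
  .symmetrize(e$vectors %*% (exp(e$values) * t(e$vectors)))
}

#' Fractional power of an SPD matrix
#'
#' `U diag(lambda^p) U'`. For `p = -1/2` this is the whitening transform used
#' by centroid alignment: `sym_power(N, -1/2) %*% N %*% sym_power(N, -1/2)`
#' is the identity.
#'
#' @param M An SPD matrix.
#' @param p A nonzero real exponent.
#' @return An SPD matrix.
#' @examples
#' sym_power(diag(c(4, 9)), 0.5) # diag(2, 3)
#' @export
sym_power <- function(M, p) {
  stopifnot(is.numeric(p), length(p) == 1L, p != 0)
  e <- .spd_eig(M, "M")
  .symmetrize(e$vectors %*% (e$values^p * t(e$vectors)))
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' The geodesic distance `sqrt(sum(log(lambda_i)^2))` where `lambda_i` are
#' the generalized eigenvalues of the pair — equivalently the Frobenius norm
#' of `log(M1^{-1/2} M2 M1^{-1/2})`. It is symmetric in its arguments, zero
#' iff the matrices are equal, and invariant under congruence
#' `M -> A M A'` by any invertible `A`.
#'
#' @param M1,M2 SPD matrices of the same dimension.
#' @return A nonnegative scalar.
#' @examples
#' riemannian_distance(diag(2), diag(c(exp(2), exp(2)))) # 2 * sqrt(2)
#' @export
riemannian_distance <- function(M1, M2) {
  .assert_square(M1, "M1")
  .assert_square(M2, "M2")
  if (!all(dim(M1) == dim(M2))) {
    stop("`M1` and `M2` must have the same dimension", call. = FALSE)
  }
  W <- sym_power(M1, -0.5)
  e <- .spd_eig(W %*% .symmetrize(M2) %*% W, "M2")
  sqrt(sum(log(e$values)^2))
}

#' Specify a matrix-mean space
#'
#' Bundles the choice of mean (Riemannian/Karcher, log-Euclidean, or
#' Euclidean) with the convergence controls of the Karcher fixed-point
#' iteration.
#'
#' @param space One of `"riemannian"`, `"log_euclidean"`, `"euclidean"`.
#' @param tol Convergence tolerance on the Frobenius norm of the mean tangent
#'   update (Riemannian mean only).
#' @param max_iter Iteration cap for the Karcher fixed point.
#' @return An object of class `mean_spec`.
#' @examples
#' mean_spec("riemannian")
#' @export
mean_spec <- function(space = c("riemannian", "log_euclidean", "euclidean"),
                      tol = 1e-8, max_iter = 50L) {
  space <- match.arg(space)
  stopifnot(is.numeric(tol), tol > 0, max_iter >= 1)
  structure(list(space = space, tol = tol, max_iter = as.integer(max_iter)),
            class = "mean_spec")
}

#' @export
print.mean_spec <- function(x, ...) {
  cat(sprintf("<mean_spec> space = %s, tol = %g, max_iter = %d\n",
              x$space, x$tol, x$max_iter))
  invisible(x)
}

#' Mean of a set of SPD matrices
#'
#' Three notions of centroid: the arithmetic (Euclidean) mean; the
#' log-Euclidean mean `exp(mean(log(M_i)))`; and the Riemannian (Karcher)
#' mean, the minimizer of the sum of squared Riemannian distances, computed
#' by the standard fixed-point iteration
#' `N <- N^{1/2} exp(mean_i log(N^{-1/2} M_i N^{-1/2})) N^{1/2}`
#' initialized at the arithmetic mean.
#'
#' @param matrices A non-empty list of SPD matrices of common dimension.
#' @param spec A [mean_spec()].
#' @return An SPD matrix with attributes `converged` (logical) and
#'   `iterations` (integer; 0 for the closed-form means). Non-convergence
#'   within `max_iter` raises a warning and returns the last iterate.
#' @examples
#' mean_spd(list(diag(c(4, 4)), diag(c(1, 1))), mean_spec("riemannian"))
#' @export
mean_spd <- function(matrices, spec = mean_spec()) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("`matrices` must be a non-empty list of SPD matrices", call. = FALSE)
  }
  dims <- vapply(matrices, function(m) dim(m)[1L], integer(1))
  if (length(unique(dims)) != 1L ||
      any(vapply(matrices, function(m) nrow(m) != ncol(m), logical(1)))) {
    stop("all matrices must be square with a common dimension", call. = FALSE)
  }
  stopifnot(inherits(spec, "mean_spec"))
  n <- length(matrices)
  arith <- .symmetrize(Reduce(`+`, matrices) / n)

  if (spec$space == "euclidean") {
    return(structure(arith, converged = TRUE, iterations = 0L))
  }
  if (spec$space == "log_euclidean") {
    logs <- lapply(matrices, sym_log)
    out <- sym_exp(Reduce(`+`, logs) / n)
    return(structure(out, converged = TRUE, iterations = 0L))
  }

  # Karcher fixed point
  N <- arith
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(spec$max_iter)) {
    W <- sym_power(N, -0.5)
    tangent <- Reduce(`+`, lapply(matrices, function(M) {
      sym_log(W %*% .symmetrize(M) %*% W)
    })) / n
    step_norm <- sqrt(sum(tangent^2))
    if (step_norm < spec$tol) {
      converged <- TRUE
      break
    }
    Nh <- sym_power(N, 0.5)
    N <- .symmetrize(Nh %*% sym_exp(tangent) %*% Nh)
  }
  if (!converged) {
    warning(sprintf(
      "Karcher mean did not converge in %d iterations (last step norm %.3g)",
      spec$max_iter, step_norm
    ), call. = FALSE)
  }
  structure(N, converged = converged, iterations = iter)
}
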