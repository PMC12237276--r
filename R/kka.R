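#' Kernel specification
#'
#' @param family `"rbf"` (`exp(-gamma ||x - y||^2)`), `"linear"` (`x'y`), or
#'   `"laplacian"` (`exp(-gamma ||x - y||_1)`).
#' @param gamma Positive bandwidth; ignored for the linear kernel. `NULL`
#'   defers to the data-driven default `1 / (d * var(X))` computed when the
#'   kernel is first evaluated (see [kernel_matrix()]).
#' @return An object of class `kernel_spec`.
#' @examples
#' kernel_spec("rbf", gamma = 0.5)
#' @export
kernel_spec <- function(family = c("rbf", "linear", "laplacian"), gamma = NULL) {
  family <- match.arg(family)
  if (!is.null(gamma)) {
    stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  }
  structure(list(family = family, gamma = gamma), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("<kernel_spec> %s%s\n", x$family,
              if (x$family == "linear") ""
              else sprintf(", gamma = %s",
                           if (is.null(x$gamma)) "auto" else format(x$gamma))))
  invisible(x)
}

# data-driven bandwidth: 1 / (feature dimension * overall feature variance)
.default_gamma <- function(X) {
  v <- stats::var(as.vector(X))
  if (!is.finite(v) || v <= 0) v <- 1
  1 / (ncol(X) * v)
}

#' Evaluate a kernel matrix between two feature sets
#'
#' Entry `(i, j)` is `k(x_i, y_j)` for rows `x_i` of `X` and `y_j` of `Y`.
#' The Laplacian kernel uses the L1 distance. With `Y` missing the Gram
#' matrix of `X` is returned (symmetric, PSD).
#'
#' @param X,Y Numeric matrices with one feature row per epoch and a common
#'   number of columns.
#' @param spec A [kernel_spec()]. A `NULL` gamma is resolved against `X`.
#' @return A `nrow(X) x nrow(Y)` numeric matrix.
#' @examples
#' kernel_matrix(diag(2), spec = kernel_spec("rbf", gamma = 1))
#' @export
kernel_matrix <- function(X, Y = X, spec = kernel_spec("rbf")) {
  stopifnot(is.matrix(X), is.matrix(Y), inherits(spec, "kernel_spec"))
  if (ncol(X) != ncol(Y)) {
    stop("`X` and `Y` must have the same feature dimension", call. = FALSE)
  }
  if (spec$family == "linear") return(tcrossprod(X, Y))
  gamma <- if (is.null(spec$gamma)) .default_gamma(X) else spec$gamma
  if (spec$family == "rbf") {
    d2 <- outer(rowSums(X^2), rowSums(Y^2), `+`) - 2 * tcrossprod(X, Y)
    d2[d2 < 0] <- 0
    K <- exp(-gamma * d2)
  } else { # laplacian, L1 distance
    d1 <- matrix(0, nrow(X), nrow(Y))
    for (j in seq_len(ncol(X))) {
      d1 <- d1 + abs(outer(X[, j], Y[, j], `-`))
    }
    K <- exp(-gamma * d1)
  }
  K
}

#' Retained eigen-system of the target kernel matrix
#'
#' Eigendecomposes the (symmetrized) target Gram matrix and keeps the top
#' top eigenpairs (at most `r_max` of them) whose eigenvalues are at least
#' `floor_ratio * lambda_1`; near-zero eigenvalues must be dropped before
#' the Nystrom step divides by them. Eigenvector signs are fixed so the
#' first nonzero component of each column is positive, making the
#' decomposition reproducible across platforms.
#'
#' @param K_t Symmetric PSD target kernel matrix (`n_t x n_t`).
#' @param r_max Maximum retained rank (default `n_t`).
#' @param floor_ratio Relative eigenvalue floor (default `1e-8`).
#' @return An object of class `eigen_system` with fields `phi_t`
#'   (`n_t x r`, orthonormal columns), `delta_t` (positive, descending),
#'   `r`, and a `phi_s_tilde` slot filled by [nystrom_extrapolate()].
#' @export
target_eigensystem <- function(K_t, r_max = NULL, floor_ratio = 1e-8) {
  .assert_square(K_t, "K_t")
  e <- .sym_eig(K_t)                      # descending eigenvalues
  if (is.null(r_max)) r_max <- nrow(K_t)
  stopifnot(r_max >= 1, floor_ratio >= 0)
  keep <- which(e$values >= floor_ratio * e$values[1] & e$values > 0)
  if (length(keep) == 0L) {
    stop("degenerate kernel: all eigenvalues fall below the retention floor",
         call. = FALSE)
  }
  r <- as.integer(min(length(keep), r_max))
  phi <- e$vectors[, seq_len(r), drop = FALSE]
  # deterministic sign convention: first nonzero component positive
  for (j in seq_len(r)) {
    col <- phi[, j]
    nz <- which(abs(col) > 1e-12)
    if (length(nz) > 0L && col[nz[1]] < 0) phi[, j] <- -col
  }
  structure(
    list(phi_t = phi, delta_t = e$values[seq_len(r)], r = r,
         phi_s_tilde = NULL),
    class = "eigen_system"
  )
}

#' @export
print.eigen_system <- function(x, ...) {
  cat(sprintf("<eigen_system> rank %d, eigenvalues [%.4g .. %.4g]%s\n",
              x$r, x$delta_t[1], x$delta_t[x$r],
              if (is.null(x$phi_s_tilde)) "" else ", source extrapolation filled"))
  invisible(x)
}

#' Nystrom extrapolation of the target eigen-system to the source field
#'
#' Fills `phi_s_tilde = K_cross %*% phi_t %*% diag(1 / delta_t)`: the
#' out-of-sample extension of the target kernel's eigenvectors to the source
#' epochs via the cross kernel. The extrapolated columns are deliberately
#' not renormalized — the Nystrom formula does not produce orthonormal
#' columns and the subsequent spectrum fit depends on their true scale.
#'
#' @param K_cross `n_s x n_t` kernel matrix between source rows and target
#'   rows.
#' @param es An `eigen_system` from [target_eigensystem()].
#' @return The `eigen_system` with `phi_s_tilde` filled (`n_s x r`).
#' @export
nystrom_extrapolate <- function(K_cross, es) {
  stopifnot(inherits(es, "eigen_system"), is.matrix(K_cross))
  if (ncol(K_cross) != nrow(es$phi_t)) {
    stop("`K_cross` must have one column per target epoch", call. = FALSE)
  }
  es$phi_s_tilde <- K_cross %*% es$phi_t %*% diag(1 / es$delta_t, es$r)
  es
}

# Equivalent nonnegative least-squares form of the spectrum QP, used when
# the active-set QP solver stalls on ill-conditioned instances. With
# t_i = sigma_i - mu * sigma_{i+1} (t_r = sigma_r), the power-law cone maps
# exactly to t >= 0 via sigma = M t, M upper triangular with powers of mu;
# the objective becomes || R M t - R^{-T} h ||^2 for any square root
# G = R'R, solved by Lawson-Hanson NNLS with column equilibration.
.spectrum_nnls <- function(G, h, mu, r) {
  M <- diag(r)
  if (r > 1L) {
    for (i in seq_len(r - 1L)) {
      M[i, (i + 1L):r] <- mu^(seq_len(r - i))
    }
  }
  R <- tryCatch(chol(G), error = function(e) {
    ev <- .sym_eig(G)
    sqrt(pmax(ev$values, 1e-12)) * t(ev$vectors)
  })
  C <- R %*% M
  d <- drop(solve(t(R), h))
  cn <- sqrt(colSums(C^2))
  cn[cn == 0] <- 1
  fit <- pracma::lsqnonneg(sweep(C, 2, cn, "/"), d)
  drop(M %*% (fit$x / cn))
}

#' Learn the adapted spectrum by quadratic programming
#'
#' Minimizes the reconstruction error of the actual source kernel,
#' `|| phi_s_tilde diag(sigma) phi_s_tilde' - K_s ||_F^2`, over spectra
#' `sigma` constrained to decay at least geometrically:
#' `sigma_i >= mu * sigma_{i+1}` and `sigma_i >= 0`, with damping factor
#' `mu >= 1`. The objective expands exactly to the quadratic form
#' `sigma' G sigma - 2 h' sigma` with `G_ij = (a_i' a_j)^2` and
#' `h_i = a_i' K_s a_i` (`a_i` the i-th extrapolated eigenvector); `G` is
#' symmetrized and ridge-stabilized by `1e-10 I` before the solve.
#'
#' @param es An `eigen_system` with `phi_s_tilde` filled.
#' @param K_s Symmetric PSD source kernel matrix.
#' @param mu Damping factor, `>= 1`.
#' @return Numeric vector `delta_star` of length `es$r` satisfying the
#'   power-law cone (feasibility tolerance `1e-8`).
#' @export
solve_spectrum_qp <- function(es, K_s, mu = 1.5) {
  stopifnot(inherits(es, "eigen_system"), !is.null(es$phi_s_tilde),
            is.numeric(mu), mu >= 1)
  .assert_square(K_s, "K_s")
  A <- es$phi_s_tilde
  r <- es$r
  # G_ij = (a_i' a_j)^2, h_i = a_i' K_s a_i
  G <- crossprod(A)^2
  h <- colSums(A * (K_s %*% A))
  G <- (G + t(G)) / 2 + diag(1e-10, r)

  if (r == 1L) {
    return(max(0, h / G[1, 1]))
  }
  # constraints: sigma_i - mu sigma_{i+1} >= 0 (r-1 rows), sigma_i >= 0 (r rows)
  C_decay <- matrix(0, r - 1L, r)
  for (i in seq_len(r - 1L)) {
    C_decay[i, i] <- 1
    C_decay[i, i + 1L] <- -mu
  }
  Cmat <- rbind(C_decay, diag(r))
  # equilibrate: sigma = d * u with d_i = 1/sqrt(G_ii). The columns of
  # phi_s_tilde scale like 1/delta_t, so G spans many orders of magnitude;
  # the diagonal change of variables keeps the solver stable and the
  # homogeneous constraint cone maps linearly.
  d <- 1 / sqrt(diag(G))
  Gu <- G * tcrossprod(d)
  Gu <- (Gu + t(Gu)) / 2
  hu <- h * d
  sigma <- tryCatch({
    sol <- quadprog::solve.QP(Dmat = 2 * Gu, dvec = 2 * hu,
                              Amat = t(Cmat * rep(d, each = nrow(Cmat))),
                              bvec = rep(0, 2L * r - 1L))
    sol$solution * d
  }, error = function(e) .spectrum_nnls(G, h, mu, r))
  sigma[sigma < 0 & sigma > -1e-8] <- 0
  if (any(sigma < 0) || any(sigma[-r] - mu * sigma[-1] < -1e-8)) {
    stop("quadratic program returned an infeasible spectrum", call. = FALSE)
  }
  sigma
}

#' Assemble the reconstructed and field-agnostic kernel matrices
#'
#' `K_s_tilde = phi_s_tilde diag(delta_star) phi_s_tilde'` and the
#' field-agnostic block kernel
#' `K_union = Phi diag(delta_star) Phi'` with `Phi` the extrapolated source
#' eigenvectors stacked above the target eigenvectors. `K_union` is
#' symmetric PSD by construction and its top-left block equals `K_s_tilde`
#' exactly.
#'
#' @param es An `eigen_system` with `phi_s_tilde` filled.
#' @param delta_star Spectrum from [solve_spectrum_qp()].
#' @return An object of class `kernel_bundle` with `K_s_tilde`, `K_union`,
#'   `delta_star`, `n_s`, `n_t`.
#' @export
build_union_kernel <- function(es, delta_star) {
  stopifnot(inherits(es, "eigen_system"), !is.null(es$phi_s_tilde),
            length(delta_star) == es$r, all(delta_star >= -1e-8))
  Phi <- rbind(es$phi_s_tilde, es$phi_t)
  D <- diag(delta_star, es$r)
  K_union <- Phi %*% D %*% t(Phi)
  K_union <- (K_union + t(K_union)) / 2
  n_s <- nrow(es$phi_s_tilde)
  structure(
    list(K_s_tilde = K_union[seq_len(n_s), seq_len(n_s), drop = FALSE],
         K_union = K_union, delta_star = delta_star,
         n_s = n_s, n_t = nrow(es$phi_t)),
    class = "kernel_bundle"
  )
}

#' @export
print.kernel_bundle <- function(x, ...) {
  cat(sprintf("<kernel_bundle> n_s = %d, n_t = %d, rank %d%s\n",
              x$n_s, x$n_t, length(x$delta_star),
              if (is.null(x$K_s)) "" else " (with raw kernels)"))
  invisible(x)
}

#' Knowledge kernel adaptation between a source and a target feature set
#'
#' Runs the full chain: raw kernels `K_s`, `K_t`, `K_cross`; target
#' eigendecomposition; Nystrom extrapolation to the source; spectrum QP under
#' the power-law constraint; and assembly of the field-agnostic union kernel.
#'
#' @param X_s,X_t Source and target feature matrices (rows = epochs).
#' @param kernel A [kernel_spec()]; a `NULL` gamma is resolved once on the
#'   pooled source and target rows so all three kernels share a bandwidth.
#' @param mu Damping factor for the spectrum QP.
#' @param r_max Maximum retained rank (default `min(n_s, n_t)`).
#' @param floor_ratio Relative eigenvalue retention floor.
#' @return A `kernel_bundle` additionally carrying `K_s`, `K_t`, `K_cross`,
#'   the `eigen_system`, `kernel` and `mu`.
#' @examples
#' X <- matrix(rnorm(40), 10)
#' b <- kka(X, X, kernel_spec("rbf", 0.5), mu = 1)
#' max(abs(b$K_union[1:10, 1:10] - b$K_t)) # identity case: ~0
#' @export
kka <- function(X_s, X_t, kernel = kernel_spec("rbf"), mu = 1.5,
                r_max = NULL, floor_ratio = 1e-8) {
  stopifnot(is.matrix(X_s), is.matrix(X_t), nrow(X_t) >= 1)
  if (is.null(kernel$gamma) && kernel$family != "linear") {
    kernel$gamma <- .default_gamma(rbind(X_s, X_t))
  }
  K_s <- kernel_matrix(X_s, X_s, kernel)
  K_t <- kernel_matrix(X_t, X_t, kernel)
  K_cross <- kernel_matrix(X_s, X_t, kernel)
  if (is.null(r_max)) r_max <- min(nrow(X_s), nrow(X_t))
  es <- target_eigensystem(K_t, r_max = r_max, floor_ratio = floor_ratio)
  es <- nystrom_extrapolate(K_cross, es)
  delta_star <- solve_spectrum_qp(es, K_s, mu = mu)
  bundle <- build_union_kernel(es, delta_star)
  bundle$K_s <- K_s
  bundle$K_t <- K_t
  bundle$K_cross <- K_cross
  bundle$eigen_system <- es
  bundle$kernel <- kernel
  bundle$mu <- mu
  bundle
}
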