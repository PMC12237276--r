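test_that("kernel matrices match direct evaluations", {
  X <- matrix(c(0, 0, 1, 1), 2, byrow = TRUE)
  K <- kernel_matrix(X, X, kernel_spec("rbf", gamma = 1))
  expect_equal(diag(K), c(1, 1))
  expect_equal(K[1, 2], exp(-2))
  expect_equal(kernel_matrix(diag(2), diag(2), kernel_spec("linear")), diag(2))
  Kl <- kernel_matrix(X, X, kernel_spec("laplacian", gamma = 0.5))
  expect_equal(Kl[1, 2], exp(-0.5 * 2)) # L1 distance 2
  expect_error(kernel_matrix(X, matrix(0, 1, 3)), "feature dimension")
})

test_that("target eigensystem retains, floors, and reconstructs", {
  es <- target_eigensystem(diag(4), r_max = 4)
  expect_equal(es$delta_t, rep(1, 4))
  expect_lt(max(abs(crossprod(es$phi_t) - diag(4))), 1e-8)

  v <- c(1, 2, 3)
  es1 <- target_eigensystem(tcrossprod(v), r_max = 3)
  expect_identical(es1$r, 1L)
  expect_equal(es1$delta_t, sum(v^2))

  K <- farka:::.with_seed(8, {
    X <- matrix(rnorm(30), 6)
    tcrossprod(X)
  })
  es2 <- target_eigensystem(K, r_max = 6, floor_ratio = 0)
  expect_lt(max(abs(es2$phi_t %*% diag(es2$delta_t) %*% t(es2$phi_t) - K)),
            1e-8)
  expect_error(target_eigensystem(matrix(0, 3, 3)), "degenerate")
})

test_that("nystrom extrapolation reproduces eigenvectors in the identity case", {
  X <- blob_features(6, d = 3, seed = 2)$vectors
  K <- kernel_matrix(X, X, kernel_spec("rbf", 0.3))
  es <- target_eigensystem(K)
  es2 <- nystrom_extrapolate(K, es) # K_cross = K_t
  expect_lt(max(abs(es2$phi_s_tilde - es$phi_t)), 1e-8)

  # empty source: degenerate shape, no error
  es3 <- nystrom_extrapolate(matrix(0, 0, nrow(K)), es)
  expect_identical(dim(es3$phi_s_tilde), c(0L, es$r))

  # genuinely out-of-sample columns are not orthonormal and must stay so
  Y <- blob_features(6, d = 3, seed = 3)$vectors * 1.5
  es4 <- nystrom_extrapolate(kernel_matrix(Y, X, kernel_spec("rbf", 0.3)), es)
  gram <- crossprod(es4$phi_s_tilde)
  expect_gt(max(abs(gram - diag(es$r))), 1e-3)
})

test_that("the spectrum QP recovers the target spectrum when source = target and mu = 1", {
  X <- blob_features(8, d = 4, seed = 4)$vectors
  K <- kernel_matrix(X, X, kernel_spec("rbf", 0.2))
  es <- nystrom_extrapolate(K, target_eigensystem(K))
  ds <- solve_spectrum_qp(es, K, mu = 1)
  expect_equal(ds, es$delta_t, tolerance = 1e-6)

  # zero source kernel: objective minimized at the origin
  expect_lt(max(abs(solve_spectrum_qp(es, matrix(0, nrow(K), ncol(K)), 1.5))),
            1e-6)
})

test_that("the spectrum QP matches the brute-force grid oracle at r = 2 and 3", {
  for (r in 2:3) {
    for (seed in 1:20) {
      mu <- c(1, 1.5, 2.5)[(seed %% 3) + 1]
      dat <- farka:::.with_seed(seed * 7 + r, {
        X_t <- matrix(rnorm(5 * 3), 5)
        X_s <- matrix(rnorm(6 * 3), 6)
        list(X_t = X_t, X_s = X_s)
      })
      ks <- kernel_spec("rbf", 0.4)
      K_t <- kernel_matrix(dat$X_t, dat$X_t, ks)
      K_s <- kernel_matrix(dat$X_s, dat$X_s, ks)
      es <- target_eigensystem(K_t, r_max = r)
      es <- nystrom_extrapolate(kernel_matrix(dat$X_s, dat$X_t, ks), es)
      sol <- solve_spectrum_qp(es, K_s, mu = mu)
      # feasibility
      expect_true(all(sol >= -1e-8))
      if (r > 1) expect_true(all(sol[-r] - mu * sol[-1] >= -1e-8))
      # oracle comparison: solution within grid resolution, objective no worse
      gh <- qp_inputs(es, K_s)
      oracle <- grid_spectrum_oracle(gh$G, gh$h, mu,
                                     n_grid = if (r == 2) 120 else 50)
      # axis-aligned grids resolve the cone face sigma_1 = mu sigma_2 only
      # to within a (1 + mu) multiple of the cell size
      expect_lt(max(abs(sol - oracle$solution)),
                2 * (1 + mu) * oracle$resolution)
      obj <- function(s) drop(t(s) %*% gh$G %*% s - 2 * sum(gh$h * s))
      expect_lte(obj(sol), oracle$objective + 1e-8)
    }
  }
})

test_that("the QP objective is non-decreasing in the damping factor", {
  X_t <- blob_features(8, d = 3, seed = 11)$vectors
  X_s <- blob_features(10, d = 3, seed = 12)$vectors
  ks <- kernel_spec("rbf", 0.3)
  K_t <- kernel_matrix(X_t, X_t, ks)
  K_s <- kernel_matrix(X_s, X_s, ks)
  es <- nystrom_extrapolate(kernel_matrix(X_s, X_t, ks),
                            target_eigensystem(K_t))
  gh <- qp_inputs(es, K_s)
  obj <- function(s) drop(t(s) %*% gh$G %*% s - 2 * sum(gh$h * s))
  vals <- vapply(c(1, 1.5, 2, 3, 5), function(mu) {
    obj(solve_spectrum_qp(es, K_s, mu))
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-6))
})

test_that("union kernel blocks, PSD-ness, and permutation equivariance hold", {
  X <- blob_features(8, d = 4, seed = 21)$vectors
  b <- kka(X, X, kernel_spec("rbf", 0.2), mu = 1)
  n <- nrow(X)
  for (blk in list(b$K_union[1:n, 1:n], b$K_union[1:n, n + 1:n],
                   b$K_union[n + 1:n, 1:n], b$K_union[n + 1:n, n + 1:n])) {
    expect_lt(max(abs(blk - b$K_t)), 1e-6)
  }

  # zero spectrum gives the zero kernel
  es <- b$eigen_system
  z <- build_union_kernel(es, rep(0, es$r))
  expect_equal(max(abs(z$K_union)), 0)

  # PSD by construction and top-left block is the reconstruction
  Y <- blob_features(6, d = 4, seed = 22)$vectors
  ns <- nrow(Y)
  b2 <- kka(Y, X, kernel_spec("rbf", 0.2), mu = 1.5)
  expect_gte(min(eigen(b2$K_union, symmetric = TRUE)$values), -1e-10)
  expect_identical(b2$K_union[seq_len(ns), seq_len(ns)], b2$K_s_tilde)

  # permuting source rows permutes the source block identically
  perm <- farka:::.with_seed(9, sample(ns))
  b3 <- kka(Y[perm, ], X, kernel_spec("rbf", 0.2), mu = 1.5)
  expect_lt(max(abs(b3$K_s_tilde - b2$K_s_tilde[perm, perm])), 1e-8)
})
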