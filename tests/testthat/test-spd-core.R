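test_that("sym_log, sym_exp and sym_power agree with closed forms on diagonals", {
  expect_equal(sym_log(diag(2)), matrix(0, 2, 2))
  expect_equal(sym_log(diag(c(exp(1), exp(2)))), diag(c(1, 2)))
  expect_equal(sym_power(diag(2), -0.5), diag(2))
  expect_equal(sym_power(diag(c(4, 9)), 0.5), diag(c(2, 3)))
})

test_that("log/exp round-trip and whitening hold on random SPD matrices", {
  for (seed in 1:5) {
    A <- rand_spd(5, seed = seed)
    expect_lt(max(abs(sym_exp(sym_log(A)) - A)), 1e-8)
    W <- sym_power(A, -0.5)
    expect_lt(max(abs(W %*% A %*% W - diag(5))), 1e-8)
  }
})

test_that("non-SPD inputs are rejected with the offending eigenvalue named", {
  M <- matrix(c(1, 2, 2, 1), 2) # eigenvalues 3, -1
  expect_error(sym_log(M), "not symmetric positive-definite.*-1")
  expect_error(sym_power(M, 0.5), "not symmetric positive-definite")
  expect_error(riemannian_distance(M, diag(2)), "not symmetric positive-definite")
  expect_error(riemannian_distance(diag(2), diag(3)), "same dimension")
})

test_that("riemannian distance matches closed forms", {
  M <- rand_spd(4, seed = 3)
  expect_equal(riemannian_distance(M, M), 0)
  expect_equal(riemannian_distance(diag(2), diag(c(exp(2), exp(2)))),
               2 * sqrt(2))
  # equals Frobenius norm of log of the whitened matrix
  M2 <- rand_spd(4, seed = 4)
  W <- sym_power(M, -0.5)
  expect_equal(riemannian_distance(M, M2),
               sqrt(sum(sym_log(W %*% M2 %*% W)^2)),
               tolerance = 1e-10)
})

test_that("riemannian distance is a metric with congruence invariance", {
  for (seed in 1:20) {
    mats <- rand_spd_list(3, 4, seed = seed)
    d12 <- riemannian_distance(mats[[1]], mats[[2]])
    d13 <- riemannian_distance(mats[[1]], mats[[3]])
    d23 <- riemannian_distance(mats[[2]], mats[[3]])
    expect_gte(d12, 0)
    # symmetry
    expect_equal(d12, riemannian_distance(mats[[2]], mats[[1]]),
                 tolerance = 1e-8)
    # triangle inequality
    expect_lte(d12, d13 + d23 + 1e-8)
    # congruence invariance
    A <- rand_invertible(4, seed = seed + 100)
    expect_equal(riemannian_distance(A %*% mats[[1]] %*% t(A),
                                     A %*% mats[[2]] %*% t(A)),
                 d12, tolerance = 1e-8)
  }
})

test_that("the three means agree with closed forms in simple cases", {
  M <- rand_spd(3, seed = 7)
  for (space in c("riemannian", "log_euclidean", "euclidean")) {
    expect_equal(unclass(mean_spd(list(M), mean_spec(space)))[1:3, 1:3],
                 M, tolerance = 1e-10, ignore_attr = TRUE)
  }
  # commuting case: geometric mean
  g <- mean_spd(list(diag(c(4, 4)), diag(c(1, 1))), mean_spec("riemannian"))
  expect_equal(matrix(g, 2), diag(c(2, 2)), tolerance = 1e-7)
  # euclidean differs on the same pair
  e <- mean_spd(list(diag(c(4, 4)), diag(c(1, 1))), mean_spec("euclidean"))
  expect_equal(matrix(e, 2), diag(c(2.5, 2.5)))
})

test_that("the karcher mean satisfies first-order optimality", {
  for (seed in 1:10) {
    mats <- rand_spd_list(5, 3, seed = seed)
    N <- mean_spd(mats, mean_spec("riemannian"))
    expect_true(attr(N, "converged"))
    W <- sym_power(N, -0.5)
    grad <- Reduce(`+`, lapply(mats, function(M) sym_log(W %*% M %*% W)))
    expect_lt(max(abs(grad)), 1e-6)
  }
})

test_that("karcher mean is congruence-equivariant and all means scale", {
  mats <- rand_spd_list(4, 4, seed = 11)
  A <- rand_invertible(4, seed = 12)
  N <- mean_spd(mats, mean_spec("riemannian"))
  N_A <- mean_spd(lapply(mats, function(M) A %*% M %*% t(A)),
                  mean_spec("riemannian"))
  expect_lt(max(abs(N_A - A %*% N %*% t(A))), 1e-6)
  for (space in c("riemannian", "log_euclidean", "euclidean")) {
    N1 <- mean_spd(mats, mean_spec(space))
    N3 <- mean_spd(lapply(mats, function(M) 3 * M), mean_spec(space))
    expect_equal(matrix(N3, 4), 3 * matrix(N1, 4), tolerance = 1e-7)
  }
})

test_that("log-euclidean equals riemannian on commuting sets, euclidean differs", {
  mats <- lapply(list(c(1, 4), c(2, 8), c(0.5, 2)), diag)
  r <- matrix(mean_spd(mats, mean_spec("riemannian")), 2)
  l <- matrix(mean_spd(mats, mean_spec("log_euclidean")), 2)
  e <- matrix(mean_spd(mats, mean_spec("euclidean")), 2)
  expect_equal(r, l, tolerance = 1e-7)
  expect_gt(max(abs(e - r)), 0.01)
})

test_that("mean_spd validates its inputs", {
  expect_error(mean_spd(list()), "non-empty")
  expect_error(mean_spd(list(diag(2), diag(3))), "common dimension")
})
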