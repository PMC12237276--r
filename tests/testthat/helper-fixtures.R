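# deterministic random SPD matrices and small synthetic objects used
# throughout the suite

rand_spd <- function(ch, seed = NULL, jitter = 0.1) {
  draw <- function() {
    X <- matrix(rnorm(ch * (ch + 2)), ch)
    tcrossprod(X) / (ch + 2) + jitter * diag(ch)
  }
  if (is.null(seed)) draw() else farka:::.with_seed(seed, draw())
}

rand_spd_list <- function(n, ch, seed) {
  farka:::.with_seed(seed, replicate(n, rand_spd(ch), simplify = FALSE))
}

rand_invertible <- function(ch, seed = NULL) {
  draw <- function() {
    repeat {
      A <- matrix(rnorm(ch * ch), ch)
      if (abs(det(A)) > 1e-3) return(A)
    }
  }
  if (is.null(seed)) draw() else farka:::.with_seed(seed, draw())
}

# two well-separated Gaussian blobs as tangent-feature stand-ins
blob_features <- function(n_per_class = 10, d = 4, sep = 2, seed = 1,
                          subject_id = "blob") {
  farka:::.with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * d, -sep / 2), n_per_class),
               matrix(rnorm(n_per_class * d, sep / 2), n_per_class))
    tangent_features(subject_id, X, rep(1:2, each = n_per_class), diag(d))
  })
}

small_population <- function(seed = 1, n_subjects = 3, n_epochs_per_class = 10,
                             ch = 4, n_samples = 128, ...) {
  make_population(population_spec(
    n_subjects = n_subjects, n_epochs_per_class = n_epochs_per_class,
    ch = ch, n_samples = n_samples,
    erd_channels = list(1L, 2L), seed = seed, ...
  ))
}

# brute-force grid minimizer of the spectrum objective over the power-law
# cone; the independent oracle for solve_spectrum_qp (r = 2 and r = 3)
grid_spectrum_oracle <- function(G, h, mu, n_grid = 120) {
  r <- length(h)
  obj <- function(s) drop(t(s) %*% G %*% s - 2 * sum(h * s))
  search <- function(axes) {
    grid <- as.matrix(expand.grid(axes))
    feas <- grid[, 1] >= 0
    for (i in seq_len(r - 1L)) feas <- feas & grid[, i] >= mu * grid[, i + 1L]
    feas <- feas & apply(grid >= 0, 1, all)
    grid <- grid[feas, , drop = FALSE]
    vals <- rowSums((grid %*% G) * grid) - 2 * drop(grid %*% h)
    k <- which.min(vals)
    list(solution = grid[k, ], objective = vals[k],
         resolution = max(vapply(axes, function(a) a[2] - a[1], numeric(1))))
  }
  if (!r %in% 2:3) stop("oracle only supports r = 2 or 3")
  smax <- max(2 * max(pmax(solve(G, h), 0)), 1e-3)
  coarse <- NULL
  for (i in 1:5) {
    coarse <- search(rep(list(seq(0, smax, length.out = n_grid)), r))
    # widen the box until the minimizer is interior
    if (max(coarse$solution) < smax - coarse$resolution) break
    smax <- 2 * smax
  }
  # refine around the coarse minimizer; the box widens with mu^(r - i) per
  # coordinate so movement along the cone edge (sigma_i ~ mu^(r-i)) stays
  # inside it
  half <- 2 * coarse$resolution * mu^(r - seq_len(r))
  lo <- pmax(coarse$solution - half, 0)
  hi <- coarse$solution + half
  fine <- search(lapply(seq_len(r), function(i) {
    seq(lo[i], hi[i], length.out = n_grid)
  }))
  fine
}

qp_inputs <- function(es, K_s) {
  A <- es$phi_s_tilde
  G <- crossprod(A)^2
  G <- (G + t(G)) / 2 + diag(1e-10, ncol(A))
  list(G = G, h = colSums(A * (K_s %*% A)))
}
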