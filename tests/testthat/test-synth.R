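test_that("population generation is deterministic and leaves the RNG alone", {
  before <- farka:::.with_seed(99, runif(1))
  set.seed(99)
  p1 <- make_population(population_spec(seed = 5))
  p2 <- make_population(population_spec(seed = 5))
  expect_identical(p1, p2)
  expect_equal(runif(1), before) # global RNG stream untouched

  expect_identical(length(p1), 5L)
  e <- p1[[1]]
  expect_s3_class(e, "epoch_set")
  expect_identical(length(e$epochs), 80L)
  expect_identical(e$labels, rep(1:2, 40))
  expect_identical(dim(e$epochs[[1]]), c(8L, 512L))
})

test_that("zero mixing strength yields the shared class covariances", {
  # mixing 0 forces A_c = I, so pooled per-class sample covariances converge
  # to the diagonal class models
  pop <- make_population(population_spec(
    n_subjects = 1, n_epochs_per_class = 200, ch = 4, n_samples = 256,
    erd_channels = list(1L, 2L), erd_depth = 0.5, subject_mixing_strength = 0,
    seed = 11
  ))
  e <- pop[[1]]
  for (k in 1:2) {
    Xs <- e$epochs[e$labels == k]
    M <- Reduce(`+`, lapply(Xs, tcrossprod)) / (length(Xs) * 256)
    expected <- diag(4)
    expected[k, k] <- 0.5
    expect_lt(max(abs(M - expected)), 0.05)
  }
})

test_that("erd_depth = 1 removes the class contrast entirely", {
  pop <- make_population(population_spec(
    n_subjects = 1, n_epochs_per_class = 30, ch = 4, n_samples = 64,
    erd_channels = list(1L, 2L), erd_depth = 1, seed = 12
  ))
  # both classes are now draws from the same distribution; the two pooled
  # class covariances agree up to sampling noise
  e <- pop[[1]]
  cov_k <- function(k) {
    Xs <- e$epochs[e$labels == k]
    Reduce(`+`, lapply(Xs, tcrossprod)) / (length(Xs) * 64)
  }
  expect_lt(max(abs(cov_k(1) - cov_k(2))), 0.2)
})

test_that("attenuate scales epochs exactly", {
  pop <- small_population(seed = 13, n_subjects = 1)
  e2 <- attenuate(pop[[1]], 0.25)
  expect_equal(e2$epochs[[3]], 0.25 * pop[[1]]$epochs[[3]])
  expect_identical(e2$labels, pop[[1]]$labels)
})

test_that("add_awgn hits the requested SNR and is a no-op at extreme SNR", {
  pop <- make_population(population_spec(
    n_subjects = 1, n_epochs_per_class = 10, ch = 4, n_samples = 5000,
    erd_channels = list(1L, 2L), seed = 14
  ))
  e <- pop[[1]]
  noisy <- add_awgn(e, snr_db = 10, seed = 3)
  p_sig <- mean(unlist(lapply(e$epochs, function(X) mean(X^2))))
  p_noise <- mean(unlist(Map(function(a, b) mean((a - b)^2),
                             noisy$epochs, e$epochs)))
  realized <- 10 * log10(p_sig / p_noise)
  expect_lt(abs(realized - 10), 0.1)

  quiet <- add_awgn(e, snr_db = 200, seed = 3)
  expect_lt(max(abs(quiet$epochs[[1]] - e$epochs[[1]])), 1e-8)
  # deterministic under a seed
  expect_identical(add_awgn(e, 10, seed = 3)$epochs, noisy$epochs)
})

test_that("bandpass passes in-band tones and rejects out-of-band ones", {
  fs <- 250
  t <- seq_len(2048) / fs
  tone <- function(f) sin(2 * pi * f * t)
  X <- rbind(tone(15), tone(50), rep(1, length(t))) # in-band, stop-band, DC
  e <- epoch_set("s", list(X), 1L, sample_rate = fs)
  filt <- bandpass_epochs(e, lo_hz = 8, hi_hz = 30)$epochs[[1]]
  mid <- 500:1500 # ignore filter edge transients
  gain <- function(i) sqrt(mean(filt[i, mid]^2) / mean(X[i, mid]^2))
  expect_gt(gain(1), 0.9)  # 15 Hz retained
  expect_lt(gain(2), 0.05) # 50 Hz suppressed
  expect_lt(sqrt(mean(filt[3, mid]^2)), 0.05) # DC removed
})

test_that("deeper desynchronization is easier to classify", {
  acc_at_depth <- function(depth) {
    pop <- make_population(population_spec(
      n_subjects = 2, n_epochs_per_class = 20, ch = 4, n_samples = 128,
      erd_channels = list(1L, 2L), erd_depth = depth, seed = 17
    ))
    feats <- lapply(pop, function(e) {
      tangent_map(align_subject(estimate_covariances(e)))
    })
    m <- farka_fit(feats[[1]], feats[[2]], farka_params())
    accuracy_score(predict(m), feats[[2]]$labels)
  }
  expect_gte(acc_at_depth(0.5), acc_at_depth(0.95))
  expect_gt(acc_at_depth(0.5), 0.8)
})
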