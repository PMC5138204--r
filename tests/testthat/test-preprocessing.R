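make_rec <- function(x, fs, events = NULL) {
  continuous_recording(matrix(x, nrow = 1), fs, events = events)
}

test_that("band-pass removes DC, passes 10 Hz, attenuates 50 Hz", {
  fs <- 512
  t <- seq(0, 10, by = 1 / fs)

  dc <- bandpass_filter(make_rec(rep(5, length(t)), fs))
  expect_lt(max(abs(dc$samples)), 0.05) # < 1% of the 5 uV input

  s10 <- bandpass_filter(make_rec(sin(2 * pi * 10 * t), fs))
  expect_equal(max(abs(s10$samples)), 1, tolerance = 0.05)

  s50 <- bandpass_filter(make_rec(sin(2 * pi * 50 * t), fs))
  mid <- seq(length(t) %/% 4, 3 * length(t) %/% 4)
  # at least 6 dB below the in-band gain
  expect_lt(max(abs(s50$samples[1, mid])), 0.5 * max(abs(s10$samples)))
})

test_that("band edges above Nyquist are rejected, events pass through", {
  fs <- 64
  ev <- data.frame(onset = c(2L, 10L), code = c(1L, 2L),
                   is_target = c(TRUE, FALSE))
  rec <- make_rec(rnorm(320), fs, events = ev)
  expect_error(bandpass_filter(rec, high = 40), "Nyquist")
  out <- bandpass_filter(rec, low = 0.5, high = 20)
  expect_identical(out$events, rec$events)
})

test_that("epoch extraction uses [onset, onset + M) and drops truncated", {
  fs <- 512
  samples <- matrix(seq_len(2 * 1500), nrow = 2) # recognisable ramp
  ev <- data.frame(onset = c(100L, 600L, 1490L), code = c(1L, 2L, 1L),
                   is_target = c(TRUE, FALSE, TRUE))
  rec <- continuous_recording(samples, fs, events = ev)
  expect_warning(es <- extract_epochs(rec), "dropped 1 truncated")
  expect_equal(dim(es$epochs), c(2, 2, 512))
  # 0-based onset 100 -> R columns 101..612
  expect_equal(es$epochs[1, , 1], samples[, 101])
  expect_equal(es$epochs[1, , 512], samples[, 612])
  expect_equal(es$labels, c(1L, 2L))
})

test_that("epoch count is conserved when nothing is truncated", {
  fs <- 32
  ev <- data.frame(onset = seq(0L, 90L, by = 10L), code = rep(1:2, 5),
                   is_target = rep(c(TRUE, FALSE), 5))
  rec <- continuous_recording(matrix(rnorm(3 * 160), nrow = 3), fs,
                              events = ev)
  es <- extract_epochs(rec)
  expect_equal(dim(es$epochs)[1], nrow(ev))
})

test_that("event validation reports non-monotone onsets and bad codes", {
  expect_error(
    continuous_recording(matrix(0, 1, 100), 10,
                         events = data.frame(onset = c(5L, 5L),
                                             code = c(1L, 1L),
                                             is_target = c(TRUE, FALSE))),
    "strictly increasing"
  )
  expect_error(
    continuous_recording(matrix(0, 1, 100), 10,
                         events = data.frame(onset = 5L, code = 0L,
                                             is_target = TRUE)),
    "positive integers"
  )
})

test_that("class prototypes are per-class arithmetic means", {
  X <- matrix(1:8, 2, 4)
  es <- tiny_epoch_set(K = 2, reps = 2, N = 2, M = 4,
                       fill = function(i) if (i %% 2 == 1) X else -X)
  # codes alternate 1,2,1,2; attended = 1 -> targets are epochs 1 and 3 (both X)
  p <- class_prototypes(es)
  expect_equal(p$target, X)
  expect_equal(p$nontarget, -X) # mean of {-X, -X}
  expect_equal(p$n_target, 2L)

  balanced <- tiny_epoch_set(K = 2, reps = 2, N = 2, M = 4,
                             fill = function(i) if (i <= 2) X else -X)
  expect_equal(class_prototypes(balanced)$nontarget, matrix(0, 2, 4))
})

test_that("a class with zero trials is an error", {
  es <- tiny_epoch_set(K = 2, reps = 1)
  only_nt <- es[es$labels == 2]
  expect_error(class_prototypes(only_nt), "no target epochs")
})

test_that("super-trials stack 3N rows and centre each row", {
  for (N in c(8, 16)) {
    M <- 20
    es <- tiny_epoch_set(K = 2, reps = 2, N = N, M = M,
                         fill = function(i) matrix(rnorm(N * M), N, M))
    p <- class_prototypes(es)
    st <- build_super_trial(get_epoch_mat(es, 1), p)
    expect_equal(nrow(st$matrix), 3 * N)
    expect_equal(rowMeans(st$matrix), rep(0, 3 * N), tolerance = 1e-12)
  }
  # explicit centring: row [2, 4] -> [-1, 1]
  es2 <- tiny_epoch_set(K = 2, reps = 1, N = 1, M = 2,
                        fill = function(i) matrix(c(2, 4), 1, 2))
  p2 <- class_prototypes(es2)
  st2 <- build_super_trial(matrix(c(2, 4), 1, 2), p2)
  expect_equal(st2$matrix[1, ], c(-1, 1))
})

test_that("shape mismatches between epoch and prototypes error", {
  es <- tiny_epoch_set(K = 2, reps = 1, N = 2, M = 4)
  p <- class_prototypes(es)
  expect_error(build_super_trial(matrix(0, 2, 5), p), "dimensions")
})

test_that("super-trial covariance matches the two-loop oracle", {
  set.seed(7)
  N <- 3
  M <- 16
  es <- tiny_epoch_set(K = 2, reps = 2, N = N, M = M,
                       fill = function(i) matrix(rnorm(N * M), N, M))
  p <- class_prototypes(es)
  st <- build_super_trial(get_epoch_mat(es, 1), p)
  C <- spd_values(supertrial_covariance(st))

  X <- st$matrix
  oracle <- matrix(0, 3 * N, 3 * N)
  for (a in seq_len(3 * N)) {
    for (b in seq_len(3 * N)) {
      oracle[a, b] <- sum(X[a, ] * X[b, ]) / (M - 1)
    }
  }
  expect_equal(C, oracle, tolerance = 1e-12)
  # leading N x N block is the plain covariance of the centred epoch
  xe <- get_epoch_mat(es, 1) - rowMeans(get_epoch_mat(es, 1))
  expect_equal(C[1:N, 1:N], xe %*% t(xe) / (M - 1), tolerance = 1e-12)
})

test_that("degenerate super-trials are loaded onto the SPD manifold", {
  st <- structure(list(matrix = matrix(0, 6, 4), n_channels = 2,
                       n_samples = 4), class = "super_trial")
  C <- supertrial_covariance(st)
  expect_true(C$loaded)
  expect_gt(min(spd_spectrum(C)), 0)
  st1 <- structure(list(matrix = matrix(c(1, -1), 1, 2), n_channels = 1,
                        n_samples = 2), class = "super_trial")
  expect_equal(spd_values(supertrial_covariance(st1))[1, 1], 2)
  st0 <- st1
  st0$n_samples <- 1
  st0$matrix <- st0$matrix[, 1, drop = FALSE]
  expect_error(supertrial_covariance(st0), "at least 2 samples")
})
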