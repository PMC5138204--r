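# Shared fixtures: random SPD matrices and a train/test split pipeline on
# simulated oddball sessions.

rand_spd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d)
  scale * (crossprod(A) / d + 0.5 * diag(d))
}

rand_invertible <- function(d) {
  repeat {
    W <- matrix(rnorm(d * d), d)
    if (abs(det(W)) > 1e-3) return(W)
  }
}

# independent distance oracle: eigenvalues of A^{-1} B via the plain
# (non-symmetric) eigendecomposition, not the whitened route the package
# uses internally
riem_dist_oracle <- function(A, B) {
  w <- Re(eigen(solve(A) %*% B, only.values = TRUE)$values)
  sqrt(sum(log(w)^2))
}

# a tiny deterministic epoch set: `reps` epochs per code per block
tiny_epoch_set <- function(K = 2, reps = 2, n_blocks = 1, N = 2, M = 8,
                           fs = 8, attended = rep(1, n_blocks),
                           fill = function(i) matrix(i, N, M)) {
  n <- K * reps * n_blocks
  arr <- array(0, dim = c(n, N, M))
  codes <- rep(rep(seq_len(K), reps), n_blocks)
  blocks <- rep(seq_len(n_blocks), each = K * reps)
  for (i in seq_len(n)) arr[i, , ] <- fill(i)
  epoch_set(arr, fs, labels = ifelse(codes == attended[blocks], 1L, 2L),
            stimulus_codes = codes, block_ids = blocks)
}

get_epoch_mat <- function(es, i) {
  m <- es$epochs[i, , , drop = FALSE]
  dim(m) <- dim(es$epochs)[2:3]
  m
}

# Simulate a session, train MDM on the first `train_blocks` blocks and
# score command selections on the remaining blocks at each averaging depth
# in `ks`.  Returns a data frame with one row per depth.
mdm_split_accuracy <- function(seed, amplitude = 5, noise_sigma = 4,
                               pink = 4, K = 5, n_blocks = 16,
                               train_blocks = 4, ks = 1, fs = 256, N = 8,
                               reps = 5) {
  cfg <- paradigm_config(K = K, fs = fs, n_channels = N,
                         reps_per_command = reps, n_blocks = n_blocks)
  erp <- erp_model(p300_amplitude = amplitude, noise_sigma = noise_sigma,
                   pink_noise_scale = pink)
  es <- simulate_epochs(cfg, erp, seed = seed)
  train <- es[es$block_ids <= train_blocks]
  test <- es[es$block_ids > train_blocks]
  proto <- class_prototypes(train)
  att <- attended_commands(es)
  rows <- lapply(ks, function(k) {
    train_k <- average_erps(train, k)
    test_k <- average_erps(test, k)
    model <- mdm_fit(supertrial_covariances(train_k, proto), train_k$labels)
    sc <- riemerp:::score_selections(test_k, att, model, proto)
    data.frame(k = k, accuracy = sc$accuracy, n = sc$n)
  })
  do.call(rbind, rows)
}
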