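# two well-separated covariance clusters: scaled identity vs scaled ramp
separable_covs <- function(n_per_class, d = 4) {
  set.seed(17)
  covs <- c(
    lapply(seq_len(n_per_class), function(i) rand_spd(d, scale = 0.01)),
    lapply(seq_len(n_per_class), function(i) rand_spd(d, scale = 100))
  )
  list(covs = covs, labels = rep(c(1L, 2L), each = n_per_class))
}

test_that("mdm_fit reduces to the inputs for singleton classes", {
  A <- rand_spd(3)
  B <- rand_spd(3)
  m <- mdm_fit(list(A, B), c(1L, 2L))
  expect_equal(spd_values(m$means[[1]]), riemerp:::sym(A), tolerance = 1e-9)
  expect_equal(spd_values(m$means[[2]]), riemerp:::sym(B), tolerance = 1e-9)
  expect_equal(m$counts, c(1L, 1L))
})

test_that("duplicating the training set leaves the class means unchanged", {
  s <- separable_covs(3)
  m1 <- mdm_fit(s$covs, s$labels)
  m2 <- mdm_fit(c(s$covs, s$covs), c(s$labels, s$labels))
  expect_equal(spd_values(m1$means[[1]]), spd_values(m2$means[[1]]),
               tolerance = 1e-7)
  expect_equal(spd_values(m1$means[[2]]), spd_values(m2$means[[2]]),
               tolerance = 1e-7)
})

test_that("mdm_fit requires both classes", {
  expect_error(mdm_fit(list(rand_spd(3)), 1L), "class 2")
})

test_that("separable clusters are classified perfectly in training", {
  s <- separable_covs(10)
  m <- mdm_fit(s$covs, s$labels)
  expect_equal(mdm_predict(m, s$covs), s$labels)
})

test_that("mdm_predict picks the nearer mean and breaks ties low", {
  s <- separable_covs(5)
  m <- mdm_fit(s$covs, s$labels)
  expect_equal(mdm_predict(m, m$means[[1]]), 1L)
  expect_equal(mdm_predict(m, m$means[[2]]), 2L)
  # geometric mean of the two class means is the geodesic midpoint
  mid <- geometric_mean(list(m$means[[1]], m$means[[2]]))
  d1 <- riemannian_distance(m$means[[1]], mid)
  d2 <- riemannian_distance(m$means[[2]], mid)
  expect_equal(d1, d2, tolerance = 1e-8)
  # identical class means force an exact tie, resolved to label 1
  C <- rand_spd(3)
  tied <- mdm_fit(list(C, C), c(1L, 2L))
  expect_equal(mdm_predict(tied, rand_spd(3)), 1L)
  expect_error(mdm_predict(m, rand_spd(7)), "dimension mismatch")
})

test_that("mdm_predict agrees with brute-force distance enumeration", {
  set.seed(23)
  s <- separable_covs(5)
  m <- mdm_fit(s$covs, s$labels)
  for (i in 1:50) {
    cv <- rand_spd(4, scale = 10^runif(1, -3, 3))
    oracle <- which.min(c(
      riem_dist_oracle(spd_values(m$means[[1]]), cv),
      riem_dist_oracle(spd_values(m$means[[2]]), cv)
    ))
    expect_equal(mdm_predict(m, cv), oracle)
  }
})

test_that("MDM decisions are invariant under a common congruence transform", {
  set.seed(29)
  s <- separable_covs(6)
  m <- mdm_fit(s$covs, s$labels)
  tests <- lapply(1:10, function(i) rand_spd(4, scale = 10^runif(1, -2, 2)))
  base <- mdm_predict(m, tests)
  for (r in 1:5) {
    W <- rand_invertible(4)
    tr <- function(C) t(W) %*% C %*% W
    mt <- mdm_fit(lapply(s$covs, tr), s$labels)
    expect_equal(mdm_predict(mt, lapply(tests, tr)), base)
  }
})

test_that("command selection scores target-likeness per stimulus code", {
  s <- separable_covs(5)
  m <- mdm_fit(s$covs, s$labels)
  # code 3 near the target mean, others near the non-target mean
  covs <- list(rand_spd(4, 100), rand_spd(4, 100), rand_spd(4, 0.01),
               rand_spd(4, 100), rand_spd(4, 100))
  dec <- command_select(m, covs)
  expect_equal(dec$decided_command, 3L)
  expect_equal(which.max(dec$scores), 3L)

  same <- rand_spd(4)
  tie <- command_select(m, list(same, same, same))
  expect_equal(tie$decided_command, 1L)

  names(covs) <- c(1, 2, 3, 4, 6) # code 5 missing
  expect_error(command_select(m, covs), "stimulus code")
})

test_that("swlda selects a perfectly separating feature first", {
  set.seed(5)
  n <- 60
  labels <- rep(c(1L, 2L), each = n / 2)
  x <- matrix(rnorm(n * 20), n)
  x[, 7] <- ifelse(labels == 1L, 10, -10) + rnorm(n, 0, 0.1)
  model <- swlda_fit(x, labels)
  expect_true(7 %in% model$selected_features)
  expect_equal(model$selected_features[1], 7L)
  expect_equal(swlda_predict(model, x), labels)
})

test_that("null features enter at roughly the p_enter rate", {
  set.seed(13)
  n <- 40
  F <- 50
  rates <- replicate(200, {
    x <- matrix(rnorm(n * F), n)
    y <- sample(rep(c(1, -1), each = n / 2))
    p <- riemerp:::swlda_entry_pvalues(x, y)
    mean(p < 0.10)
  })
  expect_gt(mean(rates), 0.05) # within +/-50% of p_enter = 0.10
  expect_lt(mean(rates), 0.15)
})

test_that("empty selection yields an intercept-only majority model", {
  set.seed(19)
  n <- 30
  x <- matrix(rnorm(n * 5), n)
  labels <- rep(c(1L, 2L), c(5, 25))
  model <- swlda_fit(x, labels, p_enter = 1e-12)
  expect_length(model$selected_features, 0)
  expect_equal(unique(swlda_predict(model, x)), 2L) # majority class
})

test_that("a score of exactly zero maps to the non-target label", {
  model <- structure(
    list(selected_features = 1L, weights = 1, intercept = 0,
         p_enter = 0.1, p_remove = 0.15, max_features = 60L,
         n_features = 2L),
    class = "swlda_model"
  )
  expect_equal(swlda_predict(model, matrix(c(0, 5), 1)), 2L)
  expect_equal(swlda_predict(model, matrix(c(3, 0), 1)), 1L)
  expect_error(swlda_scores(model, matrix(0, 1, 3)), "feature length")
})

test_that("swlda scores equal the direct matrix evaluation", {
  set.seed(37)
  n <- 50
  x <- matrix(rnorm(n * 30), n)
  labels <- ifelse(x[, 3] - x[, 12] + rnorm(n, 0, 0.5) > 0, 1L, 2L)
  model <- swlda_fit(x, labels)
  direct <- as.numeric(
    x[, model$selected_features, drop = FALSE] %*% model$weights +
      model$intercept
  )
  expect_equal(swlda_scores(model, x), direct, tolerance = 1e-12)
  # re-scoring training data is deterministic
  expect_identical(swlda_predict(model, x), swlda_predict(model, x))
})

test_that("constant feature columns are skipped, not fatal", {
  set.seed(43)
  n <- 40
  x <- matrix(rnorm(n * 10), n)
  x[, c(2, 9)] <- 1
  labels <- ifelse(x[, 5] > 0, 1L, 2L)
  model <- swlda_fit(x, labels)
  expect_false(any(c(2, 9) %in% model$selected_features))
  expect_true(5 %in% model$selected_features)
})

test_that("swlda command selection picks the highest-scoring code", {
  set.seed(47)
  n <- 60
  labels <- rep(c(1L, 2L), each = n / 2)
  x <- matrix(rnorm(n * 8), n)
  x[, 2] <- ifelse(labels == 1L, 5, -5) + rnorm(n)
  model <- swlda_fit(x, labels)
  feats <- matrix(0, 4, 8)
  feats[3, 2] <- 5 # code 3 looks like a target
  feats[-3, 2] <- -5
  dec <- command_select(model, feats)
  expect_equal(dec$decided_command, 3L)
})
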