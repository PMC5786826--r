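test_that("pair_cross_covariance matches direct summation", {
  xk <- rbind(c(1, 2, 3), c(0, 1, 0))
  xl <- rbind(c(2, 0, 1), c(1, 1, 2))
  # explicit sum over t of outer products of demeaned columns
  expected <- matrix(0, 2, 2)
  for (t in 1:3)
    expected <- expected +
      (xk[, t] - rowMeans(xk)) %*% t(xl[, t] - rowMeans(xl))
  expect_equal(pair_cross_covariance(xk, xl), expected)
  # self pair is symmetric PSD
  Rkk <- pair_cross_covariance(xk, xk)
  expect_equal(Rkk, t(Rkk))
  expect_true(all(eigen(Rkk, symmetric = TRUE)$values > -1e-12))
  # zero-mean orthogonal signals have zero cross-covariance
  a <- rbind(sin(2 * pi * (1:100) / 10))
  b <- rbind(cos(2 * pi * (1:100) / 10))
  expect_lt(max(abs(pair_cross_covariance(a, b))), 1e-10)
  expect_error(pair_cross_covariance(xk, xl[, 1:2]), "differ")
})

test_that("assemble_covariances matches the loop definitions", {
  coh <- noise_cohort(n = 4, d = 5, nt = 60, seed = 41)
  covs <- assemble_covariances(coh)
  # brute force over ordered pairs
  n <- 4
  Rw <- 0; Rb <- 0
  for (k in 1:n) {
    Rw <- Rw + pair_cross_covariance(coh$data[[k]], coh$data[[k]])
    for (l in 1:n) if (l != k)
      Rb <- Rb + pair_cross_covariance(coh$data[[k]], coh$data[[l]])
  }
  expect_lt(max(abs(covs$Rw - Rw / n)), 1e-10)
  expect_lt(max(abs(covs$Rb - Rb / (n * (n - 1)))), 1e-10)
  # pair grid transposition identity
  expect_equal(covs$pair_cov[[2, 3]], t(covs$pair_cov[[3, 2]]))
  # identical subjects: Rb equals Rw
  same <- coh; same$data <- rep(coh$data[1], 4)
  covs2 <- assemble_covariances(same)
  expect_equal(covs2$Rb, covs2$Rw)
})

test_that("identical subjects yield unit eigenvalues and ISC = K", {
  coh <- noise_cohort(n = 5, d = 6, nt = 500, seed = 42)
  coh$data <- rep(coh$data[1], 5)
  covs <- assemble_covariances(coh)
  model <- fit_corrca(covs, k = 3)
  expect_equal(model$eigenvalues, rep(1, 3), tolerance = 1e-8)
  isc <- subject_isc(coh, model, covs)
  expect_equal(unname(as.matrix(isc[, c("C1", "C2", "C3")])),
               matrix(1, 5, 3), tolerance = 1e-10)
  expect_equal(isc$isc, rep(3, 5), tolerance = 1e-10)
})

test_that("independent noise drives the top eigenvalue toward zero", {
  coh <- noise_cohort(n = 10, d = 8, nt = 2000, seed = 43)
  model <- fit_corrca(assemble_covariances(coh))
  expect_lt(model$eigenvalues[1], 0.1)
})

test_that("a planted component's forward model is recovered at SNR 1", {
  coh <- planted_cohort(n = 8, d = 8, nt = 4000, seed = 44)
  model <- fit_corrca(assemble_covariances(coh), k = 3)
  m <- attr(coh, "mixing")
  cosim <- abs(sum(model$forward[, 1] * m)) /
    sqrt(sum(model$forward[, 1]^2) * sum(m^2))
  expect_gte(cosim, 0.95)
})

test_that("subject_isc matches the brute-force printed formula on a toy", {
  set.seed(45)
  coh <- noise_cohort(n = 3, d = 2, nt = 5, seed = 45)
  coh$data <- lapply(coh$data, function(x) matrix(sample(-5:5, 10, TRUE), 2))
  covs <- assemble_covariances(coh)
  model <- fit_corrca(covs, k = 2)
  isc <- subject_isc(coh, model, covs)
  C_oracle <- brute_force_isc(coh$data, model$projections)
  expect_lt(max(abs(as.matrix(isc[, c("C1", "C2")]) - C_oracle)), 1e-12)
  expect_equal(isc$isc, rowSums(C_oracle), tolerance = 1e-12)
})

test_that("component correlations always lie in [-1, 1]", {
  for (seed in 46:50) {
    coh <- planted_cohort(n = 6, d = 5, nt = 300, seed = seed,
                          gains = runif(6, 0, 2))
    covs <- assemble_covariances(coh)
    model <- fit_corrca(covs, k = 3)
    C <- as.matrix(subject_isc(coh, model, covs)[, c("C1", "C2", "C3")])
    expect_true(all(C >= -1 - 1e-12 & C <= 1 + 1e-12))
  }
})

test_that("ISC is invariant to a common invertible spatial transform", {
  cfg <- sim_config(n_subjects = 6, n_channels = 8, duration_s = 20,
                    seed = 7, artifact_rate = 0, spatial_scale = 0.6)
  sim <- simulate_cohort(cfg, "Wimpy")
  coh <- build_cohort(lapply(sim$recordings, preprocess_recording,
                             notch = NULL), "Wimpy")
  covs <- assemble_covariances(coh)
  isc1 <- subject_isc(coh, fit_corrca(covs), covs)
  set.seed(8)
  A <- diag(8) + 0.3 * matrix(rnorm(64), 8)
  coh2 <- coh
  coh2$data <- lapply(coh$data, function(x) A %*% x)
  covs2 <- assemble_covariances(coh2)
  isc2 <- subject_isc(coh2, fit_corrca(covs2), covs2)
  expect_lt(max(abs(as.matrix(isc1[, c("C1", "C2", "C3")]) -
                    as.matrix(isc2[, c("C1", "C2", "C3")]))), 1e-8)
})

test_that("covariance normalization does not affect any C_ik", {
  coh <- planted_cohort(n = 5, d = 6, nt = 400, seed = 51)
  covs <- assemble_covariances(coh)
  model <- fit_corrca(covs)
  isc1 <- subject_isc(coh, model, covs)
  # rescale every covariance by 1/(T-1): ratios must not move
  covs2 <- covs
  covs2$Rw <- covs$Rw / (400 - 1)
  covs2$Rb <- covs$Rb / (400 - 1)
  covs2$pair_cov[] <- lapply(covs$pair_cov, function(R) R / (400 - 1))
  isc2 <- subject_isc(coh, model, covs2)
  expect_equal(isc1$isc, isc2$isc, tolerance = 1e-12)
})

test_that("fit_corrca matches random-search maximization at small D", {
  coh <- planted_cohort(n = 6, d = 4, nt = 800, seed = 52)
  covs <- assemble_covariances(coh)
  model <- fit_corrca(covs, k = 1)
  set.seed(53)
  V <- matrix(rnorm(4 * 1e5), 4)
  V <- V / rep(sqrt(colSums(V^2)), each = 4)
  ratios <- colSums(V * (covs$Rb %*% V)) / colSums(V * (covs$Rw %*% V))
  best <- max(ratios)
  expect_gte(model$eigenvalues[1], best - 1e-12)
  expect_lt(model$eigenvalues[1] - best, 0.02 * model$eigenvalues[1])
})

test_that("rank-deficient cohorts drop zeroed channels from the model", {
  coh <- planted_cohort(n = 5, d = 6, nt = 500, seed = 54)
  coh$data <- lapply(coh$data, function(x) { x[4, ] <- 0; x })
  covs <- assemble_covariances(coh)
  model <- fit_corrca(covs, k = 3)
  expect_equal(model$rank_used, 5L)
  expect_lt(max(abs(model$projections[4, ])), 1e-9)
  # asking for more components than rank warns and truncates
  tiny <- planted_cohort(n = 4, d = 3, nt = 200, seed = 55)
  tiny$data <- lapply(tiny$data, function(x) { x[2:3, ] <- 0; x })
  expect_warning(m2 <- fit_corrca(assemble_covariances(tiny), k = 3),
                 "effective rank")
  expect_equal(ncol(m2$projections), 1L)
})

test_that("held-out scoring reproduces the in-cohort rows and nulls", {
  coh <- planted_cohort(n = 6, d = 5, nt = 600, seed = 56)
  covs <- assemble_covariances(coh)
  model <- fit_corrca(covs)
  isc <- subject_isc(coh, model, covs)
  k <- 3L
  others <- coh
  others$data <- coh$data[-k]
  others$subjects <- coh$subjects[-k]
  held <- isc_against_group(coh$data[[k]], others, model)
  expect_equal(unname(held$components),
               unname(unlist(isc[k, c("C1", "C2", "C3")])),
               tolerance = 1e-12)
  # subject identical to every member scores 1 on every component
  clone <- coh
  clone$data <- rep(coh$data[1], 6)
  covs_c <- assemble_covariances(clone)
  model_c <- fit_corrca(covs_c)
  same <- isc_against_group(clone$data[[1]], clone, model_c)
  expect_equal(unname(same$components), rep(1, 3), tolerance = 1e-10)
})

test_that("mean ISC grows strictly with planted shared-signal gain", {
  gains <- c(0, 0.25, 0.5, 1)
  means <- vapply(gains, function(g) {
    cfg <- sim_config(n_subjects = 8, n_channels = 8, duration_s = 16,
                      gain_baseline = g, age_slope = 0, male_offset = 0,
                      artifact_rate = 0, eog_leak = 0, seed = 57)
    sim <- simulate_cohort(cfg, "Stim")
    coh <- build_cohort(lapply(sim$recordings, function(r) {
      r$data <- r$data[r$channel_roles == "EEG", ]
      r$channel_names <- r$channel_names[r$channel_roles == "EEG"]
      r$channel_roles <- r$channel_roles[r$channel_roles == "EEG"]
      r
    }), "Stim")
    mean_cohort_isc(coh)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("topography similarity is 1 on self, 0 on orthogonal, high on split halves", {
  coh <- planted_cohort(n = 12, d = 6, nt = 2000, seed = 58)
  covs <- assemble_covariances(coh)
  model <- fit_corrca(covs)
  expect_equal(topography_similarity(model, model), rep(1, 3))
  ortho <- model
  ortho$forward <- matrix(0, 6, 3)
  ortho$forward[cbind(4:6, 1:3)] <- 1
  model_eye <- model
  model_eye$forward <- matrix(0, 6, 3)
  model_eye$forward[cbind(1:3, 1:3)] <- 1
  expect_equal(topography_similarity(model_eye, ortho), rep(0, 3))
  # split halves of one planted simulation agree on component 1
  h1 <- coh; h1$data <- coh$data[1:6]; h1$subjects <- coh$subjects[1:6]
  h2 <- coh; h2$data <- coh$data[7:12]; h2$subjects <- coh$subjects[7:12]
  m1 <- fit_corrca(assemble_covariances(h1))
  m2 <- fit_corrca(assemble_covariances(h2))
  expect_gte(topography_similarity(m1, m2)[1], 0.9)
  zero <- model
  zero$forward[, 2] <- 0
  expect_warning(s <- topography_similarity(zero, model), "zero-norm")
  expect_true(is.nan(s[2]))
})
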