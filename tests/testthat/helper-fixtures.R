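# Shared fixture builders: everything is generated in code, seeded.

# cohort of independent white-noise subjects (no shared signal)
noise_cohort <- function(n = 8L, d = 8L, nt = 1000L, seed = 1L,
                         condition = "Rest") {
  set.seed(seed)
  structure(list(
    condition = condition,
    subjects = sprintf("S%02d", seq_len(n)),
    data = lapply(seq_len(n), function(i) matrix(stats::rnorm(d * nt), d)),
    fs = 125,
    channel_names = paste0("E", seq_len(d)),
    ages = stats::runif(n, 6, 44),
    sexes = rep(c("male", "female"), length.out = n)
  ), class = "eeg_cohort")
}

# cohort with one planted shared source: x_k = gain_k * m s(t) + noise
planted_cohort <- function(n = 8L, d = 8L, nt = 4000L, seed = 1L,
                           gains = rep(1, n), mixing = NULL,
                           noise_sd = 1, condition = "Stim") {
  set.seed(seed)
  if (is.null(mixing)) {
    mixing <- stats::rnorm(d)
    mixing <- mixing / sqrt(mean(mixing^2))  # mean per-channel SNR = gain^2
  }
  s <- stats::rnorm(nt)
  coh <- structure(list(
    condition = condition,
    subjects = sprintf("S%02d", seq_len(n)),
    data = lapply(seq_len(n), function(k)
      gains[k] * outer(mixing, s) +
        matrix(stats::rnorm(d * nt, sd = noise_sd), d)),
    fs = 125,
    channel_names = paste0("E", seq_len(d)),
    ages = stats::runif(n, 6, 44),
    sexes = rep(c("male", "female"), length.out = n)
  ), class = "eeg_cohort")
  attr(coh, "mixing") <- mixing
  coh
}

# independent brute-force evaluation of the per-subject component
# correlations: explicit loops over the printed definitions, no shared
# code with the package internals
brute_force_isc <- function(data_list, V) {
  n <- length(data_list)
  K <- ncol(V)
  cov_pair <- function(xk, xl) {
    d <- nrow(xk)
    R <- matrix(0, d, d)
    for (t in seq_len(ncol(xk)))
      R <- R + (xk[, t] - rowMeans(xk)) %*% t(xl[, t] - rowMeans(xl))
    R
  }
  C <- matrix(NA_real_, n, K)
  for (k in seq_len(n)) {
    Rbk <- 0; Rwk <- 0
    for (l in seq_len(n)) {
      if (l == k) next
      Rbk <- Rbk + cov_pair(data_list[[k]], data_list[[l]]) +
        cov_pair(data_list[[l]], data_list[[k]])
      Rwk <- Rwk + cov_pair(data_list[[k]], data_list[[k]]) +
        cov_pair(data_list[[l]], data_list[[l]])
    }
    Rbk <- Rbk / (n - 1); Rwk <- Rwk / (n - 1)
    for (i in seq_len(K))
      C[k, i] <- (t(V[, i]) %*% Rbk %*% V[, i]) /
        (t(V[, i]) %*% Rwk %*% V[, i])
  }
  C
}

mean_cohort_isc <- function(cohort, k = 3L) {
  covs <- assemble_covariances(cohort)
  model <- fit_corrca(covs, k = k)
  mean(subject_isc(cohort, model, covs)$isc)
}
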