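#' Cross-covariance between two subjects' multichannel data
#'
#' Un-normalized sum over time of outer products of temporally demeaned
#' samples:
#' \deqn{R_{kl} = \sum_t (x_k(t) - \bar x_k)(x_l(t) - \bar x_l)^T.}
#' `pair_cross_covariance(x, x)` is the (un-normalized) within-subject
#' covariance; every downstream ISC ratio is invariant to the missing
#' `1/(T-1)` factor.
#'
#' @param xk,xl numeric matrices, channels x samples, equal sample counts.
#' @return D x D numeric matrix.
#' @export
pair_cross_covariance <- function(xk, xl) {
  xk <- as.matrix(xk); xl <- as.matrix(xl)
  if (ncol(xk) != ncol(xl))
    stop("sample counts differ: ", ncol(xk), " vs ", ncol(xl))
  if (ncol(xk) < 2L) stop("need at least 2 samples")
  (xk - rowMeans(xk)) %*% t(xl - rowMeans(xl))
}

#' Pooled within- and between-subject covariances of a cohort
#'
#' Computes every pairwise cross-covariance \eqn{R_{kl}} and the two pooled
#' matrices of correlated component analysis:
#' \deqn{R_W = \frac{1}{N}\sum_k R_{kk}, \qquad
#'       R_B = \frac{1}{N(N-1)}\sum_k \sum_{l \ne k} R_{kl}.}
#'
#' @param cohort an `eeg_cohort` (N >= 2 subjects).
#' @return A list of class `covariance_set`: `pair_cov` (N x N list matrix
#'   of D x D matrices), `Rw`, `Rb`, `n_subjects`, `n_samples`,
#'   `channel_names`.
#' @export
assemble_covariances <- function(cohort) {
  n <- length(cohort$data)
  if (n < 2L) stop("need at least 2 subjects")
  centered <- lapply(cohort$data, function(x) x - rowMeans(x))
  pair_cov <- vector("list", n * n)
  dim(pair_cov) <- c(n, n)
  for (k in seq_len(n))
    for (l in seq_len(n))
      pair_cov[[k, l]] <- centered[[k]] %*% t(centered[[l]])
  d <- nrow(cohort$data[[1L]])
  Rw <- matrix(0, d, d); Rb <- matrix(0, d, d)
  for (k in seq_len(n)) {
    Rw <- Rw + pair_cov[[k, k]]
    for (l in seq_len(n)) if (l != k) Rb <- Rb + pair_cov[[k, l]]
  }
  structure(list(pair_cov = pair_cov,
                 Rw = Rw / n,
                 Rb = Rb / (n * (n - 1)),
                 n_subjects = n,
                 n_samples = ncol(cohort$data[[1L]]),
                 channel_names = cohort$channel_names),
            class = "covariance_set")
}

#' Fit correlated component analysis
#'
#' Finds spatial projections `v` maximizing between-subject correlation:
#' the eigenvectors of \eqn{R_W^{-1} R_B}. Solved as a symmetric generalized
#' eigenproblem after whitening within the principal subspace of `Rw` whose
#' eigenvalues exceed `rank_tol` times the largest — zeroed (BAD) channels
#' and any other null directions thus contribute exactly nothing. Forward
#' models (scalp topographies) are \eqn{a_i = R_W v_i / (v_i^T R_W v_i)}.
#'
#' @param covs a `covariance_set` from [assemble_covariances()].
#' @param k number of components to keep (default 3, the number of
#'   components that carry most of the between-subject correlation).
#' @param rank_tol relative eigenvalue floor for the whitening subspace.
#' @param fit_group optional label recording which subjects the model was
#'   fitted on.
#' @return A list of class `corrca_model`: `projections` (D x K, columns
#'   unit-norm with the largest-magnitude entry positive), `eigenvalues`
#'   (descending), `forward` (D x K), `rank_used`, `fit_group`,
#'   `channel_names`.
#' @export
fit_corrca <- function(covs, k = 3L, rank_tol = 1e-9, fit_group = "all") {
  Rw <- (covs$Rw + t(covs$Rw)) / 2
  Rb <- (covs$Rb + t(covs$Rb)) / 2
  ew <- eigen(Rw, symmetric = TRUE)
  keep <- ew$values > rank_tol * max(ew$values)
  rank_used <- sum(keep)
  if (rank_used < 1L) stop("within-subject covariance has no usable rank")
  if (rank_used < k) {
    warning("effective rank ", rank_used, " < k = ", k,
            "; returning ", rank_used, " components")
    k <- rank_used
  }
  # whiten: W = U_r diag(1/sqrt(d_r)); symmetric problem in whitened space
  W <- ew$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ew$values[keep]), rank_used)
  Rb_w <- t(W) %*% Rb %*% W
  Rb_w <- (Rb_w + t(Rb_w)) / 2
  eb <- eigen(Rb_w, symmetric = TRUE)
  ord <- seq_len(k)                      # eigen() already sorts descending
  V <- W %*% eb$vectors[, ord, drop = FALSE]
  # unit norm, sign: largest-|entry| positive
  V <- apply(V, 2L, function(v) {
    v <- v / sqrt(sum(v^2))
    if (v[which.max(abs(v))] < 0) -v else v
  })
  V <- matrix(V, nrow = nrow(Rw))
  fwd <- vapply(seq_len(k), function(i) {
    v <- V[, i]
    as.numeric(Rw %*% v) / as.numeric(t(v) %*% Rw %*% v)
  }, numeric(nrow(Rw)))
  rownames(V) <- rownames(fwd) <- covs$channel_names
  structure(list(projections = V,
                 eigenvalues = eb$values[ord],
                 forward = matrix(fwd, nrow = nrow(Rw)),
                 rank_used = rank_used,
                 fit_group = fit_group,
                 channel_names = covs$channel_names),
            class = "corrca_model")
}

#' @export
print.corrca_model <- function(x, ...) {
  cat(sprintf("<corrca_model> %d components over %d channels (rank %d, fit on %s)\n",
              ncol(x$projections), nrow(x$projections), x$rank_used,
              x$fit_group))
  cat("  eigenvalues:", signif(x$eigenvalues, 4), "\n")
  invisible(x)
}

#' Per-subject intersubject correlation
#'
#' For each subject `k`, each component `i` of a fitted model is scored by
#' \deqn{C_{ik} = \frac{v_i^T R_{b,k} v_i}{v_i^T R_{w,k} v_i}, \quad
#'   R_{b,k} = \frac{1}{N-1}\sum_{l \ne k}(R_{kl} + R_{lk}), \quad
#'   R_{w,k} = \frac{1}{N-1}\sum_{l \ne k}(R_{kk} + R_{ll}),}
#' and the subject's ISC is \eqn{\sum_{i=1}^{K} C_{ik}}. By Cauchy-Schwarz
#' each \eqn{C_{ik} \in [-1, 1]}.
#'
#' @param cohort an `eeg_cohort`.
#' @param model a `corrca_model` whose projection dimension matches the
#'   cohort's channel count (it may have been fitted on any subject group).
#' @param covs optional precomputed `covariance_set` for `cohort`.
#' @return A data.frame of class `isc_result`: one row per subject with
#'   columns `subject_id`, `condition`, `model_group`, `age`, `sex`,
#'   `C1..CK`, `isc`.
#' @export
subject_isc <- function(cohort, model, covs = NULL) {
  if (is.null(covs)) covs <- assemble_covariances(cohort)
  n <- covs$n_subjects
  V <- model$projections
  if (nrow(V) != nrow(covs$Rw))
    stop("model dimension does not match cohort channel count")
  K <- ncol(V)
  C <- matrix(NA_real_, n, K)
  for (k in seq_len(n)) {
    d <- nrow(covs$Rw)
    Rbk <- matrix(0, d, d); Rwk <- matrix(0, d, d)
    for (l in seq_len(n)) {
      if (l == k) next
      Rbk <- Rbk + covs$pair_cov[[k, l]] + covs$pair_cov[[l, k]]
      Rwk <- Rwk + covs$pair_cov[[k, k]] + covs$pair_cov[[l, l]]
    }
    Rbk <- Rbk / (n - 1); Rwk <- Rwk / (n - 1)
    for (i in seq_len(K)) {
      num <- as.numeric(t(V[, i]) %*% Rbk %*% V[, i])
      den <- as.numeric(t(V[, i]) %*% Rwk %*% V[, i])
      if (den == 0) {
        warning("component ", i, " has zero variance for subject ", k,
                "; C set to 0")
        C[k, i] <- 0
      } else C[k, i] <- num / den
    }
  }
  colnames(C) <- paste0("C", seq_len(K))
  out <- data.frame(subject_id = cohort$subjects,
                    condition = cohort$condition,
                    model_group = model$fit_group,
                    age = cohort$ages, sex = cohort$sexes,
                    C, isc = rowSums(C),
                    stringsAsFactors = FALSE)
  class(out) <- c("isc_result", "data.frame")
  out
}

#' ISC of one held-out subject against a reference cohort
#'
#' Scores a single subject's data against a cohort it is not part of, using
#' the same per-subject formula with the "other subjects" set equal to the
#' cohort. For a subject drawn from the cohort itself (and excluded from the
#' slabs), this reproduces the corresponding [subject_isc()] row exactly.
#'
#' @param subject_data D x T matrix for the held-out subject (same channel
#'   order and sample count as the cohort).
#' @param cohort reference `eeg_cohort` (the "all other subjects").
#' @param model a `corrca_model`.
#' @return A list with `components` (length-K named vector of correlations)
#'   and `isc` (their sum).
#' @export
isc_against_group <- function(subject_data, cohort, model) {
  subject_data <- as.matrix(subject_data)
  n <- length(cohort$data)
  d <- nrow(subject_data)
  Rkk <- pair_cross_covariance(subject_data, subject_data)
  Rbk <- matrix(0, d, d); Rwk <- matrix(0, d, d)
  for (l in seq_len(n)) {
    Rkl <- pair_cross_covariance(subject_data, cohort$data[[l]])
    Rbk <- Rbk + Rkl + t(Rkl)
    Rwk <- Rwk + Rkk + pair_cross_covariance(cohort$data[[l]],
                                             cohort$data[[l]])
  }
  Rbk <- Rbk / n; Rwk <- Rwk / n
  V <- model$projections
  comp <- vapply(seq_len(ncol(V)), function(i) {
    num <- as.numeric(t(V[, i]) %*% Rbk %*% V[, i])
    den <- as.numeric(t(V[, i]) %*% Rwk %*% V[, i])
    if (den == 0) {
      warning("component ", i, " has zero variance; C set to 0")
      0
    } else num / den
  }, numeric(1))
  names(comp) <- paste0("C", seq_len(ncol(V)))
  list(components = comp, isc = sum(comp))
}

#' Cosine similarity of forward-model topographies across two models
#'
#' Components are matched by index after the descending eigenvalue sort;
#' the absolute cosine is reported because eigenvector sign is arbitrary.
#'
#' @param model_a,model_b `corrca_model` objects with equal channel counts.
#' @return Numeric vector, one |cosine| per shared component; `NaN` with a
#'   warning for a zero-norm forward vector.
#' @export
topography_similarity <- function(model_a, model_b) {
  if (nrow(model_a$forward) != nrow(model_b$forward))
    stop("models have different channel counts")
  K <- min(ncol(model_a$forward), ncol(model_b$forward))
  vapply(seq_len(K), function(i) {
    a <- model_a$forward[, i]; b <- model_b$forward[, i]
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) {
      warning("zero-norm forward model for component ", i)
      return(NaN)
    }
    abs(sum(a * b) / (na * nb))
  }, numeric(1))
}
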