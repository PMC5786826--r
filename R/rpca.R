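#' Robust PCA by inexact augmented Lagrange multipliers
#'
#' Decomposes `M` into a low-rank part `A` and a sparse part `E` by solving
#' \deqn{\min \|A\|_* + \lambda \|E\|_1 \ \mathrm{s.t.}\ A + E = M}
#' with the inexact ALM iteration: singular-value thresholding of
#' `M - E + Y/mu` updates `A`, entrywise soft thresholding of
#' `M - A + Y/mu` at `lambda/mu` updates `E`, followed by the multiplier
#' update `Y <- Y + mu (M - A - E)` and geometric growth of `mu`.
#'
#' Defaults follow standard practice for this algorithm:
#' `lambda = 1/sqrt(max(dim(M)))`, `mu = 1.25 / ||M||_2` growing by 1.5 per
#' iteration.
#'
#' @param M numeric matrix with finite entries.
#' @param lambda sparsity weight; `NULL` for the default above.
#' @param tol stop when `||M - A - E||_F / ||M||_F <= tol`.
#' @param max_iter iteration cap; non-convergence yields a warning and
#'   `converged = FALSE`.
#' @return A list of class `rpca_result`: `low_rank` (A), `sparse` (E),
#'   `iterations`, `converged`, and `objective` — the trace of
#'   `||A||_* + lambda ||E||_1` per iteration.
#' @export
rpca_ialm <- function(M, lambda = NULL, tol = 1e-7, max_iter = 500L) {
  M <- as.matrix(M)
  if (any(!is.finite(M))) stop("M contains non-finite entries")
  m <- nrow(M); n <- ncol(M)
  if (is.null(lambda)) lambda <- 1 / sqrt(max(m, n))
  if (lambda <= 0) stop("lambda must be positive")
  normF_M <- sqrt(sum(M^2))
  if (normF_M == 0) {
    return(structure(list(low_rank = M, sparse = M, iterations = 1L,
                          converged = TRUE, objective = 0),
                     class = "rpca_result"))
  }
  norm_two <- svd(M, nu = 0L, nv = 0L)$d[1L]
  norm_inf <- max(abs(M)) / lambda
  Y <- M / max(norm_two, norm_inf)
  mu <- 1.25 / norm_two
  mu_bar <- mu * 1e7
  rho <- 1.5
  A <- matrix(0, m, n)
  E <- matrix(0, m, n)
  objective <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step: soft threshold
    G <- M - A + Y / mu
    E <- sign(G) * pmax(abs(G) - lambda / mu, 0)
    # A-step: singular value threshold
    s <- svd(M - E + Y / mu)
    dthr <- pmax(s$d - 1 / mu, 0)
    r <- sum(dthr > 0)
    A <- if (r > 0)
      s$u[, seq_len(r), drop = FALSE] %*%
        (dthr[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
    else matrix(0, m, n)
    Z <- M - A - E
    Y <- Y + mu * Z
    mu <- min(mu * rho, mu_bar)
    objective <- c(objective, sum(dthr) + lambda * sum(abs(E)))
    if (sqrt(sum(Z^2)) / normF_M <= tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("rpca_ialm did not converge in ", max_iter, " iterations")
  structure(list(low_rank = A, sparse = E, iterations = iter,
                 converged = converged, objective = objective),
            class = "rpca_result")
}

#' @export
print.rpca_result <- function(x, ...) {
  cat(sprintf("<rpca_result> %d x %d, %d iterations, converged: %s\n",
              nrow(x$low_rank), ncol(x$low_rank), x$iterations, x$converged))
  invisible(x)
}

#' Remove sparse gross outliers from a recording
#'
#' Replaces the data by the low-rank component of [rpca_ialm()] applied to
#' the channels x samples matrix, stripping brief large-amplitude artifacts
#' (electrode pops, movement spikes) while leaving the smooth low-rank EEG
#' structure intact. Applied per recording, channels as rows.
#'
#' @param rec a preprocessed `eeg_recording`.
#' @param lambda,tol,max_iter passed to [rpca_ialm()].
#' @return The cleaned `eeg_recording`.
#' @export
clean_recording <- function(rec, lambda = NULL, tol = 1e-7,
                            max_iter = 500L) {
  res <- rpca_ialm(rec$data, lambda = lambda, tol = tol,
                   max_iter = max_iter)
  rec$data <- res$low_rank
  rownames(rec$data) <- rec$channel_names
  rec
}
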