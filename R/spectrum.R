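#' Eigenvalue spectrum of a subject's channel covariance
#'
#' Eigendecomposition of the temporal covariance (normalized by `T - 1`) of
#' the mean-removed channels. The eigenvalue sum equals the total
#' per-sample variance ("overall power"); the shape of the descending
#' spectrum carries the effective dimensionality of the response.
#'
#' @param rec_data D x T numeric matrix (or an `eeg_recording`).
#' @return A list of class `spectrum_fit`: `eigenvalues` (descending),
#'   `total_power`, `slope` (NA until [fit_loglog_slope()]), `intercept`,
#'   `n_used`.
#' @export
eigenspectrum <- function(rec_data) {
  if (inherits(rec_data, "eeg_recording")) rec_data <- rec_data$data
  x <- as.matrix(rec_data)
  if (any(!is.finite(x))) stop("data contains non-finite values")
  xc <- x - rowMeans(x)
  cv <- xc %*% t(xc) / (ncol(x) - 1)
  ev <- eigen((cv + t(cv)) / 2, symmetric = TRUE, only.values = TRUE)$values
  structure(list(eigenvalues = ev, total_power = sum(ev),
                 slope = NA_real_, intercept = NA_real_,
                 n_used = NA_integer_),
            class = "spectrum_fit")
}

#' Log-log slope of an eigenvalue spectrum
#'
#' Ordinary least squares of `log10(lambda_i)` on `log10(i)` over the
#' eigenvalues above `floor_tol` times the largest (zeroed channels produce
#' exact zeros whose log is undefined; they are excluded). A shallower
#' (less negative) slope means appreciable power over more dimensions,
#' i.e. higher effective dimensionality.
#'
#' @param fit a `spectrum_fit` from [eigenspectrum()].
#' @param floor_tol relative floor below which eigenvalues are dropped.
#' @return The `spectrum_fit` with `slope`, `intercept`, `n_used` filled in.
#' @export
fit_loglog_slope <- function(fit, floor_tol = 1e-9) {
  lam <- fit$eigenvalues
  use <- lam > floor_tol * lam[1L]
  if (sum(use) < 3L)
    stop("need at least 3 eigenvalues above the floor, have ", sum(use))
  i <- seq_len(sum(use))
  lx <- log10(i); ly <- log10(lam[use])
  b <- stats::coef(stats::lm.fit(cbind(1, lx), ly))
  fit$intercept <- b[[1L]]
  fit$slope <- b[[2L]]
  fit$n_used <- length(i)
  fit
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("<spectrum_fit> %d eigenvalues, total power %.4g, slope %s\n",
              length(x$eigenvalues), x$total_power,
              if (is.na(x$slope)) "unfitted" else sprintf("%.3f", x$slope)))
  invisible(x)
}
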