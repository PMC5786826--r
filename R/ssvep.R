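#' Construct a set of flicker trials for one subject
#'
#' @param trials numeric array `n_trials x D x T` or list of D x T matrices.
#' @param fs sampling rate in Hz.
#' @param channel_names channel names (length D).
#' @param condition_labels optional per-trial contrast/background tags.
#' @param subject_id subject identifier.
#' @return An object of class `trial_set`.
#' @export
new_trial_set <- function(trials, fs, channel_names,
                          condition_labels = NULL, subject_id = "S1") {
  if (is.list(trials)) {
    d <- dim(trials[[1L]])
    arr <- array(NA_real_, c(length(trials), d[1L], d[2L]))
    for (i in seq_along(trials)) arr[i, , ] <- trials[[i]]
    trials <- arr
  }
  if (length(dim(trials)) != 3L)
    stop("trials must be an n_trials x D x T array")
  if (dim(trials)[1L] < 1L) stop("need at least one trial")
  if (length(channel_names) != dim(trials)[2L])
    stop("channel_names length does not match trial channel count")
  if (is.null(condition_labels))
    condition_labels <- rep("all", dim(trials)[1L])
  structure(list(trials = trials, fs = fs,
                 channel_names = as.character(channel_names),
                 condition_labels = condition_labels,
                 subject_id = subject_id),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf("<trial_set> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1L], d[2L], d[3L], x$fs))
  invisible(x)
}

#' Reject artifact trials by a z-score threshold
#'
#' Per electrode, each trial's power (mean squared amplitude) and peak
#' absolute amplitude are compared with their mean across trials; a trial is
#' removed when either statistic for any electrode exceeds
#' `mean + z * SD`. An electrode whose statistic has zero spread never
#' triggers rejection (its threshold is infinite).
#'
#' @param ts a `trial_set`.
#' @param z rejection threshold in SDs (default 3); `Inf` keeps everything.
#' @return The `trial_set` with offending trials removed; attribute
#'   `n_rejected` records how many were dropped.
#' @export
reject_trials <- function(ts, z = 3) {
  if (z <= 0) stop("z must be positive")
  ntr <- dim(ts$trials)[1L]
  pow <- apply(ts$trials, c(1L, 2L), function(v) mean(v^2))   # trials x D
  pk  <- apply(ts$trials, c(1L, 2L), function(v) max(abs(v)))
  flag <- function(stat) {
    mu <- colMeans(stat)
    sdv <- apply(stat, 2L, stats::sd)
    thr <- ifelse(sdv > 0, mu + z * sdv, Inf)
    apply(stat, 1L, function(row) any(row > thr))
  }
  bad <- flag(pow) | flag(pk)
  if (all(bad)) stop("all trials rejected at z = ", z)
  out <- ts
  out$trials <- ts$trials[!bad, , , drop = FALSE]
  out$condition_labels <- ts$condition_labels[!bad]
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Drop the stimulus-onset transient from every trial
#'
#' Removes the first `round(ms * fs / 1000)` samples of each trial so the
#' onset visual evoked response does not contaminate the steady-state
#' estimate (e.g. 200 ms of a 2.4 s trial at 125 Hz removes 25 of 300
#' samples).
#'
#' @param ts a `trial_set`.
#' @param ms onset duration to remove, in milliseconds.
#' @return The trimmed `trial_set`.
#' @export
trim_onset <- function(ts, ms) {
  nt <- dim(ts$trials)[3L]
  ndrop <- round(ms * ts$fs / 1000)
  if (ndrop >= nt)
    stop("onset (", ms, " ms) is not shorter than the trial")
  if (ndrop > 0)
    ts$trials <- ts$trials[, , (ndrop + 1L):nt, drop = FALSE]
  ts
}

#' Narrow-band SSVEP power at the flicker frequency
#'
#' Each trial and electrode is Fourier transformed (rectangular window, no
#' padding) and power is summed over DFT bins whose center frequencies fall
#' in `[f0 - bw/2, f0 + bw/2]`, then averaged across all retained trials
#' regardless of condition label and finally across the named electrodes.
#'
#' Normalization: bin power is `2 |X_j|^2 / T^2` (single-sided amplitude
#' convention), so a pure sinusoid of amplitude `a` whose frequency sits on
#' a bin center contributes exactly `a^2 / 2`.
#'
#' @param ts a `trial_set`.
#' @param f0 center frequency in Hz (default 25, the flicker rate).
#' @param bw band width in Hz (default 0.5).
#' @param electrodes names of the (occipital) electrodes to average over.
#' @return Single numeric: mean band power for this subject.
#' @export
band_power <- function(ts, f0 = 25, bw = 0.5, electrodes) {
  if (f0 + bw / 2 >= ts$fs / 2)
    stop("band extends beyond the Nyquist frequency")
  idx <- match(electrodes, ts$channel_names)
  if (any(is.na(idx)))
    stop("electrodes not present: ",
         paste(electrodes[is.na(idx)], collapse = ", "))
  nt <- dim(ts$trials)[3L]
  freqs <- (seq_len(nt) - 1L) * ts$fs / nt
  half <- freqs <= ts$fs / 2
  bins <- which(half & freqs >= f0 - bw / 2 & freqs <= f0 + bw / 2)
  if (!length(bins)) stop("no DFT bin falls inside the requested band")
  ntr <- dim(ts$trials)[1L]
  per_te <- matrix(NA_real_, ntr, length(idx))
  for (tr in seq_len(ntr)) {
    for (e in seq_along(idx)) {
      X <- stats::fft(ts$trials[tr, idx[e], ])
      per_te[tr, e] <- sum(2 * Mod(X[bins])^2 / nt^2)
    }
  }
  mean(colMeans(per_te))
}
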